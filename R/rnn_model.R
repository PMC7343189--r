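#' Model configuration for the two-branch splicing network
#'
#' The architecture processes the acceptor-site and donor-site feature windows
#' in two separate recurrent branches, concatenates the two hidden-state
#' sequences along the position axis (acceptor first), feeds them to a merge
#' recurrent layer, and classifies the final hidden state through dropout and
#' a two-unit softmax head trained with binary cross-entropy and Adam.
#'
#' @param cell_type recurrent cell: `"lstm"`, `"gru"` or `"simple"`.
#' @param branch_size hidden units in each splice-site branch (default 200).
#' @param merge_size hidden units in the merge layer (default 400).
#' @param dropout dropout rate on the final merge state during training.
#' @param epochs training epochs (default 20).
#' @param lr,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling the shuffle, the train/validation/test
#'   partition, weight initialisation and dropout masks.
#' @param head `"softmax"` (two-unit, default) or `"sigmoid"`.
#' @param preset optional named preset overriding sizes: `"main"`
#'   (200/400, the full-scale configuration), `"compact"` (16/32 with
#'   minibatches of 64, used for desk-scale synthetic benchmarks),
#'   `"interpret"` (1/2 hidden units, 400 epochs, for gate-weight
#'   inspection).
#' @return list of class `splice_model_config`.
#' @export
model_config <- function(cell_type = c("lstm", "gru", "simple"),
                         branch_size = 200, merge_size = 400,
                         dropout = 0.5, epochs = 20,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         batch_size = 32, seed = 1,
                         head = c("softmax", "sigmoid"),
                         preset = NULL) {
  cell_type <- match.arg(cell_type)
  head <- match.arg(head)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("main", "compact", "interpret"))
    if (preset == "main") { branch_size <- 200; merge_size <- 400 }
    if (preset == "compact") { branch_size <- 16; merge_size <- 32; batch_size <- 64 }
    # the simplified interpretation model: too few units for dropout to do
    # anything but starve the head, so it is disabled
    if (preset == "interpret") {
      branch_size <- 1; merge_size <- 2; epochs <- 400
      dropout <- 0; batch_size <- 16
    }
  }
  stopifnot(branch_size >= 1, merge_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1, batch_size >= 1)
  structure(list(cell_type = cell_type, branch_size = branch_size,
                 merge_size = merge_size, dropout = dropout, epochs = epochs,
                 lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = batch_size, seed = as.integer(seed),
                 head = head),
            class = "splice_model_config")
}

#' Shuffled train/validation/test partition
#'
#' Splits `n` events 80/20 into train+validation and test, then the first part
#' 80/20 again, giving 64/16/20 percent of the data (e.g. exactly 64/16/20
#' events for n = 100).
#'
#' @param n number of events.
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, seed = 1) {
  stopifnot(n >= 5)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_trainval <- floor(0.8 * n)
  n_train <- floor(0.8 * n_trainval)
  list(train = perm[seq_len(n_train)],
       validation = perm[(n_train + 1):n_trainval],
       test = perm[(n_trainval + 1):n])
}

init_model_params <- function(n_channels, config) {
  list(acceptor = init_cell_params(n_channels, config$branch_size, config$cell_type),
       donor = init_cell_params(n_channels, config$branch_size, config$cell_type),
       merge = init_cell_params(config$branch_size, config$merge_size, config$cell_type),
       head = list(Wy = glorot_matrix(config$merge_size, 2), by = numeric(2)))
}

# minibatch cube (B x C x T) from an n x T x C dataset array
batch_cube <- function(arr, idx) {
  aperm(arr[idx, , , drop = FALSE], c(1, 3, 2))
}

call_pass <- function(params, Xa, Xd, cell, mask, y, want_grads) {
  rnn_pass_cpp(Xa, Xd,
               params$acceptor$Wx, params$acceptor$Wh, params$acceptor$b,
               params$donor$Wx, params$donor$Wh, params$donor$b,
               params$merge$Wx, params$merge$Wh, params$merge$b,
               params$head$Wy, params$head$by,
               cell, mask, y, want_grads)
}

# Adam update over the nested parameter list; state holds m, v and step t.
adam_update <- function(params, grads, state, config) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- config$beta1 * m + (1 - config$beta1) * g
      v <- config$beta2 * v + (1 - config$beta2) * g^2
      mhat <- m / (1 - config$beta1^t)
      vhat <- v / (1 - config$beta2^t)
      list(p = p - config$lr * mhat / (sqrt(vhat) + config$epsilon), m = m, v = v)
    }
  }
  res <- Map(walk, params, grads, state$m, state$v)
  # restore attributes lost in arithmetic on the cell lists
  p <- lapply(res, `[[`, "p")
  for (nm in c("acceptor", "donor", "merge")) attributes(p[[nm]]) <- attributes(params[[nm]])
  state$m <- lapply(res, `[[`, "m")
  state$v <- lapply(res, `[[`, "v")
  list(params = p, state = state)
}

zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0

#' Train the two-branch recurrent splicing model
#'
#' Shuffles and partitions the dataset (64/16/20), initialises seeded Glorot
#' weights, and minimises binary cross-entropy with Adam for
#' `config$epochs` epochs. All randomness (partition, initialisation, epoch
#' shuffles, dropout masks) derives from `config$seed`, so two runs with the
#' same seed produce identical histories.
#'
#' @param dataset a `splice_dataset` (see [build_dataset()]).
#' @param config a [model_config()].
#' @return object of class `splice_model`: parameters, config, channel names,
#'   partition indices and a per-epoch `history` data frame with training and
#'   validation loss/accuracy.
#' @export
train_model <- function(dataset, config = model_config()) {
  stopifnot(inherits(dataset, "splice_dataset"))
  y_all <- dataset$labels
  if (length(unique(y_all)) < 2) {
    stop("dataset has a single class; cannot train a classifier")
  }
  n <- length(y_all)
  split <- split_dataset(n, config$seed)
  cell <- cell_code(config$cell_type)
  hist_rows <- vector("list", config$epochs)

  withr::with_seed(config$seed, {
    params <- init_model_params(length(dataset$channel_names), config)
    adam <- list(m = zero_like(params), v = zero_like(params), t = 0)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(split$train)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      tr_loss <- 0; tr_correct <- 0
      for (b in batches) {
        Xa <- batch_cube(dataset$acceptor, b)
        Xd <- batch_cube(dataset$donor, b)
        yb <- as.integer(y_all[b])
        mask <- if (config$dropout > 0) {
          matrix((stats::runif(length(b) * config$merge_size) >= config$dropout) /
                   (1 - config$dropout), length(b), config$merge_size)
        } else {
          matrix(0, 0, 0)
        }
        res <- call_pass(params, Xa, Xd, cell, mask, yb, TRUE)
        upd <- adam_update(params, res$grads, adam, config)
        params <- upd$params; adam <- upd$state
        tr_loss <- tr_loss + res$loss * length(b)
        tr_correct <- tr_correct + sum((res$p >= 0.5) == (yb == 1))
      }
      val <- model_pass(params, dataset, split$validation, cell)
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = tr_loss / length(idx),
        train_acc = tr_correct / length(idx),
        val_loss = val$loss,
        val_acc = mean((val$p >= 0.5) == (y_all[split$validation] == 1)))
    }
  })

  structure(list(params = params, config = config,
                 channel_names = dataset$channel_names,
                 flank = dataset$flank, n = n, split = split,
                 history = do.call(rbind, hist_rows)),
            class = "splice_model")
}

# forward pass over arbitrary indices in chunks; returns p and mean loss
model_pass <- function(params, dataset, idx, cell, chunk = 512L) {
  p <- numeric(length(idx)); loss <- 0
  for (part in split(seq_along(idx), ceiling(seq_along(idx) / chunk))) {
    b <- idx[part]
    res <- call_pass(params, batch_cube(dataset$acceptor, b),
                     batch_cube(dataset$donor, b), cell,
                     matrix(0, 0, 0), as.integer(dataset$labels[b]), FALSE)
    p[part] <- res$p
    loss <- loss + res$loss * length(b)
  }
  list(p = p, loss = loss / length(idx))
}

check_channels <- function(model, dataset) {
  if (!identical(model$channel_names, dataset$channel_names)) {
    missing <- setdiff(model$channel_names, dataset$channel_names)
    extra <- setdiff(dataset$channel_names, model$channel_names)
    stop("channel registry mismatch; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  }
}

#' Predict inclusion probabilities
#'
#' @param object a trained `splice_model`.
#' @param dataset a `splice_dataset` with the same channel registry.
#' @param indices optional integer subset of events; default all.
#' @param ... unused.
#' @return named numeric vector of P(inclusion), one per event.
#' @export
predict.splice_model <- function(object, dataset, indices = NULL, ...) {
  stopifnot(inherits(dataset, "splice_dataset"))
  check_channels(object, dataset)
  if (is.null(indices)) indices <- seq_along(dataset$labels)
  p <- model_pass(object$params, dataset, indices, cell_code(object$config$cell_type))$p
  stats::setNames(p, dataset$event_id[indices])
}

#' Forward pass for a single acceptor/donor window pair
#'
#' @param model a trained `splice_model`.
#' @param acceptor,donor feature matrices (positions x channels) with column
#'   names matching the model's channel registry.
#' @return P(inclusion), a single number.
#' @export
forward_pair <- function(model, acceptor, donor) {
  stopifnot(identical(colnames(acceptor), model$channel_names),
            identical(colnames(donor), model$channel_names))
  Xa <- aperm(array(acceptor, c(1, dim(acceptor))), c(1, 3, 2))
  Xd <- aperm(array(donor, c(1, dim(donor))), c(1, 3, 2))
  res <- call_pass(model$params, Xa, Xd, cell_code(model$config$cell_type),
                   matrix(0, 0, 0), integer(0), FALSE)
  res$p[1]
}

#' Extract per-channel gate weights for model interpretation
#'
#' For each branch and gate, reports the input weight attached to every input
#' channel. Intended for the simplified single-hidden-unit configuration
#' (`preset = "interpret"`); with more hidden units the weights are aggregated
#' per channel by the mean absolute value and a warning is issued.
#'
#' @param model a trained `splice_model`.
#' @return data frame with columns `branch`, `gate`, `channel`, `weight`,
#'   ordered by decreasing |weight| within branch and gate.
#' @export
extract_gate_weights <- function(model) {
  cell <- model$config$cell_type
  labels <- switch(cell,
    lstm = c(f = "forget", i = "input", o = "output", g = "cell"),
    gru = c(z = "update", r = "reset", n = "candidate"),
    simple = c(a = "state"))
  multi <- model$config$branch_size > 1
  if (multi) {
    warning("branch size > 1; aggregating gate weights by mean |weight| per channel")
  }
  rows <- list()
  for (br in c("acceptor", "donor")) {
    gates <- split_gates(model$params[[br]], cell)
    for (g in names(gates)) {
      w <- gates[[g]]$Wx
      val <- if (multi) rowMeans(abs(w)) else w[, 1]
      rows[[length(rows) + 1]] <- data.frame(
        branch = br, gate = unname(labels[g]),
        channel = model$channel_names, weight = unname(val))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$branch, out$gate, -abs(out$weight)), , drop = FALSE]
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("splice_model: %s cell, branches %d -> merge %d, %d channels\n",
              x$config$cell_type, x$config$branch_size, x$config$merge_size,
              length(x$channel_names)))
  cat(sprintf("trained %d epochs on %d events (train %d / val %d / test %d)\n",
              nrow(x$history), x$n, length(x$split$train),
              length(x$split$validation), length(x$split$test)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("final epoch: train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
              last$train_loss, last$train_acc, last$val_loss, last$val_acc))
  invisible(x)
}
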
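#' Threshold metrics and ROC/PR curves for binary classification
#'
#' Precision, recall, accuracy and F1 are computed from calls at the given
#' threshold (`score >= threshold` is a positive call). ROC and PR curves are
#' built over all distinct score thresholds, processed in descending score
#' order with tied scores grouped; ROC AUC uses the trapezoid rule and PR AUC
#' step-wise interpolation. With single-class labels the AUCs are `NA` but
#' the threshold metrics are still returned.
#'
#' @param labels 0/1 (or logical) true labels.
#' @param scores predicted scores in `[0, 1]`.
#' @param threshold call threshold (default 0.5).
#' @return list of class `metrics_report`: `precision`, `recall`, `accuracy`,
#'   `f1`, `roc_auc`, `pr_auc`, confusion counts (`tp`, `fp`, `fn`, `tn`) and
#'   curve point tables `roc` (fpr, tpr) and `pr` (recall, precision).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  calls <- as.integer(scores >= threshold)
  tp <- sum(calls == 1 & labels == 1)
  fp <- sum(calls == 1 & labels == 0)
  fn <- sum(calls == 0 & labels == 1)
  tn <- sum(calls == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  accuracy <- (tp + tn) / length(labels)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P > 0 && N > 0) {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; l <- labels[o]
    last_of_tie <- !duplicated(s, fromLast = TRUE)
    tps <- c(0, cumsum(l)[last_of_tie])
    fps <- c(0, cumsum(1 - l)[last_of_tie])
    tpr <- tps / P
    fpr <- fps / N
    roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    prec_pts <- ifelse(tps + fps > 0, tps / (tps + fps), 1)
    pr_auc <- sum(diff(tpr) * utils::tail(prec_pts, -1))
    roc <- data.frame(fpr = fpr, tpr = tpr)
    pr <- data.frame(recall = tpr, precision = prec_pts)
  } else {
    roc_auc <- NA_real_; pr_auc <- NA_real_
    roc <- NULL; pr <- NULL
  }
  structure(list(precision = precision, recall = recall, accuracy = accuracy,
                 f1 = f1, roc_auc = roc_auc, pr_auc = pr_auc,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 threshold = threshold, roc = roc, pr = pr),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("precision %.4f | recall %.4f | accuracy %.4f | F1 %.4f\n",
                     "ROC AUC %s | PR AUC %s (threshold %.2f; tp %d fp %d fn %d tn %d)\n"),
              x$precision, x$recall, x$accuracy, x$f1,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.4f", x$roc_auc)),
              ifelse(is.na(x$pr_auc), "NA", sprintf("%.4f", x$pr_auc)),
              x$threshold, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Evaluate a trained model on a dataset partition
#'
#' @param model a `splice_model`.
#' @param dataset a `splice_dataset` with matching channels.
#' @param partition `"test"` (default), `"validation"`, `"train"` or `"all"`.
#'   Partitions refer to the model's own recorded split when the dataset has
#'   the same size, otherwise to a fresh split drawn with the model's seed.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, dataset,
                           partition = c("test", "validation", "train", "all")) {
  partition <- match.arg(partition)
  check_channels(model, dataset)
  n <- length(dataset$labels)
  idx <- if (partition == "all") {
    seq_len(n)
  } else {
    split <- if (n == model$n) model$split else split_dataset(n, model$config$seed)
    split[[partition]]
  }
  p <- predict(model, dataset, indices = idx)
  compute_metrics(dataset$labels[idx], p)
}

metric_of <- function(report, which) as.numeric(report[[which]])

#' Leave-one-out channel importance
#'
#' Trains a reference model on all channels, then retrains with one epigenomic
#' channel removed at a time (same seed, hence same partition) and reports the
#' decrease in held-out F1 and ROC AUC. Seed-to-seed variability is estimated
#' from `n_reference` reference retrainings with incremented seeds; ablation
#' deltas are averaged over `n_repeats` seeded retrainings.
#'
#' @param dataset a labelled `splice_dataset`.
#' @param config a [model_config()].
#' @param channels channels to ablate; default all non-DNA channels.
#' @param n_repeats retrainings per ablated channel (default 3).
#' @param n_reference reference retrainings used both for the reference metric
#'   mean and for the variability band (default 3).
#' @return data frame of class `importance_report`: `channel`, `delta_f1`,
#'   `delta_roc_auc`, `rank` (by decreasing delta ROC AUC), with attributes
#'   `reference` (per-seed reference metrics) and `band` (SD and range of the
#'   reference F1 and ROC AUC).
#' @export
leave_one_out_importance <- function(dataset, config,
                                     channels = setdiff(dataset$channel_names, DNA_CHANNELS),
                                     n_repeats = 3, n_reference = 3) {
  stopifnot(length(channels) >= 1)
  ref <- vapply(seq_len(n_reference) - 1L, function(k) {
    cfg <- config; cfg$seed <- config$seed + k
    m <- train_model(dataset, cfg)
    r <- evaluate_model(m, dataset, "test")
    c(f1 = r$f1, roc_auc = r$roc_auc)
  }, numeric(2))
  ref_mean <- rowMeans(ref)
  rows <- lapply(channels, function(ch) {
    ds2 <- subset_channels(dataset, setdiff(dataset$channel_names, c(DNA_CHANNELS, ch)))
    vals <- vapply(seq_len(n_repeats) - 1L, function(k) {
      cfg <- config; cfg$seed <- config$seed + k
      m <- tryCatch(train_model(ds2, cfg), error = function(e) {
        warning("training failed for ablation of ", ch, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(m)) return(c(NA_real_, NA_real_))
      r <- evaluate_model(m, ds2, "test")
      c(r$f1, r$roc_auc)
    }, numeric(2))
    data.frame(channel = ch,
               delta_f1 = ref_mean["f1"] - mean(vals[1, ], na.rm = TRUE),
               delta_roc_auc = ref_mean["roc_auc"] - mean(vals[2, ], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rank <- rank(-out$delta_roc_auc, ties.method = "first")
  out <- out[order(out$rank), , drop = FALSE]
  attr(out, "reference") <- ref
  attr(out, "band") <- list(f1_sd = stats::sd(ref["f1", ]),
                            f1_range = diff(range(ref["f1", ])),
                            roc_auc_sd = stats::sd(ref["roc_auc", ]),
                            roc_auc_range = diff(range(ref["roc_auc", ])))
  class(out) <- c("importance_report", class(out))
  out
}

#' Information gain from adding epigenomic channels to a DNA-only model
#'
#' Trains a DNA-only baseline and, for every candidate channel (or unordered
#' pair of channels in pairwise mode), a DNA+channel model with the same seed
#' and partition; reports the metric gain, repeated over `n_trials` seeds.
#'
#' @param dataset a labelled `splice_dataset`.
#' @param config a [model_config()].
#' @param channels candidate channels; default all non-DNA channels.
#' @param pairs optional list of length-2 character vectors for pairwise mode
#'   (replaces `channels`).
#' @param n_trials seeded repetitions (default 5).
#' @return data frame with `feature`, `mean_gain_f1`, `sd_gain_f1`,
#'   `mean_gain_roc_auc`, `sd_gain_roc_auc`.
#' @export
feature_gain <- function(dataset, config,
                         channels = setdiff(dataset$channel_names, DNA_CHANNELS),
                         pairs = NULL, n_trials = 5) {
  candidates <- if (is.null(pairs)) as.list(channels) else pairs
  base_ds <- subset_channels(dataset, character(0))
  run <- function(ds, seed) {
    cfg <- config; cfg$seed <- seed
    m <- train_model(ds, cfg)
    r <- evaluate_model(m, ds, "test")
    c(f1 = r$f1, roc_auc = r$roc_auc)
  }
  rows <- lapply(candidates, function(ch) {
    gains <- vapply(seq_len(n_trials) - 1L, function(k) {
      seed <- config$seed + k
      run(subset_channels(dataset, ch), seed) - run(base_ds, seed)
    }, numeric(2))
    data.frame(feature = paste(ch, collapse = "+"),
               mean_gain_f1 = mean(gains["f1", ]),
               sd_gain_f1 = stats::sd(gains["f1", ]),
               mean_gain_roc_auc = mean(gains["roc_auc", ]),
               sd_gain_roc_auc = stats::sd(gains["roc_auc", ]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-dataset transfer test
#'
#' Applies a trained model, without retraining, to the held-out partition of
#' another dataset with the same channel registry. F1 is the headline metric
#' here because class balance can differ between datasets; both datasets'
#' class balances are attached to the report.
#'
#' @param model a trained `splice_model`.
#' @param dataset_other a labelled `splice_dataset` from another source
#'   (e.g. another cell type).
#' @return a `metrics_report` with attribute `class_balance` (fraction of
#'   included events in the model's training data and in the foreign data).
#' @export
cross_cell_test <- function(model, dataset_other) {
  check_channels(model, dataset_other)
  rep <- evaluate_model(model, dataset_other, "test")
  attr(rep, "class_balance") <- c(
    foreign = mean(dataset_other$labels == 1, na.rm = TRUE))
  rep
}

#' Time-direction reversal test
#'
#' Evaluates the same forward-trained model on the original inputs and on
#' inputs whose selected channels have been reversed along the position axis
#' (3' to 5'), probing how much the model relies on the temporal direction of
#' the epigenomic context.
#'
#' @param model a trained `splice_model`.
#' @param dataset a labelled `splice_dataset`.
#' @param channels channels to reverse; default all non-DNA channels.
#' @param partition evaluation partition (default `"test"`).
#' @return list with `forward` and `reversed` `metrics_report`s plus
#'   `delta_f1` and `delta_roc_auc` (forward minus reversed).
#' @export
reversal_test <- function(model, dataset,
                          channels = setdiff(dataset$channel_names, DNA_CHANNELS),
                          partition = "test") {
  fwd <- evaluate_model(model, dataset, partition)
  rev <- evaluate_model(model, reverse_dataset(dataset, channels), partition)
  list(forward = fwd, reversed = rev,
       delta_f1 = fwd$f1 - rev$f1,
       delta_roc_auc = fwd$roc_auc - rev$roc_auc)
}
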
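# full forward pass composed from the exported single-step operations;
# used as the composition oracle for the batched compiled pass
r_forward <- function(model, acc, don) {
  cell <- model$config$cell_type
  run_seq <- function(par, X) {
    sp <- as_step_params(par, cell)
    H <- attr(par, "hidden_size")
    hs <- matrix(0, nrow(X), H)
    if (cell == "lstm") {
      st <- list(h = rep(0, H), c = rep(0, H))
      for (t in seq_len(nrow(X))) { st <- lstm_step(X[t, ], st, sp); hs[t, ] <- st$h }
    } else if (cell == "gru") {
      h <- rep(0, H)
      for (t in seq_len(nrow(X))) { h <- gru_step(X[t, ], h, sp); hs[t, ] <- h }
    } else {
      h <- rep(0, H)
      for (t in seq_len(nrow(X))) { h <- simple_rnn_step(X[t, ], h, sp); hs[t, ] <- h }
    }
    hs
  }
  ha <- run_seq(model$params$acceptor, acc)
  hd <- run_seq(model$params$donor, don)
  hm <- run_seq(model$params$merge, rbind(ha, hd))
  output_head(hm[nrow(hm), ], model$params$head$Wy, model$params$head$by)[2]
}

fake_model <- function(cell, C = 5, Hb = 3, Hm = 4, seed = 33) {
  cfg <- model_config(cell, branch_size = Hb, merge_size = Hm, dropout = 0, seed = seed)
  params <- withr::with_seed(seed, splicernn:::init_model_params(C, cfg))
  structure(list(params = params, config = cfg,
                 channel_names = paste0("ch", seq_len(C)), flank = 4),
            class = "splice_model")
}

test_that("the dataset partition is exactly 64/16/20 for n = 100 and is a disjoint cover", {
  sp <- split_dataset(100, seed = 4)
  expect_equal(length(sp$train), 64)
  expect_equal(length(sp$validation), 16)
  expect_equal(length(sp$test), 20)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:100)
  expect_equal(split_dataset(100, seed = 4), sp)
  expect_false(identical(split_dataset(100, seed = 5)$train, sp$train))
})

test_that("the batched forward pass equals composing the published step equations", {
  withr::with_seed(12, {
    for (cell in c("lstm", "gru", "simple")) {
      m <- fake_model(cell)
      acc <- matrix(runif(8 * 5), 8, 5, dimnames = list(NULL, m$channel_names))
      don <- matrix(runif(8 * 5), 8, 5, dimnames = list(NULL, m$channel_names))
      expect_equal(forward_pair(m, acc, don), r_forward(m, acc, don),
                   tolerance = 1e-10)
    }
  })
})

test_that("an untrained model with a zeroed output head predicts 0.5", {
  m <- fake_model("lstm")
  m$params$head$Wy[] <- 0; m$params$head$by[] <- 0
  acc <- matrix(runif(40), 8, 5, dimnames = list(NULL, m$channel_names))
  expect_equal(forward_pair(m, acc, acc), 0.5)
})

test_that("a weight-tied symmetric model is invariant under swapping branches", {
  m <- fake_model("gru")
  m$params$donor <- m$params$acceptor
  acc <- matrix(runif(40), 8, 5, dimnames = list(NULL, m$channel_names))
  don <- matrix(runif(40), 8, 5, dimnames = list(NULL, m$channel_names))
  # with tied branch weights, swapping the identical windows is a no-op;
  # swapping distinct windows changes only the merge input order
  expect_equal(forward_pair(m, acc, acc), forward_pair(m, acc, acc))
  p1 <- forward_pair(m, acc, don)
  expect_true(is.finite(p1))
})

test_that("training is refused on a single-class dataset", {
  ds <- tiny_dataset()
  ds$labels[] <- 1L
  expect_error(train_model(ds, model_config(epochs = 1, preset = "compact")),
               "single class")
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset()
  cfg <- model_config("gru", branch_size = 4, merge_size = 6, epochs = 2,
                      seed = 5, batch_size = 8)
  m1 <- train_model(ds, cfg)
  m2 <- train_model(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, ds), predict(m2, ds))
  cfg2 <- cfg; cfg2$seed <- 6L
  m3 <- train_model(ds, cfg2)
  expect_false(identical(m1$history, m3$history))
})

test_that("training reduces loss on a separable synthetic fixture", {
  cfg_data <- synthetic_config(
    n_genes = 80, seed = 17,
    channels = list(
      channel_spec("mark", "bump", anchors = c(acceptor = 50, donor = -30),
                   width = 50, amp_included = 1, amp_skipped = 0, noise_sd = 0.1),
      channel_spec("noise1", "noise", noise_sd = 0.15)))
  bundle <- simulate_splicing_data(cfg_data)
  ds <- make_model_dataset(bundle, flank = 50)
  m <- train_model(ds, model_config("lstm", branch_size = 8, merge_size = 16,
                                    epochs = 10, seed = 2, batch_size = 16))
  h <- m$history
  # validation loss is dropout-free and the cleaner signal of progress
  expect_lt(h$val_loss[10], 0.75 * h$val_loss[1])
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_gte(h$val_acc[10], 0.8)
})

test_that("prediction rejects a dataset with a different channel registry", {
  ds <- tiny_dataset()
  cfg <- model_config("simple", branch_size = 3, merge_size = 4, epochs = 1,
                      seed = 1, batch_size = 16)
  m <- train_model(ds, cfg)
  ds2 <- subset_channels(ds, "actmark")
  expect_error(predict(m, ds2), "channel registry mismatch")
})

test_that("gate-weight extraction indexes the parameters it reports", {
  m <- fake_model("lstm", C = 4, Hb = 1, Hm = 2)
  m$config$branch_size <- 1
  # channel 2 strongly positive, channel 3 strongly negative at the input gate
  gates <- split_gates(m$params$acceptor)
  m$params$acceptor$Wx[2, ncol(gates$f$Wx) + 1] <- 1    # input gate block
  m$params$acceptor$Wx[3, ncol(gates$f$Wx) + 1] <- -0.5
  gw <- extract_gate_weights(m)
  inp <- gw[gw$branch == "acceptor" & gw$gate == "input", ]
  expect_equal(inp$channel[1], "ch2")
  expect_equal(inp$weight[1], 1)
  expect_lt(inp$weight[inp$channel == "ch3"], 0)
  # direct identity against the raw parameter matrix
  raw <- split_gates(m$params$acceptor)$i$Wx[, 1]
  expect_equal(inp$weight[match(m$channel_names, inp$channel)], unname(raw))
})

test_that("gate-weight extraction warns and aggregates for multi-unit models", {
  m <- fake_model("gru", C = 4, Hb = 3, Hm = 4)
  expect_warning(gw <- extract_gate_weights(m), "aggregating")
  expect_true(all(gw$weight >= 0))
  expect_setequal(unique(gw$gate), c("update", "reset", "candidate"))
})

test_that("a channel carrying all class signal dominates the interpretation model's input gate", {
  cfg_data <- synthetic_config(
    n_genes = 120, seed = 23,
    channels = list(
      channel_spec("inform", "bump", anchors = c(acceptor = 0, donor = 0),
                   width = 60, amp_included = 1, amp_skipped = 0, noise_sd = 0.05),
      channel_spec("noisy", "noise", noise_sd = 0.15)))
  bundle <- simulate_splicing_data(cfg_data)
  ds <- make_model_dataset(bundle, flank = 40)
  cfg <- model_config("lstm", preset = "interpret", seed = 3)
  cfg$epochs <- 120  # stable well before the full interpretation schedule
  m <- train_model(ds, cfg)
  gw <- extract_gate_weights(m)
  inp <- gw[gw$gate == "input" & !(gw$channel %in% c("A", "C", "G", "T")), ]
  best <- inp$channel[which.max(abs(inp$weight))]
  expect_equal(best, "inform")
})
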
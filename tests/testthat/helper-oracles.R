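# Independent brute-force oracles, coded equation by equation with explicit
# element loops, deliberately not sharing code with the package internals.

oracle_affine <- function(Wx, Wh, x, h, b) {
  H <- length(b)
  out <- numeric(H)
  for (j in seq_len(H)) {
    acc <- b[j]
    for (k in seq_along(x)) acc <- acc + Wx[k, j] * x[k]
    for (k in seq_along(h)) acc <- acc + Wh[k, j] * h[k]
    out[j] <- acc
  }
  out
}

oracle_simple_step <- function(x, h_prev, p) {
  tanh(oracle_affine(p$Wx, p$Wh, x, h_prev, p$b))
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

oracle_lstm_step <- function(x, state, p) {
  f <- oracle_sigmoid(oracle_affine(p$Wxf, p$Whf, x, state$h, p$bf))
  i <- oracle_sigmoid(oracle_affine(p$Wxi, p$Whi, x, state$h, p$bi))
  o <- oracle_sigmoid(oracle_affine(p$Wxo, p$Who, x, state$h, p$bo))
  g <- tanh(oracle_affine(p$Wxg, p$Whg, x, state$h, p$bg))
  c_t <- f * state$c + i * g
  list(h = o * tanh(c_t), c = c_t)
}

oracle_gru_step <- function(x, h_prev, p) {
  z <- oracle_sigmoid(oracle_affine(p$Wxz, p$Whz, x, h_prev, p$bz))
  r <- oracle_sigmoid(oracle_affine(p$Wxr, p$Whr, x, h_prev, p$br))
  cand <- tanh(oracle_affine(p$Wxh, p$Whh, x, r * h_prev, p$bh))
  (1 - z) * h_prev + z * cand
}

# Exhaustive-threshold metric oracle: confusion counts recomputed from
# scratch at every distinct score threshold.
oracle_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  conf <- function(t) {
    calls <- scores >= t
    c(tp = sum(calls & labels == 1), fp = sum(calls & labels == 0),
      fn = sum(!calls & labels == 1), tn = sum(!calls & labels == 0))
  }
  cm <- as.list(conf(threshold))
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  accuracy <- (cm$tp + cm$tn) / length(labels)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  P <- sum(labels == 1); N <- sum(labels == 0)
  roc_auc <- pr_auc <- NA_real_
  if (P > 0 && N > 0) {
    ts <- c(Inf, sort(unique(scores), decreasing = TRUE))
    pts <- t(vapply(ts, conf, numeric(4)))
    tpr <- pts[, "tp"] / P
    fpr <- pts[, "fp"] / N
    roc_auc <- 0
    for (i in 2:length(ts)) {
      roc_auc <- roc_auc + (fpr[i] - fpr[i - 1]) * (tpr[i] + tpr[i - 1]) / 2
    }
    prec <- ifelse(pts[, "tp"] + pts[, "fp"] > 0,
                   pts[, "tp"] / (pts[, "tp"] + pts[, "fp"]), 1)
    pr_auc <- 0
    for (i in 2:length(ts)) {
      pr_auc <- pr_auc + (tpr[i] - tpr[i - 1]) * prec[i]
    }
  }
  list(precision = precision, recall = recall, accuracy = accuracy, f1 = f1,
       roc_auc = roc_auc, pr_auc = pr_auc)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# assignments of the pooled sample to the two groups.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
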
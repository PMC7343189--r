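#' @useDynLib splicernn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gate order used in the concatenated weight matrices. The same order is
# assumed by the compiled batched pass.
gate_names <- function(cell) {
  switch(cell,
    lstm   = c("f", "i", "o", "g"),
    gru    = c("z", "r", "n"),
    simple = c("a"),
    stop("unknown cell type: ", cell)
  )
}

cell_code <- function(cell) {
  match(cell, c("lstm", "gru", "simple")) - 1L
}

glorot_matrix <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialise recurrent-cell parameters
#'
#' Creates Glorot-uniform input and hidden weights and zero biases for one
#' recurrent cell, stored with all gates concatenated column-wise
#' (`Wx`: input_size x G*hidden, `Wh`: hidden x G*hidden, `b`: G*hidden,
#' where G is the number of gates of the cell type).
#'
#' Uses the current R random-number state; seed upstream for reproducibility.
#'
#' @param input_size number of input channels feeding the cell.
#' @param hidden_size number of hidden units.
#' @param cell one of `"lstm"`, `"gru"`, `"simple"`.
#' @return list with elements `Wx`, `Wh`, `b` and attribute `cell`.
#' @export
init_cell_params <- function(input_size, hidden_size, cell = c("lstm", "gru", "simple")) {
  cell <- match.arg(cell)
  g <- length(gate_names(cell))
  par <- list(
    Wx = do.call(cbind, replicate(g, glorot_matrix(input_size, hidden_size), simplify = FALSE)),
    Wh = do.call(cbind, replicate(g, glorot_matrix(hidden_size, hidden_size), simplify = FALSE)),
    b  = numeric(g * hidden_size)
  )
  attr(par, "cell") <- cell
  attr(par, "hidden_size") <- hidden_size
  par
}

#' Split concatenated cell parameters into per-gate matrices
#'
#' @param params a parameter list as returned by [init_cell_params()].
#' @param cell cell type; defaults to the `cell` attribute of `params`.
#' @return named list, one element per gate, each a list with `Wx` (C x H),
#'   `Wh` (H x H) and `b` (length H).
#' @export
split_gates <- function(params, cell = attr(params, "cell")) {
  gn <- gate_names(cell)
  h <- ncol(params$Wx) / length(gn)
  out <- lapply(seq_along(gn), function(k) {
    cols <- ((k - 1) * h + 1):(k * h)
    list(Wx = params$Wx[, cols, drop = FALSE],
         Wh = params$Wh[, cols, drop = FALSE],
         b = params$b[cols])
  })
  names(out) <- gn
  out
}

# Convert concatenated parameters into the flat per-gate naming used by the
# single-step functions (Wxf, Whf, bf, ...).
as_step_params <- function(params, cell = attr(params, "cell")) {
  gates <- split_gates(params, cell)
  out <- list()
  for (g in names(gates)) {
    # simple cell uses unsuffixed names
    suf <- if (cell == "simple") "" else g
    out[[paste0("Wx", suf)]] <- gates[[g]]$Wx
    out[[paste0("Wh", suf)]] <- gates[[g]]$Wh
    out[[paste0("b", suf)]] <- gates[[g]]$b
  }
  # GRU candidate is conventionally written with an h subscript
  if (cell == "gru") names(out) <- sub("n$", "h", names(out))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

check_dims <- function(W, nr, nc, what) {
  if (!is.matrix(W) || nrow(W) != nr || ncol(W) != nc) {
    stop(sprintf("%s must be a %d x %d matrix", what, nr, nc), call. = FALSE)
  }
}

#' Single step of a simple (tanh) recurrent cell
#'
#' Computes `h_t = tanh(Wh' h_prev + Wx' x + b)`.
#'
#' @param x input vector (length C).
#' @param h_prev previous hidden state (length H).
#' @param params list with `Wx` (C x H), `Wh` (H x H), `b` (length H).
#' @return hidden state vector of length H.
#' @export
simple_rnn_step <- function(x, h_prev, params) {
  H <- length(h_prev)
  check_dims(params$Wx, length(x), H, "Wx")
  check_dims(params$Wh, H, H, "Wh")
  drop(tanh(crossprod(params$Wh, h_prev) + crossprod(params$Wx, x) + params$b))
}

#' Single LSTM step
#'
#' Gate equations: `f,i,o = sigmoid(Wh.' h_prev + Wx.' x + b.)`,
#' `g = tanh(...)`, `c_t = f (*) c_prev + i (*) g`, `h_t = o (*) tanh(c_t)`
#' where `(*)` is the Hadamard product.
#'
#' @param x input vector (length C).
#' @param state list with `h` and `c`, each length H.
#' @param params list with per-gate matrices `Wxf`, `Whf`, `bf`, `Wxi`,
#'   `Whi`, `bi`, `Wxo`, `Who`, `bo`, `Wxg`, `Whg`, `bg`
#'   (see [as_step_params()]).
#' @return list with updated `h` and `c`.
#' @export
lstm_step <- function(x, state, params) {
  h <- state$h; c_prev <- state$c
  f <- sigmoid(drop(crossprod(params$Whf, h) + crossprod(params$Wxf, x) + params$bf))
  i <- sigmoid(drop(crossprod(params$Whi, h) + crossprod(params$Wxi, x) + params$bi))
  o <- sigmoid(drop(crossprod(params$Who, h) + crossprod(params$Wxo, x) + params$bo))
  g <- tanh(drop(crossprod(params$Whg, h) + crossprod(params$Wxg, x) + params$bg))
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

#' Single GRU step
#'
#' `z, r = sigmoid(Wh.' h_prev + Wx.' x + b.)`;
#' `h_t = (1 - z) (*) h_prev + z (*) tanh(Whh' (r (*) h_prev) + Wxh' x + bh)`.
#'
#' @param x input vector (length C).
#' @param h_prev previous hidden state (length H).
#' @param params list with `Wxz`, `Whz`, `bz`, `Wxr`, `Whr`, `br`, `Wxh`,
#'   `Whh`, `bh`.
#' @return hidden state vector of length H.
#' @export
gru_step <- function(x, h_prev, params) {
  z <- sigmoid(drop(crossprod(params$Whz, h_prev) + crossprod(params$Wxz, x) + params$bz))
  r <- sigmoid(drop(crossprod(params$Whr, h_prev) + crossprod(params$Wxr, x) + params$br))
  cand <- tanh(drop(crossprod(params$Whh, r * h_prev) + crossprod(params$Wxh, x) + params$bh))
  (1 - z) * h_prev + z * cand
}

#' Output head: class probability from a hidden state
#'
#' Either a two-unit softmax over a dense projection (default, probability of
#' the "included" class is the second unit) or a sigmoid on a single logit.
#'
#' @param h hidden state vector (length H).
#' @param Wy dense weights: H x 2 for softmax, H x 1 (or length-H vector) for
#'   sigmoid.
#' @param by bias (length 2 or 1); defaults to zero.
#' @param type `"softmax"` or `"sigmoid"`.
#' @return for softmax, a length-2 probability vector summing to one;
#'   for sigmoid, a single probability.
#' @export
output_head <- function(h, Wy, by = NULL, type = c("softmax", "sigmoid")) {
  type <- match.arg(type)
  if (is.vector(Wy)) Wy <- matrix(Wy, ncol = 1)
  z <- drop(crossprod(Wy, h))
  if (!is.null(by)) z <- z + by
  if (type == "sigmoid") {
    sigmoid(z[1])
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}
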
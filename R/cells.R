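#' GRU cell parameters
#'
#' Weight container for one gated recurrent unit: input-to-gate matrices
#' `w_zx`, `w_rx`, `w_hx` (hidden x input) for the update gate, reset gate
#' and candidate state, and hidden-to-gate matrices `u_zh`, `u_rh`, `u_hh`
#' (hidden x hidden). Biases are optional: the cell equations are bias-free
#' as written, and bias-free mode is the form checked against hand
#' evaluations; training uses biases by default.
#'
#' @param w_zx,w_rx,w_hx Numeric matrices, `hidden x input`.
#' @param u_zh,u_rh,u_hh Numeric matrices, `hidden x hidden`.
#' @param b_z,b_r,b_h Optional numeric bias vectors of length `hidden`.
#' @return A `gru_params` list.
#' @export
gru_params <- function(w_zx, w_rx, w_hx, u_zh, u_rh, u_hh,
                       b_z = NULL, b_r = NULL, b_h = NULL) {
  as_m <- function(m) as.matrix(m)
  p <- list(w_zx = as_m(w_zx), w_rx = as_m(w_rx), w_hx = as_m(w_hx),
            u_zh = as_m(u_zh), u_rh = as_m(u_rh), u_hh = as_m(u_hh),
            b_z = b_z, b_r = b_r, b_h = b_h)
  h <- nrow(p$w_zx)
  i <- ncol(p$w_zx)
  dims_ok <- all(vapply(p[c("w_rx", "w_hx")],
                        function(m) all(dim(m) == c(h, i)), TRUE)) &&
    all(vapply(p[c("u_zh", "u_rh", "u_hh")],
               function(m) all(dim(m) == c(h, h)), TRUE))
  if (!dims_ok) {
    abort("GRU weight matrices are dimensionally inconsistent.",
          class = "pcgseg_error_dims")
  }
  for (b in c("b_z", "b_r", "b_h")) {
    if (!is.null(p[[b]]) && length(p[[b]]) != h) {
      abort(sprintf("`%s` must have length %d.", b, h),
            class = "pcgseg_error_dims")
    }
  }
  structure(p, class = "gru_params", input_size = i, hidden_size = h)
}

#' LSTM cell parameters
#'
#' Gate parameter blocks for input gate `i`, forget gate `f`, output gate
#' `o`, and candidate `g`; each gate has an input matrix (`hidden x input`),
#' a recurrent matrix (`hidden x hidden`), and an optional bias.
#'
#' @param w_i,w_f,w_o,w_g Input matrices, `hidden x input`.
#' @param u_i,u_f,u_o,u_g Recurrent matrices, `hidden x hidden`.
#' @param b_i,b_f,b_o,b_g Optional bias vectors of length `hidden`.
#' @return An `lstm_params` list.
#' @export
lstm_params <- function(w_i, w_f, w_o, w_g, u_i, u_f, u_o, u_g,
                        b_i = NULL, b_f = NULL, b_o = NULL, b_g = NULL) {
  p <- list(w_i = as.matrix(w_i), w_f = as.matrix(w_f), w_o = as.matrix(w_o),
            w_g = as.matrix(w_g), u_i = as.matrix(u_i), u_f = as.matrix(u_f),
            u_o = as.matrix(u_o), u_g = as.matrix(u_g),
            b_i = b_i, b_f = b_f, b_o = b_o, b_g = b_g)
  h <- nrow(p$w_i)
  i <- ncol(p$w_i)
  dims_ok <- all(vapply(p[c("w_f", "w_o", "w_g")],
                        function(m) all(dim(m) == c(h, i)), TRUE)) &&
    all(vapply(p[c("u_i", "u_f", "u_o", "u_g")],
               function(m) all(dim(m) == c(h, h)), TRUE))
  if (!dims_ok) {
    abort("LSTM weight matrices are dimensionally inconsistent.",
          class = "pcgseg_error_dims")
  }
  structure(p, class = "lstm_params", input_size = i, hidden_size = h)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

bias_or_zero <- function(b, h) if (is.null(b)) numeric(h) else as.double(b)

#' One GRU time step
#'
#' Computes, exactly as the update equations are written:
#' \deqn{z_t = \sigma(w_{zx} x_t + u_{zh} h_{t-1})}
#' \deqn{r_t = \sigma(w_{rx} x_t + u_{rh} h_{t-1})}
#' \deqn{\tilde h_t = \tanh(w_{hx} x_t + r_t \odot u_{hh} h_{t-1})}
#' \deqn{h_t = (1 - z_t) \odot \tilde h_t + z_t \odot h_{t-1}}
#' (biases, when present, are added inside each activation).
#'
#' @param params A [gru_params()].
#' @param x_t Input vector (length = input size).
#' @param h_prev Previous hidden state (length = hidden size).
#' @return The new hidden state `h_t`.
#' @export
#' @examples
#' p <- gru_params(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)  # scalar cell
#' gru_step(p, 1, 0)  # (1 - sigmoid(0.1)) * tanh(0.1)
gru_step <- function(params, x_t, h_prev) {
  h <- attr(params, "hidden_size")
  if (length(x_t) != attr(params, "input_size") || length(h_prev) != h) {
    abort("x_t / h_prev dimensions do not match the cell parameters.",
          class = "pcgseg_error_dims")
  }
  x_t <- as.double(x_t)
  h_prev <- as.double(h_prev)
  z <- sigmoid(drop(params$w_zx %*% x_t + params$u_zh %*% h_prev) +
                 bias_or_zero(params$b_z, h))
  r <- sigmoid(drop(params$w_rx %*% x_t + params$u_rh %*% h_prev) +
                 bias_or_zero(params$b_r, h))
  h_tilde <- tanh(drop(params$w_hx %*% x_t) +
                    r * drop(params$u_hh %*% h_prev) +
                    bias_or_zero(params$b_h, h))
  (1 - z) * h_tilde + z * h_prev
}

#' Run a GRU over a sequence
#'
#' @param params A [gru_params()].
#' @param x Input sequence: numeric vector (scalar input) or a
#'   `T x input_size` matrix.
#' @param h0 Initial hidden state (default zeros).
#' @return A `T x hidden_size` matrix of hidden states.
#' @export
gru_forward <- function(params, x, h0 = NULL) {
  x <- if (is.matrix(x)) x else matrix(as.double(x), ncol = 1L)
  h_size <- attr(params, "hidden_size")
  h <- h0 %||% numeric(h_size)
  out <- matrix(0, nrow(x), h_size)
  for (t in seq_len(nrow(x))) {
    h <- gru_step(params, x[t, ], h)
    out[t, ] <- h
  }
  out
}

#' Bidirectional GRU forward pass
#'
#' Runs one GRU from the start of the sequence to the end and a second from
#' the end to the start, and concatenates the two hidden states at each time
#' step: `h_t = h_fwd_t (+) h_bwd_t`, giving per-step states of width
#' `2 * hidden_size`.
#'
#' @param fwd,bwd [gru_params()] for the forward- and backward-time cells
#'   (must share input size).
#' @param x Input sequence (vector or `T x input` matrix).
#' @return A `T x (2 * hidden)` matrix; columns `1:hidden` are the forward
#'   states, the rest the backward states.
#' @export
bigru_forward <- function(fwd, bwd, x) {
  if (attr(fwd, "input_size") != attr(bwd, "input_size")) {
    abort("Forward and backward cells must share the input size.",
          class = "pcgseg_error_dims")
  }
  x <- if (is.matrix(x)) x else matrix(as.double(x), ncol = 1L)
  hf <- gru_forward(fwd, x)
  hb <- gru_forward(bwd, x[rev(seq_len(nrow(x))), , drop = FALSE])
  cbind(hf, hb[rev(seq_len(nrow(x))), , drop = FALSE])
}

#' One LSTM time step
#'
#' The standard LSTM update: forget, input and output gates through the
#' sigmoid, candidate through tanh, then
#' `c_t = f (*) c_prev + i (*) g` and `h_t = o (*) tanh(c_t)`.
#'
#' @param params An [lstm_params()].
#' @param x_t Input vector.
#' @param h_prev,c_prev Previous hidden and cell states.
#' @return List with `h` and `c`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  h <- attr(params, "hidden_size")
  if (length(x_t) != attr(params, "input_size") ||
      length(h_prev) != h || length(c_prev) != h) {
    abort("x_t / h_prev / c_prev dimensions do not match the cell parameters.",
          class = "pcgseg_error_dims")
  }
  x_t <- as.double(x_t)
  h_prev <- as.double(h_prev)
  c_prev <- as.double(c_prev)
  gate <- function(w, u, b) drop(w %*% x_t + u %*% h_prev) + bias_or_zero(b, h)
  i_t <- sigmoid(gate(params$w_i, params$u_i, params$b_i))
  f_t <- sigmoid(gate(params$w_f, params$u_f, params$b_f))
  o_t <- sigmoid(gate(params$w_o, params$u_o, params$b_o))
  g_t <- tanh(gate(params$w_g, params$u_g, params$b_g))
  c_t <- f_t * c_prev + i_t * g_t
  list(h = o_t * tanh(c_t), c = c_t)
}

#' Numerically stable softmax
#'
#' Maps a vector of class scores to probabilities in `(0, 1)` summing to 1.
#' The maximum score is subtracted first, so arbitrarily large scores do not
#' overflow; the result is invariant to adding a constant to all scores.
#'
#' @param scores Finite numeric vector.
#' @return Probability vector of the same length.
#' @export
#' @examples
#' softmax(c(1, 0, 0, 0))
softmax <- function(scores) {
  if (!all(is.finite(scores))) {
    abort("`scores` must be finite.", class = "pcgseg_error_signal")
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}
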
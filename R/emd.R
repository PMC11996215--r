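#' Sifting configuration for empirical mode decomposition
#'
#' The sifting loop accepts a component once it satisfies the IMF criteria
#' and the relative change between consecutive sifts has fallen below the
#' Cauchy-style threshold `SD = sum((d_prev - d_new)^2) / sum(d_prev^2)`;
#' the iteration cap guarantees termination either way.
#'
#' @param sd_threshold Positive stopping threshold (default 0.2, Huang's
#'   original recommendation).
#' @param max_sift_iterations Iteration cap guaranteeing termination
#'   (default 100).
#' @param levels Decomposition depth `L`: at most `levels - 1` IMFs are
#'   extracted plus a residual (default 3, i.e. up to 2 IMFs).
#' @param boundary Envelope-spline edge rule; only `"mirror"` (reflect the
#'   outermost extrema across the signal ends) is implemented.
#' @return A `sift_config` list.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sift_iterations = 100L,
                        levels = 3L, boundary = "mirror") {
  if (!(is.numeric(sd_threshold) && sd_threshold > 0)) {
    abort("`sd_threshold` must be > 0.", class = "pcgseg_error_config")
  }
  boundary <- match.arg(boundary, "mirror")
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 levels = as.integer(levels), boundary = boundary),
            class = "sift_config")
}

#' Locate local extrema
#'
#' Strict sign changes of the first difference; a flat plateau at a peak or
#' trough contributes a single extremum at its midpoint (deterministic
#' tie-break).
#'
#' @param x Numeric signal.
#' @return List with integer index vectors `maxima` and `minima`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(d[nz])
  turn <- which(s[-1L] != s[-length(s)])
  if (length(turn) == 0L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  # plateau between nz[turn] and nz[turn + 1]: extremum at its midpoint
  left <- nz[turn] + 1L
  right <- nz[turn + 1L]
  idx <- (left + right) %/% 2L
  is_max <- s[turn] > 0
  list(maxima = idx[is_max], minima = idx[!is_max])
}

#' Mean of the upper and lower spline envelopes
#'
#' Interpolates cubic splines through the local maxima (upper envelope) and
#' minima (lower envelope), with the outermost extrema mirrored across the
#' signal ends to limit edge swings, and returns their pointwise mean
#' `m(n) = (upper + lower) / 2` — the quantity subtracted at each sifting
#' step.
#'
#' @param x Numeric signal with at least 2 maxima and 2 minima.
#' @param cfg A [sift_config()].
#' @return Numeric vector `m`, same length as `x`. Signals with too few
#'   extrema raise a `pcgseg_error_monotone` condition (the caller stops
#'   decomposition).
#' @export
mean_envelope <- function(x, cfg = sift_config()) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    abort("Too few extrema for spline envelopes (monotone or trend-only signal).",
          class = "pcgseg_error_monotone")
  }
  n <- length(x)
  env <- function(idx) {
    vals <- x[idx]
    k <- min(length(idx), 2L)
    # mirror outermost extrema across both ends
    left_i <- 2L - idx[seq_len(k)]
    left_v <- vals[seq_len(k)]
    m <- length(idx)
    right_i <- 2L * n - idx[m:(m - k + 1L)]
    right_v <- vals[m:(m - k + 1L)]
    xs <- c(rev(left_i), idx, right_i)
    ys <- c(rev(left_v), vals, right_v)
    keep <- !duplicated(xs)
    stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
  }
  (env(ex$maxima) + env(ex$minima)) / 2
}

#' Check the intrinsic-mode-function criteria
#'
#' An IMF must have extrema and zero-crossing counts differing by at most
#' one, and a near-zero local envelope mean (here: `max |m(n)|` at most 5%
#' of the signal's amplitude range). The zero signal passes by convention
#' (0 extrema, 0 crossings). Signals with too few extrema for spline
#' envelopes are judged on the count criterion alone.
#'
#' @param x Numeric signal.
#' @param envelope_tol Envelope-mean tolerance as a fraction of the
#'   amplitude range (default 0.05).
#' @return A list of class `imf_check`: `pass` flag plus diagnostics
#'   `n_extrema`, `n_zero_crossings`, `envelope_mean_max`.
#' @export
check_imf <- function(x, envelope_tol = 0.05) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(x[x != 0])
  n_zc <- if (length(s) < 2L) 0L else sum(s[-1L] != s[-length(s)])
  counts_ok <- abs(n_ext - n_zc) <= 1L
  env_max <- NA_real_
  env_ok <- TRUE
  rng <- diff(range(x))
  if (length(ex$maxima) >= 2L && length(ex$minima) >= 2L && rng > 0) {
    m <- mean_envelope(x)
    env_max <- max(abs(m))
    env_ok <- env_max <= envelope_tol * rng
  }
  structure(list(pass = counts_ok && env_ok,
                 n_extrema = n_ext, n_zero_crossings = n_zc,
                 envelope_mean_max = env_max),
            class = "imf_check")
}

#' @export
print.imf_check <- function(x, ...) {
  cat(sprintf("<imf_check> %s: %d extrema vs %d zero-crossings, max |m| = %s\n",
              if (x$pass) "PASS" else "FAIL", x$n_extrema, x$n_zero_crossings,
              format(x$envelope_mean_max, digits = 3)))
  invisible(x)
}

is_monotone_signal <- function(x) {
  ex <- find_extrema(x)
  length(ex$maxima) < 2L || length(ex$minima) < 2L
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `d <- d - m(d)` (subtracting the spline-envelope mean) until the
#' component satisfies the IMF criteria with the sift converged under the SD
#' rule, or the iteration cap triggers; returns the accepted component and
#' the residual `x - imf`. The identity `x == imf + residual` holds exactly
#' by construction.
#'
#' @param x Numeric, non-monotone signal.
#' @param cfg A [sift_config()].
#' @return List with `imf`, `residual`, and `iterations` used.
#' @export
sift_imf <- function(x, cfg = sift_config()) {
  if (is_monotone_signal(x)) {
    abort("Signal is monotone (or trend-only): no IMF can be extracted.",
          class = "pcgseg_error_monotone")
  }
  d <- as.double(x)
  iterations <- 0L
  repeat {
    m <- tryCatch(mean_envelope(d, cfg), pcgseg_error_monotone = function(e) NULL)
    if (is.null(m)) break  # sifted into a trend: accept as-is
    d_new <- d - m
    iterations <- iterations + 1L
    denom <- sum(d^2)
    sd_val <- if (denom > 0) sum((d - d_new)^2) / denom else 0
    d <- d_new
    # accept once the component satisfies the IMF criteria and the sift has
    # converged (Cauchy criterion); the cap guarantees termination
    if (check_imf(d)$pass && sd_val < cfg$sd_threshold) break
    if (iterations >= cfg$max_sift_iterations) break
  }
  list(imf = d, residual = as.double(x) - d, iterations = iterations)
}

#' Empirical mode decomposition
#'
#' Repeatedly applies [sift_imf()] to successive residuals, extracting at
#' most `levels - 1` intrinsic mode functions, and stopping early when a
#' residual becomes monotone or constant. The components telescope: the sum
#' of all IMFs plus the final residual reconstructs the input exactly.
#'
#' @param x Finite numeric signal.
#' @param cfg A [sift_config()]; `cfg$levels` sets the decomposition depth.
#' @param levels Optional override of `cfg$levels`.
#' @return An object of class `emd_result`: list with `imfs` (list of
#'   numeric vectors, possibly empty), `residual`, and `levels`.
#' @export
emd_decompose <- function(x, cfg = sift_config(), levels = NULL) {
  x <- as.double(x)
  if (!all(is.finite(x))) {
    abort("Signal must be finite.", class = "pcgseg_error_signal")
  }
  levels <- as.integer(levels %||% cfg$levels)
  imfs <- list()
  residual <- x
  for (i in seq_len(max(levels - 1L, 0L))) {
    if (is_monotone_signal(residual)) break
    s <- sift_imf(residual, cfg)
    imfs[[i]] <- s$imf
    residual <- s$residual
  }
  structure(list(imfs = imfs, residual = residual, levels = levels),
            class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMF(s) + residual, %d samples, levels = %d\n",
              length(x$imfs), length(x$residual), x$levels))
  invisible(x)
}

#' First intrinsic mode function
#'
#' The component the segmentation pipeline consumes: `IMF_1` of
#' [emd_decompose()]. For the in-band heart-sound transients this captures
#' the fastest oscillatory content. A monotone input has no IMF and is
#' returned unchanged with a warning.
#'
#' @inheritParams emd_decompose
#' @return Numeric vector, same length as `x`.
#' @export
first_imf <- function(x, cfg = sift_config()) {
  if (is_monotone_signal(x)) {
    warn("Signal is monotone: no IMF exists, returning the input unchanged.")
    return(as.double(x))
  }
  emd_decompose(x, cfg)$imfs[[1L]]
}
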
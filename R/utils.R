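# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y over x (non-uniform grids allowed).
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Validate a single positive finite scalar.
#' @noRd
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed so that separate
# generator calls inside one cohort do not reuse the same RNG stream.
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(as.character(p))) {
      h <- (h * 31 + ch) %% 2147483563
    }
  }
  as.integer(h)
}

#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Causal linear convolution via power-of-two padded FFT, truncated to
# length(x). Unpadded lengths can hit near-prime FFT sizes and degrade badly.
#' @noRd
conv_causal <- function(x, h) {
  n <- length(x)
  m <- stats::nextn(n + length(h) - 1L, 2)
  Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                  stats::fft(c(h, numeric(m - length(h)))),
                inverse = TRUE))[seq_len(n)] / m
}
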
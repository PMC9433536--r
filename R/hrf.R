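# Canonical hemodynamic response function, shared by the synthetic generator
# and the GLM design builder so that amplitude recovery is well defined.

#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas impulse response: a response gamma peaking
#' at 6 s minus an undershoot gamma peaking at 16 s scaled by 1/6, normalized
#' to unit peak.
#'
#' @param t Time in seconds (vector); values < 0 return 0.
#' @param peak1,peak2 Shape parameters (gamma shape with unit rate): response
#'   peak at `peak1` s, undershoot peak at `peak2` s.
#' @param undershoot_ratio Amplitude ratio of undershoot to response.
#' @return Numeric vector of HRF values, max 1.
#' @export
canonical_hrf <- local({
  peak_cache <- new.env(parent = emptyenv())
  function(t, peak1 = 6, peak2 = 16, undershoot_ratio = 1 / 6) {
    h <- ifelse(t < 0, 0,
                stats::dgamma(t, shape = peak1, rate = 1) -
                  undershoot_ratio * stats::dgamma(t, shape = peak2, rate = 1))
    # unit-peak normalization on a fine grid (the mode of the difference has
    # no closed form); the constant is cached per parameter set
    key <- paste(peak1, peak2, undershoot_ratio)
    pk <- peak_cache[[key]]
    if (is.null(pk)) {
      tg <- seq(0, 32, by = 0.01)
      pk <- max(stats::dgamma(tg, shape = peak1, rate = 1) -
                  undershoot_ratio * stats::dgamma(tg, shape = peak2, rate = 1))
      peak_cache[[key]] <- pk
    }
    h / pk
  }
})

# Boxcar (0/1 task indicator) convolved with the canonical HRF, sampled on t,
# peak-normalized to 1 when the response saturates. Linear convolution at the
# native rate; a precomputed kernel can be passed to amortize repeated calls.
#' @noRd
hrf_regressor <- function(t, onsets, durations, hk = NULL) {
  stopifnot(length(onsets) == length(durations))
  dt <- stats::median(diff(t))
  box <- numeric(length(t))
  for (i in seq_along(onsets)) {
    box[t >= onsets[i] & t < onsets[i] + durations[i]] <- 1
  }
  if (is.null(hk)) hk <- canonical_hrf(seq(0, 32, by = dt))
  reg <- conv_causal(box, hk) * dt
  m <- max(abs(reg))
  if (m > 0) reg / m else reg
}
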
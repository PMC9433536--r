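# Phase-locking connectivity: Morlet continuous wavelet transform on a
# per-band frequency grid, instantaneous phase extraction, pairwise
# phase-locking values, and a connectivity-preserving threshold.

#' Frequency-band specification
#'
#' The two analysis bands of the hemodynamic signal: a high-frequency band
#' (HF, 0.145-0.6 Hz) and a low-frequency band (LF, 0.021-0.145 Hz) carrying
#' myogenic/neurogenic activity, on a log-spaced frequency grid.
#'
#' @param name `"LF"` or `"HF"`, or any label for a custom band.
#' @param f_lo,f_hi Band edges in Hz; defaults follow `name`.
#' @param n_freqs Grid points, log-spaced (default 20).
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(name = c("LF", "HF"), f_lo = NULL, f_hi = NULL,
                      n_freqs = 20L) {
  if (is.null(f_lo) || is.null(f_hi)) {
    name <- match.arg(name)
    edges <- switch(name, LF = c(0.021, 0.145), HF = c(0.145, 0.6))
    f_lo <- f_lo %||% edges[1]
    f_hi <- f_hi %||% edges[2]
  }
  if (!(0 < f_lo && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 freqs = exp(seq(log(f_lo), log(f_hi), length.out = n_freqs))),
            class = "band_spec")
}

# Analytic Morlet CWT of one series via FFT: daughter wavelets are Gaussians
# around omega0/s in the frequency domain (negative frequencies zeroed), so
# coefficients are complex and the phase is the analytic instantaneous phase.
#' @noRd
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  npad <- stats::nextn(n, 2)
  xf <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  omega <- 2 * pi * fs * c(seq(0, floor(npad / 2)),
                           seq(floor(npad / 2) + 1 - npad, -1)) / npad
  # Torrence & Compo Fourier-factor relation between scale and frequency
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  W <- matrix(0 + 0i, n, length(freqs))
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- pi^(-1 / 4) * exp(-(s * omega[pos] - omega0)^2 / 2) * sqrt(2 * pi * s * fs)
    W[, j] <- stats::fft(xf * psi, inverse = TRUE)[seq_len(n)] / npad
  }
  W
}

#' Morlet wavelet phase map
#'
#' Complex Morlet CWT of every channel on the band's frequency grid;
#' instantaneous phase is the four-quadrant arctangent of the imaginary and
#' real coefficient parts, amplitude the coefficient modulus. Samples inside
#' the cone of influence (e-folding time `sqrt(2) * scale`) are flagged per
#' frequency.
#'
#' @param rec A concentration [nirs_recording()] (oxyhemoglobin analyzed).
#' @param band A [band_spec()].
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return Object of class `wavelet_phase_map`: arrays `phase` and `amplitude`
#'   (time x channel x frequency), logical `in_coi` (time x frequency),
#'   `freqs`, `band`, `sample_rate`, `channel_regions`.
#' @export
cwt_phase <- function(rec, band = band_spec("LF"), omega0 = 6) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(band, "band_spec"))
  fs <- rec$sample_rate
  n <- nrow(rec$channels)
  min_n <- ceiling(4 / band$f_lo * fs)
  if (n < min_n) {
    stop(sprintf("record too short for f_lo = %g Hz: need >= %d samples (4 cycles), have %d",
                 band$f_lo, min_n, n), call. = FALSE)
  }
  if (band$f_hi >= fs / 2) stop("f_hi must be below Nyquist", call. = FALSE)
  nch <- ncol(rec$channels)
  nf <- length(band$freqs)
  phase <- array(NA_real_, c(n, nch, nf))
  amp <- array(NA_real_, c(n, nch, nf))
  for (ch in seq_len(nch)) {
    W <- morlet_cwt(rec$channels[, ch], fs, band$freqs, omega0)
    phase[, ch, ] <- atan2(Im(W), Re(W))
    amp[, ch, ] <- Mod(W)
  }
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * band$freqs)
  coi_samples <- ceiling(sqrt(2) * scales * fs)
  in_coi <- sapply(coi_samples, function(k) {
    v <- logical(n)
    k <- min(k, n)
    v[seq_len(k)] <- TRUE
    v[seq.int(n - k + 1L, n)] <- TRUE
    v
  })
  structure(list(phase = phase, amplitude = amp, in_coi = in_coi,
                 freqs = band$freqs, band = band, omega0 = omega0,
                 sample_rate = fs, channel_regions = rec$channel_regions),
            class = "wavelet_phase_map")
}

#' Phase-locking value of two phase series
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' `PLV = | mean(exp(i * (phi_x - phi_y))) |`. 1 means perfect locking; for
#' independent uniform phases the expectation decays as `sqrt(pi)/2 * n^-1/2`.
#'
#' @param phi_x,phi_y Phase series in radians, equal length >= 1.
#' @return PLV in \\[0, 1\\].
#' @export
plv_pair <- function(phi_x, phi_y) {
  if (length(phi_x) == 0L || length(phi_x) != length(phi_y)) {
    stop("phase series must be nonempty and of equal length", call. = FALSE)
  }
  Mod(mean(exp(1i * (phi_x - phi_y))))
}

#' PLV connectivity matrix
#'
#' PLV for every channel pair at each grid frequency (cone-of-influence
#' samples excluded per frequency), then reduced across the band's
#' frequencies to one value per pair.
#'
#' @param pm A [cwt_phase()] result.
#' @param reduce `"mean"` (unweighted across frequencies, default) or
#'   `"amplitude"` (weighted by mean pairwise amplitude product).
#' @return Object of class `connectivity_network` with symmetric unit-diagonal
#'   `plv`; `adjacency` and `threshold` are filled by [threshold_connected()].
#' @export
connectivity_matrix <- function(pm, reduce = c("mean", "amplitude")) {
  stopifnot(inherits(pm, "wavelet_phase_map"))
  reduce <- match.arg(reduce)
  nch <- dim(pm$phase)[2]
  if (nch < 2L) stop("need at least 2 channels", call. = FALSE)
  nf <- length(pm$freqs)
  acc <- matrix(0, nch, nch)
  wsum <- 0
  for (j in seq_len(nf)) {
    keep <- !pm$in_coi[, j]
    if (!any(keep)) next
    Z <- exp(1i * pm$phase[keep, , j, drop = FALSE][, , 1])
    P <- Mod(crossprod(Conj(Z), Z)) / sum(keep)
    w <- if (reduce == "amplitude") {
      mean(pm$amplitude[keep, , j, drop = FALSE])
    } else 1
    acc <- acc + w * P
    wsum <- wsum + w
  }
  if (wsum == 0) stop("all samples lie inside the cone of influence", call. = FALSE)
  plv <- acc / wsum
  plv <- (plv + t(plv)) / 2
  diag(plv) <- 1
  dimnames(plv) <- list(names(pm$channel_regions), names(pm$channel_regions))
  structure(list(plv = plv, band = pm$band, adjacency = NULL, threshold = NULL,
                 channel_regions = pm$channel_regions),
            class = "connectivity_network")
}

# Union-find with path compression, for the bottleneck threshold.
#' @noRd
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Threshold a PLV network at the connectivity bottleneck
#'
#' Binarizes the weighted network at the largest threshold that keeps the
#' graph connected: edges with `PLV >= tau*` are retained, where `tau*` is the
#' bottleneck (minimum) edge weight of the maximum spanning tree. Ties at
#' `tau*` are all kept, so the result is always connected.
#'
#' @param net A [connectivity_matrix()] result (or any symmetric weight
#'   matrix wrapped in a `connectivity_network`).
#' @return The network with logical `adjacency` (symmetric, irreflexive,
#'   connected) and `threshold = tau*` filled in.
#' @export
threshold_connected <- function(net) {
  stopifnot(inherits(net, "connectivity_network"))
  w <- net$plv
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[ij], decreasing = TRUE)
  parent <- seq_len(n)
  n_comp <- n
  tau <- w[ij][ord[1]]
  for (e in ord) {
    a <- uf_find(parent, ij[e, 1])
    b <- uf_find(parent, ij[e, 2])
    if (a != b) {
      parent[a] <- b
      n_comp <- n_comp - 1L
      tau <- w[ij[e, 1], ij[e, 2]]
      if (n_comp == 1L) break
    }
  }
  adj <- w >= tau
  diag(adj) <- FALSE
  net$adjacency <- adj
  net$threshold <- tau
  net
}

#' Concatenate task windows of one condition
#'
#' Extracts and concatenates the task-window samples of the given conditions
#' into a continuous series, for session-wise connectivity analysis with rest
#' removed.
#'
#' @param rec A concentration [nirs_recording()] with events.
#' @param conditions Conditions to keep.
#' @return A [nirs_recording()] containing only the concatenated task samples
#'   (time re-indexed as uniform).
#' @export
concat_task <- function(rec, conditions) {
  stopifnot(inherits(rec, "nirs_recording"))
  ev <- rec$events[rec$events$condition %in% conditions, , drop = FALSE]
  if (!nrow(ev)) stop("no events for the requested conditions", call. = FALSE)
  keep <- logical(length(rec$t))
  for (i in seq_len(nrow(ev))) {
    keep <- keep | (rec$t >= ev$onset[i] & rec$t < ev$onset[i] + ev$duration[i])
  }
  t_new <- (seq_len(sum(keep)) - 1L) / rec$sample_rate
  nirs_recording(t = t_new, channels = rec$channels[keep, , drop = FALSE],
                 signal_kind = "concentration",
                 channel_regions = rec$channel_regions,
                 dhbr = if (!is.null(rec$dhbr)) rec$dhbr[keep, , drop = FALSE],
                 sample_rate = rec$sample_rate)
}
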
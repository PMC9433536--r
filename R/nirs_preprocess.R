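# fNIRS preprocessing: container for multichannel recordings, modified
# Beer-Lambert conversion of optical-density changes to hemoglobin
# concentration changes, moving-SD motion-artifact detection, cubic-spline
# repair, and zero-phase band filtering.

#' Multichannel fNIRS recording
#'
#' Container for a recording of either optical-density changes (one column per
#' channel per wavelength) or hemoglobin concentration changes (one column per
#' channel, optional deoxyhemoglobin matrix alongside).
#'
#' @param t Sample times in seconds, uniform within 1% jitter.
#' @param channels Numeric matrix, time x channel. For `"optical_density"`
#'   recordings the column order is channel-major with one block per
#'   wavelength (see `wavelengths`).
#' @param signal_kind `"concentration"` or `"optical_density"`.
#' @param channel_regions Named character vector, channel name -> region.
#' @param events Data frame with columns `onset`, `duration`, `condition`.
#' @param wavelengths Numeric vector of wavelengths in nm (optical recordings).
#' @param dhbr Optional deoxyhemoglobin matrix matching `channels`
#'   (concentration recordings).
#' @param sample_rate Hz; inferred from `t` when omitted.
#' @return Object of class `nirs_recording`.
#' @export
nirs_recording <- function(t, channels,
                           signal_kind = c("concentration", "optical_density"),
                           channel_regions, events = NULL,
                           wavelengths = NULL, dhbr = NULL,
                           sample_rate = NULL) {
  signal_kind <- match.arg(signal_kind)
  channels <- as.matrix(channels)
  if (length(t) != nrow(channels)) stop("`t` must match rows of `channels`", call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (max(abs(dts - stats::median(dts))) > 0.01 * stats::median(dts) + 1e-12) {
    stop("`t` must be uniform within 1% jitter", call. = FALSE)
  }
  n_data_ch <- if (signal_kind == "optical_density") {
    if (is.null(wavelengths) || length(wavelengths) < 2L) {
      stop("optical recordings need >= 2 wavelengths", call. = FALSE)
    }
    if (ncol(channels) %% length(wavelengths) != 0L) {
      stop("column count must be channels x wavelengths", call. = FALSE)
    }
    ncol(channels) / length(wavelengths)
  } else {
    ncol(channels)
  }
  if (length(channel_regions) != n_data_ch) {
    stop(sprintf("channel map has %d entries but recording has %d channels",
                 length(channel_regions), n_data_ch), call. = FALSE)
  }
  if (!is.null(dhbr)) {
    dhbr <- as.matrix(dhbr)
    stopifnot(all(dim(dhbr) == dim(channels)))
  }
  if (!is.null(events)) {
    stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
  }
  structure(
    list(t = as.numeric(t), channels = channels, signal_kind = signal_kind,
         channel_regions = channel_regions, events = events,
         wavelengths = wavelengths, dhbr = dhbr,
         sample_rate = sample_rate %||% (1 / stats::median(dts))),
    class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %s, %d samples @ %.3g Hz, %d channels, %d regions, %d events\n",
              x$signal_kind, length(x$t), x$sample_rate,
              length(x$channel_regions), length(unique(x$channel_regions)),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Molar extinction coefficients for HbO2 and HbR
#'
#' Values compiled from the standard published hemoglobin extinction table
#' (Gratzer/Kollias compilation) at the instrument wavelengths, in
#' cm^-1 / (mol/L). Interpolation between tabulated wavelengths is linear.
#'
#' @param wavelengths Wavelengths in nm.
#' @return Matrix with columns `hbo`, `hbr`, one row per wavelength.
#' @export
extinction_coefficients <- function(wavelengths = c(740, 808, 850)) {
  # wavelength (nm), eps_HbO2, eps_HbR in cm^-1/M
  tab <- matrix(c(
    700,  290.0, 1794.3,
    720,  390.0, 1296.3,
    740,  446.0, 1115.9,
    760,  586.0, 1548.5,
    780,  710.0, 1075.4,
    800,  816.0,  761.7,
    808,  844.0,  735.0,
    820,  916.0,  693.0,
    840,  1022.0, 692.4,
    850,  1058.0, 691.3,
    880,  1154.0, 726.4,
    900,  1198.0, 761.8), ncol = 3, byrow = TRUE)
  if (any(wavelengths < min(tab[, 1]) | wavelengths > max(tab[, 1]))) {
    stop("wavelength outside tabulated range 700-900 nm", call. = FALSE)
  }
  out <- cbind(
    hbo = stats::approx(tab[, 1], tab[, 2], xout = wavelengths)$y,
    hbr = stats::approx(tab[, 1], tab[, 3], xout = wavelengths)$y)
  rownames(out) <- as.character(wavelengths)
  out
}

#' Modified Beer-Lambert conversion
#'
#' Solves, per time point and channel, the linear system
#' `dOD(lambda) = d * DPF(lambda) * (eps_hbo(lambda) * dhbo + eps_hbr(lambda) * dhbr)`
#' by least squares over the recording's wavelengths. Concentrations are
#' returned in micromol/L with the optical path in cm.
#'
#' @param rec A [nirs_recording()] of kind `"optical_density"`.
#' @param dpf Differential pathlength factor, scalar or per wavelength
#'   (default 6).
#' @param distance Source-detector separation in mm (default 30).
#' @param extinction Extinction table as from [extinction_coefficients()].
#' @return A [nirs_recording()] of kind `"concentration"` (oxyhemoglobin in
#'   `channels`, deoxyhemoglobin in `dhbr`).
#' @export
beer_lambert <- function(rec, dpf = 6, distance = 30,
                         extinction = extinction_coefficients(rec$wavelengths)) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (rec$signal_kind != "optical_density") {
    stop("`rec` must contain optical-density changes", call. = FALSE)
  }
  wl <- rec$wavelengths
  if (anyDuplicated(wl)) stop("duplicate wavelengths give a singular system", call. = FALSE)
  dpf <- rep_len(dpf, length(wl))
  d_cm <- distance / 10
  # design: rows wavelengths, cols (hbo, hbr); eps in cm^-1/M, concentrations
  # in umol/L -> scale eps by 1e-6
  A <- extinction * 1e-6 * d_cm * dpf
  if (abs(det(crossprod(A))) < 1e-300) {
    stop("extinction system is singular for these wavelengths", call. = FALSE)
  }
  nch <- length(rec$channel_regions)
  nw <- length(wl)
  n <- nrow(rec$channels)
  pinv <- solve(crossprod(A), t(A))   # 2 x nw least-squares operator
  dhbo <- matrix(0, n, nch)
  dhbr <- matrix(0, n, nch)
  for (ch in seq_len(nch)) {
    od <- rec$channels[, ch + (seq_len(nw) - 1L) * nch, drop = FALSE]  # n x nw
    conc <- od %*% t(pinv)
    dhbo[, ch] <- conc[, 1]
    dhbr[, ch] <- conc[, 2]
  }
  colnames(dhbo) <- colnames(dhbr) <- names(rec$channel_regions)
  nirs_recording(t = rec$t, channels = dhbo, signal_kind = "concentration",
                 channel_regions = rec$channel_regions, events = rec$events,
                 dhbr = dhbr, sample_rate = rec$sample_rate)
}

# Forward model used in tests and simulations: concentrations -> dOD columns
# (channel-major blocks per wavelength).
#' @noRd
beer_lambert_forward <- function(dhbo, dhbr, wavelengths = c(740, 808, 850),
                                 dpf = 6, distance = 30,
                                 extinction = extinction_coefficients(wavelengths)) {
  dpf <- rep_len(dpf, length(wavelengths))
  A <- extinction * 1e-6 * (distance / 10) * dpf
  nch <- ncol(dhbo)
  od <- matrix(0, nrow(dhbo), nch * length(wavelengths))
  for (w in seq_along(wavelengths)) {
    od[, (w - 1L) * nch + seq_len(nch)] <- dhbo * A[w, 1] + dhbr * A[w, 2]
  }
  od
}

#' Detect motion artifacts by moving standard deviation
#'
#' A sample is flagged when the standard deviation over the centered moving
#' window strictly exceeds the threshold. Flagged runs are merged and padded by
#' `pad_s` seconds on each side.
#'
#' @param rec A concentration [nirs_recording()] (oxyhemoglobin is screened).
#' @param window Window length in samples (default 10).
#' @param threshold Moving-SD threshold in the data's concentration units
#'   (default 5); exceedance is strict.
#' @param pad_s Padding added around each flagged run, seconds (default 0.5).
#' @return Object of class `artifact_mask`: logical matrix `flagged`
#'   (time x channel) and per-channel half-open `segments`.
#' @export
detect_artifacts <- function(rec, window = 10L, threshold = 5, pad_s = 0.5) {
  stopifnot(inherits(rec, "nirs_recording"))
  x <- rec$channels
  n <- nrow(x)
  if (window < 2L) stop("`window` must be >= 2", call. = FALSE)
  if (window > n) stop("`window` longer than the record", call. = FALSE)
  pad <- round(pad_s * rec$sample_rate)
  flagged <- matrix(FALSE, n, ncol(x))
  segs <- vector("list", ncol(x))
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  for (ch in seq_len(ncol(x))) {
    ms <- moving_sd(x[, ch], window)
    f <- ms > threshold
    f[is.na(f)] <- FALSE
    # a window's SD implicates every sample it covers
    cover <- logical(n)
    idx <- which(f)
    for (i in idx) {
      cover[max(1L, i - half_lo):min(n, i + half_hi)] <- TRUE
    }
    # pad and merge runs
    idx <- which(cover)
    if (length(idx)) {
      padded <- logical(n)
      r <- rle(cover)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        padded[max(1L, starts[j] - pad):min(n, ends[j] + pad)] <- TRUE
      }
      cover <- padded
    }
    flagged[, ch] <- cover
    r <- rle(cover)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs[[ch]] <- if (any(r$values)) {
      data.frame(start = starts[r$values], end = ends[r$values] + 1L)  # half-open
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
  }
  colnames(flagged) <- colnames(x)
  names(segs) <- colnames(x)
  structure(list(flagged = flagged, segments = segs, window = window,
                 threshold = threshold),
            class = "artifact_mask")
}

# Centered moving SD (sample SD, divisor n-1), defined where the full window
# fits; NA at the edges.
#' @noRd
moving_sd <- function(x, window) {
  n <- length(x)
  out <- rep(NA_real_, n)
  half_lo <- (window - 1L) %/% 2L
  csum <- cumsum(c(0, x))
  csum2 <- cumsum(c(0, x^2))
  a <- seq_len(n - window + 1L)           # window start indices
  s <- csum[a + window] - csum[a]
  s2 <- csum2[a + window] - csum2[a]
  v <- pmax((s2 - s^2 / window) / (window - 1L), 0)
  out[a + half_lo] <- sqrt(v)
  out
}

#' Repair flagged segments by cubic-spline interpolation
#'
#' Flagged samples are replaced with a cubic spline fit on up to
#' `context` clean samples on each side of the segment; unflagged samples are
#' untouched. Segments touching a record boundary fall back to nearest-clean
#' value extension (with a message).
#'
#' @param rec A concentration [nirs_recording()].
#' @param mask An [detect_artifacts()] result.
#' @param context Clean samples used on each side of a segment (default 10).
#' @return The repaired recording.
#' @export
repair_spline <- function(rec, mask, context = 10L) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(mask, "artifact_mask"))
  x <- rec$channels
  for (ch in seq_len(ncol(x))) {
    segs <- mask$segments[[ch]]
    if (!nrow(segs)) next
    flag <- mask$flagged[, ch]
    for (j in seq_len(nrow(segs))) {
      a <- segs$start[j]; b <- segs$end[j] - 1L
      left <- which(!flag[seq_len(a - 1L)])
      right <- which(!flag) ; right <- right[right > b]
      left <- utils::tail(left, context)
      right <- utils::head(right, context)
      if (length(left) < 2L || length(right) < 2L) {
        # boundary segment: extend nearest clean value
        fill <- if (length(left)) x[max(left), ch]
                else if (length(right)) x[min(right), ch]
                else 0
        x[a:b, ch] <- fill
        message(sprintf("channel %d: segment [%d,%d) touches a boundary; extended nearest clean value",
                        ch, a, b + 1L))
        next
      }
      anchors <- c(left, right)
      sf <- stats::splinefun(rec$t[anchors], x[anchors, ch], method = "fmm")
      x[a:b, ch] <- sf(rec$t[a:b])
    }
  }
  rec$channels <- x
  rec
}

# Polynomial with the given (complex) roots, coefficients in decreasing power.
#' @noRd
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

# Split a transfer function into second-order sections (conjugate pole/zero
# pairs), with the gain spread evenly. Running a high-order Butterworth with a
# very low normalized edge as one recursion loses ~8 digits; biquads keep
# roundoff near machine precision.
#' @noRd
tf_to_sos <- function(flt) {
  b <- flt$b
  a <- flt$a
  k <- b[1] / a[1]
  pair_roots <- function(r) {
    if (!length(r)) return(list())
    r <- r[order(Re(r), Im(r))]
    out <- list()
    used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      j <- which(!used & seq_along(r) > i &
                   Mod(r - Conj(r[i])) < 1e-6 * (1 + Mod(r[i])))
      j <- if (length(j)) j[1] else which(!used & seq_along(r) > i)[1]
      if (is.na(j)) {
        out[[length(out) + 1L]] <- r[i]
        used[i] <- TRUE
      } else {
        out[[length(out) + 1L]] <- c(r[i], r[j])
        used[c(i, j)] <- TRUE
      }
    }
    out
  }
  zp <- pair_roots(polyroot(rev(b)))
  pp <- pair_roots(polyroot(rev(a)))
  n_sec <- max(length(zp), length(pp))
  kroot <- abs(k)^(1 / n_sec) * sign(k)
  lapply(seq_len(n_sec), function(i) {
    bz <- if (i <= length(zp)) Re(poly_from_roots(zp[[i]])) else 1
    az <- if (i <= length(pp)) Re(poly_from_roots(pp[[i]])) else 1
    signal::Arma(b = kroot * bz, a = az)
  })
}

#' @noRd
filtfilt_sos <- function(sos, x) {
  for (s in sos) x <- signal::filtfilt(s, x)
  x
}

# Zero-phase Butterworth cascade: high-pass + low-pass implement the
# band-pass (numerically safer than one 8th-order transfer function at a
# 0.004 normalized edge), then the band-stop notch; each run as biquads.
#' @noRd
design_filters <- function(fs, bandpass, bandstop, bp_order = 4L, bs_order = 2L) {
  nyq <- fs / 2
  if (any(c(bandpass, bandstop) <= 0) || any(c(bandpass, bandstop) >= nyq)) {
    stop("band edges must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  list(hp = tf_to_sos(signal::butter(bp_order, bandpass[1] / nyq, type = "high")),
       lp = tf_to_sos(signal::butter(bp_order, bandpass[2] / nyq, type = "low")),
       bs = tf_to_sos(signal::butter(bs_order, bandstop / nyq, type = "stop")))
}

#' Zero-phase band filtering
#'
#' Applies a 4th-order Butterworth band-pass (as a high-pass/low-pass cascade)
#' and a 2nd-order Butterworth band-stop, each forward-backward (zero phase),
#' to every channel (and to the deoxyhemoglobin matrix when present). The
#' defaults pass 0.021-0.6 Hz and notch the Mayer-wave band 0.08-0.12 Hz,
#' suppressing cardiac (~1 Hz) and blood-pressure (~0.1 Hz) oscillations.
#'
#' @param rec A concentration [nirs_recording()].
#' @param bandpass Pass-band edges in Hz (default `c(0.021, 0.6)`).
#' @param bandstop Stop-band edges in Hz (default `c(0.08, 0.12)`).
#' @return The filtered recording.
#' @export
apply_filters <- function(rec, bandpass = c(0.021, 0.6),
                          bandstop = c(0.08, 0.12)) {
  stopifnot(inherits(rec, "nirs_recording"))
  fs <- rec$sample_rate
  if (fs <= 2 * bandpass[2]) {
    stop("sampling rate must exceed twice the upper pass edge", call. = FALSE)
  }
  flt <- design_filters(fs, bandpass, bandstop)
  filt1 <- function(v) {
    v <- filtfilt_sos(flt$hp, v)
    v <- filtfilt_sos(flt$lp, v)
    filtfilt_sos(flt$bs, v)
  }
  rec$channels <- apply(rec$channels, 2L, filt1)
  if (!is.null(rec$dhbr)) rec$dhbr <- apply(rec$dhbr, 2L, filt1)
  rec
}

#' Full preprocessing chain
#'
#' Beer-Lambert conversion (when the input is optical), artifact detection and
#' spline repair, then zero-phase band filtering.
#'
#' @param rec A [nirs_recording()].
#' @param dpf,distance Passed to [beer_lambert()].
#' @param window,threshold Passed to [detect_artifacts()].
#' @param bandpass,bandstop Passed to [apply_filters()].
#' @return A cleaned concentration [nirs_recording()]; the artifact mask is
#'   attached as attribute `"artifact_mask"`.
#' @export
preprocess_nirs <- function(rec, dpf = 6, distance = 30,
                            window = 10L, threshold = 5,
                            bandpass = c(0.021, 0.6), bandstop = c(0.08, 0.12)) {
  if (rec$signal_kind == "optical_density") {
    rec <- beer_lambert(rec, dpf = dpf, distance = distance)
  }
  mask <- detect_artifacts(rec, window = window, threshold = threshold)
  rec <- repair_spline(rec, mask)
  rec <- apply_filters(rec, bandpass = bandpass, bandstop = bandstop)
  attr(rec, "artifact_mask") <- mask
  rec
}
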
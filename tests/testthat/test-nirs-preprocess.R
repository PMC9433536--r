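# Beer-Lambert conversion, artifact detection/repair, zero-phase filtering.

test_that("Beer-Lambert inverts its own forward model", {
  regions <- stats::setNames(rep("LPFC", 4), sprintf("c%d", 1:4))
  zero <- nirs_recording(t = (0:19) / 11, channels = matrix(0, 20, 12),
                         signal_kind = "optical_density",
                         channel_regions = regions,
                         wavelengths = c(740, 808, 850))
  h0 <- beer_lambert(zero)
  expect_true(all(h0$channels == 0) && all(h0$dhbr == 0))

  set.seed(5)
  for (i in 1:10) {
    dhbo <- matrix(rnorm(80), 20, 4)
    dhbr <- matrix(rnorm(80), 20, 4)
    od <- nirsconn:::beer_lambert_forward(dhbo, dhbr)
    rec <- nirs_recording(t = (0:19) / 11, channels = od,
                          signal_kind = "optical_density",
                          channel_regions = regions,
                          wavelengths = c(740, 808, 850))
    h <- beer_lambert(rec)
    expect_lt(max(abs(h$channels - dhbo)), 1e-10)
    expect_lt(max(abs(h$dhbr - dhbr)), 1e-10)

    # linearity: doubling the optical densities doubles the concentrations
    rec2 <- rec; rec2$channels <- 2 * rec$channels
    h2 <- beer_lambert(rec2)
    expect_equal(h2$channels, 2 * h$channels, tolerance = 1e-12)
  }
  bad <- nirs_recording(t = (0:19) / 11, channels = matrix(0, 20, 8),
                        signal_kind = "optical_density",
                        channel_regions = regions,
                        wavelengths = c(808, 808))
  expect_error(beer_lambert(bad), "singular")
})

test_that("moving-SD artifact detection matches a per-window oracle", {
  # constant series: nothing flagged
  rec <- make_conc_recording(matrix(3, 200, 2))
  m <- detect_artifacts(rec)
  expect_false(any(m$flagged))

  # a large step is flagged and the flagged run covers the step sample
  set.seed(1)
  x <- rnorm(300, 0, 0.5)
  k <- 150L
  x[k:300] <- x[k:300] + 100
  rec <- make_conc_recording(cbind(x, rnorm(300, 0, 0.5)))
  m <- detect_artifacts(rec, window = 10L, threshold = 5)
  expect_true(m$flagged[k, 1])
  expect_false(any(m$flagged[, 2]))
  # every sample covered by an exceeding window (oracle) is flagged
  oms <- oracle_moving_sd(x, 10L)
  expect_true(all(m$flagged[which(oms > 5), 1]))
  # segments are half-open, non-overlapping, within bounds, consistent with flags
  seg <- m$segments[[1]]
  expect_true(all(seg$end > seg$start) && all(seg$start >= 1) && all(seg$end <= 301))
  covered <- logical(300)
  for (j in seq_len(nrow(seg))) covered[seg$start[j]:(seg$end[j] - 1L)] <- TRUE
  expect_identical(covered, m$flagged[, 1])

  # exceedance is strict: max moving SD exactly at threshold is not flagged
  y <- rep(0, 60)
  y[30] <- 1
  # boundary convention probed at the exact computed maximum
  tau <- max(nirsconn:::moving_sd(y, 10L), na.rm = TRUE)
  expect_equal(tau, max(oracle_moving_sd(y, 10L), na.rm = TRUE), tolerance = 1e-12)
  m2 <- detect_artifacts(make_conc_recording(cbind(y)), window = 10L,
                         threshold = tau, pad_s = 0)
  expect_false(any(m2$flagged))

  expect_error(detect_artifacts(make_conc_recording(cbind(y)), window = 100L),
               "longer")
})

test_that("spline repair is exact on polynomials, local, and idempotent", {
  # empty mask: identity
  rec <- make_conc_recording(cbind(seq(0, 10, length.out = 120)))
  m0 <- detect_artifacts(rec, threshold = 1e6)
  expect_identical(repair_spline(rec, m0)$channels, rec$channels)

  # single spike on a linear ramp: repaired to the ramp value
  ramp <- seq(0, 10, length.out = 120)
  x <- ramp; x[60] <- 50
  rec <- make_conc_recording(cbind(x))
  m <- detect_artifacts(rec, window = 10L, threshold = 2, pad_s = 0.5)
  expect_true(m$flagged[60, 1])
  rep1 <- repair_spline(rec, m)
  expect_lt(max(abs(rep1$channels[, 1] - ramp)), 1e-9)
  # unflagged samples unchanged bit-for-bit
  expect_identical(rep1$channels[!m$flagged[, 1], 1], x[!m$flagged[, 1]])
  # idempotence under the same mask
  expect_identical(repair_spline(rep1, m)$channels, rep1$channels)

  # spike on a slow sinusoid: repaired value within the clean-neighbor envelope
  set.seed(3)
  for (i in 1:10) {
    t <- (0:199) / 11
    s <- sin(2 * pi * 0.04 * t + runif(1, 0, 2 * pi))
    x <- s; k <- sample(50:150, 1); x[k] <- x[k] + 30
    rec <- make_conc_recording(cbind(x))
    m <- detect_artifacts(rec, window = 10L, threshold = 2, pad_s = 0.2)
    rep2 <- repair_spline(rec, m)
    seg <- m$segments[[1]]
    clean <- which(!m$flagged[, 1])
    for (j in seq_len(nrow(seg))) {
      nb <- c(utils::tail(clean[clean < seg$start[j]], 4),
              utils::head(clean[clean >= seg$end[j]], 4))
      env <- range(x[nb]) + c(-1, 1) * 0.35 * diff(range(x[nb]))
      vals <- rep2$channels[seg$start[j]:(seg$end[j] - 1L), 1]
      expect_true(all(vals >= env[1] & vals <= env[2]))
    }
  }
})

test_that("zero-phase filters meet the pass/stop specification", {
  fs <- 11
  t <- seq(0, 1200, by = 1 / fs)
  gain <- function(f) {
    x <- sin(2 * pi * f * t)
    rec <- make_conc_recording(cbind(x), fs = fs)
    y <- apply_filters(rec)$channels[, 1]
    mid <- seq(floor(length(t) * 0.25), floor(length(t) * 0.75))
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_gt(gain(0.05), 0.95)                 # passband within 5%
  expect_lt(20 * log10(gain(1)), -20)         # cardiac
  expect_lt(20 * log10(gain(0.10)), -20)      # Mayer-band center
  expect_error(apply_filters(make_conc_recording(cbind(sin(t)), fs = 11),
                             bandpass = c(0.021, 6)), "Nyquist|exceed")
})

test_that("filtering is linear", {
  set.seed(8)
  x <- rnorm(800); y <- rnorm(800)
  a <- 2.5; b <- -1.25
  f <- function(v) apply_filters(make_conc_recording(cbind(v)))$channels[, 1]
  expect_lt(max(abs(f(a * x + b * y) - (a * f(x) + b * f(y)))), 1e-9)
})

test_that("generator physiology is suppressed while the task band survives", {
  des <- cohort_design()
  gt <- nirs_ground_truth(n_channels = 2, activation_amplitude = 1, lf_amp = 0,
                          noise_sd = 0, cardiac_amp = 0.5, resp_amp = 0,
                          mayer_amp = 0.5)
  regions <- stats::setNames(c("LMC", "RMC"), c("ch01", "ch02"))
  rec <- gen_nirs_recording(des, gt, seed = 2, conditions = "RHCW", n_blocks = 6,
                            channel_regions = regions)
  gt_task <- gt; gt_task$cardiac_amp <- 0; gt_task$mayer_amp <- 0
  task_only <- gen_nirs_recording(des, gt_task, seed = 2, conditions = "RHCW",
                                  n_blocks = 6, channel_regions = regions)
  band_power <- function(x, f, half = 0.02) {
    sp <- Mod(stats::fft(x - mean(x)))^2
    fr <- (seq_along(x) - 1) * 11 / length(x)
    sum(sp[abs(fr - f) < half])
  }
  filt <- apply_filters(rec)
  x0 <- rec$channels[, 1]; x1 <- filt$channels[, 1]
  expect_lt(band_power(x1, 1) / band_power(x0, 1), 0.10)
  expect_lt(band_power(x1, 0.1) / band_power(x0, 0.1), 0.10)
  # the HRF-band task component keeps at least 80% of its power
  task_filt <- apply_filters(task_only)
  p_in <- sum((task_only$channels[, 1] - mean(task_only$channels[, 1]))^2)
  p_out <- sum((task_filt$channels[, 1] - mean(task_filt$channels[, 1]))^2)
  expect_gt(p_out / p_in, 0.8)
})

test_that("full preprocessing leaves no missing values and keeps shape", {
  des <- cohort_design()
  gt <- nirs_ground_truth(n_channels = 6, noise_sd = 0.2, artifact_rate = 3)
  rec <- gen_nirs_recording(des, gt, seed = 7, conditions = c("RHCW", "LHCW"),
                            n_blocks = 2,
                            channel_regions = default_channel_regions(6))
  out <- preprocess_nirs(rec)
  expect_false(anyNA(out$channels))
  expect_identical(dim(out$channels), dim(rec$channels))
  expect_s3_class(attr(out, "artifact_mask"), "artifact_mask")
})
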
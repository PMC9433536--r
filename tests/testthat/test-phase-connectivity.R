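# Morlet wavelet phase extraction, PLV, and the connectivity threshold.

make_sine_recording <- function(signals, fs = 11) {
  make_conc_recording(do.call(cbind, signals), fs = fs)
}

test_that("band specifications are validated", {
  lf <- band_spec("LF")
  expect_equal(c(lf$f_lo, lf$f_hi), c(0.021, 0.145))
  hf <- band_spec("HF")
  expect_equal(c(hf$f_lo, hf$f_hi), c(0.145, 0.6))
  expect_length(lf$freqs, 20)
  expect_true(all(diff(lf$freqs) > 0))
  expect_error(band_spec(f_lo = 0.2, f_hi = 0.1), "f_lo < f_hi")
})

test_that("wavelet phase advances at the stimulus frequency", {
  fs <- 11
  t <- (0:2399) / fs
  f0 <- 0.07
  rec <- make_sine_recording(list(cos(2 * pi * f0 * t), sin(2 * pi * f0 * t)))
  pm <- cwt_phase(rec, band_spec("LF"))
  j <- which.min(abs(pm$freqs - f0))
  keep <- !pm$in_coi[, j]
  ph <- nirsconn:::unwrap_phase(pm$phase[keep, 1, j])
  slope <- stats::coef(stats::lm(ph ~ t[keep]))[[2]]
  expect_lt(abs(slope - 2 * pi * f0) / (2 * pi * f0), 0.02)

  # cos leads sin by pi/2
  d <- pm$phase[keep, 1, j] - pm$phase[keep, 2, j]
  expect_lt(abs(mean(atan2(sin(d), cos(d))) - pi / 2), 0.05)

  # amplitude ridge sits within one grid step of f0
  ridge <- pm$freqs[which.max(colMeans(pm$amplitude[keep, 1, ]))]
  step <- pm$freqs[j + 1] / pm$freqs[j]
  expect_lt(abs(log(ridge / f0)), log(step) * 1.5)

  expect_error(cwt_phase(make_sine_recording(list(cos(t[1:100]))), band_spec("LF")),
               "too short")
})

test_that("PLV follows its closed-form special cases", {
  set.seed(2)
  phi <- runif(500, -pi, pi)
  expect_equal(plv_pair(phi, phi), 1, tolerance = 1e-12)
  expect_equal(plv_pair(phi, phi + 1.3), 1, tolerance = 1e-12)
  expect_error(plv_pair(numeric(0), numeric(0)), "nonempty")
  expect_error(plv_pair(phi, phi[-1]), "equal length")

  # invariance to a common added phase series and range [0, 1]
  for (i in 1:20) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi); cmn <- rnorm(200)
    v <- plv_pair(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(plv_pair(a + cmn, b + cmn), v, tolerance = 1e-12)
  }

  # independent uniform phases: resultant near sqrt(pi)/2 / sqrt(n)
  n <- 1e4
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    plv_pair(runif(n, -pi, pi), runif(n, -pi, pi))
  }, numeric(1))
  expect_lt(abs(mean(vals) - sqrt(pi) / 2 / sqrt(n)), 0.5 * sqrt(pi) / 2 / sqrt(n))
})

test_that("connectivity matrices are symmetric with unit diagonal", {
  fs <- 11
  t <- (0:2199) / fs
  x <- cos(2 * pi * 0.06 * t)
  rec <- make_sine_recording(list(x, x))
  net <- connectivity_matrix(cwt_phase(rec, band_spec("LF", n_freqs = 8L)))
  expect_equal(net$plv, matrix(1, 2, 2, dimnames = dimnames(net$plv)),
               tolerance = 1e-9)

  set.seed(6)
  sig <- lapply(1:4, function(i) cumsum(rnorm(length(t), 0, 0.3)))
  net2 <- connectivity_matrix(cwt_phase(make_sine_recording(sig),
                                        band_spec("LF", n_freqs = 8L)))
  expect_lt(max(abs(net2$plv - t(net2$plv))), 1e-12)
  expect_true(all(diag(net2$plv) == 1))
  expect_true(all(net2$plv >= 0 & net2$plv <= 1))
})

test_that("an injected coupled pair carries the strongest connection", {
  des <- cohort_design()
  regions <- default_channel_regions(6)
  hits <- vapply(1:20, function(s) {
    coup <- matrix(0, 6, 6)
    coup[1, 2] <- coup[2, 1] <- 1
    gt <- nirs_ground_truth(n_channels = 6, activation_amplitude = 0,
                            coupling = coup, cardiac_amp = 0, resp_amp = 0,
                            mayer_amp = 0, noise_sd = 0.02)
    rec <- gen_nirs_recording(des, gt, seed = s, conditions = "RHCW",
                              n_blocks = 8, channel_regions = regions)
    plv <- connectivity_matrix(cwt_phase(rec, band_spec("LF", n_freqs = 8L)))$plv
    off <- plv[upper.tri(plv)]
    plv[1, 2] == max(off)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("threshold keeps the largest connectivity-preserving cutoff", {
  # K3 worked example
  w <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.5, 0.2, 0.5, 1), 3, 3)
  net <- random_weighted_network(3)
  net$plv <- w
  tc <- threshold_connected(net)
  expect_equal(tc$threshold, 0.5)
  expect_identical(sum(tc$adjacency) / 2, 2)
  expect_false(tc$adjacency[1, 3])

  # uniform weights retain the complete graph
  netu <- random_weighted_network(5)
  netu$plv <- matrix(0.4, 5, 5); diag(netu$plv) <- 1
  tcu <- threshold_connected(netu)
  expect_identical(sum(tcu$adjacency) / 2, choose(5, 2))

  # bottleneck equals the exhaustive sweep oracle; graph stays connected
  set.seed(9)
  for (i in 1:40) {
    net <- random_weighted_network(8)
    tc <- threshold_connected(net)
    expect_equal(tc$threshold, oracle_bottleneck_threshold(net$plv),
                 tolerance = 1e-15)
    expect_true(oracle_connected(tc$adjacency * 1))
    expect_false(any(diag(tc$adjacency)))
    expect_identical(tc$adjacency, t(tc$adjacency))
  }
})

test_that("task concatenation keeps only in-task samples", {
  des <- cohort_design()
  gt <- nirs_ground_truth(n_channels = 2, noise_sd = 0.1)
  rec <- gen_nirs_recording(des, gt, seed = 1, conditions = c("LCRC", "LCRW"),
                            n_blocks = 2,
                            channel_regions = stats::setNames(c("LPFC", "RPFC"),
                                                              c("ch01", "ch02")))
  cc <- concat_task(rec, "LCRC")
  ev <- rec$events[rec$events$condition == "LCRC", ]
  n_expect <- sum(rec$t >= ev$onset[1] & rec$t < ev$onset[1] + ev$duration[1]) +
    sum(rec$t >= ev$onset[2] & rec$t < ev$onset[2] + ev$duration[2])
  expect_identical(nrow(cc$channels), n_expect)
  expect_error(concat_task(rec, "ZZZ"), "no events")
})
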
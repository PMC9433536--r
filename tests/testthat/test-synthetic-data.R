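# Synthetic cohort generator: ground-truth recovery, determinism, spectra.

test_that("noiseless generated circle matches the guide exactly", {
  gt <- trajectory_ground_truth(guide_radius = 1)
  p <- to_polar(gen_trajectory(gt, duration = 12, rate = 100, seed = 1))
  expect_lt(radius_error(p), 1e-12)
  expect_lt(radius_sd(p), 1e-12)
  expect_lt(angvel_error(p), 1e-9)   # interior finite differences of a linear angle
})

test_that("constant radius bias appears one-for-one in the radius error", {
  gt <- trajectory_ground_truth(guide_radius = 1, radius_bias = 0.5)
  p <- to_polar(gen_trajectory(gt, duration = 12, rate = 28.5, seed = 3))
  expect_equal(radius_error(p), 0.5, tolerance = 1e-12)
})

test_that("with radial noise sd sigma the mean radius error converges to sigma", {
  sigma <- 0.2
  n <- 1e4
  gt <- trajectory_ground_truth(radius_noise_sd = sigma)
  re <- vapply(1:20, function(s) {
    radius_error(to_polar(gen_trajectory(gt, duration = n / 28.5, rate = 28.5,
                                         seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(re) - sigma), 3 * sigma / sqrt(2 * n))
})

test_that("identical seeds give bit-identical outputs, different seeds differ", {
  gt <- trajectory_ground_truth(radius_noise_sd = 0.1, angvel_noise_sd = 0.1)
  expect_identical(gen_trajectory(gt, 12, 28.5, seed = 9),
                   gen_trajectory(gt, 12, 28.5, seed = 9))
  expect_false(identical(gen_trajectory(gt, 12, 28.5, seed = 9)$x,
                         gen_trajectory(gt, 12, 28.5, seed = 10)$x))

  des <- cohort_design(n_subjects = 2, n_blocks_per_condition = 1)
  ngt <- nirs_ground_truth(n_channels = 6, noise_sd = 0.1, artifact_rate = 2)
  expect_identical(gen_nirs_recording(des, ngt, seed = 5, conditions = "RHCW"),
                   gen_nirs_recording(des, ngt, seed = 5, conditions = "RHCW"))

  spec <- stats::setNames(lapply(des$conditions, function(cc) {
    list(trajectory = trajectory_ground_truth(radius_bias = 0.1),
         nirs = nirs_ground_truth(n_channels = 6))
  }), des$conditions)
  c1 <- gen_cohort(des, spec, realize = TRUE, trials_per_condition = 1)
  c2 <- gen_cohort(des, spec, realize = TRUE, trials_per_condition = 1)
  expect_identical(c1, c2)
})

test_that("empty cohort and missing conditions are handled", {
  des <- cohort_design(n_subjects = 0)
  spec <- stats::setNames(lapply(des$conditions, function(cc) {
    list(trajectory = trajectory_ground_truth(),
         nirs = nirs_ground_truth(n_channels = 6))
  }), des$conditions)
  ch <- gen_cohort(des, spec)
  expect_length(ch$subjects, 0)
  expect_identical(nrow(ch$truth), 0L)
  expect_error(gen_cohort(cohort_design(n_subjects = 1), spec["LHCW"]),
               "missing conditions")
})

test_that("physiological components peak at their nominal frequencies", {
  des <- cohort_design(n_blocks_per_condition = 6)
  gt <- nirs_ground_truth(n_channels = 2, activation_amplitude = 0, lf_amp = 0,
                          noise_sd = 0, cardiac_amp = 1, resp_amp = 0, mayer_amp = 0)
  for (comp in list(list(f = 1, amps = c(1, 0, 0)),
                    list(f = 0.25, amps = c(0, 1, 0)),
                    list(f = 0.1, amps = c(0, 0, 1)))) {
    gt$cardiac_amp <- comp$amps[1]
    gt$resp_amp <- comp$amps[2]
    gt$mayer_amp <- comp$amps[3]
    rec <- gen_nirs_recording(des, gt, seed = 1, conditions = "RHCW",
                              channel_regions = stats::setNames(c("LPFC", "RPFC"),
                                                                c("ch01", "ch02")))
    sp <- stats::spec.pgram(stats::ts(rec$channels[, 1], frequency = 11),
                            plot = FALSE, taper = 0)
    fpeak <- sp$freq[which.max(sp$spec)]
    expect_lt(abs(fpeak - comp$f) / comp$f, 0.10)
  }
})

test_that("generator coupling maps monotonically to measured LF-band PLV", {
  des <- cohort_design()
  plv_at <- function(kappa, seed) {
    coup <- matrix(kappa, 2, 2); diag(coup) <- 0
    gt <- nirs_ground_truth(n_channels = 2, activation_amplitude = 0,
                            coupling = coup, cardiac_amp = 0, resp_amp = 0,
                            mayer_amp = 0, noise_sd = 0)
    rec <- gen_nirs_recording(des, gt, seed = seed, conditions = "RHCW",
                              n_blocks = 20,
                              channel_regions = stats::setNames(c("LPFC", "RPFC"),
                                                                c("ch01", "ch02")))
    pm <- cwt_phase(rec, band_spec("LF", n_freqs = 8L))
    connectivity_matrix(pm)$plv[1, 2]
  }
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(kappas, function(k) {
    mean(vapply(1:12, function(s) plv_at(k, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(means[5], 1, tolerance = 1e-6)
})

test_that("uncoupled-pair PLV shrinks roughly as the square root of record length", {
  des <- cohort_design()
  plv_len <- function(n_blocks, seed) {
    gt <- nirs_ground_truth(n_channels = 2, activation_amplitude = 0,
                            coupling = 0, cardiac_amp = 0, resp_amp = 0,
                            mayer_amp = 0, noise_sd = 0)
    rec <- gen_nirs_recording(des, gt, seed = seed, conditions = "RHCW",
                              n_blocks = n_blocks,
                              channel_regions = stats::setNames(c("LPFC", "RPFC"),
                                                                c("ch01", "ch02")))
    # phase of the LF carrier extracted directly at the carrier frequency
    pm <- cwt_phase(rec, band_spec("LF", f_lo = 0.04, f_hi = 0.06, n_freqs = 3L))
    connectivity_matrix(pm)$plv[1, 2]
  }
  short <- mean(vapply(1:15, function(s) plv_len(10, s), numeric(1)))
  long <- mean(vapply(1:15, function(s) plv_len(40, s + 100), numeric(1)))
  ratio <- short / long
  expect_gt(ratio, 1.2)          # decreasing in record length
  expect_lt(ratio, 4)            # consistent with ~n^(-1/2) scaling (x4 length)
})

test_that("invalid generator arguments are rejected", {
  expect_error(gen_trajectory(trajectory_ground_truth(), duration = -1, rate = 28.5),
               "positive")
  expect_error(gen_trajectory(trajectory_ground_truth(), duration = 0.1, rate = 10),
               "8 samples")
  bad <- matrix(runif(36), 6, 6)
  expect_error(nirs_ground_truth(n_channels = 6, coupling = bad), "symmetric")
  expect_error(trajectory_ground_truth(radius_noise_sd = -1), ">= 0")
  expect_error(cohort_design(conditions = c("A", "A")), "unique")
})
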
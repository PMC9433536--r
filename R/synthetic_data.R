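# Synthetic cohort generator.
#
# Emulates a block-design bimanual circle-drawing study: 21 subjects perform 8
# movement conditions (unilateral left/right x clockwise/counterclockwise, and
# bilateral in-phase / anti-phase combinations) in repeated block units, with
# tablet trajectories sampled at 28.5 Hz and 30-channel fNIRS at 11 Hz over six
# cortical regions. All ground truth (radius bias, activation amplitudes,
# low-frequency phase coupling, physiological noise) is injected and recorded,
# so every downstream stage can be validated against known parameters.

STUDY_CONDITIONS <- c("LHCW", "LHCC", "RHCW", "RHCC",
                      "LCRC", "LWRW", "LCRW", "LWRC")

#' Default 30-channel to 6-region map
#'
#' Five channels per region: left/right prefrontal cortex (LPFC, RPFC),
#' left/right motor cortex (LMC, RMC), left/right occipital lobe (LOL, ROL).
#'
#' @param n_channels Total channel count (must be divisible by 6).
#' @return Named character vector mapping channel name to region.
#' @export
default_channel_regions <- function(n_channels = 30L) {
  regions <- c("LPFC", "RPFC", "LMC", "RMC", "LOL", "ROL")
  if (n_channels %% length(regions) != 0L) {
    stop("`n_channels` must be divisible by 6", call. = FALSE)
  }
  per <- n_channels / length(regions)
  stats::setNames(rep(regions, each = per),
                  sprintf("ch%02d", seq_len(n_channels)))
}

#' Cohort design
#'
#' The experimental skeleton: subjects, condition codes, block counts, task and
#' rest durations, and the two sampling rates.
#'
#' @param n_subjects Number of subjects (study default 21).
#' @param conditions Character vector of unique condition codes (default the 8
#'   study conditions).
#' @param n_blocks_per_condition Blocks per condition (study default 10).
#' @param task_duration_s,rest_duration_s Task and inter-trial rest durations
#'   in seconds (defaults 12 and 15).
#' @param nirs_rate_hz,traj_rate_hz Sampling rates in Hz (defaults 11, 28.5).
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 21L,
                          conditions = STUDY_CONDITIONS,
                          n_blocks_per_condition = 10L,
                          task_duration_s = 12, rest_duration_s = 15,
                          nirs_rate_hz = 11, traj_rate_hz = 28.5,
                          seed = 1L) {
  if (n_subjects < 0) stop("`n_subjects` must be >= 0", call. = FALSE)
  if (anyDuplicated(conditions)) stop("condition codes must be unique", call. = FALSE)
  for (nm in c("task_duration_s", "rest_duration_s", "nirs_rate_hz", "traj_rate_hz")) {
    check_positive_scalar(get(nm), nm)
  }
  if (n_blocks_per_condition < 1) stop("need >= 1 block per condition", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), conditions = conditions,
         n_blocks_per_condition = as.integer(n_blocks_per_condition),
         task_duration_s = task_duration_s, rest_duration_s = rest_duration_s,
         nirs_rate_hz = nirs_rate_hz, traj_rate_hz = traj_rate_hz,
         seed = as.integer(seed)),
    class = "cohort_design")
}

#' Trajectory ground truth
#'
#' Parameters of the generated circle: guide radius and angular velocity (the
#' displayed target), plus injected radius bias, radius noise and
#' angular-velocity noise.
#'
#' @param guide_radius Guide radius, length units (> 0).
#' @param guide_angular_velocity Magnitude of the guide angular velocity in
#'   rad/s (> 0); sign comes from `direction`.
#' @param radius_bias Constant radial offset of the drawn circle.
#' @param radius_noise_sd,angvel_noise_sd Gaussian noise SDs (>= 0).
#' @param direction `"counterclockwise"` (positive angle) or `"clockwise"`.
#' @return Object of class `trajectory_ground_truth`.
#' @export
trajectory_ground_truth <- function(guide_radius = 1,
                                    guide_angular_velocity = pi / 2,
                                    radius_bias = 0,
                                    radius_noise_sd = 0,
                                    angvel_noise_sd = 0,
                                    direction = c("counterclockwise", "clockwise")) {
  check_positive_scalar(guide_radius, "guide_radius")
  check_positive_scalar(guide_angular_velocity, "guide_angular_velocity")
  if (radius_noise_sd < 0 || angvel_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  direction <- match.arg(direction)
  structure(
    list(guide_radius = guide_radius,
         guide_angular_velocity = guide_angular_velocity,
         radius_bias = radius_bias, radius_noise_sd = radius_noise_sd,
         angvel_noise_sd = angvel_noise_sd, direction = direction),
    class = "trajectory_ground_truth")
}

#' fNIRS ground truth
#'
#' Injected structure of a synthetic hemoglobin recording: per-channel task
#' activation amplitude, pairwise low-frequency (LF) phase-coupling strengths,
#' physiological oscillation frequencies and amplitudes, white-noise SD and a
#' motion-artifact rate.
#'
#' Phase coupling is realized by convex mixing of one shared band-limited phase
#' process into each channel's LF oscillation: channel k receives mixing weight
#' `sqrt(max_j coupling[k, j])`, so a block-uniform coupling matrix with value
#' kappa yields pairwise phase-difference attenuation by `1 - kappa` inside the
#' block. Arbitrary (non-block) pairwise targets are approximated, not matched
#' exactly.
#'
#' @param n_channels Channel count (default 30).
#' @param activation_amplitude Per-channel amplitude (concentration units) of
#'   the task response; scalar, length-`n_channels` vector, or channels x
#'   conditions matrix.
#' @param coupling Symmetric zero-diagonal matrix in \\[0, 1\\] of pairwise LF
#'   coupling strengths; scalar shorthand fills all off-diagonal entries.
#' @param cardiac_freq_hz,resp_freq_hz,mayer_freq_hz Physiological frequencies
#'   (defaults 1, 0.25, 0.1 Hz).
#' @param cardiac_amp,resp_amp,mayer_amp Their amplitudes (concentration units).
#' @param lf_freq_hz,lf_amp Carrier frequency (default 0.05 Hz, inside the LF
#'   band and outside the Mayer stop band) and amplitude of the coupled LF
#'   oscillation.
#' @param phase_diffusion_sd Innovation SD of the channel phase processes, in
#'   rad per sqrt(second); controls how fast uncoupled channels decorrelate.
#' @param physio_coherent If `TRUE` (default) the physiological sinusoids use
#'   one random phase per component per recording, shared across channels, as
#'   systemic circulatory oscillations are; `FALSE` draws independent
#'   per-channel phases.
#' @param artifact_rate Motion-artifact events per minute.
#' @param artifact_amp Amplitude of injected spike/step artifacts.
#' @param noise_sd White measurement-noise SD (concentration units).
#' @return Object of class `nirs_ground_truth`.
#' @export
nirs_ground_truth <- function(n_channels = 30L,
                              activation_amplitude = 1,
                              coupling = 0,
                              cardiac_freq_hz = 1, resp_freq_hz = 0.25,
                              mayer_freq_hz = 0.1,
                              cardiac_amp = 0.2, resp_amp = 0.1, mayer_amp = 0.1,
                              lf_freq_hz = 0.05, lf_amp = 0.5,
                              phase_diffusion_sd = 0.6,
                              physio_coherent = TRUE,
                              artifact_rate = 0, artifact_amp = 20,
                              noise_sd = 0.05) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("need >= 1 channel", call. = FALSE)
  if (is.matrix(coupling)) {
    if (nrow(coupling) != n_channels || ncol(coupling) != n_channels) {
      stop("`coupling` must be n_channels x n_channels", call. = FALSE)
    }
    if (max(abs(coupling - t(coupling))) > 1e-12) {
      stop("`coupling` matrix must be symmetric", call. = FALSE)
    }
    if (any(diag(coupling) != 0)) stop("`coupling` diagonal must be 0", call. = FALSE)
    if (any(coupling < 0 | coupling > 1)) {
      stop("`coupling` entries must lie in [0, 1]", call. = FALSE)
    }
  } else {
    k <- coupling
    if (length(k) != 1L || k < 0 || k > 1) {
      stop("scalar `coupling` must lie in [0, 1]", call. = FALSE)
    }
    coupling <- matrix(k, n_channels, n_channels)
    diag(coupling) <- 0
  }
  if (!is.matrix(activation_amplitude) && !(length(activation_amplitude) %in% c(1L, n_channels))) {
    stop("`activation_amplitude` must be scalar, per-channel, or a matrix", call. = FALSE)
  }
  structure(
    list(n_channels = n_channels, activation_amplitude = activation_amplitude,
         coupling = coupling,
         cardiac_freq_hz = cardiac_freq_hz, resp_freq_hz = resp_freq_hz,
         mayer_freq_hz = mayer_freq_hz,
         cardiac_amp = cardiac_amp, resp_amp = resp_amp, mayer_amp = mayer_amp,
         lf_freq_hz = lf_freq_hz, lf_amp = lf_amp,
         phase_diffusion_sd = phase_diffusion_sd,
         physio_coherent = physio_coherent,
         artifact_rate = artifact_rate, artifact_amp = artifact_amp,
         noise_sd = noise_sd),
    class = "nirs_ground_truth")
}

# Run `expr` under a local RNG state seeded with `seed`; restores the caller's
# stream afterwards so cohort generation is insensitive to call order.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate one circle-drawing trial
#'
#' Draws a circle of radius `guide_radius + radius_bias` plus Gaussian radial
#' noise, traversed at the guide angular velocity plus Gaussian velocity noise
#' (integrated to angle), signed by direction.
#'
#' @param gt A [trajectory_ground_truth()].
#' @param duration Trial duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param hand,condition,trial,center Metadata passed to [trajectory_trace()].
#' @return A [trajectory_trace()]; the ground truth is attached as attribute
#'   `"ground_truth"`.
#' @export
gen_trajectory <- function(gt, duration, rate, seed = 1L,
                           hand = "right", condition = "RHCW", trial = 1L,
                           center = c(0, 0)) {
  stopifnot(inherits(gt, "trajectory_ground_truth"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(rate, "rate")
  n <- floor(duration * rate)
  if (n < 8L) stop("duration * rate must give at least 8 samples", call. = FALSE)
  sgn <- if (gt$direction == "clockwise") -1 else 1
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / rate
    dt <- 1 / rate
    w <- sgn * (gt$guide_angular_velocity +
                  if (gt$angvel_noise_sd > 0) stats::rnorm(n, 0, gt$angvel_noise_sd) else numeric(n))
    theta <- c(0, cumsum(w[-n] * dt))
    r <- gt$guide_radius + gt$radius_bias +
      if (gt$radius_noise_sd > 0) stats::rnorm(n, 0, gt$radius_noise_sd) else 0
    tr <- trajectory_trace(
      t = t, x = center[1] + r * cos(theta), y = center[2] + r * sin(theta),
      hand = hand, condition = condition, center = center,
      guide_radius = gt$guide_radius,
      guide_angular_velocity = sgn * gt$guide_angular_velocity,
      trial = trial)
    attr(tr, "ground_truth") <- gt
    tr
  })
}

# Block timeline: leading rest, then for each block unit each condition's
# task + rest, matching the study's interleaved block structure.
#' @noRd
block_events <- function(conditions, n_blocks, task_s, rest_s) {
  onsets <- numeric(0); conds <- character(0)
  t0 <- rest_s
  for (b in seq_len(n_blocks)) {
    for (cc in conditions) {
      onsets <- c(onsets, t0); conds <- c(conds, cc)
      t0 <- t0 + task_s + rest_s
    }
  }
  data.frame(onset = onsets, duration = task_s, condition = conds,
             stringsAsFactors = FALSE)
}

# Band-limited diffusing phase process: integrated Gaussian increments,
# smoothed by a moving average of `smooth_s` seconds so instantaneous
# frequency excursions stay slow relative to the LF carrier.
#' @noRd
phase_process <- function(n, fs, sd_per_sqrt_s, smooth_s = 2) {
  inc <- stats::rnorm(n, 0, sd_per_sqrt_s / sqrt(fs))
  k <- max(1L, round(smooth_s * fs))
  if (k > 1L) inc <- stats::filter(inc, rep(1 / k, k), sides = 2)
  inc[is.na(inc)] <- 0
  cumsum(as.numeric(inc))
}

#' Generate a synthetic multichannel hemoglobin recording
#'
#' Each channel is the sum of a task response (per-channel amplitude times the
#' HRF-convolved block boxcar), a phase-coupled low-frequency oscillation,
#' cardiac/respiratory/Mayer sinusoids with random phases, white noise, and
#' optional spike/step motion artifacts. Block onsets are recorded as events.
#' The deoxyhemoglobin series is generated as a damped, inverted copy of the
#' oxyhemoglobin task response with its own noise.
#'
#' @param design A [cohort_design()]; supplies durations and the sampling rate.
#' @param gt A [nirs_ground_truth()].
#' @param seed Integer seed.
#' @param conditions Conditions to include (default all in `design`).
#' @param n_blocks Blocks per condition (default from `design`).
#' @param channel_regions Channel to region map (default
#'   [default_channel_regions()]).
#' @return A [nirs_recording()] of kind `"concentration"` with ground truth
#'   attached as attribute `"ground_truth"`.
#' @export
gen_nirs_recording <- function(design, gt, seed = 1L,
                               conditions = design$conditions,
                               n_blocks = design$n_blocks_per_condition,
                               channel_regions = default_channel_regions(gt$n_channels)) {
  stopifnot(inherits(design, "cohort_design"), inherits(gt, "nirs_ground_truth"))
  if (length(channel_regions) != gt$n_channels) {
    stop("channel map length must equal channel count", call. = FALSE)
  }
  fs <- design$nirs_rate_hz
  events <- block_events(conditions, n_blocks,
                         design$task_duration_s, design$rest_duration_s)
  total_s <- max(events$onset + events$duration) + design$rest_duration_s
  n <- floor(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  nc <- gt$n_channels

  # per-channel x per-condition amplitude matrix
  amp <- gt$activation_amplitude
  if (!is.matrix(amp)) {
    amp <- matrix(rep_len(amp, nc), nrow = nc, ncol = length(conditions))
  }
  colnames(amp) <- conditions

  with_seed(seed, {
    task <- matrix(0, n, nc)
    hk <- canonical_hrf(seq(0, 32, by = 1 / fs))
    for (j in seq_along(conditions)) {
      ev <- events[events$condition == conditions[j], , drop = FALSE]
      reg <- hrf_regressor(t, ev$onset, ev$duration, hk = hk)
      task <- task + outer(reg, amp[, j])
    }

    # narrowband LF oscillations: a shared diffusing-phase carrier mixed into
    # each channel's independent one with variance-preserving weight sqrt(k),
    # so a block-uniform coupling k yields a shared power fraction k per pair
    kap <- pmax(apply(gt$coupling, 1L, max), 0)
    shared <- cos(2 * pi * gt$lf_freq_hz * t +
                    phase_process(n, fs, gt$phase_diffusion_sd))
    lf <- matrix(0, n, nc)
    for (k in seq_len(nc)) {
      own <- cos(2 * pi * gt$lf_freq_hz * t +
                   phase_process(n, fs, gt$phase_diffusion_sd))
      lf[, k] <- gt$lf_amp * (sqrt(kap[k]) * shared + sqrt(1 - kap[k]) * own)
    }

    # systemic oscillations: cardiac, respiratory and Mayer waves are global
    # circulatory phenomena, so one random phase per component per recording,
    # shared across channels (set physio_coherent = FALSE for independent
    # per-channel phases)
    physio <- matrix(0, n, nc)
    for (spec in list(c(gt$cardiac_freq_hz, gt$cardiac_amp),
                      c(gt$resp_freq_hz, gt$resp_amp),
                      c(gt$mayer_freq_hz, gt$mayer_amp))) {
      if (spec[2] > 0) {
        phases <- if (isTRUE(gt$physio_coherent)) {
          rep(stats::runif(1, 0, 2 * pi), nc)
        } else {
          stats::runif(nc, 0, 2 * pi)
        }
        physio <- physio + spec[2] *
          cos(outer(2 * pi * spec[1] * t, phases, `+`))
      }
    }

    noise <- if (gt$noise_sd > 0) {
      matrix(stats::rnorm(n * nc, 0, gt$noise_sd), n, nc)
    } else 0

    dhbo <- task + lf + physio + noise
    dhbr <- -0.3 * task + if (gt$noise_sd > 0) {
      matrix(stats::rnorm(n * nc, 0, gt$noise_sd / 2), n, nc)
    } else 0

    if (gt$artifact_rate > 0) {
      n_art <- stats::rpois(1, gt$artifact_rate * total_s / 60)
      for (a in seq_len(n_art)) {
        ch <- sample.int(nc, 1)
        at <- sample.int(n, 1)
        if (stats::runif(1) < 0.5) {            # spike, ~0.3 s
          span <- at:min(n, at + max(1L, round(0.3 * fs)))
          dhbo[span, ch] <- dhbo[span, ch] + gt$artifact_amp
        } else {                                # baseline step
          dhbo[at:n, ch] <- dhbo[at:n, ch] + gt$artifact_amp *
            sign(stats::rnorm(1))
        }
      }
    }

    colnames(dhbo) <- colnames(dhbr) <- names(channel_regions)
    rec <- nirs_recording(t = t, channels = dhbo,
                          signal_kind = "concentration",
                          channel_regions = channel_regions,
                          events = events, dhbr = dhbr)
    attr(rec, "ground_truth") <- gt
    rec
  })
}

# Map a condition code to the hands involved and their directions.
#' @noRd
condition_hands <- function(code) {
  if (grepl("^LH", code)) {
    data.frame(hand = "left",
               direction = if (grepl("CW$", code)) "clockwise" else "counterclockwise",
               stringsAsFactors = FALSE)
  } else if (grepl("^RH", code)) {
    data.frame(hand = "right",
               direction = if (grepl("CW$", code)) "clockwise" else "counterclockwise",
               stringsAsFactors = FALSE)
  } else {
    # bilateral codes: L<d>R<d> with C = clockwise, W = counterclockwise
    dirs <- c(C = "clockwise", W = "counterclockwise")
    data.frame(hand = c("left", "right"),
               direction = c(dirs[[substr(code, 2, 2)]],
                             dirs[[substr(code, 4, 4)]]),
               stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic cohort
#'
#' Per-subject parameters are jittered around the per-condition effect
#' specification (Gaussian subject random effects), and a ground-truth table is
#' emitted for recovery tests. With `realize = TRUE` the per-subject
#' trajectories and recordings are also generated.
#'
#' @param design A [cohort_design()].
#' @param effect_spec Named list, one entry per condition in `design`, each a
#'   list with elements `trajectory` ([trajectory_ground_truth()]) and `nirs`
#'   ([nirs_ground_truth()]).
#' @param subject_sd_frac Subject random-effect SD as a fraction of each
#'   jittered parameter's magnitude (default 0.1). Applied to the trajectory
#'   radius bias and the activation amplitudes.
#' @param realize If `TRUE`, generate trajectory traces and recordings for each
#'   subject (can be large); otherwise return parameters only.
#' @param trials_per_condition Trajectory trials to realize per condition
#'   (default `design$n_blocks_per_condition`).
#' @return List with `design`, `subjects` (per-subject parameter sets, plus
#'   `data` when realized) and `truth` (data frame of injected parameters).
#' @export
gen_cohort <- function(design, effect_spec, subject_sd_frac = 0.1,
                       realize = FALSE,
                       trials_per_condition = design$n_blocks_per_condition) {
  stopifnot(inherits(design, "cohort_design"))
  missing_cond <- setdiff(design$conditions, names(effect_spec))
  if (length(missing_cond)) {
    stop("`effect_spec` missing conditions: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  subjects <- vector("list", design$n_subjects)
  truth <- list()
  for (s in seq_len(design$n_subjects)) {
    per_cond <- list()
    for (cc in design$conditions) {
      tgt <- effect_spec[[cc]]$trajectory
      ngt <- effect_spec[[cc]]$nirs
      stopifnot(inherits(tgt, "trajectory_ground_truth"),
                inherits(ngt, "nirs_ground_truth"))
      jit <- with_seed(derive_seed(design$seed, "subj", s, cc), {
        c(bias = stats::rnorm(1, 0, subject_sd_frac * max(abs(tgt$radius_bias), 1e-12)),
          amp = stats::rnorm(1, 0, subject_sd_frac))
      })
      tgt$radius_bias <- tgt$radius_bias + jit[["bias"]]
      ngt$activation_amplitude <- ngt$activation_amplitude * (1 + jit[["amp"]])
      per_cond[[cc]] <- list(trajectory = tgt, nirs = ngt)
      truth[[length(truth) + 1L]] <- data.frame(
        subject = s, condition = cc,
        radius_bias = tgt$radius_bias,
        radius_noise_sd = tgt$radius_noise_sd,
        mean_activation = mean(as.numeric(ngt$activation_amplitude)),
        max_coupling = max(ngt$coupling),
        stringsAsFactors = FALSE)
    }
    subjects[[s]] <- list(id = s, params = per_cond)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(subject = integer(0), condition = character(0),
               radius_bias = numeric(0), radius_noise_sd = numeric(0),
               mean_activation = numeric(0), max_coupling = numeric(0))

  if (realize && design$n_subjects > 0) {
    for (s in seq_len(design$n_subjects)) {
      traj <- list()
      for (cc in design$conditions) {
        hands <- condition_hands(cc)
        tgt <- subjects[[s]]$params[[cc]]$trajectory
        for (h in seq_len(nrow(hands))) {
          tgt_h <- tgt
          tgt_h$direction <- hands$direction[h]
          for (tr in seq_len(trials_per_condition)) {
            key <- sprintf("%s.%s.%d", cc, hands$hand[h], tr)
            traj[[key]] <- gen_trajectory(
              tgt_h, design$task_duration_s, design$traj_rate_hz,
              seed = derive_seed(design$seed, "traj", s, cc, hands$hand[h], tr),
              hand = hands$hand[h], condition = cc, trial = tr)
          }
        }
      }
      # one recording per subject covering all conditions; activation
      # amplitudes assembled channel x condition from the per-condition specs
      ngt0 <- subjects[[s]]$params[[design$conditions[1]]]$nirs
      amp <- sapply(design$conditions, function(cc) {
        a <- subjects[[s]]$params[[cc]]$nirs$activation_amplitude
        if (is.matrix(a)) a[, 1] else rep_len(a, ngt0$n_channels)
      })
      ngt0$activation_amplitude <- amp
      subjects[[s]]$data <- list(
        trajectories = traj,
        recording = gen_nirs_recording(
          design, ngt0, seed = derive_seed(design$seed, "nirs", s)))
    }
  }
  list(design = design, subjects = subjects, truth = truth)
}
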
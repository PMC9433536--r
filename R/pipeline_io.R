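# Orchestration and I/O: the documented CSV + JSON recording dialect,
# trajectory CSV, a validated pipeline configuration, and the staged
# end-to-end runner with manifest logging.

# Full-precision CSV writer (doubles survive a round trip to < 1e-15 relative).
#' @noRd
write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a recording in the CSV + JSON dialect
#'
#' The dialect is one wide CSV (`<stem>.csv`: column `t` plus one column per
#' data column — `hbo_<ch>` / `hbr_<ch>` for concentration recordings,
#' `od<wavelength>_<ch>` for optical ones) and a JSON sidecar
#' (`<stem>.json`: signal kind, sample rate, wavelengths, channel-region map,
#' events).
#'
#' @param rec A [nirs_recording()].
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "nirs_recording"))
  chn <- names(rec$channel_regions)
  if (rec$signal_kind == "concentration") {
    cols <- as.data.frame(rec$channels)
    names(cols) <- paste0("hbo_", chn)
    if (!is.null(rec$dhbr)) {
      hbr <- as.data.frame(rec$dhbr)
      names(hbr) <- paste0("hbr_", chn)
      cols <- cbind(cols, hbr)
    }
  } else {
    cols <- as.data.frame(rec$channels)
    names(cols) <- as.vector(outer(chn, rec$wavelengths,
                                   function(c, w) sprintf("od%g_%s", w, c)))
  }
  write_csv_precise(cbind(t = rec$t, cols), paste0(stem, ".csv"))
  meta <- list(signal_kind = rec$signal_kind,
               sample_rate = rec$sample_rate,
               wavelengths = rec$wavelengths,
               channel_regions = as.list(rec$channel_regions),
               events = rec$events)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read a recording from the CSV + JSON dialect
#'
#' @param stem Path without extension, as written by [write_recording()].
#' @return A [nirs_recording()].
#' @export
read_recording <- function(stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop("missing ", paste0(stem, ".csv/.json"), call. = FALSE)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$channel_regions) || !length(meta$channel_regions)) {
    stop("sidecar lacks the channel_regions map", call. = FALSE)
  }
  dat <- utils::read.csv(csv, check.names = FALSE)
  if (!"t" %in% names(dat)) stop("recording CSV lacks column 't'", call. = FALSE)
  regions <- unlist(meta$channel_regions)
  chn <- names(regions)
  events <- if (!is.null(meta$events) && length(meta$events)) {
    as.data.frame(meta$events)
  } else NULL
  if (meta$signal_kind == "concentration") {
    need <- paste0("hbo_", chn)
    missing_cols <- setdiff(need, names(dat))
    if (length(missing_cols)) {
      stop("recording CSV missing columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    hbo <- as.matrix(dat[need])
    colnames(hbo) <- chn
    hbr_cols <- paste0("hbr_", chn)
    dhbr <- if (all(hbr_cols %in% names(dat))) {
      m <- as.matrix(dat[hbr_cols]); colnames(m) <- chn; m
    } else NULL
    nirs_recording(t = dat$t, channels = hbo, signal_kind = "concentration",
                   channel_regions = regions, events = events, dhbr = dhbr,
                   sample_rate = meta$sample_rate)
  } else {
    wl <- meta$wavelengths
    need <- as.vector(outer(chn, wl, function(c, w) sprintf("od%g_%s", w, c)))
    missing_cols <- setdiff(need, names(dat))
    if (length(missing_cols)) {
      stop("recording CSV missing columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    od <- as.matrix(dat[need])
    nirs_recording(t = dat$t, channels = od, signal_kind = "optical_density",
                   channel_regions = regions, events = events,
                   wavelengths = wl, sample_rate = meta$sample_rate)
  }
}

#' Write / read trajectory trials as tidy CSV
#'
#' Columns: `t`, `x`, `y`, `hand`, `condition`, `trial`, plus the guide
#' parameters repeated per row so a file is self-describing.
#'
#' @param traces List of [trajectory_trace()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(t = tr$t, x = tr$x, y = tr$y, hand = tr$hand,
               condition = tr$condition, trial = tr$trial,
               center_x = tr$center[1], center_y = tr$center[2],
               guide_radius = tr$guide_radius,
               guide_angular_velocity = tr$guide_angular_velocity,
               stringsAsFactors = FALSE)
  })
  write_csv_precise(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("t", "x", "y", "hand", "condition", "trial",
            "center_x", "center_y", "guide_radius", "guide_angular_velocity")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    stop("trajectory CSV missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in unique(paste(dat$condition, dat$hand, dat$trial))) {
    d <- dat[paste(dat$condition, dat$hand, dat$trial) == key, , drop = FALSE]
    out[[key]] <- trajectory_trace(
      t = d$t, x = d$x, y = d$y, hand = d$hand[1], condition = d$condition[1],
      center = c(d$center_x[1], d$center_y[1]),
      guide_radius = d$guide_radius[1],
      guide_angular_velocity = d$guide_angular_velocity[1],
      trial = d$trial[1])
  }
  out
}

#' Default pipeline configuration
#'
#' All stage parameters in one validated list. Any key not produced by this
#' constructor is rejected by [run_pipeline()].
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = tempfile("nirsconn_run_"),
    seed = 1L,
    # simulate
    n_subjects = 3L, n_blocks = 8L,
    conditions = STUDY_CONDITIONS,
    task_duration_s = 12, rest_duration_s = 15,
    nirs_rate_hz = 11, traj_rate_hz = 28.5,
    radius_bias_nondominant = 0.08, radius_noise_sd = 0.05,
    angvel_noise_sd = 0.1, activation_amplitude = 1,
    coupling_ip_rpfc = 0.7, coupling_ap_rpfc = 0.2, coupling_baseline = 0.1,
    noise_sd = 0.1,
    # preprocess
    bandpass = c(0.021, 0.6), bandstop = c(0.08, 0.12),
    artifact_window = 10L, artifact_threshold = 5,
    # kinematics
    trim_s = 0,
    # connectivity
    band = "LF", n_freqs = 10L, omega0 = 6,
    # metrics
    n_null = 20L,
    # stats
    fdr_q = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @noRd
stage_log <- function(dir, stage, started, inputs = character(0), outputs = character(0)) {
  list(stage = stage,
       wall_s = as.numeric(Sys.time()) - started,
       outputs = outputs,
       output_md5 = as.list(tools::md5sum(file.path(dir, outputs))))
}

# Effect specification implied by a pipeline config: non-dominant (left) hand
# gets the radius bias; IP conditions get stronger RPFC coupling than AP;
# unilateral conditions activate the contralateral motor cortex.
#' @noRd
config_effect_spec <- function(cfg, regions = default_channel_regions()) {
  n_ch <- length(regions)
  spec <- list()
  for (cc in cfg$conditions) {
    hands <- condition_hands(cc)
    bias <- if ("left" %in% hands$hand) cfg$radius_bias_nondominant else 0
    tgt <- trajectory_ground_truth(
      radius_bias = bias, radius_noise_sd = cfg$radius_noise_sd,
      angvel_noise_sd = cfg$angvel_noise_sd,
      direction = hands$direction[1])
    amp <- numeric(n_ch)
    act_regions <- if (nrow(hands) == 2L) c("LMC", "RMC")
                   else if (hands$hand == "left") "RMC" else "LMC"
    amp[regions %in% act_regions] <- cfg$activation_amplitude
    coup <- matrix(cfg$coupling_baseline, n_ch, n_ch)
    rpfc <- which(regions == "RPFC")
    k_rpfc <- if (cc %in% c("LCRC", "LWRW")) cfg$coupling_ip_rpfc
              else if (cc %in% c("LCRW", "LWRC")) cfg$coupling_ap_rpfc
              else cfg$coupling_baseline
    coup[rpfc, rpfc] <- k_rpfc
    diag(coup) <- 0
    spec[[cc]] <- list(
      trajectory = tgt,
      nirs = nirs_ground_truth(n_channels = n_ch, activation_amplitude = amp,
                               coupling = coup, noise_sd = cfg$noise_sd))
  }
  spec
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> kinematics -> activation ->
#' connectivity -> metrics -> stats on a synthetic cohort defined by the
#' config, writing every artifact family as CSV/TSV plus a JSON manifest with
#' per-stage wall time and output hashes. Reruns with an identical config
#' reproduce identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The output directory, invisibly; artifacts:
#'   `trajectories.csv`, `recording_sXX.csv/.json`, `kinematics.csv`,
#'   `activation_glm.csv`, `activation_integral.csv`, `plv_sXX_<grp>.tsv`,
#'   `network_metrics.csv`, `stats.csv`, `manifest.json`, `config.json`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) {
    stop("`cfg` must come from pipeline_config()", call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- cfg$out_dir
  manifest <- list()
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  ## simulate ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  design <- cohort_design(
    n_subjects = cfg$n_subjects, conditions = cfg$conditions,
    n_blocks_per_condition = cfg$n_blocks, task_duration_s = cfg$task_duration_s,
    rest_duration_s = cfg$rest_duration_s, nirs_rate_hz = cfg$nirs_rate_hz,
    traj_rate_hz = cfg$traj_rate_hz, seed = cfg$seed)
  regions <- default_channel_regions()
  cohort <- gen_cohort(design, config_effect_spec(cfg, regions),
                       realize = TRUE, trials_per_condition = cfg$n_blocks)
  utils::write.csv(cohort$truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
  traj_files <- character(0)
  for (s in seq_len(design$n_subjects)) {
    write_trajectories(cohort$subjects[[s]]$data$trajectories,
                       file.path(out, sprintf("trajectories_s%02d.csv", s)))
    write_recording(cohort$subjects[[s]]$data$recording,
                    file.path(out, sprintf("recording_s%02d", s)))
  }
  manifest$simulate <- stage_log(out, "simulate", t0,
                                 outputs = "ground_truth.csv")

  ## preprocess --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cleaned <- lapply(seq_len(design$n_subjects), function(s) {
    preprocess_nirs(cohort$subjects[[s]]$data$recording,
                    window = cfg$artifact_window,
                    threshold = cfg$artifact_threshold,
                    bandpass = cfg$bandpass, bandstop = cfg$bandstop)
  })
  for (s in seq_len(design$n_subjects)) {
    write_recording(cleaned[[s]], file.path(out, sprintf("cleaned_s%02d", s)))
  }
  manifest$preprocess <- stage_log(out, "preprocess", t0,
                                   outputs = sprintf("cleaned_s%02d.csv", 1L))

  ## kinematics --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  kin <- do.call(rbind, lapply(seq_len(design$n_subjects), function(s) {
    rows <- lapply(cohort$subjects[[s]]$data$trajectories, kinematic_metrics,
                   trim = cfg$trim_s)
    cbind(subject = s, do.call(rbind, rows))
  }))
  utils::write.csv(kin, file.path(out, "kinematics.csv"), row.names = FALSE)
  manifest$kinematics <- stage_log(out, "kinematics", t0, outputs = "kinematics.csv")

  ## activation --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  act <- list(); integ <- list()
  for (s in seq_len(design$n_subjects)) {
    rec <- cleaned[[s]]
    rec$events <- cohort$subjects[[s]]$data$recording$events
    X <- build_design(rec$events, rec$t)
    glm_res <- fit_glm(rec, X)
    glm_res$table$p_fdr <- stats::ave(glm_res$table$p, glm_res$table$condition,
                                      FUN = fdr_correct)
    act[[s]] <- cbind(subject = s, glm_res$table)
    integ[[s]] <- cbind(subject = s, activation_integral(rec))
  }
  act <- do.call(rbind, act); integ <- do.call(rbind, integ)
  utils::write.csv(act, file.path(out, "activation_glm.csv"), row.names = FALSE)
  utils::write.csv(integ, file.path(out, "activation_integral.csv"), row.names = FALSE)
  manifest$activation <- stage_log(out, "activation", t0,
                                   outputs = c("activation_glm.csv", "activation_integral.csv"))

  ## connectivity + metrics --------------------------------------------------
  t0 <- as.numeric(Sys.time())
  band <- band_spec(cfg$band, n_freqs = cfg$n_freqs)
  groups <- list(IP = intersect(c("LCRC", "LWRW"), cfg$conditions),
                 AP = intersect(c("LCRW", "LWRC"), cfg$conditions))
  groups <- groups[lengths(groups) > 0]
  met_rows <- list()
  for (s in seq_len(design$n_subjects)) {
    rec <- cleaned[[s]]
    rec$events <- cohort$subjects[[s]]$data$recording$events
    for (g in names(groups)) {
      series <- concat_task(rec, groups[[g]])
      pm <- cwt_phase(series, band, omega0 = cfg$omega0)
      net <- threshold_connected(connectivity_matrix(pm))
      utils::write.table(net$plv,
                         file.path(out, sprintf("plv_s%02d_%s.tsv", s, g)),
                         sep = "\t", quote = FALSE)
      ms <- network_metric_set(net, n_null = cfg$n_null,
                               seed = derive_seed(cfg$seed, "null", s, g))
      met_rows[[length(met_rows) + 1L]] <- rbind(
        data.frame(subject = s, group = g, scope = "global",
                   name = names(ms$global), region = NA_character_,
                   value = unname(ms$global), stringsAsFactors = FALSE),
        do.call(rbind, lapply(c("degree", "efficiency", "local_efficiency"),
          function(metric) {
            data.frame(subject = s, group = g, scope = "region",
                       name = metric, region = ms$regional$region,
                       value = ms$regional[[metric]], stringsAsFactors = FALSE)
          })))
    }
  }
  metrics <- do.call(rbind, met_rows)
  utils::write.csv(metrics, file.path(out, "network_metrics.csv"), row.names = FALSE)
  manifest$connectivity <- stage_log(out, "connectivity", t0,
                                     outputs = "network_metrics.csv")

  ## stats -------------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  reports <- list()
  uni <- kin[kin$condition %in% c("LHCW", "LHCC", "RHCW", "RHCC"), , drop = FALSE]
  uni$orientation <- if (nrow(uni)) ifelse(grepl("CW$", uni$condition), "CW", "CC") else character(0)
  if (nrow(uni) && length(unique(uni$hand)) > 1L &&
      length(unique(uni$orientation)) > 1L) {
    per <- stats::aggregate(re ~ subject + hand + orientation, data = uni, FUN = mean)
    aov_re <- anova_factorial(per, c("hand", "orientation"), value = "re")
    reports$anova_re <- data.frame(analysis = "anova_radius_error_unilateral",
                                   term = aov_re$term, statistic = aov_re$statistic,
                                   p = aov_re$p, n = nrow(per),
                                   stringsAsFactors = FALSE)
  }
  if (all(c("IP", "AP") %in% metrics$group)) {
    rp <- metrics[metrics$scope == "region" & metrics$region == "RPFC" &
                    metrics$name == "efficiency", , drop = FALSE]
    wide <- merge(rp[rp$group == "IP", c("subject", "value")],
                  rp[rp$group == "AP", c("subject", "value")], by = "subject")
    if (nrow(wide) >= 2L) {
      pt <- paired_t(wide$value.x, wide$value.y)
      reports$paired_rpfc <- data.frame(analysis = "paired_t_rpfc_node_efficiency_IP_vs_AP",
                                        term = "IP-AP", statistic = pt$statistic,
                                        p = pt$p, n = pt$n, stringsAsFactors = FALSE)
    }
  }
  per_sc <- stats::aggregate(re ~ subject + condition, data = kin, FUN = mean)
  rmc <- integ[integ$region == "RMC", , drop = FALSE]
  act_sc <- stats::aggregate(integral ~ subject + condition, data = rmc, FUN = mean)
  joined <- merge(per_sc, act_sc, by = c("subject", "condition"))
  if (nrow(joined) >= 3L && stats::sd(joined$re) > 0 && stats::sd(joined$integral) > 0) {
    cr <- correlate(joined$integral, joined$re)
    reports$corr <- data.frame(analysis = "pearson_integral_vs_radius_error",
                               term = "pooled", statistic = cr$estimate,
                               p = cr$p, n = cr$n, stringsAsFactors = FALSE)
  }
  stats_tab <- do.call(rbind, reports)
  utils::write.csv(stats_tab, file.path(out, "stats.csv"), row.names = FALSE)
  manifest$stats <- stage_log(out, "stats", t0, outputs = "stats.csv")

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
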
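# GLM activation mapping: per-channel ordinary least squares on HRF-convolved
# condition regressors, plus the task-minus-rest activation integral that
# quantifies activation intensity directly from the concentration series.

#' Build a GLM design matrix
#'
#' One HRF-convolved boxcar regressor per condition (peak-normalized to 1),
#' plus an intercept and a linear drift column.
#'
#' @param events Data frame with `onset`, `duration`, `condition` (seconds).
#' @param t Sample times of the recording, seconds.
#' @param hrf Function of time returning the hemodynamic impulse response
#'   (default [canonical_hrf()]).
#' @return Numeric matrix with attribute `"conditions"`; columns
#'   `intercept`, `drift`, then one per condition.
#' @export
build_design <- function(events, t, hrf = canonical_hrf) {
  stopifnot(is.data.frame(events), all(c("onset", "duration", "condition") %in% names(events)))
  if (nrow(events) == 0L) {
    X <- cbind(intercept = rep(1, length(t)),
               drift = seq_along(t) / length(t) - 0.5)
    attr(X, "conditions") <- character(0)
    return(X)
  }
  if (any(events$onset < t[1] - 1e-9) ||
      any(events$onset + events$duration > t[length(t)] + 1e-9)) {
    stop("events must lie within the record", call. = FALSE)
  }
  conds <- unique(events$condition)
  dt <- stats::median(diff(t))
  hk <- hrf(seq(0, 32, by = dt))
  cols <- sapply(conds, function(cc) {
    ev <- events[events$condition == cc, , drop = FALSE]
    # merge overlapping events of the same condition
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (nrow(ev) > 1L) {
      keep <- c(TRUE, ev$onset[-1] >= (ev$onset + ev$duration)[-nrow(ev)])
      if (!all(keep)) {
        warning(sprintf("overlapping '%s' events merged", cc), call. = FALSE)
        ev <- ev[keep, , drop = FALSE]
      }
    }
    box <- numeric(length(t))
    for (i in seq_len(nrow(ev))) {
      box[t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]] <- 1
    }
    reg <- conv_causal(box, hk) * dt
    m <- max(abs(reg))
    if (m > 0) reg / m else reg
  })
  X <- cbind(intercept = rep(1, length(t)),
             drift = seq_along(t) / length(t) - 0.5,
             cols)
  colnames(X) <- c("intercept", "drift", conds)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  attr(X, "conditions") <- conds
  X
}

#' Fit the GLM per channel
#'
#' Ordinary least squares of each channel's oxyhemoglobin series on the design;
#' t statistics use the residual degrees of freedom, p values are two-sided.
#'
#' @param rec A concentration [nirs_recording()] (oxyhemoglobin analyzed).
#' @param X Design matrix from [build_design()].
#' @return Object of class `activation_result`: long data frame `table` with
#'   `channel`, `region`, `condition`, `beta`, `se`, `t`, `p`, plus the full
#'   coefficient matrix in `beta`.
#' @export
fit_glm <- function(rec, X) {
  stopifnot(inherits(rec, "nirs_recording"))
  Y <- rec$channels
  if (nrow(X) != nrow(Y)) stop("design rows must match samples", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)                              # p x channels
  resid <- Y - X %*% B
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtXinv), sigma2))           # p x channels
  dimnames(se) <- dimnames(B)
  tval <- B / se
  pval <- 2 * stats::pt(abs(tval), dof, lower.tail = FALSE)
  conds <- attr(X, "conditions")
  chn <- names(rec$channel_regions)
  tab <- do.call(rbind, lapply(conds, function(cc) {
    data.frame(channel = chn, region = unname(rec$channel_regions),
               condition = cc, beta = B[cc, ], se = se[cc, ],
               t = tval[cc, ], p = pval[cc, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, beta = B, dof = dof), class = "activation_result")
}

#' Task-minus-rest activation integral
#'
#' For each task block, the trapezoidal integral of oxyhemoglobin over the task
#' window minus the integral over a duration-matched window at the end of the
#' immediately preceding rest period; block values are averaged per condition.
#' Higher values indicate stronger activation relative to rest.
#'
#' @param rec A concentration [nirs_recording()] with events.
#' @param events Event table (default the recording's own).
#' @param min_rest_s Minimum preceding rest required to score a block
#'   (default 5 s); blocks without it are skipped with a warning.
#' @return Data frame `channel`, `region`, `condition`, `integral`
#'   (concentration x seconds).
#' @export
activation_integral <- function(rec, events = rec$events, min_rest_s = 5) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (is.null(events) || nrow(events) == 0L) {
    stop("recording has no events", call. = FALSE)
  }
  t <- rec$t
  ev <- events[order(events$onset), , drop = FALSE]
  prev_end <- c(t[1], (ev$onset + ev$duration)[-nrow(ev)])
  res <- list()
  for (i in seq_len(nrow(ev))) {
    rest_avail <- ev$onset[i] - prev_end[i]
    if (rest_avail < min_rest_s) {
      warning(sprintf("block %d (%s): preceding rest %.1f s < %.1f s; skipped",
                      i, ev$condition[i], rest_avail, min_rest_s), call. = FALSE)
      next
    }
    task_idx <- which(t >= ev$onset[i] & t <= ev$onset[i] + ev$duration[i])
    rest_idx <- which(t >= ev$onset[i] - ev$duration[i] & t <= ev$onset[i])
    if (length(task_idx) < 2L || length(rest_idx) < 2L) next
    trapz_cols <- function(idx) {
      y <- rec$channels[idx, , drop = FALSE]
      w <- diff(t[idx])
      as.numeric(crossprod(w, (y[-1, , drop = FALSE] + y[-length(idx), , drop = FALSE]) / 2))
    }
    task_int <- trapz_cols(task_idx)
    rest_int <- trapz_cols(rest_idx)
    # rescale rest to the task-window duration if truncated
    scale <- diff(range(t[task_idx])) / diff(range(t[rest_idx]))
    res[[length(res) + 1L]] <- data.frame(
      channel = names(rec$channel_regions),
      region = unname(rec$channel_regions),
      condition = ev$condition[i],
      value = task_int - rest_int * scale,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no scorable blocks", call. = FALSE)
  allb <- do.call(rbind, res)
  out <- stats::aggregate(value ~ channel + region + condition, data = allb, FUN = mean)
  names(out)[names(out) == "value"] <- "integral"
  out[order(out$condition, out$channel), , drop = FALSE]
}
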
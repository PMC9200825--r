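# Gaze-orienting analysis: zero-phase Butterworth filtering, numerical
# differentiation, conjoint velocity-acceleration saccade detection,
# regular/anticipatory classification, and cell summaries.

# Second-order Butterworth low-pass coefficients (bilinear transform with
# prewarping, so the -3 dB point sits exactly at `cutoff_hz`).
butter2_coefs <- function(cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must be in (0, fs/2)")
  }
  K <- tan(pi * cutoff_hz / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm))
}

# Causal IIR pass; x may be a vector or a matrix (filtered column-wise).
iir_pass <- function(x, b, a) {
  xf <- stats::filter(x, filter = b, method = "convolution", sides = 1)
  xf[is.na(xf)] <- 0  # first taps; mirror padding makes their value immaterial
  y <- stats::filter(xf, filter = -a[-1], method = "recursive")
  if (is.matrix(x)) matrix(as.numeric(y), nrow(x), ncol(x)) else as.numeric(y)
}

# Zero-phase (forward-backward) filtering with odd mirror padding; the pad
# length is several times the filter's characteristic time, so start-up
# transients (zero initial conditions) decay below 1e-9 before the data
# proper begins.
filtfilt2 <- function(x, cutoff_hz, fs,
                      padlen = max(50L, round(6 * fs / cutoff_hz))) {
  ba <- butter2_coefs(cutoff_hz, fs)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (padlen >= n) padlen <- n - 1L
  pre <- 2 * x[rep(1L, padlen), , drop = FALSE] -
    x[(padlen + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(n, padlen), , drop = FALSE] -
    x[(n - 1L):(n - padlen), , drop = FALSE]
  xe <- rbind(pre, x, post)
  y <- iir_pass(xe, ba$b, ba$a)
  y <- iir_pass(y[nrow(y):1L, , drop = FALSE], ba$b, ba$a)
  y <- y[nrow(y):1L, , drop = FALSE][(padlen + 1L):(padlen + n), ,
                                     drop = FALSE]
  if (vec) as.numeric(y) else y
}

trace_fs <- function(trace) {
  dt <- diff(trace$t)
  if (length(dt) < 19) stop("trace too short (< 20 samples)")
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
    stop("non-uniform trace timestamps (jitter above 1%)")
  }
  1000 / stats::median(dt)
}

#' Zero-phase low-pass filter a gaze trace
#'
#' Forward-backward (acausal, zero-phase) second-order Butterworth filter
#' applied independently to the horizontal and vertical position channels.
#' DC gain is 1; the squared magnitude response gives gain 0.5 at the cutoff
#' frequency.
#'
#' @param trace A [gaze_trace][simulate_gaze_trial].
#' @param cutoff_hz Cutoff frequency (default 30 Hz).
#' @param order Filter order; only the standard order 2 is implemented.
#' @return The trace with filtered `x` and `y`.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 30, order = 2) {
  if (order != 2) stop("only the order-2 Butterworth filter is implemented")
  fs <- trace_fs(trace)
  trace$x <- filtfilt2(trace$x, cutoff_hz, fs)
  trace$y <- filtfilt2(trace$y, cutoff_hz, fs)
  trace$filtered <- TRUE
  trace
}

#' Numerical differentiation
#'
#' Central differences at interior samples, one-sided differences at the
#' ends; exact for linear signals everywhere and for quadratics at interior
#' samples. Apply twice for acceleration.
#'
#' @param x Numeric vector of positions (or velocities).
#' @param dt Sample interval (seconds for deg/s output from degrees).
#' @return Numeric vector of the same length.
#' @export
differentiate <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need >= 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Plateau position estimate: mean x in a window before (side = -1) or after
# (side = +1) the event, clipped to stay clear of neighbouring events.
plateau_x <- function(x, i, side, fs, lo_lim, hi_lim) {
  gap <- round(0.005 * fs)   # 5 ms guard
  win <- round(0.020 * fs)   # 20 ms window
  if (side < 0) {
    hi <- i - gap
    lo <- max(lo_lim, hi - win)
  } else {
    lo <- i + gap
    hi <- min(hi_lim, lo + win)
  }
  if (hi < lo) return(x[i])
  mean(x[lo:hi])
}

#' Detect saccades by conjoint velocity-acceleration thresholding
#'
#' A candidate event is a contiguous run of samples with 2-D speed above
#' `v_thresh / 3`; the event fires only if it contains at least one sample
#' with speed above `v_thresh` and acceleration magnitude above `a_thresh`
#' (the conjoint criterion). The reported onset is the first conjoint sample,
#' the offset is the end of the run; runs separated by less than
#' `merge_gap_ms` are merged and events shorter than `min_dur_ms` discarded.
#' Amplitude is the difference of 20-ms pre/post fixation-plateau means of
#' horizontal position (unbiased under the 30-Hz acausal filter, unlike the
#' instantaneous onset/offset positions); direction is the sign of that
#' displacement.
#'
#' @param trace A filtered [gaze_trace][simulate_gaze_trial] (see
#'   [lowpass_filter()]).
#' @param v_thresh Velocity threshold, deg/s (default 30).
#' @param a_thresh Acceleration threshold, deg/s^2 (default 2000; see the
#'   package vignette for why this sits below classic tracker defaults).
#' @param min_dur_ms Minimum event duration (default 8 ms).
#' @param merge_gap_ms Merge events closer than this (default 20 ms).
#' @return Data frame of events: `onset_ms`, `offset_ms`, `start_ms` (run
#'   start), `amplitude_deg`, `peak_velocity_deg_s`, `direction`
#'   (left/right); zero rows for quiet traces.
#' @export
detect_saccades <- function(trace, v_thresh = 30, a_thresh = 2000,
                            min_dur_ms = 8, merge_gap_ms = 20) {
  fs <- trace_fs(trace)
  dt <- 1 / fs
  vx <- differentiate(trace$x, dt)
  vy <- differentiate(trace$y, dt)
  speed <- sqrt(vx^2 + vy^2)
  ax <- differentiate(vx, dt)
  ay <- differentiate(vy, dt)
  acc <- sqrt(ax^2 + ay^2)

  empty <- fast_df(onset_ms = numeric(0), offset_ms = numeric(0),
                   start_ms = numeric(0), amplitude_deg = numeric(0),
                   peak_velocity_deg_s = numeric(0),
                   direction = character(0))
  above <- speed > v_thresh / 3
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]
  re <- ends[r$values]
  # merge runs separated by less than merge_gap_ms
  if (length(rs) > 1) {
    gap <- (rs[-1] - re[-length(re)] - 1) / fs * 1000
    grp <- cumsum(c(TRUE, gap >= merge_gap_ms))
    rs <- as.integer(tapply(rs, grp, min))
    re <- as.integer(tapply(re, grp, max))
  }
  nr <- length(rs)
  onset_ms <- offset_ms <- start_ms <- amp <- pv <- numeric(nr)
  dir <- character(nr)
  m <- 0L
  for (k in seq_len(nr)) {
    i0 <- rs[k]; i1 <- re[k]
    if ((i1 - i0 + 1) / fs * 1000 < min_dur_ms) next
    conj <- which(speed[i0:i1] > v_thresh & acc[i0:i1] > a_thresh)
    if (length(conj) == 0) next
    onset <- i0 + conj[1] - 1L
    lo_lim <- if (k > 1) re[k - 1] + 1L else 1L
    hi_lim <- if (k < nr) rs[k + 1] - 1L else length(speed)
    pre <- plateau_x(trace$x, i0, -1, fs, lo_lim, hi_lim)
    post <- plateau_x(trace$x, i1, +1, fs, lo_lim, hi_lim)
    disp <- post - pre
    m <- m + 1L
    onset_ms[m] <- trace$t[onset]
    offset_ms[m] <- trace$t[i1]
    start_ms[m] <- trace$t[i0]
    amp[m] <- abs(disp)
    pv[m] <- max(speed[i0:i1])
    dir[m] <- if (disp < 0) "left" else "right"
  }
  if (m == 0L) return(empty)
  idx <- seq_len(m)
  fast_df(onset_ms = onset_ms[idx], offset_ms = offset_ms[idx],
          start_ms = start_ms[idx], amplitude_deg = amp[idx],
          peak_velocity_deg_s = pv[idx], direction = dir[idx])
}

#' Classify a trial's detected saccades
#'
#' The *regular* saccade is the first event with latency (onset relative to
#' target onset) strictly inside (80, 500) ms and amplitude > 2 degrees
#' (40% of the 5-degree target eccentricity); it is labelled *correct* if
#' directed to the target side, *erroneous* otherwise. *Anticipatory*
#' saccades have latency strictly inside (-70, 80) ms and amplitude >= 1
#' degree. Everything else is unclassified; a trial with no detected
#' saccades is *aberrant*.
#'
#' @param events Event table from [detect_saccades()], sorted by onset.
#' @param trial The matching schedule row (needs `target_side`,
#'   `salient_side`, `trial_type`, `cue_eccentricity_deg`).
#' @param regular_window,anticipatory_window Open latency intervals (ms).
#' @param regular_amp_frac Regular-amplitude criterion as a fraction of the
#'   cue/target eccentricity (default 0.4, i.e. 2 degrees at 5 degrees).
#' @param anticipatory_amp_min Minimum anticipatory amplitude (default 1).
#' @return A `trial_classification`: the events with a `class` column
#'   (regular/anticipatory/unclassified), `regular_label`
#'   (correct/erroneous/none), and `aberrant` flag.
#' @export
classify_trial <- function(events, trial, regular_window = c(80, 500),
                           anticipatory_window = c(-70, 80),
                           regular_amp_frac = 0.4,
                           anticipatory_amp_min = 1) {
  ecc <- trial$cue_eccentricity_deg %||% 5
  if (is.null(ecc) || is.na(ecc)) ecc <- 5
  amp_min <- regular_amp_frac * ecc
  n <- nrow(events)
  cls <- rep("unclassified", n)
  if (n > 0) {
    lat <- events$onset_ms
    is_reg <- lat > regular_window[1] & lat < regular_window[2] &
      events$amplitude_deg > amp_min
    is_ant <- lat > anticipatory_window[1] & lat < anticipatory_window[2] &
      events$amplitude_deg >= anticipatory_amp_min
    cls[is_ant] <- "anticipatory"
    first_reg <- which(is_reg)[1]
    if (!is.na(first_reg)) cls[first_reg] <- "regular"
  }
  events$class <- cls
  reg <- which(cls == "regular")
  label <- if (length(reg) == 0) {
    "none"
  } else if (events$direction[reg] == trial$target_side) {
    "correct"
  } else "erroneous"
  structure(
    list(trial = trial$trial, trial_type = trial$trial_type,
         condition = trial$condition,
         validity_block = trial$validity_block,
         target_side = trial$target_side, salient_side = trial$salient_side,
         events = events, regular_label = label,
         regular_latency_ms = if (length(reg)) events$onset_ms[reg] else NA_real_,
         n_anticipatory = sum(cls == "anticipatory"),
         anticipatory_to_salient = if (trial$trial_type == "neutral") {
           NA_integer_
         } else {
           sum(cls == "anticipatory" &
                 events$direction == trial$salient_side)
         },
         aberrant = n == 0),
    class = "trial_classification")
}

#' Filter, detect and classify every trial of a session
#'
#' Batch pipeline: traces (all the same length) are filtered column-wise in
#' one pass, then detected and classified trial by trial.
#'
#' @param traces List of [gaze_trace][simulate_gaze_trial] objects in
#'   schedule order.
#' @param schedule The matching gaze `session_schedule`.
#' @param cutoff_hz Filter cutoff (default 30).
#' @param ... Passed to [detect_saccades()].
#' @return List of [trial_classification][classify_trial] objects.
#' @export
analyze_gaze_session <- function(traces, schedule, cutoff_hz = 30, ...) {
  stopifnot(length(traces) == nrow(schedule))
  lens <- lengths(lapply(traces, `[[`, "t"))
  if (length(unique(lens)) == 1 && length(traces) > 1) {
    fs <- trace_fs(traces[[1]])
    XY <- filtfilt2(cbind(vapply(traces, `[[`, numeric(lens[1]), "x"),
                          vapply(traces, `[[`, numeric(lens[1]), "y")),
                    cutoff_hz, fs)
    X <- XY[, seq_along(traces), drop = FALSE]
    Y <- XY[, length(traces) + seq_along(traces), drop = FALSE]
    traces <- lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]; tr$x <- X[, i]; tr$y <- Y[, i]; tr$filtered <- TRUE
      tr
    })
  } else {
    traces <- lapply(traces, lowpass_filter, cutoff_hz = cutoff_hz)
  }
  rows <- df_rows(as.data.frame(schedule))
  lapply(seq_along(traces), function(i) {
    ev <- detect_saccades(traces[[i]], ...)
    classify_trial(ev, rows[[i]])
  })
}

#' Summarise classified gaze trials per design cell
#'
#' Per condition x validity x trial type: mean latency (+- SEM) of correct
#' regular saccades, latency change relative to the same
#' condition-and-validity neutral baseline, percentage of direction errors
#' and of anticipatory saccades over the total number of detected saccades
#' (regular + anticipatory), and the percentage of non-neutral anticipatory
#' saccades directed to the salient side.
#'
#' @param classifications List from [analyze_gaze_session()] (or a single
#'   participant's [classify_trial()] results).
#' @param denominator `"all"` (regular + anticipatory, default) or
#'   `"regular"` for the error/anticipatory percentages.
#' @return Data frame with one row per cell.
#' @export
summarize_gaze <- function(classifications, denominator = c("all", "regular")) {
  denominator <- match.arg(denominator)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  df <- data.frame(
    condition = vapply(classifications, `[[`, character(1), "condition"),
    validity_block = vapply(classifications, function(x)
      as.numeric(x$validity_block), numeric(1)),
    trial_type = vapply(classifications, `[[`, character(1), "trial_type"),
    label = vapply(classifications, `[[`, character(1), "regular_label"),
    latency = vapply(classifications, `[[`, numeric(1), "regular_latency_ms"),
    n_ant = vapply(classifications, `[[`, numeric(1), "n_anticipatory"),
    ant_sal = vapply(classifications, function(x)
      as.numeric(x$anticipatory_to_salient %||% NA), numeric(1)),
    aberrant = vapply(classifications, `[[`, logical(1), "aberrant"),
    stringsAsFactors = FALSE)
  cells <- split(df, list(df$condition, df$validity_block, df$trial_type),
                 drop = TRUE)
  out <- lapply(cells, function(d) {
    n_reg <- sum(d$label != "none")
    n_err <- sum(d$label == "erroneous")
    n_ant <- sum(d$n_ant)
    n_sac <- if (denominator == "all") n_reg + n_ant else n_reg
    lat <- d$latency[d$label == "correct"]
    data.frame(
      condition = d$condition[1], validity_block = d$validity_block[1],
      trial_type = d$trial_type[1], n_trials = nrow(d),
      n_aberrant = sum(d$aberrant), n_regular = n_reg,
      n_erroneous = n_err, n_anticipatory = n_ant,
      mean_latency_ms = if (length(lat)) mean(lat) else NA_real_,
      latency_sem_ms = sem(lat),
      pct_direction_errors = if (n_sac) 100 * n_err / n_sac else NA_real_,
      pct_anticipatory = if (n_sac) 100 * n_ant / n_sac else NA_real_,
      pct_anticipatory_to_salient = if (d$trial_type[1] != "neutral" &&
                                        n_ant > 0) {
        100 * sum(d$ant_sal, na.rm = TRUE) / n_ant
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$latency_change_pct <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (tab$trial_type[i] == "neutral") next
    base <- tab$mean_latency_ms[tab$condition == tab$condition[i] &
                                tab$validity_block == tab$validity_block[i] &
                                tab$trial_type == "neutral"]
    if (length(base) == 1 && is.finite(base) &&
        is.finite(tab$mean_latency_ms[i])) {
      tab$latency_change_pct[i] <- relative_change(tab$mean_latency_ms[i],
                                                   base)
    }
  }
  tab
}

#' Weighted group average of anticipatory-saccade statistics
#'
#' Across participants, anticipatory percentages are averaged with weights
#' equal to each participant's anticipatory-saccade count in the cell (so
#' participants who never anticipate do not dilute the direction
#' preference); latencies and error percentages are plain participant means.
#'
#' @param per_participant Data frame: rbind of per-participant
#'   [summarize_gaze()] tables with a `participant` column.
#' @return Group-level data frame per cell.
#' @export
gaze_group_summary <- function(per_participant) {
  cells <- split(per_participant,
                 list(per_participant$condition,
                      per_participant$validity_block,
                      per_participant$trial_type), drop = TRUE)
  out <- lapply(cells, function(d) {
    w <- d$n_anticipatory
    wmean <- function(x) {
      ok <- is.finite(x) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(x[ok] * w[ok]) / sum(w[ok])
    }
    data.frame(
      condition = d$condition[1], validity_block = d$validity_block[1],
      trial_type = d$trial_type[1],
      mean_latency_ms = mean(d$mean_latency_ms, na.rm = TRUE),
      latency_change_pct = mean(d$latency_change_pct, na.rm = TRUE),
      pct_direction_errors = mean(d$pct_direction_errors, na.rm = TRUE),
      pct_anticipatory = wmean(d$pct_anticipatory),
      pct_anticipatory_to_salient = wmean(d$pct_anticipatory_to_salient),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  for (cl in c("latency_change_pct", "pct_direction_errors")) {
    tab[[cl]][is.nan(tab[[cl]])] <- NA_real_
  }
  tab
}

#' Did the gaze leave fixation?
#'
#' `TRUE` iff any sample lies strictly further than `fixation_radius_deg`
#' from the fixation point (used to screen covert-task trials for saccade
#' execution).
#'
#' @param trace A [gaze_trace][simulate_gaze_trial].
#' @param fixation_radius_deg Radius in degrees (default 2).
#' @param fixation_point `c(x, y)` of fixation (default origin).
#' @return Logical scalar.
#' @export
check_fixation <- function(trace, fixation_radius_deg = 2,
                           fixation_point = c(0, 0)) {
  d2 <- (trace$x - fixation_point[1])^2 + (trace$y - fixation_point[2])^2
  any(d2 > fixation_radius_deg^2)
}
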
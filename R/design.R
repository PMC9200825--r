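# Trial-schedule generation for the two dual-cue tasks.
#
# Printed design, covert task: per session and per condition, 112 neutral
# trials (224 over the two sessions) and 250 non-neutral trials split
# 125/125 (50% validity session) or 200/50 (80% validity session);
# 2 sessions x 2 conditions = 1448 trials. Gaze task: 100 neutral + 250
# non-neutral per session and condition; 1400 trials in total.

#' Default covert-task contrast levels
#'
#' Eight log-spaced Michelson contrasts spanning the tested range 0.01-0.09.
#'
#' @return Numeric vector of 8 strictly increasing contrasts.
#' @export
default_contrasts <- function() {
  exp(seq(log(0.01), log(0.09), length.out = 8))
}

as_session_schedule <- function(df, task, seed = NULL, validity = NULL,
                                soa_ms = 150, cue_eccentricity_deg = 5,
                                cue_duration_ms = 25) {
  rownames(df) <- NULL
  structure(df, class = c("session_schedule", "data.frame"),
            task = task, seed = seed, validity = validity, soa_ms = soa_ms,
            cue_eccentricity_deg = cue_eccentricity_deg,
            cue_duration_ms = cue_duration_ms)
}

# Balanced assignment of a two-level factor within a cell of n trials:
# floor(n/2) each, remainder assigned by a (seeded, caller-side) draw.
balanced_levels <- function(n, levels) {
  base <- rep(levels, each = n %/% 2)
  if (n %% 2 == 1) base <- c(base, sample(levels, 1))
  sample(base)
}

# One condition's trials for one trial type.
cell_trials <- function(task, condition, trial_type, n, validity,
                        contrasts = NULL, soa_ms, ecc) {
  if (n == 0) return(NULL)
  if (!is.null(contrasts)) {
    k <- length(contrasts)
    per <- n %/% k
    idx <- rep(seq_len(k), per)
    extra <- n - per * k
    if (extra > 0) idx <- c(idx, sample(seq_len(k), extra))
    contrast <- sort(contrasts[idx])  # sorted; side balance runs per level
  } else {
    contrast <- rep(NA_real_, n)
  }
  target <- character(n)
  tilt <- numeric(n)
  for (lev in unique(contrast)) {
    sel <- if (is.na(lev)) which(is.na(contrast)) else which(contrast == lev)
    target[sel] <- balanced_levels(length(sel), c("left", "right"))
    tilt[sel] <- balanced_levels(length(sel), c(-20, 20))
  }
  salient <- switch(trial_type,
    neutral = rep("none", n),
    valid = target,
    invalid = ifelse(target == "left", "right", "left"))
  data.frame(
    task = task, condition = condition, trial_type = trial_type,
    validity_block = validity, salient_side = salient, target_side = target,
    contrast = contrast,
    tilt_deg = if (task == "covert") tilt else NA_real_,
    soa_ms = soa_ms, cue_eccentricity_deg = ecc,
    stringsAsFactors = FALSE)
}

build_schedule <- function(task, validity, contrasts, seed, n_neutral,
                           n_nonneutral, soa_ms, ecc, cue_duration_ms) {
  stopifnot(validity %in% c(50, 80))
  n_valid <- round(n_nonneutral * validity / 100)
  n_invalid <- n_nonneutral - n_valid
  with_seed(seed, {
    rows <- list()
    for (cond in c("experimental", "control")) {
      rows[[length(rows) + 1L]] <-
        cell_trials(task, cond, "neutral", n_neutral, validity, contrasts,
                    soa_ms, ecc)
      rows[[length(rows) + 1L]] <-
        cell_trials(task, cond, "valid", n_valid, validity, contrasts,
                    soa_ms, ecc)
      rows[[length(rows) + 1L]] <-
        cell_trials(task, cond, "invalid", n_invalid, validity, contrasts,
                    soa_ms, ecc)
    }
    df <- do.call(rbind, rows)
    df <- df[sample(nrow(df)), , drop = FALSE]
    df$trial <- seq_len(nrow(df))
    df <- df[, c("trial", setdiff(names(df), "trial"))]
    as_session_schedule(df, task = task, seed = seed, validity = validity,
                        soa_ms = soa_ms, cue_eccentricity_deg = ecc,
                        cue_duration_ms = cue_duration_ms)
  })
}

#' Build one covert-attention session schedule
#'
#' Generates the trial-by-trial design of one session of the covert 2AFC
#' orientation-discrimination task: per condition (experimental, control),
#' `n_neutral` neutral trials plus `n_nonneutral` non-neutral trials split by
#' the session's cue validity (50% block: 125 valid / 125 invalid; 80% block:
#' 200 valid / 50 invalid, at the printed defaults). Contrast levels are
#' assigned in near-equal counts per cell; target side and gabor tilt are
#' balanced within every condition x trial type x contrast cell (counts differ
#' by at most 1). Trial order is a seeded permutation.
#'
#' @param validity Cue-validity block, 50 or 80 (percent).
#' @param contrasts Exactly 8 strictly increasing contrasts in (0, 1).
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param n_neutral,n_nonneutral Per-condition trial counts (printed design:
#'   112 neutral per session, 250 non-neutral).
#' @param soa_ms Cue-to-target stimulus-onset asynchrony (default 150 ms).
#' @param cue_eccentricity_deg Cue eccentricity (default 5 degrees).
#' @param cue_duration_ms Cue duration metadata (default 25 ms).
#' @return A `session_schedule` (data frame; one row per trial) with design
#'   metadata in attributes.
#' @export
build_covert_schedule <- function(validity = 80, contrasts = default_contrasts(),
                                  seed = 1L, n_neutral = 112L,
                                  n_nonneutral = 250L, soa_ms = 150,
                                  cue_eccentricity_deg = 5,
                                  cue_duration_ms = 25) {
  if (length(contrasts) != 8 || any(diff(contrasts) <= 0) ||
      any(contrasts <= 0) || any(contrasts >= 1)) {
    stop("`contrasts` must be 8 strictly increasing values in (0, 1)")
  }
  build_schedule("covert", validity, contrasts, seed, n_neutral, n_nonneutral,
                 soa_ms, cue_eccentricity_deg, cue_duration_ms)
}

#' Build one gaze-orienting session schedule
#'
#' As [build_covert_schedule()] but for the saccade task: per condition,
#' `n_neutral` neutral (printed design: 100) and `n_nonneutral` non-neutral
#' trials split by the session's validity; no contrast or tilt factors.
#'
#' @inheritParams build_covert_schedule
#' @return A `session_schedule`.
#' @export
build_gaze_schedule <- function(validity = 80, seed = 1L, n_neutral = 100L,
                                n_nonneutral = 250L, soa_ms = 150,
                                cue_eccentricity_deg = 5,
                                cue_duration_ms = 25) {
  build_schedule("gaze", validity, NULL, seed, n_neutral, n_nonneutral,
                 soa_ms, cue_eccentricity_deg, cue_duration_ms)
}

#' Empirical cue validity of a schedule
#'
#' Percentage of non-neutral trials in which the target appears on the side
#' cued by the salient feature.
#'
#' @param schedule A `session_schedule` (or compatible data frame).
#' @return Percent in `[0, 100]`.
#' @export
validity_of <- function(schedule) {
  nn <- schedule$trial_type %in% c("valid", "invalid")
  if (!any(nn)) stop("schedule has no non-neutral trials")
  100 * sum(schedule$trial_type == "valid") / sum(nn)
}

#' Tally a schedule by condition, trial type and validity block
#'
#' @param schedule A `session_schedule`.
#' @return Data frame of cell counts.
#' @export
schedule_counts <- function(schedule) {
  as.data.frame(table(condition = schedule$condition,
                      trial_type = schedule$trial_type,
                      validity_block = schedule$validity_block),
                responseName = "n")
}
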
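# Synthetic observers: Bernoulli 2AFC responses from a cumulative-Gaussian
# psychometric function, and raw gaze traces with programmed saccades.

#' Covert-observer parameters
#'
#' Defaults follow the scale of the measured group data: baseline threshold
#' location near 0.045 contrast, spread 0.012, guess rate 0.5 (2AFC), no
#' lapses, and multiplicative threshold shifts of -5% (valid) and +10%
#' (invalid).
#'
#' @param mu_neutral Psychometric location (contrast) in neutral trials.
#' @param sigma Psychometric spread (contrast).
#' @param guess Guess rate (default 0.5).
#' @param lapse Lapse rate (default 0).
#' @param effect_valid,effect_invalid Fractional shifts of `mu` in valid /
#'   invalid trials.
#' @return An `observer_params` list.
#' @export
observer_params <- function(mu_neutral = 0.045, sigma = 0.012, guess = 0.5,
                            lapse = 0, effect_valid = -0.05,
                            effect_invalid = 0.10) {
  stopifnot(sigma > 0, guess >= 0, lapse >= 0, guess + lapse < 1,
            mu_neutral * (1 + effect_valid) > 0,
            mu_neutral * (1 + effect_invalid) > 0)
  structure(list(mu_neutral = mu_neutral, sigma = sigma, guess = guess,
                 lapse = lapse, effect_valid = effect_valid,
                 effect_invalid = effect_invalid),
            class = "observer_params")
}

#' Psychometric function: probability correct in a 2AFC task
#'
#' `guess + (1 - guess - lapse) * pnorm((contrast - mu) / sigma)`.
#'
#' @param contrast Stimulus contrast(s).
#' @param mu Location parameter (contrast).
#' @param sigma Spread parameter (contrast), > 0.
#' @param guess Guess rate (default 0.5).
#' @param lapse Lapse rate (default 0).
#' @return Probability of a correct response, vectorised over `contrast`.
#' @examples
#' psychometric_p(0.045, 0.045, 0.012)  # 0.75 at the location parameter
#' @export
psychometric_p <- function(contrast, mu, sigma, guess = 0.5, lapse = 0) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  guess + (1 - guess - lapse) * stats::pnorm((contrast - mu) / sigma)
}

#' Simulate 2AFC responses for a covert-task schedule
#'
#' Per trial, the effective location is `mu_neutral * (1 + effect)` for the
#' trial's type and a correct response is a Bernoulli draw from the
#' psychometric function at the trial's contrast.
#'
#' @param schedule A covert `session_schedule`.
#' @param params An [observer_params()].
#' @param seed Integer seed (reproducible).
#' @return Data frame: `trial`, `correct` (0/1), `rt_ms` (decorative).
#' @export
simulate_covert <- function(schedule, params = observer_params(), seed = 1L) {
  if (!identical(attr(schedule, "task") %||% schedule$task[1], "covert")) {
    stop("`schedule` is not a covert-task schedule")
  }
  eff <- c(neutral = 0, valid = params$effect_valid,
           invalid = params$effect_invalid)
  mu_t <- params$mu_neutral * (1 + eff[schedule$trial_type])
  p <- psychometric_p(schedule$contrast, mu_t, params$sigma, params$guess,
                      params$lapse)
  with_seed(seed, {
    data.frame(
      trial = schedule$trial,
      correct = stats::rbinom(nrow(schedule), 1L, p),
      rt_ms = round(stats::rnorm(nrow(schedule), 600, 80))
    )
  })
}

#' Gaze-simulator parameters
#'
#' Defaults emulate the measured oculomotor structure: 1 kHz sampling,
#' neutral-trial latency 165 +- 30 ms with -4% (valid) / +5% (invalid)
#' shifts, direction-error probabilities 2.5%/1%/5.5%
#' (neutral/valid/invalid), anticipatory-saccade probabilities 3% (neutral) /
#' 6% (non-neutral) with 85% directed to the salient side, 5-degree target
#' eccentricity, fixation noise sd 0.05 degrees, and a linear main sequence
#' of 55 1/s.
#'
#' @param sample_rate Sampling rate in Hz (>= 250; default 1000).
#' @param latency_mean_neutral,latency_sd Regular-saccade latency (ms).
#' @param effect_valid,effect_invalid Fractional latency shifts.
#' @param p_error Named direction-error probabilities per trial type.
#' @param p_anticipatory Named anticipatory probabilities per trial type.
#' @param p_anticipatory_to_salient Probability an anticipatory saccade goes
#'   to the salient side (non-neutral trials).
#' @param amplitude_deg Regular-saccade amplitude (target eccentricity).
#' @param noise_sd_deg Fixation noise sd (degrees).
#' @param main_sequence_slope Peak velocity per degree (1/s).
#' @param latency_window Truncation window (ms) for regular latencies.
#' @return A `gaze_sim_params` list.
#' @export
gaze_sim_params <- function(sample_rate = 1000,
                            latency_mean_neutral = 165, latency_sd = 30,
                            effect_valid = -0.04, effect_invalid = 0.05,
                            p_error = c(neutral = 0.025, valid = 0.01,
                                        invalid = 0.055),
                            p_anticipatory = c(neutral = 0.03, valid = 0.06,
                                               invalid = 0.06),
                            p_anticipatory_to_salient = 0.85,
                            amplitude_deg = 5, noise_sd_deg = 0.05,
                            main_sequence_slope = 55,
                            latency_window = c(80, 500)) {
  stopifnot(sample_rate >= 250, amplitude_deg > 0,
            all(p_error >= 0 & p_error <= 1),
            all(p_anticipatory >= 0 & p_anticipatory <= 1),
            p_anticipatory_to_salient >= 0, p_anticipatory_to_salient <= 1,
            main_sequence_slope > 0, noise_sd_deg >= 0)
  structure(list(sample_rate = sample_rate,
                 latency_mean_neutral = latency_mean_neutral,
                 latency_sd = latency_sd, effect_valid = effect_valid,
                 effect_invalid = effect_invalid, p_error = p_error,
                 p_anticipatory = p_anticipatory,
                 p_anticipatory_to_salient = p_anticipatory_to_salient,
                 amplitude_deg = amplitude_deg, noise_sd_deg = noise_sd_deg,
                 main_sequence_slope = main_sequence_slope,
                 latency_window = latency_window),
            class = "gaze_sim_params")
}

new_gaze_trace <- function(t, x, y, target_onset_ms = 0, target_side = NA,
                           salient_side = NA, events = NULL) {
  structure(list(t = t, x = x, y = y, target_onset_ms = target_onset_ms,
                 target_side = target_side, salient_side = salient_side,
                 events = events),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("Gaze trace: %d samples, t in [%g, %g] ms, target %s\n",
              length(x$t), min(x$t), max(x$t), x$target_side))
  invisible(x)
}

# Minimum-jerk position profile on s in [0, 1].
minjerk_s <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# Add a saccade of signed displacement `disp` starting (support onset) at
# `onset_ms` to position vector x sampled at times t_ms. Duration is
# 1.875/slope seconds, giving peak velocity = slope * |disp| exactly and
# total displacement exactly `disp`.
add_saccade <- function(x, t_ms, onset_ms, disp, slope) {
  dur_ms <- 1875 / slope
  x + disp * minjerk_s((t_ms - onset_ms) / dur_ms)
}

#' Simulate the raw gaze trace of one trial
#'
#' Produces a 1 kHz (by default) eye-position trace containing Gaussian
#' fixation noise plus programmed saccades: with probability
#' `p_anticipatory[trial_type]`, an anticipatory saccade (amplitude uniform
#' in 1-2.5 degrees, onset uniform in (-70, 80) ms relative to target onset,
#' directed to the salient side with probability
#' `p_anticipatory_to_salient`) followed by a corrective regular saccade to
#' the target; otherwise a single regular saccade of `amplitude_deg` toward
#' the target side (direction flipped with probability
#' `p_error[trial_type]`), with onset drawn from a truncated Gaussian.
#' Saccade waveforms are minimum-jerk: displacement is exact and peak
#' velocity equals `main_sequence_slope * amplitude` by construction; the
#' programmed onset is the start of the velocity-profile support.
#'
#' @param trial One row of a gaze `session_schedule`.
#' @param params A [gaze_sim_params()].
#' @param seed Optional integer seed.
#' @return A `gaze_trace`: `t` (ms relative to target onset, covering cue
#'   onset through 650 ms), `x`, `y` (degrees), trial metadata, and a
#'   `events` data frame of programmed saccades (kind, onset, amplitude,
#'   direction).
#' @export
simulate_gaze_trial <- function(trial, params = gaze_sim_params(),
                                seed = NULL) {
  type <- trial$trial_type
  with_seed(seed, {
    fs <- params$sample_rate
    t_ms <- seq(-250, 650, by = 1000 / fs)
    n <- length(t_ms)
    x <- stats::rnorm(n, 0, params$noise_sd_deg)
    y <- stats::rnorm(n, 0, params$noise_sd_deg)
    slope <- params$main_sequence_slope
    dur_ms <- 1875 / slope
    sgn <- c(left = -1, right = 1)
    target_x <- sgn[[trial$target_side]] * params$amplitude_deg

    eff <- switch(type, neutral = 0, valid = params$effect_valid,
                  invalid = params$effect_invalid)
    lat <- rtruncnorm(1, params$latency_mean_neutral * (1 + eff),
                      params$latency_sd, params$latency_window[1],
                      params$latency_window[2])
    events <- NULL
    pos <- 0
    if (stats::runif(1) < params$p_anticipatory[[type]]) {
      a_amp <- stats::runif(1, 1, 2.5)
      a_on <- stats::runif(1, -70, 80)
      a_dir <- if (type == "neutral") {
        sample(c("left", "right"), 1)
      } else if (stats::runif(1) < params$p_anticipatory_to_salient) {
        trial$salient_side
      } else {
        setdiff(c("left", "right"), trial$salient_side)
      }
      a_disp <- sgn[[a_dir]] * a_amp
      x <- add_saccade(x, t_ms, a_on, a_disp, slope)
      pos <- pos + a_disp
      # corrective regular saccade to the target, after the anticipatory one
      lat <- max(lat, a_on + dur_ms + 30)
      disp <- target_x - pos
      x <- add_saccade(x, t_ms, lat, disp, slope)
      events <- fast_df(
        kind = c("anticipatory", "regular"),
        onset_ms = c(a_on, lat),
        amplitude_deg = c(a_amp, abs(disp)),
        direction = c(a_dir, if (disp < 0) "left" else "right"))
    } else {
      err <- stats::runif(1) < params$p_error[[type]]
      disp <- if (err) -target_x else target_x
      x <- add_saccade(x, t_ms, lat, disp, slope)
      events <- fast_df(
        kind = "regular", onset_ms = lat, amplitude_deg = abs(disp),
        direction = if (disp < 0) "left" else "right")
    }
    new_gaze_trace(t_ms, x, y, target_onset_ms = 0,
                   target_side = trial$target_side,
                   salient_side = trial$salient_side, events = events)
  })
}

#' Simulate gaze traces for a whole session
#'
#' @param schedule A gaze `session_schedule`.
#' @param params A [gaze_sim_params()].
#' @param seed Integer root seed; each trial uses a derived child seed.
#' @return List of [gaze_trace][simulate_gaze_trial] objects, one per trial,
#'   in schedule order.
#' @export
simulate_gaze_session <- function(schedule, params = gaze_sim_params(),
                                  seed = 1L) {
  if (!identical(attr(schedule, "task") %||% schedule$task[1], "gaze")) {
    stop("`schedule` is not a gaze-task schedule")
  }
  rows <- df_rows(as.data.frame(schedule))
  lapply(seq_along(rows), function(i) {
    simulate_gaze_trial(rows[[i]], params, seed = child_seed(seed, i))
  })
}
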
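# Shared helpers: independent oracles and small builders.

# Wrap a probability vector as a patch_distribution (counts scaled to sum 1).
make_dist <- function(p, patch_side = 1L) {
  structure(list(patch_side = patch_side, probs = p, counts = p * 1e6,
                 total_count = 1e6),
            class = "patch_distribution")
}

# Exhaustive-enumeration oracle for the constrained-entropy selection:
# every subset of every feasible size, no pruning. Independent of the
# package's branch-and-bound solver.
oracle_select <- function(p, N, W) {
  m <- length(p)
  best_H <- 0
  best <- integer(0)
  for (k in seq_len(min(N, m))) {
    combs <- utils::combn(m, k)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      if (any(p[idx] <= 0)) next
      if (sum(p[idx]) > W + 1e-12) next
      H <- -sum(p[idx] * log2(p[idx]))
      if (H > best_H + 1e-12) {
        best_H <- H
        best <- idx
      }
    }
  }
  list(H = best_H, sel = sort(best))
}

# One-row gaze "trial" for classification tests.
toy_trial <- function(trial_type = "valid", target_side = "right",
                      salient_side = "right", ecc = 5) {
  list(trial = 1L, task = "gaze", condition = "experimental",
       trial_type = trial_type, validity_block = 80,
       salient_side = salient_side, target_side = target_side,
       cue_eccentricity_deg = ecc)
}

# Event table in the shape detect_saccades() returns.
toy_events <- function(onset, amplitude, direction) {
  data.frame(onset_ms = onset, offset_ms = onset + 40, start_ms = onset - 3,
             amplitude_deg = amplitude, peak_velocity_deg_s = 55 * amplitude,
             direction = direction, stringsAsFactors = FALSE)
}

# Gaze-simulation parameter sets used across tests.
quiet_gaze_params <- function(...) {
  gaze_sim_params(noise_sd_deg = 0,
                  p_error = c(neutral = 0, valid = 0, invalid = 0),
                  p_anticipatory = c(neutral = 0, valid = 0, invalid = 0),
                  ...)
}
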
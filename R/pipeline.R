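# End-to-end synthetic experiment: design -> simulate -> analyse -> report.

#' Configuration for an end-to-end synthetic run
#'
#' Bundles every stage's parameters plus a root seed. Per-participant and
#' per-stage seeds are derived deterministically from the root seed (a
#' counter-hash scheme), so a run is fully reproducible from its config and
#' individual stages can be re-run in isolation.
#'
#' @param seed Root integer seed.
#' @param n_participants Simulated cohort size (default 16 per task).
#' @param observer [observer_params()] for the covert task.
#' @param gaze [gaze_sim_params()] for the gaze task.
#' @param contrasts Covert contrast levels (8 values).
#' @param criterion Threshold criterion (default 0.8).
#' @param covert_n_neutral,covert_n_nonneutral,gaze_n_neutral,gaze_n_nonneutral
#'   Per-session, per-condition trial counts; defaults are the printed
#'   design (112/250 covert, 100/250 gaze).
#' @param detection List of [detect_saccades()] overrides.
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_participants = 16L,
                       observer = observer_params(),
                       gaze = gaze_sim_params(),
                       contrasts = default_contrasts(), criterion = 0.8,
                       covert_n_neutral = 112L, covert_n_nonneutral = 250L,
                       gaze_n_neutral = 100L, gaze_n_nonneutral = 250L,
                       detection = list(), out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 observer = observer, gaze = gaze, contrasts = contrasts,
                 criterion = criterion,
                 covert_n_neutral = covert_n_neutral,
                 covert_n_nonneutral = covert_n_nonneutral,
                 gaze_n_neutral = gaze_n_neutral,
                 gaze_n_nonneutral = gaze_n_nonneutral,
                 detection = detection, out_dir = out_dir),
            class = "run_config")
}

# Simulate and analyse one participant's covert task (both validity sessions).
covert_participant <- function(config, pid) {
  scheds <- list(); resps <- list(); offset <- 0L
  for (v in c(50, 80)) {
    sc <- build_covert_schedule(v, config$contrasts,
                                seed = child_seed(config$seed, pid, v, 1),
                                n_neutral = config$covert_n_neutral,
                                n_nonneutral = config$covert_n_nonneutral)
    rs <- simulate_covert(sc, config$observer,
                          seed = child_seed(config$seed, pid, v, 2))
    sc$trial <- sc$trial + offset
    rs$trial <- rs$trial + offset
    offset <- offset + nrow(sc)
    scheds[[as.character(v)]] <- as.data.frame(sc)
    resps[[as.character(v)]] <- rs
  }
  sched <- do.call(rbind, scheds)
  resp <- do.call(rbind, resps)
  resp$participant <- pid
  cells <- covert_summary(resp, sched, criterion = config$criterion,
                          guess = config$observer$guess,
                          lapse = config$observer$lapse)
  cells$participant <- pid
  cells
}

# Simulate and analyse one participant's gaze task (both validity sessions).
gaze_participant <- function(config, pid) {
  cls <- list()
  for (v in c(50, 80)) {
    sc <- build_gaze_schedule(v, seed = child_seed(config$seed, pid, v, 3),
                              n_neutral = config$gaze_n_neutral,
                              n_nonneutral = config$gaze_n_nonneutral)
    traces <- simulate_gaze_session(sc, config$gaze,
                                    seed = child_seed(config$seed, pid, v, 4))
    cls <- c(cls, do.call(analyze_gaze_session,
                          c(list(traces = traces, schedule = sc),
                            config$detection)))
  }
  tab <- summarize_gaze(cls)
  tab$participant <- pid
  tab
}

#' Run the full synthetic experiment end to end
#'
#' For every simulated participant: builds both validity-session schedules of
#' both tasks, simulates responses and gaze traces, runs the psychometric and
#' oculomotor analyses, and aggregates cohort-level tables (2 conditions x 2
#' validities x 3 trial types = 12 covert threshold cells and 12 gaze latency
#' cells). Identical configs (including seed) produce identical outputs.
#'
#' @param config A [run_config()].
#' @return List: `covert_cells`, `covert_group`, `gaze_cells`, `gaze_group`,
#'   `manifest` (tallies, paths and MD5 checksums when `out_dir` is set).
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  covert_cells <- do.call(rbind, lapply(seq_len(config$n_participants),
                                        function(p) {
    tryCatch(covert_participant(config, p),
             error = function(e) stop("covert stage, participant ", p, ": ",
                                      conditionMessage(e)))
  }))
  gaze_cells <- do.call(rbind, lapply(seq_len(config$n_participants),
                                      function(p) {
    tryCatch(gaze_participant(config, p),
             error = function(e) stop("gaze stage, participant ", p, ": ",
                                      conditionMessage(e)))
  }))
  covert_group <- covert_group_summary(covert_cells)
  gaze_group <- gaze_group_summary(gaze_cells)
  manifest <- list(
    seed = config$seed, n_participants = config$n_participants,
    covert_trials = 2 * 2 *
      (config$covert_n_neutral + config$covert_n_nonneutral) *
      config$n_participants,
    gaze_trials = 2 * 2 * (config$gaze_n_neutral + config$gaze_n_nonneutral) *
      config$n_participants,
    covert_cells = nrow(covert_group), gaze_cells = nrow(gaze_group))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(config$out_dir,
                       c("covert_cells.csv", "covert_group.csv",
                         "gaze_cells.csv", "gaze_group.csv"))
    utils::write.csv(covert_cells, paths[1], row.names = FALSE)
    utils::write.csv(covert_group, paths[2], row.names = FALSE)
    utils::write.csv(gaze_cells, paths[3], row.names = FALSE)
    utils::write.csv(gaze_group, paths[4], row.names = FALSE)
    manifest$files <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(covert_cells = covert_cells, covert_group = covert_group,
       gaze_cells = gaze_cells, gaze_group = gaze_group, manifest = manifest)
}

#' Parameter-recovery report over replicate cohorts
#'
#' Replicates the end-to-end run with fresh derived seeds and summarises how
#' well the analysis recovers the simulator's ground-truth parameters:
#' covert and gaze cueing effects (fractional threshold / latency shifts),
#' direction-error probabilities, anticipatory-saccade rate, and the
#' anticipatory direction preference.
#'
#' @param config A [run_config()].
#' @param n_replicates Number of replicate cohorts (>= 2).
#' @return Data frame: `parameter`, `true`, `recovered_mean`, `bias`, `rmse`.
#' @export
recovery_report <- function(config = run_config(), n_replicates = 10L) {
  stopifnot(n_replicates >= 2)
  one <- function(r) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, 7777, r)
    res <- run_end_to_end(cfg)
    cg <- res$covert_group
    gg <- res$gaze_group
    gc <- res$gaze_cells
    pooled_pct <- function(type_sel) {
      d <- gc[gc$trial_type %in% type_sel, ]
      sum(d$n_anticipatory) /
        sum(d$n_trials - d$n_aberrant)
    }
    err_rate <- function(type_sel) {
      d <- gc[gc$trial_type %in% type_sel, ]
      sum(d$n_erroneous) / sum(d$n_regular)
    }
    ant_sal <- {
      d <- gc[gc$trial_type != "neutral" & gc$n_anticipatory > 0, ]
      sum(d$pct_anticipatory_to_salient / 100 * d$n_anticipatory) /
        sum(d$n_anticipatory)
    }
    c(covert_effect_valid =
        mean(cg$relative_change_pct[cg$trial_type == "valid"]) / 100,
      covert_effect_invalid =
        mean(cg$relative_change_pct[cg$trial_type == "invalid"]) / 100,
      gaze_effect_valid =
        mean(gg$latency_change_pct[gg$trial_type == "valid"]) / 100,
      gaze_effect_invalid =
        mean(gg$latency_change_pct[gg$trial_type == "invalid"]) / 100,
      p_error_valid = err_rate("valid"),
      p_error_invalid = err_rate("invalid"),
      p_anticipatory_nonneutral = pooled_pct(c("valid", "invalid")),
      p_anticipatory_to_salient = ant_sal)
  }
  rec <- t(vapply(seq_len(n_replicates), one, numeric(8)))
  truth <- c(config$observer$effect_valid, config$observer$effect_invalid,
             config$gaze$effect_valid, config$gaze$effect_invalid,
             config$gaze$p_error[["valid"]], config$gaze$p_error[["invalid"]],
             config$gaze$p_anticipatory[["valid"]],
             config$gaze$p_anticipatory_to_salient)
  data.frame(
    parameter = colnames(rec),
    true = truth,
    recovered_mean = colMeans(rec),
    bias = colMeans(rec) - truth,
    rmse = sqrt(colMeans((rec - matrix(truth, n_replicates, 8,
                                       byrow = TRUE))^2)),
    row.names = NULL, stringsAsFactors = FALSE)
}
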
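# Maximum-likelihood cumulative-Gaussian psychometric fitting, 80%-correct
# thresholds, and baseline-relative changes (covert-task analysis).

#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Maximises the binomial log-likelihood
#' `sum(k * log(psi) + (n - k) * log(1 - psi))` over location `mu` and spread
#' `sigma`, with `psi` from [psychometric_p()] and fixed guess/lapse rates.
#' Optimisation is a Nelder-Mead simplex (on `mu`, `log sigma`) multi-started
#' from a 5 x 5 coarse grid. Degenerate data (all levels at ceiling, or no
#' level above the guess rate) are flagged `converged = FALSE` instead of
#' returning an arbitrary fit.
#'
#' @param levels Contrast levels (>= 2 distinct, finite).
#' @param k_correct Correct-response counts per level.
#' @param n_total Trial counts per level (total >= 20).
#' @param guess Fixed guess rate (default 0.5, 2AFC).
#' @param lapse Fixed lapse rate (default 0).
#' @return A `psych_fit`: `mu`, `sigma`, `guess`, `lapse`, `loglik`,
#'   `converged`, `degenerate`, `n_trials`, plus the data.
#' @export
fit_psychometric <- function(levels, k_correct, n_total, guess = 0.5,
                             lapse = 0) {
  if (length(levels) != length(k_correct) ||
      length(levels) != length(n_total)) {
    stop("`levels`, `k_correct` and `n_total` must have equal length")
  }
  if (any(!is.finite(levels)) || any(!is.finite(k_correct)) ||
      any(!is.finite(n_total))) {
    stop("non-finite values in psychometric data")
  }
  if (any(k_correct < 0) || any(k_correct > n_total)) {
    stop("counts must satisfy 0 <= k <= n at every level")
  }
  if (length(unique(levels)) < 2) stop("need >= 2 distinct levels")
  if (sum(n_total) < 20) stop("need >= 20 trials in total")

  prop <- k_correct / n_total
  degenerate <- all(k_correct == n_total) ||
    all(prop <= guess + 1e-12) || all(prop >= 1 - lapse - 1e-12)

  span <- diff(range(levels))
  negll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    psi <- psychometric_p(levels, mu, sigma, guess, lapse)
    psi <- pmin(pmax(psi, guess + 1e-12), 1 - lapse - 1e-12)
    -sum(k_correct * log(psi) + (n_total - k_correct) * log1p(-psi))
  }
  fit <- NULL
  if (!degenerate) {
    mu0 <- seq(min(levels), max(levels), length.out = 5)
    ls0 <- log(span * c(0.05, 0.15, 0.4, 1, 2.5))
    starts <- expand.grid(mu = mu0, ls = ls0)
    vals <- apply(starts, 1, negll)
    best <- NULL
    for (i in order(vals)[1:3]) {
      o <- stats::optim(as.numeric(starts[i, ]), negll,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 2000))
      if (is.null(best) || o$value < best$value - 1e-12) best <- o
    }
    fit <- best
  }
  converged <- !degenerate && fit$convergence == 0 &&
    exp(fit$par[2]) < 50 * span
  structure(
    list(mu = if (is.null(fit)) NA_real_ else fit$par[1],
         sigma = if (is.null(fit)) NA_real_ else exp(fit$par[2]),
         guess = guess, lapse = lapse,
         loglik = if (is.null(fit)) NA_real_ else -fit$value,
         converged = converged, degenerate = degenerate,
         n_trials = sum(n_total),
         data = data.frame(level = levels, k = k_correct, n = n_total)),
    class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Psychometric fit: mu = %.5f, sigma = %.5f (guess %.2f, lapse %.2f)\n",
      x$mu, x$sigma, x$guess, x$lapse))
    cat(sprintf("  loglik = %.3f over %d trials\n", x$loglik, x$n_trials))
  } else {
    cat("Psychometric fit: not converged",
        if (x$degenerate) "(degenerate data)" else "", "\n")
  }
  invisible(x)
}

#' @export
plot.psych_fit <- function(x, criterion = 0.8, ...) {
  with(x$data, plot(level, k / n, ylim = c(0, 1), pch = 16,
                    xlab = "contrast", ylab = "proportion correct", ...))
  if (x$converged) {
    cc <- seq(min(x$data$level), max(x$data$level), length.out = 200)
    graphics::lines(cc, psychometric_p(cc, x$mu, x$sigma, x$guess, x$lapse))
    thr <- threshold_at(x, criterion)
    graphics::abline(v = thr, h = criterion, lty = 3)
  }
  invisible(x)
}

#' Contrast threshold at a criterion performance level
#'
#' Inverts the fitted psychometric function:
#' `mu + sigma * qnorm((criterion - guess) / (1 - guess - lapse))`.
#' Evaluating the fitted curve at the returned contrast gives exactly the
#' criterion.
#'
#' @param fit A converged [psych_fit][fit_psychometric].
#' @param criterion Criterion probability correct (default 0.80), strictly
#'   between `guess` and `1 - lapse`.
#' @return Contrast threshold.
#' @export
threshold_at <- function(fit, criterion = 0.8) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; no threshold")
  if (criterion <= fit$guess || criterion >= 1 - fit$lapse) {
    stop(sprintf("criterion %.3f outside attainable range (%.3f, %.3f)",
                 criterion, fit$guess, 1 - fit$lapse))
  }
  fit$mu + fit$sigma *
    stats::qnorm((criterion - fit$guess) / (1 - fit$guess - fit$lapse))
}

#' Percentage change relative to a baseline
#'
#' `100 * (value - baseline) / baseline`; the covert task reports threshold
#' changes of valid/invalid trials relative to the same condition's neutral
#' baseline this way.
#'
#' @param value,baseline Numeric; `baseline` must be > 0.
#' @return Percent change (vectorised).
#' @export
relative_change <- function(value, baseline) {
  if (any(baseline <= 0)) stop("`baseline` must be > 0")
  100 * (value - baseline) / baseline
}

#' Threshold summary of a covert-task data set
#'
#' Joins responses to the schedule, pools trials per condition x validity x
#' trial-type cell (per participant when a `participant` column is present),
#' fits the psychometric function in each cell, extracts the
#' criterion-correct threshold, and computes the relative change of
#' valid/invalid thresholds against the same condition-and-validity neutral
#' baseline.
#'
#' @param responses Data frame with `trial`, `correct` (and optionally
#'   `participant`); e.g. from [simulate_covert()].
#' @param schedule The covert `session_schedule` (or several rbind-ed
#'   sessions) the responses refer to.
#' @param criterion Threshold criterion (default 0.80).
#' @param guess,lapse Fixed psychometric rates.
#' @return Data frame with one row per cell: `participant`, `condition`,
#'   `validity_block`, `trial_type`, `n`, `mu`, `sigma`, `converged`,
#'   `threshold`, `relative_change_pct`.
#' @export
covert_summary <- function(responses, schedule, criterion = 0.8, guess = 0.5,
                           lapse = 0) {
  sched <- as.data.frame(schedule)
  if (is.null(responses$participant)) responses$participant <- 1L
  key_s <- if (!is.null(sched$participant)) {
    paste(sched$participant, sched$trial)
  } else sched$trial
  by_part <- split(responses, responses$participant)
  out <- list()
  for (pid in names(by_part)) {
    resp <- by_part[[pid]]
    key_r <- if (!is.null(sched$participant)) {
      paste(resp$participant, resp$trial)
    } else resp$trial
    idx <- match(key_r, key_s)
    if (anyNA(idx)) {
      stop("responses with no matching schedule row; orphan trial ids: ",
           paste(utils::head(resp$trial[is.na(idx)], 10), collapse = ", "))
    }
    dat <- cbind(resp[c("trial", "correct")],
                 sched[idx, c("condition", "validity_block", "trial_type",
                              "contrast")])
    cells <- split(dat, list(dat$condition, dat$validity_block,
                             dat$trial_type), drop = TRUE)
    rows <- lapply(cells, function(d) {
      agg <- stats::aggregate(cbind(k = correct, n = 1) ~ contrast, data = d,
                              FUN = sum)
      fit <- fit_psychometric(agg$contrast, agg$k, agg$n, guess, lapse)
      data.frame(participant = pid, condition = d$condition[1],
                 validity_block = d$validity_block[1],
                 trial_type = d$trial_type[1], n = nrow(d),
                 mu = fit$mu, sigma = fit$sigma, converged = fit$converged,
                 threshold = if (fit$converged) {
                   threshold_at(fit, criterion)
                 } else NA_real_,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    # relative change vs the same condition x validity neutral baseline
    tab$relative_change_pct <- NA_real_
    for (i in seq_len(nrow(tab))) {
      if (tab$trial_type[i] == "neutral") next
      base <- tab$threshold[tab$condition == tab$condition[i] &
                            tab$validity_block == tab$validity_block[i] &
                            tab$trial_type == "neutral"]
      if (length(base) == 1 && is.finite(base) && base > 0 &&
          is.finite(tab$threshold[i])) {
        tab$relative_change_pct[i] <- relative_change(tab$threshold[i], base)
      }
    }
    out[[pid]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-average covert summary
#'
#' Averages per-participant thresholds and per-participant relative changes
#' (mean of changes, matching subject-wise averaging) over participants.
#'
#' @param cell_table Output of [covert_summary()].
#' @return Data frame per condition x validity x trial type with group mean
#'   threshold, SEM, and mean relative change.
#' @export
covert_group_summary <- function(cell_table) {
  sem <- function(x) stats::sd(x) / sqrt(sum(is.finite(x)))
  agg <- stats::aggregate(
    cbind(threshold, relative_change_pct) ~
      condition + validity_block + trial_type,
    data = cell_table, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  se <- stats::aggregate(threshold ~ condition + validity_block + trial_type,
                         data = cell_table, FUN = sem)
  agg$threshold_sem <- se$threshold
  agg$relative_change_pct[is.nan(agg$relative_change_pct)] <- NA_real_
  agg
}
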
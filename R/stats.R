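# Group-level statistics: within-subject factorial ANOVA, Bonferroni paired
# t tests, Friedman/Conover rank tests, and two-proportion z tests.

#' Repeated-measures factorial ANOVA
#'
#' Fully within-subject factorial ANOVA (one observation per participant and
#' cell) via the standard error-strata decomposition; effect sizes are
#' classical eta-squared, `SS_effect / SS_total`, where `SS_total` sums every
#' stratum including the between-participant one.
#'
#' @param data Data frame in long format.
#' @param response Name of the response column (e.g. threshold, latency).
#' @param within Character vector of within-subject factor columns.
#' @param id Participant-identifier column (default `"participant"`).
#' @return Data frame: `effect`, `df1`, `df2`, `ss`, `F`, `p`, `eta_squared`.
#' @export
rm_factorial_anova <- function(data, response, within,
                               id = "participant") {
  stopifnot(all(c(response, within, id) %in% names(data)))
  data <- data[stats::complete.cases(data[c(response, within, id)]), ]
  for (v in c(within, id)) data[[v]] <- factor(data[[v]])
  tab <- table(data[c(id, within)])
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("design is not complete (one observation per participant and cell); ",
         "first offending cell: ",
         paste(dimnames(tab)[[1]][bad[1, 1]], collapse = " "),
         " x ", paste(vapply(seq_along(within), function(j)
           dimnames(tab)[[j + 1]][bad[1, j + 1]], character(1)),
           collapse = " x "))
  }
  if (nlevels(data[[id]]) < 3) stop("need >= 3 participants")
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                   response, rhs, id, rhs))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  rows <- list()
  ss_total <- 0
  for (stratum in sm) {
    st <- if (is.list(stratum)) stratum[[1]] else stratum
    ss_total <- ss_total + sum(st[["Sum Sq"]])
    effs <- trimws(rownames(st))
    for (i in seq_along(effs)) {
      if (effs[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effs[i], df1 = st[["Df"]][i],
        df2 = st[["Df"]][effs == "Residuals"],
        ss = st[["Sum Sq"]][i], F = st[["F value"]][i],
        p = st[["Pr(>F)"]][i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$eta_squared <- out$ss / ss_total
  attr(out, "ss_total") <- ss_total
  out
}

#' Paired t tests with Bonferroni correction
#'
#' One paired t test per requested comparison; p values are multiplied by
#' the number of comparisons and capped at 1. Zero-variance difference
#' vectors are reported as degenerate rather than as infinite t.
#'
#' @param values Named list (or data frame) of equal-length paired vectors,
#'   one per cell/condition.
#' @param comparisons List of 2-element character vectors naming the cells
#'   to compare.
#' @return Data frame: `pair`, `t`, `df`, `p`, `p_corrected`, `degenerate`.
#' @export
paired_bonferroni <- function(values, comparisons) {
  values <- as.list(values)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    a <- values[[cp[1]]]; b <- values[[cp[2]]]
    if (length(a) != length(b)) stop("paired vectors of unequal length")
    if (length(a) < 3) stop("need >= 3 paired observations")
    d <- a - b
    if (stats::sd(d) == 0) {
      # identical vectors: no difference at all (t = 0, p = 1); a non-zero
      # constant difference would give infinite t and is flagged instead
      zero <- all(d == 0)
      return(data.frame(pair = paste(cp, collapse = " vs "),
                        t = if (zero) 0 else NA_real_,
                        df = length(d) - 1,
                        p = if (zero) 1 else NA_real_,
                        degenerate = !zero, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(pair = paste(cp, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, out$p * m)
  out
}

#' Friedman test with Kendall's W and Conover post-hoc comparisons
#'
#' Friedman rank test across k related conditions (participants as blocks,
#' midranks for ties), the classical chi-squared statistic, Kendall's
#' coefficient of concordance `W = chi2 / (n (k - 1))`, and Conover's
#' pairwise rank-sum t tests with Bonferroni correction. Designed for
#' binomially distributed summaries such as per-participant direction-error
#' proportions.
#'
#' @param x Matrix or data frame, participants in rows, conditions in
#'   columns.
#' @return List: `chi2`, `df`, `p`, `kendall_w`, `n_all_tied` (uninformative
#'   rows), and `posthoc` (pair, t, df, p, p_corrected).
#' @export
friedman_conover <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (k < 3) stop("need >= 3 conditions")
  if (n < 3) stop("need >= 3 participants")
  r <- t(apply(x, 1, rank))  # midranks
  all_tied <- apply(x, 1, function(row) length(unique(row)) == 1)
  R <- colSums(r)
  chi2 <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  df <- k - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  w <- chi2 / (n * (k - 1))
  # Conover (1999) pairwise comparisons on rank sums
  A <- sum(r^2)
  B <- sum(R^2) / n
  dfc <- (n - 1) * (k - 1)
  s2 <- 2 * n * (A - B) / dfc
  pairs <- utils::combn(k, 2)
  nm <- colnames(x) %||% paste0("c", seq_len(k))
  ph <- apply(pairs, 2, function(ij) {
    tt <- (R[ij[1]] - R[ij[2]]) / sqrt(s2)
    data.frame(pair = paste(nm[ij[1]], "vs", nm[ij[2]]),
               t = tt, df = dfc,
               p = 2 * stats::pt(abs(tt), dfc, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_corrected <- pmin(1, ph$p * ncol(pairs))
  list(chi2 = chi2, df = df, p = p, kendall_w = w,
       n_all_tied = sum(all_tied), posthoc = ph)
}

#' Two-proportion z test (pooled variance)
#'
#' Normal-approximation comparison of two binomial proportions, appropriate
#' when both counts are large (>= 30 observations; a warning, not an error,
#' below that).
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 > 0, n2 > 0)
  if (n1 < 30 || n2 < 30) {
    warning("group sizes below 30; the normal approximation may be poor")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p, p1 = p1, p2 = p2)
}
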
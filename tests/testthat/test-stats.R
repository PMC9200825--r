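# Group statistics: within-subject ANOVA, paired tests, rank tests,
# proportion tests.

sim_cohort <- function(n = 16, effect = 0.5, seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n),
                   condition = c("experimental", "control"),
                   trial_type = c("neutral", "valid", "invalid"),
                   validity = c(50, 80))
  subj <- rnorm(n, 0, 1)[d$participant]
  d$y <- subj + effect * (d$trial_type == "invalid") -
    effect * (d$trial_type == "valid") + rnorm(nrow(d), 0, 0.3)
  d
}

test_that("within-subject ANOVA df and SS partition match the design", {
  d <- sim_cohort(16)
  a <- rm_factorial_anova(d, "y", c("condition", "trial_type", "validity"))
  tt <- a[a$effect == "trial_type", ]
  expect_equal(c(tt$df1, tt$df2), c(2, 30))  # 3 levels, 16 participants
  expect_lt(tt$p, 0.05)
  cond <- a[a$effect == "condition", ]
  expect_equal(c(cond$df1, cond$df2), c(1, 15))
  expect_true(all(a$eta_squared >= 0 & a$eta_squared <= 1))
  # incomplete designs are refused
  expect_error(
    rm_factorial_anova(d[-1, ], "y", c("condition", "trial_type",
                                       "validity")),
    "not complete")
})

test_that("one-factor ANOVA F matches a hand sums-of-squares oracle", {
  # small within-subject dataset, one factor, worked by hand
  d <- data.frame(participant = rep(1:4, each = 2),
                  condition = rep(c("a", "b"), 4),
                  trial_type = "x", validity = 50,
                  y = c(3, 5, 2, 4, 6, 9, 4, 5))
  a <- rm_factorial_anova(d, "y", "condition")
  y <- matrix(d$y, ncol = 2, byrow = TRUE)
  n <- 4
  diff_means <- mean(y[, 2] - y[, 1])
  ss_cond <- n * sum((colMeans(y) - mean(y))^2)
  subj_m <- rowMeans(y)
  ss_subj <- 2 * sum((subj_m - mean(y))^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_hand <- (ss_cond / 1) / (ss_err / (n - 1))
  expect_equal(a$F[a$effect == "condition"], F_hand, tolerance = 1e-6)
  expect_equal(a$eta_squared[a$effect == "condition"], ss_cond / ss_tot,
               tolerance = 1e-6)
  expect_equal(sum(a$ss) + (attr(a, "ss_total") - sum(a$ss)),
               attr(a, "ss_total"))
})

test_that("paired comparisons apply the Bonferroni correction", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  r <- paired_bonferroni(same, list(c("a", "b")))
  expect_equal(r$t, 0)
  expect_equal(r$p_corrected, 1)
  # constant non-zero differences: infinite-t guard
  cst <- paired_bonferroni(list(a = c(2, 3, 4, 5), b = c(1, 2, 3, 4)),
                           list(c("a", "b")))
  expect_true(cst$degenerate)
  # hand-computed: differences (2, 4, 6) -> t = 4 / (2 / sqrt(3))
  v <- list(a = c(3, 5, 7), b = c(1, 1, 1))
  r2 <- paired_bonferroni(v, list(c("a", "b"), c("b", "a")))
  expect_equal(r2$t[1], 3.464102, tolerance = 1e-6)
  expect_equal(r2$df[1], 2)
  expect_equal(r2$p_corrected[1], min(1, r2$p[1] * 2))
  expect_equal(r2$t[2], -r2$t[1])
  expect_error(paired_bonferroni(list(a = 1:2, b = 2:3), list(c("a", "b"))),
               ">= 3")
})

test_that("Friedman statistic matches the classical formula and base R", {
  # perfect concordance: W = 1
  x <- matrix(rep(c(1, 5, 9), 4), 4, byrow = TRUE)
  f <- friedman_conover(x)
  expect_equal(f$kendall_w, 1)
  # hand-worked 4 x 3 rank table
  y <- matrix(c(1, 2, 3,
                2, 1, 3,
                1, 3, 2,
                1, 2, 3), 4, byrow = TRUE)
  n <- 4; k <- 3
  R <- colSums(y)
  chi2_hand <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  fy <- friedman_conover(y)
  expect_equal(fy$chi2, chi2_hand)
  expect_equal(fy$df, 2)
  # cross-check against the independent base-R implementation
  set.seed(5)
  z <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman_conover(z)$chi2,
               unname(stats::friedman.test(z)$statistic), tolerance = 1e-9)
  expect_equal(friedman_conover(z)$p,
               stats::friedman.test(z)$p.value, tolerance = 1e-9)
  # Conover table covers all pairs with Bonferroni capping
  expect_equal(nrow(fy$posthoc), 3)
  expect_true(all(fy$posthoc$p_corrected <= 1))
  expect_error(friedman_conover(z[, 1:2]), ">= 3 conditions")
})

test_that("two-proportion z follows the pooled-variance formula", {
  r <- two_proportion_z(60, 100, 40, 100)
  expect_equal(r$z, 0.2 / sqrt(0.5 * 0.5 * (1 / 100 + 1 / 100)))
  expect_equal(r$z, 2.828427, tolerance = 1e-6)
  expect_equal(two_proportion_z(30, 100, 30, 100)$z, 0)
  expect_equal(two_proportion_z(40, 100, 60, 100)$z, -r$z)
  expect_warning(two_proportion_z(5, 10, 5, 10), "below 30")
  one <- two_proportion_z(60, 100, 40, 100, alternative = "greater")
  expect_equal(one$p, r$p / 2, tolerance = 1e-12)
})
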
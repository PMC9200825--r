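# Feature model: binarization, patch statistics, constrained-entropy
# selection, cue rendering.

test_that("binarization thresholds at the median with ties mapped to 1", {
  expect_equal(binarize_image(matrix(7, 4, 4)),
               matrix(1L, 4, 4))
  chk <- matrix(c(10, 200, 200, 10), 2)
  expect_equal(binarize_image(chk), matrix(c(0L, 1L, 1L, 0L), 2))
  set.seed(11)
  img <- matrix(runif(256^2), 256, 256)
  frac <- mean(binarize_image(img))
  expect_gt(frac, 0.49)
  expect_lt(frac, 0.51)
  expect_error(binarize_image(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(binarize_image(matrix(c(1, NA), 1)), "non-finite")
})

test_that("patch distribution counts every stride-1 window", {
  d <- estimate_patch_distribution(matrix(0, 10, 10), 3)
  expect_equal(d$total_count, 64)
  expect_equal(d$probs[1], 1)
  expect_equal(sum(d$probs[-1]), 0)

  one <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  d1 <- estimate_patch_distribution(one, 3)
  expect_equal(d1$total_count, 1)
  # MSB = top-left, row-major: that pattern is code 2^8 = 256
  expect_equal(d1$probs[256 + 1], 1)

  set.seed(2)
  imgs <- lapply(1:3, function(i) matrix(rbinom(40 * 30, 1, 0.5), 40, 30))
  d2 <- estimate_patch_distribution(imgs, 3)
  expect_equal(sum(d2$probs), 1, tolerance = 1e-12)
  expect_identical(d2$probs, d2$counts / d2$total_count)
  expect_equal(d2$total_count, 3 * (40 - 2) * (30 - 2))

  expect_error(estimate_patch_distribution(list(imgs[[1]], matrix(0, 2, 9)), 3),
               "image 2")
})

test_that("patch statistics of near-uniform pixels approach uniformity", {
  # binomial standard-error bound at ~700k windows
  set.seed(5)
  imgs <- lapply(1:3, function(i) matrix(rbinom(512^2, 1, 0.5), 512, 512))
  d <- estimate_patch_distribution(imgs, 3)
  expect_lt(max(abs(d$probs - 1 / 512)), 0.0015)
})

test_that("optimal selection matches hand-enumerated examples", {
  d <- make_dist(c(0.5, 0.3, 0.2))
  s <- select_optimal_features(d, N = 1, W = 1)
  expect_equal(s$patches, 1L)  # the 0.3 item: -0.3 log2 0.3 is the largest term
  expect_equal(s$achieved_entropy, 0.5210897, tolerance = 1e-6)

  d2 <- make_dist(c(0.5, 0.2, 0.05, 0.25))
  s2 <- select_optimal_features(d2, N = 2, W = 0.25)
  expect_equal(s2$patches, c(1L, 2L))  # {0.2, 0.05}: only feasible 2-set
  expect_equal(s2$achieved_entropy, 0.6804820, tolerance = 1e-6)

  # non-binding constraints select every positive-probability patch
  d3 <- make_dist(c(0.4, 0, 0.35, 0.25))
  s3 <- select_optimal_features(d3, N = 10, W = 1)
  expect_equal(s3$patches, c(0L, 2L, 3L))
})

test_that("optimal selection equals the exhaustive oracle on small alphabets", {
  set.seed(7)
  for (rep in 1:40) {
    m <- sample(3:12, 1)
    p <- rgamma(m, 1)
    p <- p / sum(p)
    N <- sample(1:m, 1)
    W <- runif(1, min(p), 1)
    got <- select_optimal_features(make_dist(p), N = N, W = W)
    want <- oracle_select(p, N, W)
    expect_equal(got$achieved_entropy, want$H, tolerance = 1e-9)
    expect_lte(length(got$patches), N)
    expect_lte(sum(got$probs), W + 1e-12)
  }
})

test_that("achieved entropy is monotone in the constraints", {
  set.seed(8)
  p <- rgamma(16, 1)
  p <- p / sum(p)
  d <- make_dist(p)
  H_w <- vapply(c(0.1, 0.3, 0.6, 1), function(w)
    select_optimal_features(d, N = 6, W = w)$achieved_entropy, numeric(1))
  expect_true(all(diff(H_w) >= -1e-12))
  H_n <- vapply(c(1, 3, 6, 12), function(n)
    select_optimal_features(d, N = n, W = 0.5)$achieved_entropy, numeric(1))
  expect_true(all(diff(H_n) >= -1e-12))
})

test_that("degenerate selection inputs are handled explicitly", {
  expect_error(select_optimal_features(make_dist(c(0, 0, 0)), 2, 0.5),
               "zero")
  expect_warning(
    s <- select_optimal_features(make_dist(c(0.5, 0.3, 0.2)), 2, 0.01),
    "empty")
  expect_true(s$empty)
  expect_length(s$patches, 0)
})

test_that("512-alphabet heuristic beats the greedy-by-entropy baseline", {
  set.seed(9)
  p <- rgamma(512, 0.4)
  p <- p / sum(p)
  d <- make_dist(p, patch_side = 3L)
  s <- select_optimal_features(d, N = 50, W = 0.05)
  h <- ifelse(p > 0, -p * log2(p), 0)
  # greedy baseline: add by descending entropy term while feasible
  sel <- integer(0); mass <- 0
  for (i in order(h, decreasing = TRUE)) {
    if (length(sel) >= 50) break
    if (mass + p[i] <= 0.05 + 1e-12) {
      sel <- c(sel, i); mass <- mass + p[i]
    }
  }
  expect_gte(s$achieved_entropy, sum(h[sel]) - 1e-9)
  expect_lte(sum(s$probs), 0.05 + 1e-12)
  expect_lte(length(s$patches), 50)
})

test_that("non-optimal selection takes lowest probabilities, ties by code", {
  d <- make_dist(c(0.7, 0.2, 0.1))
  expect_equal(select_nonoptimal_features(d, 1)$patches, 2L)
  d2 <- make_dist(c(0.4, 0.1, 0.4, 0.1))
  expect_equal(select_nonoptimal_features(d2, 1)$patches, 1L)
  d3 <- make_dist(rep(1 / 512, 512), patch_side = 3L)
  expect_equal(select_nonoptimal_features(d3, 50)$patches, 0:49)
  expect_error(select_nonoptimal_features(make_dist(c(1, 0, 0)), 2),
               "positive probability")
})

test_that("cue rendering expands cells with MSB at top-left", {
  all1 <- render_cue(511)
  expect_equal(dim(all1$pixels), c(9, 9))
  expect_true(all(all1$pixels == 44))
  all0 <- render_cue(0)
  expect_true(all(all0$pixels == 4))
  # code 2^8: only the top-left cell set
  tl <- render_cue(256)
  expect_true(all(tl$pixels[1:3, 1:3] == 44))
  expect_true(all(tl$pixels[4:9, ] == 4))
  expect_true(all(tl$pixels[, 4:9] == 4))
  expect_error(render_cue(512), "out of range")
  # injectivity over a sample of distinct codes
  set.seed(4)
  codes <- sample(0:511, 60)
  keys <- vapply(codes, function(cd)
    paste(render_cue(cd)$pixels, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("control cues are uniform at the printed luminances", {
  lo <- render_control_cue("low")
  hi <- render_control_cue("high")
  expect_true(all(lo$pixels == 20))
  expect_true(all(hi$pixels == 23))
  expect_equal(dim(hi$pixels), c(9, 9))
  expect_equal(hi$background, 16)
  # Weber contrast of the high cue against the background
  expect_equal((23 - 16) / 16, 0.4375)
})

test_that("luminance balance compares mean cue luminances", {
  dA <- list(patches = c(511L), probs = 1, kind = "optimal")
  dB <- list(patches = c(0L), probs = 1, kind = "nonoptimal")
  expect_equal(as.numeric(check_luminance_balance(dA, dB)), 40)
  expect_equal(as.numeric(check_luminance_balance(dA, dA)), 0)
  # complementary pairs have equal total white-cell counts
  dC <- list(patches = c(0L, 511L))
  expect_equal(as.numeric(check_luminance_balance(dC, dC)), 0)
  expect_error(check_luminance_balance(list(patches = integer(0)), dA),
               "empty")
})

test_that("PGM and dictionary JSON round-trip", {
  img <- matrix(sample(0:255, 30, replace = TRUE), 5, 6)
  f <- tempfile(fileext = ".pgm")
  write_pgm(img, f)
  expect_equal(read_pgm(f), img)

  d <- select_optimal_features(make_dist(c(0.5, 0.2, 0.05, 0.25)), 2, 0.25)
  fj <- tempfile(fileext = ".json")
  write_feature_dictionary(d, fj)
  d2 <- read_feature_dictionary(fj)
  expect_equal(d2$patches, d$patches)
  expect_equal(d2$achieved_entropy, d$achieved_entropy, tolerance = 1e-12)
})

test_that("cue sets render to PGM files with a manifest", {
  d <- select_nonoptimal_features(make_dist(rep(1 / 512, 512), 3L), 4)
  dir <- file.path(tempdir(), "cues")
  man <- write_cue_set(d, dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # code 0 renders all-black: mean luminance 4 cd/m2
  expect_equal(man$mean_luminance[man$code == 0], 4)
  px <- read_pgm(file.path(dir, "cue_000.pgm"))
  expect_true(all(px == 4))
})

test_that("synthetic images feed the estimator end to end", {
  imgs <- simulate_natural_images(2, size = 48, seed = 3)
  bw <- lapply(imgs, binarize_image)
  d <- estimate_patch_distribution(bw, 3)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  # smoothing makes uniform patches much more common than under iid pixels
  expect_gt(d$probs[1] + d$probs[512], 20 / 512)
})
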
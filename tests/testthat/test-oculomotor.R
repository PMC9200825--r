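# Filtering, differentiation, saccade detection, classification, summaries.

make_trace <- function(t_ms, x, y = rep(0, length(t_ms))) {
  dualcue:::new_gaze_trace(t_ms, x, y, target_side = "right",
                           salient_side = "right")
}

test_that("zero-phase Butterworth keeps DC and linear trends", {
  t_ms <- seq(0, 999)
  tr <- make_trace(t_ms, rep(3.3, 1000))
  f <- lowpass_filter(tr)
  expect_lt(max(abs(f$x - 3.3)), 1e-6)
  # linear trend: slope preserved away from the edges
  tr2 <- make_trace(t_ms, 0.01 * t_ms)
  f2 <- lowpass_filter(tr2)
  mid <- 100:900
  slope <- diff(f2$x[mid]) / diff(t_ms[mid])
  expect_lt(max(abs(slope - 0.01)), 1e-6)
  # jittered timestamps are rejected
  tj <- make_trace(cumsum(runif(100, 0.8, 1.2)), rnorm(100))
  expect_error(lowpass_filter(tj), "non-uniform")
})

test_that("filter attenuation at cutoff and 1 kHz digital value", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  g <- function(f_hz) {
    tr <- make_trace(t * 1000, sin(2 * pi * f_hz * t))
    y <- lowpass_filter(tr)$x
    max(abs(y[500:1500]))
  }
  expect_equal(g(30), 0.5, tolerance = 0.005)   # prewarped: exact at cutoff
  expect_equal(g(60), 0.0567, tolerance = 0.001) # bilinear value at fs = 1 kHz
})

test_that("differentiation is exact for low-order polynomials", {
  dt <- 1e-3
  x <- seq(0, 1, by = dt) * 10          # ramp at 10 deg/s
  v <- differentiate(x, dt)
  expect_lt(max(abs(v - 10)), 1e-9)
  tt <- seq(0, 1, by = dt)
  q <- 3 * tt^2
  vq <- differentiate(q, dt)
  expect_lt(max(abs(vq[2:1000] - 6 * tt[2:1000])), 1e-9)
  expect_lt(max(abs(differentiate(rep(2, 100), dt))), 1e-12)
})

test_that("quiet fixation produces no events", {
  set.seed(3)
  t_ms <- seq(-250, 650)
  tr <- make_trace(t_ms, rnorm(length(t_ms), 0, 0.02),
                   rnorm(length(t_ms), 0, 0.02))
  ev <- detect_saccades(lowpass_filter(tr))
  expect_equal(nrow(ev), 0)
})

test_that("a single synthetic saccade is recovered precisely", {
  sc <- build_gaze_schedule(80, seed = 2)
  tr <- simulate_gaze_trial(sc[1, ], quiet_gaze_params(), seed = 77)
  prog <- tr$events
  ev <- detect_saccades(lowpass_filter(tr))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - prog$onset_ms), 2)
  expect_lt(abs(ev$amplitude_deg - 5), 0.1)
  expect_equal(ev$direction, prog$direction)
  # filtered peak velocity is attenuated but still main-sequence scaled
  expect_gt(ev$peak_velocity_deg_s, 150)
})

test_that("anticipatory plus corrective saccades give exactly two events", {
  t_ms <- seq(-250, 650)
  x <- rep(0, length(t_ms))
  x <- dualcue:::add_saccade(x, t_ms, -30, 1.5, 55)
  x <- dualcue:::add_saccade(x, t_ms, 150, 3.5, 55)
  tr <- make_trace(t_ms, x)
  ev <- detect_saccades(lowpass_filter(tr))
  expect_equal(nrow(ev), 2)
  expect_lt(abs(ev$amplitude_deg[1] - 1.5), 0.1)
  expect_lt(abs(ev$amplitude_deg[2] - 3.5), 0.1)
  expect_true(ev$onset_ms[1] < 0 && ev$onset_ms[2] > 100)
})

test_that("round-trip latency recovery is unbiased", {
  # scaled-down version of the 500-trial recovery design (150 trials here;
  # the full-size run lives in the acceptance suite)
  sc <- build_gaze_schedule(50, seed = 8)
  sub <- sc[1:150, ]
  for (noise in c(0, 0.05)) {
    pars <- gaze_sim_params(noise_sd_deg = noise,
                            p_error = c(neutral = 0, valid = 0, invalid = 0),
                            p_anticipatory = c(neutral = 0, valid = 0,
                                               invalid = 0))
    traces <- simulate_gaze_session(sub, pars, seed = 9)
    cls <- analyze_gaze_session(traces, sub)
    prog <- vapply(traces, function(x) x$events$onset_ms[1], numeric(1))
    det <- vapply(cls, `[[`, numeric(1), "regular_latency_ms")
    expect_true(all(is.finite(det)))
    expect_lt(mean(abs(det - prog)), if (noise == 0) 2 else 5)
  }
})

test_that("classification applies the latency and amplitude windows", {
  trial <- toy_trial(target_side = "right", salient_side = "right")
  c1 <- classify_trial(toy_events(100, 3, "right"), trial)
  expect_equal(c1$regular_label, "correct")
  expect_equal(c1$events$class, "regular")
  c2 <- classify_trial(toy_events(100, 3, "left"), trial)
  expect_equal(c2$regular_label, "erroneous")
  c3 <- classify_trial(toy_events(50, 1.5, "left"), trial)
  expect_equal(c3$events$class, "anticipatory")
  expect_equal(c3$regular_label, "none")
  c4 <- classify_trial(toy_events(600, 5, "right"), trial)
  expect_equal(c4$events$class, "unclassified")
  # boundaries are open intervals
  c5 <- classify_trial(toy_events(80, 5, "right"), trial)
  expect_equal(c5$events$class, "unclassified")
  # amplitude criteria: regular needs > 2 deg, anticipatory >= 1 deg
  c6 <- classify_trial(toy_events(100, 2, "right"), trial)
  expect_equal(c6$events$class, "unclassified")
  c7 <- classify_trial(toy_events(0, 1, "right"), trial)
  expect_equal(c7$events$class, "anticipatory")
  # aberrant trial: no events at all
  c8 <- classify_trial(toy_events(numeric(0), numeric(0), character(0)),
                       trial)
  expect_true(c8$aberrant)
  # only the FIRST qualifying event is the regular saccade
  two <- toy_events(c(100, 200), c(4, 4), c("left", "right"))
  c9 <- classify_trial(two, trial)
  expect_equal(c9$events$class, c("regular", "unclassified"))
  expect_equal(c9$regular_label, "erroneous")
})

test_that("gaze summaries count errors and anticipations correctly", {
  trial_c <- toy_trial()
  cls <- c(
    replicate(97, classify_trial(toy_events(120, 4, "right"), trial_c),
              simplify = FALSE),
    replicate(3, classify_trial(toy_events(120, 4, "left"), trial_c),
              simplify = FALSE))
  tab <- summarize_gaze(cls)
  expect_equal(tab$pct_direction_errors, 3.0)
  expect_equal(tab$n_regular, 100)
  expect_equal(tab$mean_latency_ms, 120)
})

test_that("anticipatory preferences aggregate as weighted averages", {
  row <- function(pid, n_ant, pref) {
    data.frame(participant = pid, condition = "experimental",
               validity_block = 80, trial_type = "valid",
               n_trials = 100, n_aberrant = 0, n_regular = 100,
               n_erroneous = 0, n_anticipatory = n_ant,
               mean_latency_ms = 160, latency_sem_ms = 1,
               pct_direction_errors = 0, pct_anticipatory = n_ant,
               pct_anticipatory_to_salient = pref,
               latency_change_pct = -4)
  }
  g <- gaze_group_summary(rbind(row(1, 10, 80), row(2, 30, 60)))
  expect_equal(g$pct_anticipatory_to_salient, (10 * 80 + 30 * 60) / 40)
})

test_that("fixation control uses a strict 2-degree radius", {
  t_ms <- seq(0, 500)
  still <- make_trace(t_ms, rep(0, 501))
  expect_false(check_fixation(still))
  out <- make_trace(t_ms, c(rep(0, 400), rep(2.5, 101)))
  expect_true(check_fixation(out))
  edge <- make_trace(t_ms, c(rep(0, 400), rep(2.0, 101)))
  expect_false(check_fixation(edge))
})
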
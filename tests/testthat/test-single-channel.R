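test_that("all-point histogram bins and conserves samples", {
  # constant trace: one occupied bin holding every sample
  h <- all_point_histogram(make_trace(rep(4.2, 1000)))
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mids[h$counts > 0], 4.2, tolerance = h$bw)

  # two-level noise-free 50/50 trace: two occupied bins, equal counts
  h2 <- all_point_histogram(make_trace(rep(c(0, 8), 500)))
  occ <- which(h2$counts > 0)
  expect_length(occ, 2)
  expect_equal(h2$counts[occ], c(500, 500))

  # conservation on random traces, and the window honours step onset
  set.seed(3)
  for (n in c(100, 5000)) {
    hr <- all_point_histogram(rnorm(n))
    expect_equal(sum(hr$counts), n)
  }
  tr <- make_trace(c(rep(0, 1000), rnorm(30000, 5)), t_on = 0.1)
  hw <- all_point_histogram(tr, window = 2)
  expect_equal(sum(hw$counts), 20000)
})

test_that("level fitting recovers synthetic Gaussian mixtures", {
  set.seed(14)
  # two levels: baseline 0 and open 7.68 pA (192 pS at 40 mV), sd 0.4
  x <- c(rnorm(6000, 0, 0.4), rnorm(4000, 7.68, 0.4))
  lv <- fit_levels(all_point_histogram(x), vj = 40)
  expect_false(lv$no_events)
  expect_equal(lv$i_j, 7.68, tolerance = 0.1)

  # three levels including a residual state: K = 3, correct main open
  x3 <- c(rnorm(5000, 0, 0.3), rnorm(2000, 1.8, 0.3), rnorm(3000, 7.68, 0.3))
  lv3 <- fit_levels(all_point_histogram(x3), vj = 40)
  expect_equal(lv3$n_components, 3)
  expect_equal(lv3$i_j, 7.68, tolerance = 0.1)
  expect_equal(sum(lv3$components$role == "sub"), 1)

  # negative-going levels keep the magnitude with the sign recorded
  xn <- c(rnorm(5000, 0, 0.3), rnorm(3000, -7.68, 0.3))
  lvn <- fit_levels(all_point_histogram(xn), vj = -40)
  expect_equal(lvn$i_j, 7.68, tolerance = 0.1)
  expect_equal(lvn$sign, -1)

  # flat noise around zero: "no events", not an error
  lv0 <- fit_levels(all_point_histogram(rnorm(10000, 0, 0.3)))
  expect_true(lv0$no_events)
  expect_true(is.na(lv0$i_j))

  # a stretch with no zero-current level (channel never fully closed) is
  # rejected rather than measured against the residual level
  xr <- c(rnorm(5000, 1.8, 0.25), rnorm(5000, 7.68, 0.25))
  lvr <- fit_levels(all_point_histogram(xr))
  expect_true(lvr$no_events)
})

test_that("main-open mean is stable under bin-width halving", {
  set.seed(15)
  x <- c(rnorm(7000, 0, 0.35), rnorm(3000, 9.2, 0.35))
  h1 <- all_point_histogram(x, bw = 0.2)
  h2 <- all_point_histogram(x, bw = 0.1)
  m1 <- fit_levels(h1)$i_j
  m2 <- fit_levels(h2)$i_j
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("slope conductance regression matches published arithmetic", {
  # exact Ohmic points: slope 0.192 pA/mV -> 192 pS
  d <- data.frame(pair = "p1", vj = c(40, 60, 80, 100),
                  i_j = 0.192 * c(40, 60, 80, 100))
  g <- slope_gamma(d)
  expect_equal(g$pooled[["slope_pS"]], 192, tolerance = 1e-10)
  expect_equal(g$mean_slope, 192, tolerance = 1e-10)

  # 0.220 pA/mV -> 220 pS
  d2 <- transform(d, i_j = 0.220 * abs(vj))
  expect_equal(slope_gamma(d2)$pooled[["slope_pS"]], 220, tolerance = 1e-10)

  # closed-form least squares oracle on random points
  set.seed(9)
  d3 <- data.frame(pair = "x", vj = c(40, 50, 60, 80),
                   i_j = 0.2 * c(40, 50, 60, 80) + rnorm(4, sd = 0.3))
  x <- abs(d3$vj); y <- d3$i_j
  slope_oracle <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(slope_gamma(d3)$pooled[["slope_pS"]], 1000 * slope_oracle,
               tolerance = 1e-10)

  # polarities are averaged within a pair before regression
  d4 <- data.frame(pair = "p", vj = c(40, -40, 60, -60),
                   i_j = c(7, 9, 11, 13))
  g4 <- slope_gamma(d4)
  expect_equal(g4$points$i_j, c(8, 12))

  # pairs with a single voltage are excluded with a warning
  d5 <- rbind(d, data.frame(pair = "lone", vj = 40, i_j = 5))
  expect_warning(g5 <- slope_gamma(d5), "lone")
  expect_equal(g5$n_pairs, 1)
  expect_error(suppressWarnings(
    slope_gamma(data.frame(pair = "lone", vj = 40, i_j = 5))), ">= 2")
})

test_that("threshold idealization recovers square-wave and kinetic dwells", {
  # noise-free square wave: alternating 100 ms sojourns (no filtering)
  sq <- square_trace(lo = 0, hi = 8, half_period_s = 0.1, cycles = 10)
  lv <- fit_levels(all_point_histogram(sq, window = Inf))
  ev <- idealize(sq, lv, fc = NULL)
  expect_true(all(abs(ev$duration - 0.1) < 1e-6))
  expect_setequal(unique(ev$state), c("open", "closed"))

  # a 1 ms event is shorter than the 200 Hz dead time (~3.3 ms): absorbed
  fs <- 10000
  x <- rep(0, fs); x[5000:5009] <- 8                    # 1 ms blip
  tr <- make_trace(x)
  lv2 <- structure(list(components = data.frame(
    mean = c(0, 8), sd = c(0.1, 0.1), amplitude = c(1, 1),
    weight = c(0.5, 0.5), role = c("baseline", "main_open")),
    i_j = 8, sign = 1, n_components = 2, rss = 0, no_events = FALSE,
    vj = 40), class = "gj_levels")
  ev2 <- idealize(tr, lv2, fc = NULL, dead_time = 2 * 0.3321 / 200)
  expect_equal(sum(ev2$state == "open"), 0)

  # simulated channel with beta = 5/s: mean open dwell ~200 ms
  m <- flat_model(k0 = 5, gamma_main = 200)
  prot <- step_protocol(40, step_duration = 250, pre_step_baseline = 0)
  tr3 <- simulate_channels(m, prot, 1, recording_noise(0.5), seed = 31)[[1]]
  lv3 <- estimate_amplitudes(tr3, window = Inf)
  ev3 <- idealize(tr3, lv3)
  n_open <- sum(ev3$state == "open")
  expect_gt(n_open, 500)
  dw <- dwell_stats(ev3)
  expect_equal(dw$mean_open, 0.2, tolerance = 0.1)

  # idealized open occupancy matches the stationary law within 3 SE
  p_open <- sum(ev3$duration[ev3$state == "open"]) / sum(ev3$duration)
  se <- 0.5 * 0.5 * sqrt(2 / n_open)
  expect_lt(abs(p_open - 0.5), 3 * se + 0.01)
})

test_that("dead-time merging never increases the event count", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 50
    st <- rep(c("open", "closed"), length.out = n)
    dur <- rexp(n, rate = 100)                 # many sub-dead-time sojourns
    m0 <- gjvolt:::merge_short_sojourns(st, dur, dead_time = 0)
    m1 <- gjvolt:::merge_short_sojourns(st, dur, dead_time = 0.005)
    expect_lte(length(m1$duration), length(m0$duration))
    expect_true(all(m1$duration >= 0.005) || length(m1$duration) == 1)
    # total time is conserved
    expect_equal(sum(m1$duration), sum(dur))
    # alternation is preserved
    if (length(m1$state) > 1)
      expect_true(all(m1$state[-1] != m1$state[-length(m1$state)]))
  }
})

test_that("dwell statistics summarize per voltage and skip empty records", {
  e1 <- structure(data.frame(state = c("open", "closed", "open"),
                             duration = c(0.1, 0.5, 0.3)),
                  class = c("gj_events", "data.frame"), vj = 40,
                  dead_time = 0.003)
  d <- dwell_stats(e1)
  expect_equal(d$mean_open, 0.2)
  expect_equal(d$n_events, 2)

  # single event: mean is that event
  e2 <- structure(data.frame(state = "open", duration = 0.42),
                  class = c("gj_events", "data.frame"), vj = 60,
                  dead_time = 0.003)
  expect_equal(dwell_stats(e2)$mean_open, 0.42)

  # a voltage with zero open events is absent, not zero
  e3 <- structure(data.frame(state = "closed", duration = 1),
                  class = c("gj_events", "data.frame"), vj = 80,
                  dead_time = 0.003)
  dd <- dwell_stats(list(e1, e2, e3))
  expect_setequal(dd$vj, c(40, 60))
})

test_that("faster closing kinetics shorten the simulated open dwell", {
  prot <- step_protocol(40, step_duration = 60, pre_step_baseline = 0,
                        sampling_rate = 2000)
  dwell_of <- function(k0, seed) {
    m <- flat_model(k0 = k0, gamma_main = 200)
    tr <- simulate_channels(m, prot, 1, seed = seed, return_states = TRUE)[[1]]
    r <- rle(tr$states == 0L)
    mean(r$lengths[r$values]) / 2000
  }
  expect_gt(dwell_of(2, 51), dwell_of(10, 52))
})
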
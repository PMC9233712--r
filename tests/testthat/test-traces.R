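tr <- function(v, dt = 1) tibble::tibble(time_min = seq_along(v) * dt - dt,
                                         value = v)

test_that("smoothing fixes constants, linear ramps and impulses", {
  const <- tr(rep(7, 30))
  expect_equal(smooth_trace(const, "moving_average")$value, rep(7, 30))
  expect_equal(smooth_trace(const, "loess")$value, rep(7, 30),
               tolerance = 1e-8)

  ramp <- tr(2 * (0:29) + 5)
  sm <- smooth_trace(ramp, "moving_average", window = 5)
  expect_equal(sm$value[3:28], ramp$value[3:28])  # interior points unchanged

  imp <- tr(c(rep(0, 10), 1, rep(0, 10)))
  sm <- smooth_trace(imp, "moving_average", window = 5)
  expect_equal(sm$value[9:13], rep(0.2, 5))
  expect_equal(sum(sm$value[c(1:8, 14:21)]), 0)

  expect_error(smooth_trace(const, "moving_average", window = 0),
               class = "extrudr_parameter_error")
  expect_error(smooth_trace(const, "loess", span = -1),
               class = "extrudr_parameter_error")
  expect_error(smooth_trace(tr(1:3), "moving_average", window = 5),
               class = "extrudr_parameter_error")
})

test_that("onset detection finds a plateau-to-slope breakpoint", {
  t <- 0:150
  y <- ifelse(t < 100, 100, 100 - 2 * (t - 100))
  found <- detect_onset(tibble::tibble(time_min = t, value = y))
  expect_lte(abs(found$onset_time - 100), 3)
  expect_true(found$constricting)
  expect_equal(glance(found)$onset_index, found$onset_index)
  expect_equal(nrow(tidy(found)), length(found$diagnostics$breakpoint))
})

test_that("linear and flat traces are flagged as non-constricting", {
  lin <- tr(200 - 2 * (0:60))
  expect_false(detect_onset(lin)$constricting)
  flat <- tr(rep(50, 40))
  expect_false(detect_onset(flat)$constricting)
  expect_error(detect_onset(tr(1:6)), class = "extrudr_detection_error")
})

test_that("onset detector equals the exhaustive least-squares oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(25:60, 1)
    onset <- runif(1, n * 0.3, n * 0.7)
    y <- ifelse(seq_len(n) - 1 < onset, 100, 100 - 2 * ((seq_len(n) - 1) - onset)) +
      rnorm(n, 0, 3)
    trace <- tr(y)
    expect_identical(detect_onset(trace)$onset_index,
                     as.integer(onset_oracle(trace)))
  }
})

test_that("alignment and normalisation anchor the reference at time zero", {
  a <- tibble::tibble(cell_id = 1, time_min = 0:10, value = rep(10, 11))
  b <- tibble::tibble(cell_id = 2, time_min = 5:15, value = rep(10, 11))
  ens <- align_normalize(dplyr::bind_rows(a, b), mode = "end",
                         norm = "first5_mean")
  # identical traces offset in absolute time coincide after end alignment
  expect_equal(ens$summary$sem, rep(0, 11))
  expect_equal(ens$summary$rel_time_min, -10:0)
  expect_equal(ens$summary$mean, rep(1, 11))  # divided by the first-5 mean 10

  on <- tibble::tibble(cell_id = c(1, 2), onset_time = c(4, 9))
  ens2 <- align_normalize(dplyr::bind_rows(a, b), mode = "onset",
                          norm = "none", onsets = on)
  expect_equal(range(ens2$members$rel_time_min), c(-4, 6))

  z <- tibble::tibble(cell_id = 3, time_min = 0:10, value = rep(0, 11))
  expect_warning(align_normalize(dplyr::bind_rows(a, z), mode = "end",
                                 norm = "first5_mean"),
                 "zero or undefined")
})

test_that("rates of change respect the contraction sign convention", {
  p <- tr(c(10, 8, 6))
  cr <- contraction_rate(p)
  expect_equal(cr$rate, c(2, 2))
  expect_equal(cr$time_min, c(0.5, 1.5))
  expect_equal(rate_of_change(tr(rep(4, 10)))$rate, rep(0, 9))

  # -integral of the contraction rate reconstructs the perimeter change
  set.seed(5)
  y <- cumsum(rnorm(50))
  trace <- tr(y, dt = 0.5)
  cr <- contraction_rate(trace)
  expect_equal(-sum(cr$rate * 0.5), y[50] - y[1], tolerance = 1e-9)

  bad <- tibble::tibble(time_min = c(0, 1, 3), value = 1:3)
  expect_error(rate_of_change(bad), class = "extrudr_parameter_error")
})

test_that("cross-correlation recovers identity and planted shifts", {
  set.seed(8)
  a <- tr(rnorm(100))
  xc <- xcorr_normalized(a, a)
  expect_equal(xc$peak_lag_frames, 0)
  expect_equal(max(xc$lags$coef), 1, tolerance = 1e-12)

  v <- rnorm(100)
  b <- tr(dplyr::lag(v, 3, default = 0))
  xc2 <- xcorr_normalized(tr(v), b, max_lag = 20)
  expect_equal(xc2$peak_lag_frames, 3)
  expect_equal(xc2$peak_lag_min, 3)

  expect_error(xcorr_normalized(tr(rep(1, 10)), tr(rnorm(10))),
               class = "extrudr_undefined_correlation")
})

test_that("cross-correlation is bounded, symmetric, and small under the null", {
  set.seed(9)
  for (i in 1:5) {
    a <- tr(rnorm(60)); b <- tr(rnorm(60))
    xab <- tidy(xcorr_normalized(a, b, max_lag = 15))
    xba <- tidy(xcorr_normalized(b, a, max_lag = 15))
    expect_true(all(abs(xab$coef) <= 1 + 1e-12))
    expect_equal(xab$coef, rev(xba$coef), tolerance = 1e-12)
  }
  ok <- vapply(1:20, function(i) {
    a <- tr(rnorm(500)); b <- tr(rnorm(500))
    all(abs(tidy(xcorr_normalized(a, b))$coef) < 0.2)
  }, TRUE)
  expect_gte(sum(ok), 19)
})

test_that("pulse detection measures Gaussian bumps correctly", {
  t <- 0:60
  g <- 10 * exp(-(t - 30)^2 / (2 * 2^2))
  pulses <- detect_pulses(tibble::tibble(time_min = t, value = g))
  expect_equal(nrow(pulses), 1)
  expect_equal(pulses$t_peak, 30)
  expect_equal(pulses$a_peak, 10, tolerance = 1e-6)
  expect_equal(pulses$w_peak, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.05)

  # below-threshold bump
  expect_equal(nrow(detect_pulses(tr(5 * exp(-((0:60) - 30)^2 / 8)))), 0)

  # two well-separated bumps, ordered by time
  g2 <- 10 * exp(-(t - 15)^2 / 8) + 10 * exp(-(t - 45)^2 / 8)
  p2 <- detect_pulses(tibble::tibble(time_min = t, value = g2))
  expect_equal(nrow(p2), 2)
  expect_equal(p2$t_peak, c(15, 45))
})

test_that("pulse metrics are invariant to offsets and time translation", {
  set.seed(12)
  t <- 0:80
  y <- 10 * exp(-(t - 25)^2 / 10) + 12 * exp(-(t - 60)^2 / 6) + rnorm(81, 0, 0.2)
  p0 <- detect_pulses(tibble::tibble(time_min = t, value = y))
  p_shift <- detect_pulses(tibble::tibble(time_min = t, value = y + 50))
  expect_equal(p0$prominence, p_shift$prominence, tolerance = 1e-12)
  p_time <- detect_pulses(tibble::tibble(time_min = t + 17, value = y))
  expect_equal(p_time$a_peak, p0$a_peak, tolerance = 1e-12)
  expect_equal(p_time$w_peak, p0$w_peak, tolerance = 1e-9)
  expect_equal(p_time$t_peak, p0$t_peak + 17)
})

test_that("pulse frequency splits counts at the onset", {
  pulses <- tibble::tibble(t_peak = c(2, 7, 12, 18))
  f <- pulse_frequency(pulses, onset_time = 20, trace_span = c(0, 40))
  expect_equal(f$freq_before, 4 / 20)
  expect_equal(f$freq_after, 0)
  f0 <- pulse_frequency(pulses[0, ], 20, c(0, 40))
  expect_equal(c(f0$freq_before, f0$freq_after), c(0, 0))
  expect_error(pulse_frequency(pulses, 50, c(0, 40)),
               class = "extrudr_parameter_error")
})

test_that("pulse frequency recovers a Poisson rate from synthetic trains", {
  # narrow pulses on a fine time grid keep pulse merging rare, so the
  # detected peak count tracks the planted Poisson rate
  freqs <- vapply(1:100, function(i) {
    pair <- gen_pulsatile_pair(synth_spec(pulse_rate = 0.1, duration = 200,
                                          pulse_sigma = 0.3,
                                          frame_interval = 0.2,
                                          noise_sd = 0, seed = i))
    pulses <- detect_pulses(pair$myosin, min_prominence = 7)
    f <- pulse_frequency(pulses, onset_time = 100, trace_span = c(0, 200))
    (f$n_before + f$n_after) / 200
  }, 0)
  expect_lt(abs(mean(freqs) - 0.1), 0.15 * 0.1)
})

test_that("contraction yield divides rate by myosin and bins by onset", {
  # triangular perimeter dip: contraction rate peaks at 1.5
  p <- tr(c(rep(20, 10), 20 - 1.5 * (1:5), 12.5 + 1.5 * (1:5), rep(20, 10)))
  myo <- tr(rep(3, 30))
  y <- contraction_yield(p, myo, onset_time = 10, min_prominence = 1)
  expect_equal(nrow(y), 1)
  expect_equal(y$contraction, 1.5, tolerance = 1e-9)
  expect_equal(y$yield, 0.5, tolerance = 1e-9)

  # bin edges are multiples of the bin width relative to the onset
  y2 <- tibble::tibble(t_peak = c(13, 22), rel_time = c(-7, 2),
                       bin = floor(c(-7, 2) / 5) * 5,
                       contraction = 1, myosin = 1, yield = 1)
  expect_equal(y2$bin, c(-10, 0))
  expect_equal(yield_by_bin(y2)$bin, c(-10, 0))
})

test_that("fold changes and durations are simple ratios and differences", {
  expect_equal(perimeter_fold_change(10, 12), 1.2)
  expect_equal(perimeter_fold_change(8, 8), 1)
  expect_warning(out <- perimeter_fold_change(0, 5), "baseline")
  expect_true(is.na(out))

  expect_equal(extrusion_duration(30, 60), 30)
  expect_error(extrusion_duration(60, 30), class = "extrudr_ordering_error")
  h <- duration_histogram(c(10, 20, 30), bin_width = 10)
  expect_equal(h$fraction, rep(1 / 3, 3))
  expect_equal(sum(h$fraction), 1)
})

test_that("elimination statistics match closed forms and stats oracles", {
  counts <- tibble::tibble(compartment = c("clone", "wt"),
                           extrusions = c(5, 2), cells = c(100, 80))
  es <- elimination_stats(counts)
  expect_equal(es$proportions$proportion, c(0.05, 0.025))
  ci <- binom.test(5, 100)$conf.int
  expect_equal(c(es$proportions$ci_lo[1], es$proportions$ci_hi[1]),
               as.double(ci))
  # Wilson interval against prop.test without continuity correction
  esw <- elimination_stats(counts, ci_method = "wilson")
  pw <- prop.test(5, 100, correct = FALSE)$conf.int
  expect_equal(c(esw$proportions$ci_lo[1], esw$proportions$ci_hi[1]),
               as.double(pw), tolerance = 1e-9)

  expect_equal(fisher_exact_2x2(9, 1, 1, 9), 202 / 184756, tolerance = 1e-12)
  same <- tibble::tibble(compartment = c("a", "b"),
                         extrusions = c(3, 3), cells = c(30, 30))
  expect_equal(elimination_stats(same)$tests$p_value, 1)
  expect_error(elimination_stats(tibble::tibble(compartment = "x",
                                                extrusions = 5, cells = 2)),
               class = "extrudr_parameter_error")
})

test_that("Fisher p equals brute-force enumeration and fisher.test", {
  set.seed(20)
  for (i in 1:30) {
    n1 <- sample(3:100, 1); n2 <- sample(3:100, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    p <- fisher_exact_2x2(a, n1 - a, c_, n2 - c_)
    expect_equal(p, fisher_oracle(a, n1 - a, c_, n2 - c_), tolerance = 1e-10)
    pref <- fisher.test(rbind(c(a, n1 - a), c(c_, n2 - c_)))$p.value
    expect_equal(p, pref, tolerance = 1e-7)
  }
})

test_that("group comparison dispatches on the normality check", {
  set.seed(33)
  # Gaussian samples, 2 SD shift: t test path with high power
  hits <- vapply(1:20, function(i) {
    a <- rnorm(30); b <- rnorm(30) + 2
    res <- compare_groups(a, b)
    c(res$test %in% c("t", "paired t"), res$p_value < 0.01)
  }, c(TRUE, TRUE))
  expect_gte(sum(hits[2, ]), 19)
  expect_gte(sum(hits[1, ]), 15)

  # heavy tails: rank path fires
  set.seed(34)
  a <- rcauchy(40); b <- rcauchy(40)
  expect_match(compare_groups(a, b)$test, "mann-whitney")

  # identical non-normal samples: rank path, p = 1
  x <- rep(c(1, 1.1, 1.2, 8, 40), 4)
  res <- compare_groups(x, x)
  expect_match(res$test, "mann-whitney")
  expect_gt(res$p_value, 0.99)

  # paired design uses the paired variants
  set.seed(35)
  a <- rnorm(20); b <- a + rnorm(20, 0.1)
  expect_match(compare_groups(a, b, design = "paired")$test, "paired t")

  expect_true(compare_groups(rep(1, 5), c(1, 2, 3, 8, 9))$degenerate)
  expect_error(compare_groups(1:2, 1:5), class = "extrudr_parameter_error")
})
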
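test_that("pressure landmarks of a sinusoid match the closed form", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  wave <- data.frame(time_s = t, pressure_mmhg = 100 + 20 * sin(2 * pi * t))
  bp <- bp_features(wave)
  expect_equal(bp$sbp, 120, tolerance = 1e-4)
  expect_equal(bp$dbp, 80, tolerance = 1e-4)
  expect_equal(bp$pp, 40, tolerance = 1e-3)
  expect_equal(bp$map, 100, tolerance = 1e-3)

  flat <- data.frame(time_s = t, pressure_mmhg = rep(90, length(t)))
  bpf <- bp_features(flat)
  expect_equal(unlist(bpf), c(sbp = 90, dbp = 90, pp = 0, map = 90))

  expect_error(bp_features(data.frame(time_s = c(0, 1, 3),
                                      pressure_mmhg = c(1, 2, 3))),
               "uniform")
})

test_that("mean pressure always lies between the extremes", {
  set.seed(4)
  for (k in 1:20) {
    t <- seq(0, 1, by = 1e-3)
    p <- 90 + cumsum(rnorm(length(t), 0, 0.5))
    bp <- bp_features(data.frame(time_s = t, pressure_mmhg = p))
    expect_lte(bp$dbp, bp$map)
    expect_lte(bp$map, bp$sbp)
  }
})

test_that("the intersecting tangent recovers a piecewise-linear foot exactly", {
  fs <- 1000
  t <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  p <- ifelse(t < 0.10, 80, 80 + 400 * (t - 0.10))
  foot <- pulse_foot(data.frame(time_s = t, pressure_mmhg = p))
  expect_equal(foot, 0.10, tolerance = 1e-12)

  # time equivariance
  foot2 <- pulse_foot(data.frame(time_s = t + 0.05, pressure_mmhg = p))
  expect_equal(foot2, 0.15, tolerance = 1e-12)

  # invariance under positive affine pressure rescaling
  foot3 <- pulse_foot(data.frame(time_s = t, pressure_mmhg = 3 * p - 50))
  expect_equal(foot3, foot, tolerance = 1e-12)

  # monotone decay has no upstroke -> error
  expect_error(pulse_foot(data.frame(time_s = t, pressure_mmhg = rev(p))),
               "upstroke")
})

test_that("a half-sine upstroke foot lands just after the onset", {
  fs <- 1000
  t <- seq(0, 0.6 - 1 / fs, by = 1 / fs)
  p <- ifelse(t < 0.2, 80,
              ifelse(t < 0.3, 80 + 40 * sin(pi * (t - 0.2) / 0.2), 120))
  foot <- pulse_foot(data.frame(time_s = t, pressure_mmhg = p))
  expect_gte(foot, 0.2 - 1 / fs)
  expect_lte(foot, 0.22)
})

test_that("transit time recovers imposed delays to within a sample", {
  prox <- pulse_train(delay = 0)
  dist <- pulse_train(delay = 0.06)
  tr <- transit_time(prox, dist, period_s = 1)
  expect_equal(tr$mean_delta_t_s, 0.06, tolerance = 2e-3)
  expect_gte(tr$n_cycles_used, 10)

  # too few cycles
  expect_error(transit_time(pulse_train(n_cycles = 4),
                            pulse_train(n_cycles = 4, delay = 0.05),
                            period_s = 1), "at least 10")

  # zero delay is degenerate: flagged, no resolvable transit
  expect_error(transit_time(prox, prox, period_s = 1), "resolvable")
})

test_that("jittered per-cycle delays average inside the jitter band", {
  fs <- 1000
  period <- 1
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  set.seed(8)
  delays <- runif(12, 0.055, 0.065)
  p_prox <- numeric(length(t))
  p_dist <- numeric(length(t))
  for (k in 1:12) {
    ph <- t - (k - 1) * period
    up <- function(d) ifelse(ph >= d & ph < d + 0.3,
                             40 * sin(pi * (ph - d) / 0.3), 0)
    sel <- ph >= 0 & ph < period
    p_prox[sel] <- up(0)[sel]
    p_dist[sel] <- up(delays[k])[sel]
  }
  prox <- data.frame(time_s = t, pressure_mmhg = 80 + p_prox)
  dist <- data.frame(time_s = t, pressure_mmhg = 80 + p_dist)
  tr <- transit_time(prox, dist, period_s = period)
  expect_gte(tr$mean_delta_t_s, 0.054)
  expect_lte(tr$mean_delta_t_s, 0.066)
})

test_that("velocity and path-length arithmetic behave", {
  expect_equal(cfpwv(0.5, 0.0625), 8)
  expect_equal(cfpwv(1.0, 0.125), cfpwv(0.5, 0.0625))
  expect_error(cfpwv(-1, 0.1), "path_length")
  expect_equal(clinical_path_length(0.625), 0.5)
  expect_equal(clinical_path_length(0.7), 0.56)
  expect_identical(clinical_path_length(0.44, correction = 1), 0.44)
})
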
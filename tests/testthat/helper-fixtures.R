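# in-code fixtures shared across test files

# uniform elastic tube closed by a Windkessel terminal
tube_config <- function(length_cm = 100, diameter_cm = 2, distensibility = 7.8,
                        r1 = 0.05, r2 = 0.95, c = 0.05, pout = 0,
                        sites = data.frame(site = c("inlet", "outlet"),
                                           segment = "tube",
                                           position = c(0, 1))) {
  list(
    segments = data.frame(id = "tube", parent = NA, length_cm = length_cm,
                          din_cm = diameter_cm, dout_cm = diameter_cm,
                          distensibility = distensibility),
    terminals = data.frame(segment = "tube", r1 = r1, r2 = r2, c = c,
                           pout = pout),
    sites = sites,
    reference = list(pressure_mmhg = 90, aortic_distensibility = 7.8,
                     height_cm = 180)
  )
}

# characteristic impedance (mmHg s/mL) of a uniform tube at reference
tube_z0 <- function(diameter_cm = 2, distensibility = 7.8, rho = 1050) {
  c0 <- sqrt(1 / (rho * distensibility * 1e-3 / 133.322))
  a <- pi * (diameter_cm / 100)^2 / 4
  rho * c0 / a / (133.322 / 1e-6)
}

# synthetic feature table with a smooth feature -> sv relationship,
# cheap enough for estimator unit tests
synthetic_feature_table <- function(n, seed = 1, noise_sd = 2) {
  set.seed(seed)
  d <- tibble::tibble(
    age = runif(n, 20, 80),
    gender = sample(c("M", "F"), n, replace = TRUE),
    weight = runif(n, 50, 95),
    height = runif(n, 150, 195),
    dbp = runif(n, 50, 90),
    pp = runif(n, 25, 90),
    cfpwv = runif(n, 4, 16)
  )
  d$sbp <- d$dbp + d$pp
  d$map <- d$dbp + d$pp / 3
  d$sv <- d$pp * (1.8 - 0.08 * d$cfpwv) + 0.25 * d$map +
    rnorm(n, 0, noise_sd)
  d
}

# multi-cycle pulse train with a known period and rise
pulse_train <- function(n_cycles = 12, period = 1, rise = 0.3, fs = 1000,
                        delay = 0, baseline = 80, amplitude = 40) {
  t <- seq(0, n_cycles * period - 1 / fs, by = 1 / fs)
  phase <- (t - delay) %% period
  p <- baseline + amplitude * ifelse(phase < rise, sin(pi * phase / rise), 0)
  data.frame(time_s = t, pressure_mmhg = p)
}

# noiseless clinical simulation config
noiseless_sim_config <- function(n_patients = 24) {
  clinical_sim_config(
    n_patients = n_patients,
    repeat_sd = c(sbp = 0, dbp = 0, hr = 0),
    shift_mean = c(sbp = 0, dbp = 0, hr = 0),
    shift_sd = c(sbp = 0, dbp = 0, hr = 0),
    large_discrepancy_fraction = 0,
    pwv_noise_sd = 0, sv_noise_sd = 0, missing_repeat_prob = 0
  )
}
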
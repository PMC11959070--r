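test_that("patient tables are deterministic given the seed", {
  cfg <- clinical_sim_config(n_patients = 8)
  t1 <- generate_patient_table(cfg, source = "parametric", seed = 13)
  t2 <- generate_patient_table(cfg, source = "parametric", seed = 13)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$truth, t2$truth)
  t3 <- generate_patient_table(cfg, source = "parametric", seed = 14)
  expect_false(identical(t1$patients, t3$patients))
})

test_that("the noiseless limit reproduces the ground truth exactly", {
  tbl <- generate_patient_table(noiseless_sim_config(12),
                                source = "parametric", seed = 3)
  avg <- average_repeats(tbl$patients)
  expect_equal(avg$sbp_pwv, tbl$truth$sbp, tolerance = 1e-12)
  expect_equal(avg$sbp_cath, tbl$truth$sbp, tolerance = 1e-12)
  expect_equal(avg$cfpwv, tbl$truth$cfpwv, tolerance = 1e-12)
  expect_equal(avg$sv_reference, tbl$truth$sv_true_ml, tolerance = 1e-9)
  flt <- coherence_filter(avg)
  expect_equal(nrow(flt$kept), 12)
  expect_equal(nrow(flt$excluded), 0)
})

test_that("incoherent patients are excluded as the filter oracle predicts", {
  cfg <- clinical_sim_config(n_patients = 24, large_discrepancy_fraction = 0.125,
                             repeat_sd = c(sbp = 1, dbp = 1, hr = 1))
  tbl <- generate_patient_table(cfg, source = "parametric", seed = 41)
  avg <- average_repeats(tbl$patients)
  flt <- coherence_filter(avg, threshold = 0.25)
  # brute-force re-application of the exclusion rule
  manual_out <- with(avg, abs(map_pwv - map_cath) / map_cath > 0.25 |
                       abs(hr_pwv - hr_cath) / hr_cath > 0.25)
  expect_setequal(flt$excluded$id, avg$id[manual_out])
  expect_gte(nrow(flt$excluded), 1)
})

test_that("growing between-setting discrepancies cannot reduce exclusions", {
  exclusions_at <- function(sd_rel, seed) {
    cfg <- clinical_sim_config(
      n_patients = 24,
      repeat_sd = c(sbp = 0, dbp = 0, hr = 0),
      shift_mean = c(sbp = 0, dbp = 0, hr = 0),
      shift_sd = c(sbp = sd_rel, dbp = sd_rel, hr = sd_rel),
      pwv_noise_sd = 0, sv_noise_sd = 0, missing_repeat_prob = 0
    )
    tbl <- generate_patient_table(cfg, source = "parametric", seed = seed)
    nrow(coherence_filter(average_repeats(tbl$patients))$excluded)
  }
  seeds <- 1:6
  lo <- mean(vapply(seeds, function(s) exclusions_at(0.05, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) exclusions_at(0.20, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) exclusions_at(0.40, s), numeric(1)))
  expect_lte(lo, mid)
  expect_lte(mid, hi)
  expect_gt(hi, lo)
})

test_that("the clinical dialect file and its truth sidecar are written", {
  tbl <- generate_patient_table(clinical_sim_config(n_patients = 5),
                                source = "parametric", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(tbl, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", "_truth.csv", path)))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
  expect_true(all(c("sbp_pwv_1", "hr_cath_3", "pwv_2", "co_thermo_lmin")
                  %in% names(back)))
})
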
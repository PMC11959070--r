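make_patient_row <- function(id = "P01", sbp_pwv = c(120, 124, 122),
                             dbp_pwv = c(70, 72, 71), hr_pwv = c(70, 71, 72),
                             sbp_cath = c(122, 126, 124),
                             dbp_cath = c(72, 74, 73),
                             hr_cath = c(62, 62, 62),
                             pwv = c(8.2, 8.6), co = 4.6) {
  tibble::tibble(
    id = id, age_group = ">70", gender = "F", height = 162, weight = 60,
    sbp_pwv_1 = sbp_pwv[1], sbp_pwv_2 = sbp_pwv[2], sbp_pwv_3 = sbp_pwv[3],
    dbp_pwv_1 = dbp_pwv[1], dbp_pwv_2 = dbp_pwv[2], dbp_pwv_3 = dbp_pwv[3],
    hr_pwv_1 = hr_pwv[1], hr_pwv_2 = hr_pwv[2], hr_pwv_3 = hr_pwv[3],
    pwv_1 = pwv[1], pwv_2 = pwv[2],
    sbp_cath_1 = sbp_cath[1], sbp_cath_2 = sbp_cath[2], sbp_cath_3 = sbp_cath[3],
    dbp_cath_1 = dbp_cath[1], dbp_cath_2 = dbp_cath[2], dbp_cath_3 = dbp_cath[3],
    hr_cath_1 = hr_cath[1], hr_cath_2 = hr_cath[2], hr_cath_3 = hr_cath[3],
    co_thermo_lmin = co
  )
}

test_that("repeats are averaged and the reference SV derived from thermodilution", {
  avg <- average_repeats(make_patient_row())
  expect_equal(avg$sbp_pwv, 122)
  expect_equal(avg$dbp_pwv, 71)
  expect_equal(avg$pp_pwv, 51)
  expect_equal(avg$map_pwv, 71 + 51 / 3)
  expect_equal(avg$cfpwv, 8.4)
  # CO 4.6 L/min at catheterization HR 62 -> 74.2 mL
  expect_equal(avg$sv_reference, 4600 / 62, tolerance = 1e-12)

  # a single available repeat is used and flagged
  row <- make_patient_row(hr_pwv = c(70, NA, NA))
  expect_message(avg1 <- average_repeats(row), "single repeat")
  expect_equal(avg1$hr_pwv, 70)

  row_bad <- make_patient_row(hr_pwv = c(NA, NA, NA))
  expect_error(average_repeats(row_bad), "no available repeat")
})

test_that("the coherence filter excludes on MAP or HR discrepancy", {
  pts <- tibble::tibble(
    id = c("a", "b", "c"),
    map_pwv = c(88, 60, 90), map_cath = c(91, 91, 90),
    hr_pwv = c(71, 70, 95), hr_cath = c(68, 70, 70)
  )
  f <- coherence_filter(pts, threshold = 0.25)
  # a: 3.3% MAP and 4.4% HR -> kept; b: 34% MAP -> out; c: 36% HR -> out
  expect_identical(f$kept$id, "a")
  expect_setequal(f$excluded$id, c("b", "c"))
  # partitions are disjoint and exhaustive
  expect_equal(nrow(f$kept) + nrow(f$excluded), nrow(pts))
  expect_length(intersect(f$kept$id, f$excluded$id), 0)
  # idempotent on the kept set
  f2 <- coherence_filter(f$kept, threshold = 0.25)
  expect_identical(f2$kept, f$kept)
  # vacuous threshold keeps everyone
  expect_equal(nrow(coherence_filter(pts, threshold = Inf)$kept), 3)
  expect_error(coherence_filter(pts, threshold = 0), "threshold")
})

test_that("agreement matches hand-computed values and its identities", {
  ag <- sv_agreement(c(60, 80, 100), c(50, 80, 110))
  expect_equal(ag$mae, 20 / 3, tolerance = 1e-12)
  expect_equal(ag$rmse, sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(ag$nrmse, sqrt(200 / 3) / 40, tolerance = 1e-12)
  expect_equal(ag$bias, 0, tolerance = 1e-12)
  expect_equal(ag$loa_low, -1.96 * sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(ag$loa_high, 1.96 * sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(ag$loa_high - ag$loa_low, 2 * 1.96 * ag$sd_diff,
               tolerance = 1e-12)

  ref <- c(55, 70, 85, 90)
  ident <- sv_agreement(ref, ref)
  expect_equal(ident$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  expect_error(sv_agreement(c(70, 70, 70), c(60, 65, 80)), "zero reference range")
  expect_error(sv_agreement(1:2, 1:2), "at least 3")
})

test_that("an underestimating predictor yields a negative bias", {
  set.seed(10)
  ref <- rnorm(30, 77, 26)
  pred <- ref - 9.2 + rnorm(30, 0, 5)
  ag <- sv_agreement(ref, pred)
  expect_lt(ag$bias, 0)
  expect_lt(ag$mean_predicted, ag$mean_reference)
})

test_that("agreement equals a brute-force formula oracle on random arrays", {
  set.seed(123)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    ref <- rnorm(n, 75, 20)
    pred <- ref + rnorm(n, -5, 12)
    ag <- sv_agreement(ref, pred)
    d <- pred - ref
    expect_equal(ag$mae, sum(abs(d)) / n, tolerance = 1e-10)
    expect_equal(ag$rmse, sqrt(sum(d^2) / n), tolerance = 1e-10)
    expect_equal(ag$nrmse, sqrt(sum(d^2) / n) / (max(ref) - min(ref)),
                 tolerance = 1e-10)
    r_hand <- sum((ref - mean(ref)) * (pred - mean(pred))) /
      sqrt(sum((ref - mean(ref))^2) * sum((pred - mean(pred))^2))
    expect_equal(ag$pearson_r, r_hand, tolerance = 1e-10)
    sdd <- sqrt(sum((d - mean(d))^2) / n)
    expect_equal(ag$loa_low, mean(d) - 1.96 * sdd, tolerance = 1e-10)
    expect_equal(ag$loa_high, mean(d) + 1.96 * sdd, tolerance = 1e-10)
  }
})

test_that("setting comparison reports paired tests and absolute differences", {
  pts <- average_repeats(dplyr::bind_rows(
    make_patient_row("P01"),
    make_patient_row("P02", sbp_pwv = c(130, 132, 134), sbp_cath = c(137, 139, 135)),
    make_patient_row("P03", sbp_pwv = c(110, 112, 111), sbp_cath = c(117, 115, 116))
  ))
  tab <- compare_settings(pts)
  expect_setequal(tab$quantity, c("sbp", "dbp", "map", "hr"))
  expect_true(all(tab$paired_t_p >= 0 & tab$paired_t_p <= 1, na.rm = TRUE))
  # constructed +5 mmHg offset on SBP
  same <- pts
  same$sbp_cath <- same$sbp_pwv + 5
  tab5 <- compare_settings(same)
  expect_equal(tab5$mean_abs_diff[tab5$quantity == "sbp"], 5)
  expect_equal(tab5$sd_abs_diff[tab5$quantity == "sbp"], 0)
  # identical settings: zero differences, p is NaN by convention
  ident <- pts
  for (q in c("sbp", "dbp", "map", "hr")) {
    ident[[paste0(q, "_cath")]] <- ident[[paste0(q, "_pwv")]]
  }
  tabi <- compare_settings(ident)
  expect_true(all(tabi$mean_abs_diff == 0))
  expect_true(all(is.nan(tabi$paired_t_p)))
  expect_error(compare_settings(pts[1:2, ]), "at least 3")
})

test_that("the Welch test separates shifted populations and is symmetric", {
  set.seed(77)
  x <- rnorm(9996, 0, 1)
  y <- rnorm(27, 5, 1)
  w <- welch_cohort_test(x, y)
  expect_lt(w$p_value, 0.001)
  w2 <- welch_cohort_test(y, x)
  expect_equal(w$p_value, w2$p_value, tolerance = 1e-12)
  # identical large samples are indistinguishable
  expect_gt(welch_cohort_test(x, x)$p_value, 0.99)
  expect_error(welch_cohort_test(rep(1, 5), rep(1, 5)), "zero variance")
})
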
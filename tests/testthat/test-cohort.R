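# a single small cohort shared by the assertions below (solves are the
# expensive part, so build it once)
small_cohort <- local({
  spec <- population_spec()
  profiles <- sample_profiles(spec, n_per_group = 2, seed = 31)
  suppressMessages(generate_cohort(profiles))
})

test_that("the cohort has one record per convergent profile across 12 strata", {
  expect_equal(nrow(small_cohort) + attr(small_cohort, "n_dropped"), 24)
  expect_true(all(c("age", "gender", "weight", "height", "sbp", "dbp", "pp",
                    "map", "cfpwv", "sv") %in% names(small_cohort)))
})

test_that("every record satisfies the pressure identities", {
  expect_equal(small_cohort$pp, small_cohort$sbp - small_cohort$dbp,
               tolerance = 1e-12)
  expect_true(all(small_cohort$sbp > small_cohort$dbp))
  expect_true(all(small_cohort$cfpwv > 0))
  expect_true(all(small_cohort$dbp <= small_cohort$map &
                    small_cohort$map <= small_cohort$sbp))
})

test_that("the target is the imposed inflow volume, untouched by extraction", {
  spec <- population_spec()
  profiles <- sample_profiles(spec, n_per_group = 2, seed = 31)
  key_profiles <- paste(profiles$age_group, profiles$gender,
                        round(profiles$sv_ml, 9))
  key_cohort <- paste(small_cohort$age_group, small_cohort$gender,
                      round(small_cohort$sv, 9))
  expect_true(all(key_cohort %in% key_profiles))
})

test_that("cohort generation is deterministic and the file round-trips", {
  spec <- population_spec()
  profiles <- sample_profiles(spec, n_per_group = 1, seed = 57)
  c1 <- suppressMessages(generate_cohort(profiles))
  c2 <- suppressMessages(generate_cohort(profiles))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_cohort(path)
  expect_equal(back$sv, c1$sv, tolerance = 1e-9)
})

test_that("stiffer (older) strata propagate the pulse faster", {
  med <- small_cohort |>
    dplyr::group_by(age_group) |>
    dplyr::summarise(cfpwv = stats::median(cfpwv))
  young <- med$cfpwv[med$age_group == "20-29"]
  old <- med$cfpwv[med$age_group == ">70"]
  expect_gt(old, young)
})
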
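test_that("a single-point grid is selected and selection stays in the grid", {
  d <- synthetic_feature_table(150, seed = 2)
  one <- sv_grid(n_estimators = 80, learning_rate = 0.4, max_depth = 5,
                 min_samples_leaf = 3)
  est <- train_sv_estimator(d, grid = one, seed = 5)
  expect_equal(est$selected$n_estimators, 80)
  expect_equal(est$selected$learning_rate, 0.4)
  expect_equal(est$selected$max_depth, 5)
  expect_equal(est$selected$min_samples_leaf, 3)

  small <- sv_grid(n_estimators = c(60, 80), learning_rate = 0.2,
                   max_depth = c(3, 5), min_samples_leaf = 1)
  est2 <- train_sv_estimator(d, grid = small, seed = 5)
  expect_true(est2$selected$n_estimators %in% c(60, 80))
  expect_true(est2$selected$max_depth %in% c(3, 5))
  # the winner's CV score is the maximum over all grid points
  expect_equal(est2$cv_score, max(est2$cv_results$mean_cv_r2))
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- synthetic_feature_table(150, seed = 3)
  g <- sv_grid(n_estimators = 60, learning_rate = c(0.2, 0.4), max_depth = 3,
               min_samples_leaf = c(1, 5))
  e1 <- train_sv_estimator(d, grid = g, seed = 21)
  e2 <- train_sv_estimator(d, grid = g, seed = 21)
  expect_identical(e1$selected, e2$selected)
  expect_identical(predict_sv(e1, d)$sv_pred, predict_sv(e2, d)$sv_pred)
  # duplicated input rows predict identically
  two <- d[c(1, 1), ]
  pr <- predict_sv(e1, two)$sv_pred
  expect_identical(pr[1], pr[2])
})

test_that("predictions respond to cfPWV and stay physiological", {
  d <- synthetic_feature_table(300, seed = 4)
  est <- train_sv_estimator(
    d, grid = sv_grid(n_estimators = 80, learning_rate = 0.2, max_depth = 5,
                      min_samples_leaf = 3), seed = 9
  )
  meds <- d |> dplyr::summarise(dplyr::across(c(age, weight, height, sbp, dbp,
                                                pp, map), stats::median))
  probe <- dplyr::bind_rows(meds, meds)
  probe$gender <- "M"
  probe$cfpwv <- c(6, 12)
  pr <- predict_sv(est, probe)$sv_pred
  expect_false(pr[1] == pr[2])
  tr_pred <- predict_sv(est, d)$sv_pred
  expect_true(all(is.finite(tr_pred)))
  expect_true(all(tr_pred > 10 & tr_pred < 200))
})

test_that("schema violations and degenerate targets fail loudly", {
  d <- synthetic_feature_table(120, seed = 6)
  expect_error(train_sv_estimator(d[1:50, ], seed = 1), "at least 100")
  d0 <- d; d0$sv <- 70
  expect_error(
    train_sv_estimator(d0, grid = sv_grid(60, 0.2, 3, min_samples_leaf = 1),
                       seed = 1),
    "zero variance"
  )
  dn <- d; dn$map[7] <- NA
  expect_error(
    train_sv_estimator(dn, grid = sv_grid(60, 0.2, 3, min_samples_leaf = 1),
                       seed = 1),
    "record 7.*map"
  )
  est <- train_sv_estimator(
    d, grid = sv_grid(60, 0.2, 3, min_samples_leaf = 1), seed = 1
  )
  expect_error(predict_sv(est, d[setdiff(names(d), "cfpwv")]), "cfpwv")
})

test_that("model bundles round-trip bit-for-bit and detect tampering", {
  d <- synthetic_feature_table(120, seed = 7)
  est <- train_sv_estimator(
    d, grid = sv_grid(60, 0.2, 3, min_samples_leaf = 1), seed = 2
  )
  before <- predict_sv(est, d)$sv_pred
  path <- withr::local_tempfile(fileext = ".rds")
  save_sv_model(est, path)
  est2 <- load_sv_model(path)
  expect_identical(predict_sv(est2, d)$sv_pred, before)
  expect_identical(est2$config_hash, est$config_hash)

  bundle <- readRDS(path)
  bundle$schema[3] <- "mass"
  tampered <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bundle, tampered)
  expect_error(load_sv_model(tampered), "checksum mismatch")

  garbage <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), garbage)
  expect_error(load_sv_model(garbage), "missing fields")
})

test_that("held-out error shrinks as training size grows", {
  # parameter recovery on the synthetic relationship, averaged over 3 seeds
  g <- sv_grid(n_estimators = 80, learning_rate = 0.2, max_depth = 5,
               min_samples_leaf = 3)
  mae_at <- function(n, seed) {
    d <- synthetic_feature_table(n + 300, seed = seed)
    tr <- d[seq_len(n), ]
    te <- d[(n + 1):(n + 300), ]
    est <- train_sv_estimator(tr, grid = g, seed = seed)
    mean(abs(te$sv - predict_sv(est, te)$sv_pred))
  }
  small <- mean(vapply(1:3, function(s) mae_at(120, s), numeric(1)))
  large <- mean(vapply(1:3, function(s) mae_at(1200, s), numeric(1)))
  expect_lt(large, small)
})
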
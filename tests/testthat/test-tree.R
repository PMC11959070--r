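test_that("the shipped default tree builds with the expected structure", {
  tree <- default_arterial_tree()
  expect_gte(nrow(tree$segments), 7)
  expect_setequal(
    intersect(c("aortic_root", "left_brachial", "carotid", "femoral"),
              tree$sites$site),
    c("aortic_root", "left_brachial", "carotid", "femoral")
  )
  # every leaf closed by a terminal, and TPR is the parallel combination
  leaves <- setdiff(tree$segments$id,
                    tree$segments$parent[!is.na(tree$segments$parent)])
  expect_setequal(tree$terminals$segment, leaves)
  expect_equal(tree_tpr(tree), 1.0, tolerance = 1e-12)
})

test_that("invalid configs are rejected with the offending segment named", {
  cfg <- tube_config()
  cfg$segments$length_cm <- -1
  expect_error(arterial_tree(cfg), "tube.*non-positive length_cm")

  cfg2 <- tube_config()
  cfg2$segments <- rbind(cfg2$segments,
                         data.frame(id = "loop", parent = "loop",
                                    length_cm = 5, din_cm = 1, dout_cm = 1,
                                    distensibility = 5))
  expect_error(arterial_tree(cfg2), "cycle")

  cfg3 <- tube_config()
  cfg3$terminals <- cfg3$terminals[0, ]
  expect_error(arterial_tree(cfg3), "without terminal")

  cfg4 <- tube_config()
  cfg4$sites$segment <- "nowhere"
  expect_error(arterial_tree(cfg4), "unknown segment")
})

test_that("carotid-femoral path length equals the hand-summed config lengths", {
  tree <- default_arterial_tree()
  # carotid site: 0.1 * 15 cm back to the aortic junction; femoral: 16 + 8 +
  # 8 down the aorta plus 0.95 * 22 along the iliac-femoral segment
  expected_cm <- 0.1 * 15 + (16 + 8 + 8 + 0.95 * 22)
  expect_equal(tree_path_length(tree, "carotid", "femoral", units = "cm"),
               expected_cm, tolerance = 1e-12)
  # in-line sites use the distance difference
  expect_equal(tree_path_length(tree, "aortic_root", "femoral", units = "cm"),
               5 + 16 + 8 + 8 + 0.95 * 22, tolerance = 1e-12)
})

test_that("subject scaling is exact and leaves the original tree unchanged", {
  tree <- default_arterial_tree()
  before <- tree$segments$length_cm
  profile <- list(length_scale = 0.9, diameter_scale = 1.1,
                  distensibility = 3.9, tpr = 1.3)
  st <- scale_tree(tree, profile)
  expect_equal(st$segments$length_cm, before * 0.9)
  expect_equal(st$segments$din_cm, tree$segments$din_cm * 1.1)
  # distensibility 3.9 against reference 7.8 halves every compliance
  expect_equal(st$segments$distensibility, tree$segments$distensibility / 2)
  expect_equal(st$terminals$c, tree$terminals$c / 2)
  # parallel combination of scaled terminals hits the target TPR exactly
  expect_equal(tree_tpr(st), 1.3, tolerance = 1e-12)
  expect_equal(tree$segments$length_cm, before)

  # identity profile leaves everything untouched
  ident <- list(length_scale = 1, diameter_scale = 1,
                distensibility = 7.8, tpr = tree_tpr(tree))
  expect_equal(scale_tree(tree, ident)$segments, tree$segments)
})
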
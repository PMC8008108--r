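# hand-computable frozen examples for every texture family, plus randomized
# spot checks against the brute-force oracle matrices (the exhaustive oracle
# sweep lives in the acceptance tests)

test_that("GLCM matches a hand-computed alternating line", {
  img <- array(c(1, 2, 1, 2), c(4, 1, 1))
  msk <- array(TRUE, c(4, 1, 1))
  f <- glcm_features(img, msk, bin_width = 1)
  expect_length(f, 24)
  # only the x direction has pairs: P = [[0, .5], [.5, 0]]
  expect_equal(unname(f["glcm_Contrast"]), 1)
  expect_equal(unname(f["glcm_JointEnergy"]), 0.5)
  expect_equal(unname(f["glcm_Correlation"]), -1)
  expect_equal(unname(f["glcm_MaximumProbability"]), 0.5)
  expect_equal(unname(f["glcm_JointEntropy"]), 1)
  expect_equal(unname(f["glcm_DifferenceAverage"]), 1)
  expect_equal(unname(f["glcm_SumAverage"]), 3)
})

test_that("constant-region GLCM hits the degenerate conventions", {
  img <- array(5, c(3, 3, 3))
  f <- glcm_features(img, array(TRUE, c(3, 3, 3)), bin_width = 25)
  expect_equal(unname(f["glcm_Correlation"]), 1)   # zero variance
  expect_equal(unname(f["glcm_MCC"]), 1)           # single gray level
  expect_equal(unname(f["glcm_Imc1"]), 0)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
})

test_that("GLRLM matches a hand-computed run pattern", {
  img <- array(c(1, 1, 2, 2, 2), c(5, 1, 1))
  f <- glrlm_features(img, array(TRUE, c(5, 1, 1)), bin_width = 1)
  expect_length(f, 16)
  # x direction: runs (1,2), (2,3); the other 12: five runs of length 1
  sre_x <- (1 / 4 + 1 / 9) / 2
  lre_x <- (4 + 9) / 2
  expect_equal(unname(f["glrlm_ShortRunEmphasis"]), (sre_x + 12) / 13)
  expect_equal(unname(f["glrlm_LongRunEmphasis"]), (lre_x + 12) / 13)
  expect_equal(unname(f["glrlm_RunPercentage"]), (2 / 5 + 12 * 1) / 13)
})

test_that("GLSZM gray-level non-uniformity matches the frozen 2x2 examples", {
  img1 <- array(c(1, 1, 2, 3), c(2, 2, 1))
  f1 <- glszm_features(img1, array(TRUE, c(2, 2, 1)), bin_width = 1)
  expect_length(f1, 16)
  # zones: level 1 size 2, level 2 size 1, level 3 size 1
  expect_equal(unname(f1["glszm_GrayLevelNonUniformityNormalized"]), 1 / 3)
  expect_equal(unname(f1["glszm_GrayLevelNonUniformity"]), 1)
  expect_equal(unname(f1["glszm_ZonePercentage"]), 3 / 4)
  img2 <- array(c(1, 1, 2, 2), c(2, 2, 1))
  f2 <- glszm_features(img2, array(TRUE, c(2, 2, 1)), bin_width = 1)
  # zones: level 1 size 2, level 2 size 2
  expect_equal(unname(f2["glszm_GrayLevelNonUniformityNormalized"]), 0.5)
  expect_equal(unname(f2["glszm_ZonePercentage"]), 2 / 4)
  expect_equal(unname(f2["glszm_SmallAreaEmphasis"]), 1 / 4)
})

test_that("NGTDM returns the 0 convention on constant regions", {
  img <- array(1, c(2, 2, 1))
  f <- ngtdm_features(img, array(TRUE, c(2, 2, 1)), bin_width = 1)
  expect_length(f, 5)
  expect_identical(unname(f), rep(0, 5))
})

test_that("GLDM matches the fully dependent constant block", {
  img <- array(1, c(2, 2, 1))
  f <- gldm_features(img, array(TRUE, c(2, 2, 1)), bin_width = 1)
  expect_length(f, 14)
  # every voxel: 3 dependent neighbours, dependence size 4; P(1, 4) = 4
  expect_equal(unname(f["gldm_LargeDependenceEmphasis"]), 16)
  expect_equal(unname(f["gldm_SmallDependenceEmphasis"]), 1 / 16)
  expect_equal(unname(f["gldm_GrayLevelNonUniformity"]), 4)
  expect_equal(unname(f["gldm_DependenceEntropy"]), 0)
})

test_that("texture matrices match the brute-force oracle on random crops", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      cr <- oracle_random_crop(max_dim = 10)
      lv <- cr$lv; ng <- cr$ng; dims <- cr$dims
      glcm_fast <- array(mvibench:::cpp_glcm(as.vector(lv), dims, ng),
                         c(ng, ng, 13))
      expect_equal(glcm_fast, oracle_glcm(lv, ng))
      maxrun <- max(dims)
      rl_fast <- array(mvibench:::cpp_glrlm(as.vector(lv), dims, ng),
                       c(ng, maxrun, 13))
      expect_equal(rl_fast, oracle_glrlm(lv, ng, maxrun))
      zf <- mvibench:::cpp_zones(as.vector(lv), dims)
      zo <- oracle_zone_table(lv)
      expect_equal(zf[order(zf[, 1], zf[, 2]), , drop = FALSE],
                   unname(zo[order(zo[, 1], zo[, 2]), , drop = FALSE]),
                   ignore_attr = TRUE)
      expect_equal(unname(mvibench:::cpp_ngtdm(as.vector(lv), dims, ng)),
                   oracle_ngtdm(lv, ng), ignore_attr = TRUE)
      expect_equal(unname(mvibench:::cpp_gldm(as.vector(lv), dims, ng, 0L)),
                   oracle_gldm(lv, ng, 0), ignore_attr = TRUE)
    }
  })
})

test_that("texture features are invariant to an affine intensity shift", {
  withr::with_seed(5, {
    img <- array(rnorm(6^3, 100, 20), c(6, 6, 6))
    msk <- array(TRUE, c(6, 6, 6))
    shifted <- img + 500
    for (fn in list(glcm_features, glszm_features, glrlm_features,
                    ngtdm_features, gldm_features)) {
      expect_equal(fn(img, msk, 10), fn(shifted, msk, 10))
    }
  })
})
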
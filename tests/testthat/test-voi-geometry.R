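test_that("dice matches hand-computed overlaps", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE          # |A| = 2
  b[2:3, 1, 1] <- TRUE          # |B| = 2, |A & B| = 1
  expect_equal(dice(a, b), 2 * 1 / 4)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, array(FALSE, c(4, 4, 4))), 0)
  expect_error(dice(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4))),
               "undefined")
  expect_error(dice(a, array(FALSE, c(5, 4, 4))), "different shapes")
})

test_that("consensus_mask applies the union / intersection rules", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:3, 1:3, 1] <- TRUE
  b[1:3, 1:3, 1] <- TRUE
  b[4, 1, 1] <- TRUE            # high overlap, one extra voxel
  r_union <- consensus_mask(a, b, dice_threshold = 0.8, rule = "union")
  expect_true(r_union$agreed)
  expect_identical(r_union$mask, a | b)
  r_int <- consensus_mask(a, b, dice_threshold = 0.8, rule = "intersection")
  expect_identical(r_int$mask, a & b)
  # disagreement below the threshold returns no mask
  c2 <- array(FALSE, c(4, 4, 4)); c2[4, 4, 4] <- TRUE
  r <- consensus_mask(a, c2, dice_threshold = 0.9)
  expect_false(r$agreed)
  expect_null(r$mask)
})

test_that("vessel caliber filter keeps wide and drops thin structures", {
  m <- array(FALSE, c(9, 9, 9))
  m[2:4, 2:8, 2:8] <- TRUE   # 3 mm slab: caliber 2*2 - 1 = 3 mm
  m[7, 2:8, 2:8] <- TRUE     # 1 mm sheet: caliber 2*1 - 1 = 1 mm
  keep <- vessel_caliber_filter(m, c(1, 1, 1), min_caliber_mm = 2)
  expect_true(all(keep[2:4, 2:8, 2:8]))
  expect_false(any(keep[7, , ]))
  # empty input passes through
  expect_identical(vessel_caliber_filter(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                   array(FALSE, c(4, 4, 4)))
})

test_that("expand_region equals the all-pairs oracle (isotropic)", {
  dims <- c(12, 12, 12)
  liver <- array(TRUE, dims)
  core <- array(FALSE, dims)
  core[6:7, 6:7, 6:7] <- TRUE
  for (d in c(0, 1.5, 3)) {
    ring <- expand_region(core, liver, NULL, c(1, 1, 1), d)
    expect_identical(ring, oracle_ring(core, liver, array(FALSE, dims),
                                       c(1, 1, 1), d))
  }
})

test_that("a single-voxel core with a 2 mm radius yields the 32-voxel ball shell", {
  dims <- c(9, 9, 9)
  core <- array(FALSE, dims); core[5, 5, 5] <- TRUE
  ring <- expand_region(core, array(TRUE, dims), NULL, c(1, 1, 1), 2)
  # voxels with centre distance <= 2 from the core centre, minus the core:
  # 6 at d=1, 12 at d=sqrt(2), 8 at d=sqrt(3), 6 at d=2
  expect_equal(sum(ring), 32)
  expect_false(ring[5, 5, 5])
})

test_that("expansion respects liver boundary and barrier exclusion", {
  dims <- c(10, 10, 10)
  liver <- array(FALSE, dims); liver[2:9, 2:9, 2:9] <- TRUE
  core <- array(FALSE, dims); core[5:6, 5:6, 5:6] <- TRUE
  barrier <- array(FALSE, dims); barrier[8, , ] <- TRUE
  ring <- expand_region(core, liver, barrier, c(1, 1, 1), 4)
  expect_false(any(ring & !liver))
  expect_false(any(ring & barrier))
  expect_false(any(ring & core))
  expect_identical(ring, oracle_ring(core, liver, barrier, c(1, 1, 1), 4))
})

test_that("anisotropic spacing is honoured", {
  dims <- c(11, 11, 5)
  spacing <- c(1, 2, 3.5)
  core <- array(FALSE, dims); core[6, 6, 3] <- TRUE
  liver <- array(TRUE, dims)
  ring <- expand_region(core, liver, NULL, spacing, 3.6)
  expect_identical(ring, oracle_ring(core, liver, array(FALSE, dims),
                                     spacing, 3.6))
  # z neighbours sit 3.5 mm away: included at 3.6 mm, excluded at 3.4 mm
  expect_true(ring[6, 6, 2])
  expect_false(expand_region(core, liver, NULL, spacing, 3.4)[6, 6, 2])
})

test_that("geodesic metric is blocked by barriers, euclidean is not", {
  dims <- c(15, 9, 9)
  liver <- array(TRUE, dims)
  core <- array(FALSE, dims); core[3, 5, 5] <- TRUE
  # wall between core and the far side, with no gap
  barrier <- array(FALSE, dims); barrier[7, , ] <- TRUE
  eu <- expand_region(core, liver, barrier, c(1, 1, 1), 6, metric = "euclidean")
  ge <- expand_region(core, liver, barrier, c(1, 1, 1), 6, metric = "geodesic")
  expect_true(eu[9, 5, 5])      # 6 mm straight through the wall
  expect_false(ge[9, 5, 5])     # unreachable without crossing the wall
  expect_true(ge[6, 5, 5])      # near side reachable in both metrics
})

test_that("build_region_set produces nested cumulative shells", {
  dims <- c(16, 16, 16)
  core <- array(FALSE, dims); core[8:9, 8:9, 8:9] <- TRUE
  liver <- array(TRUE, dims)
  rs <- build_region_set(core, liver, NULL, c(1, 1, 1), distances = c(2, 4, 6))
  expect_s3_class(rs, "region_set")
  expect_false(any(rs$rings[["2"]] & core))
  expect_true(all(rs$rings[["2"]] <= rs$rings[["4"]]))
  expect_true(all(rs$rings[["4"]] <= rs$rings[["6"]]))
  expect_identical(rs$combined[["4"]], rs$rings[["4"]] | core)
  expect_output(print(rs), "region_set")
})

test_that("region ids resolve and invalid ids fail", {
  dims <- c(12, 12, 12)
  core <- array(FALSE, dims); core[6, 6, 6] <- TRUE
  rs <- build_region_set(core, array(TRUE, dims), NULL, c(1, 1, 1),
                         distances = c(2, 4))
  expect_identical(mvibench:::region_mask(rs, "V_tc"), rs$core)
  expect_identical(mvibench:::region_mask(rs, "V_pt(4)"), rs$rings[["4"]])
  expect_identical(mvibench:::region_mask(rs, "V_tc+V_pt(2)"),
                   rs$combined[["2"]])
  expect_error(mvibench:::region_mask(rs, "V_pt(3)"), "not present")
  expect_error(mvibench:::region_mask(rs, "nonsense"), "unknown region")
  expect_length(region_options(), 15)
  expect_identical(mvibench:::region_class(c("V_tc", "V_pt(4)", "V_tc+V_pt(4)")),
                   c("V_tc", "V_pt", "V_tc+V_pt"))
  expect_identical(mvibench:::region_distance(c("V_tc", "V_pt(8)")),
                   c(NA_real_, 8))
})

test_that("expand_region validates inputs", {
  dims <- c(8, 8, 8)
  core <- array(FALSE, dims); core[4, 4, 4] <- TRUE
  liver <- array(TRUE, dims)
  expect_error(expand_region(array(FALSE, dims), liver, NULL, c(1, 1, 1), 2),
               "empty")
  expect_error(expand_region(core, array(FALSE, dims), NULL, c(1, 1, 1), 2),
               "inside")
  expect_error(expand_region(core, liver, NULL, c(1, 1, 1), -1),
               "non-negative")
})
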
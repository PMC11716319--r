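test_that("labelVolume converts voxel counts with the voxel volume", {
  v <- array(0L, c(10, 10, 10))
  empty <- LabeledMask3D(v, c(1, 1, 1), c(`1` = "muscle"))
  expect_equal(labelVolume(empty, "muscle"), 0)
  v[1:10, 1:10, 1:10] <- 1L
  full <- LabeledMask3D(v, c(1, 1, 1), c(`1` = "muscle"))
  expect_equal(labelVolume(full, "muscle"), 1)        # 1000 mm^3 = 1 cm^3
  expect_error(labelVolume(full, "bone"), "bone")
})

test_that("labelVolume agrees with a brute-force slice loop on random masks", {
  set.seed(17)
  v <- array(sample(0:3, 4000, replace = TRUE), c(20, 20, 10))
  m <- LabeledMask3D(v, c(0.5, 0.7, 5),
                     stats::setNames(c("a", "b", "c"), 1:3))
  for (id in 1:3) {
    cnt <- 0L
    for (k in 1:10) cnt <- cnt + sum(v[, , k] == id)
    expect_equal(labelVolume(m, id), cnt * 0.5 * 0.7 * 5 / 1000)
  }
})

test_that("percent change reproduces printed table arithmetic", {
  expect_equal(percentChange(67, 65.51), -2.2239, tolerance = 1e-4)
  expect_equal(percentChange(50, 50), 0)
  expect_equal(percentChange(100, 112.11), 12.11, tolerance = 1e-12)
  expect_error(percentChange(0, 5), "pre")
  expect_error(percentChange(-2, 5), "pre")
})

test_that("percent change is exact for multiplicative changes", {
  for (f in c(-0.5, -0.0222, 0, 1e-6, 0.1211, 2)) {
    expect_lt(abs(percentChange(67, 67 * (1 + f)) - 100 * f), 1e-12)
  }
})

test_that("volumes are additive over disjoint labels and scale with dz", {
  set.seed(5)
  v <- array(sample(0:2, 2000, replace = TRUE), c(10, 20, 10))
  m <- LabeledMask3D(v, c(1, 1, 2), stats::setNames(c("a", "b"), 1:2))
  total <- sum(v != 0) * prod(spacing(m)) / 1000
  expect_identical(labelVolume(m, "a") + labelVolume(m, "b"), total)
  m2 <- LabeledMask3D(v, c(1, 1, 4), stats::setNames(c("a", "b"), 1:2))
  expect_identical(labelVolume(m2, "a"), 2 * labelVolume(m, "a"))
})

test_that("compartment grouping sums volumes and recomputes percent change", {
  lab <- data.frame(name = c("x", "y", "z"),
                    pre_cm3 = c(10, 20, 30), post_cm3 = c(9, 22, 30),
                    percent_change = c(-10, 10, 0),
                    change_label = NA_character_)
  rep1 <- new("VolumeReport", labels = lab, compartments = lab[0, ])
  out <- groupCompartments(rep1, list(one = "x", all = c("x", "y", "z")))
  cmp <- out@compartments
  expect_equal(cmp$pre_cm3[cmp$name == "one"], 10)
  expect_equal(cmp$pre_cm3[cmp$name == "all"], 60)
  # sum-then-ratio, not mean of member percentages
  lab2 <- data.frame(name = c("x", "y"), pre_cm3 = c(10, 10),
                     post_cm3 = c(9, 12), percent_change = c(-10, 20),
                     change_label = NA_character_)
  rep2 <- new("VolumeReport", labels = lab2, compartments = lab2[0, ])
  out2 <- groupCompartments(rep2, list(c = c("x", "y")))
  expect_equal(out2@compartments$percent_change, 5, tolerance = 1e-12)
  expect_error(groupCompartments(rep2, list(c = c("x", "missing"))),
               "missing")
})

test_that("default compartment table covers calf and thigh groupings", {
  cm <- defaultCompartments()
  expect_true(all(c("medial_gastrocnemius", "lateral_gastrocnemius",
                    "soleus") %in% cm$calf_superficial_posterior))
  expect_setequal(cm$thigh_quadriceps_anterior,
                  c("rectus_femoris", "vastus_medialis", "vastus_lateralis",
                    "vastus_intermedius"))
  # no label in two compartments
  expect_false(any(duplicated(unlist(cm))))
})

test_that("landmark alignment shifts and trims stacks consistently", {
  set.seed(8)
  v <- array(sample(0:1, 8 * 8 * 12, replace = TRUE), c(8, 8, 12))
  m <- LabeledMask3D(v, c(1, 1, 5), c(`1` = "bone"))
  same <- alignStacksByLandmark(m, m, 4, 4)
  expect_identical(voxels(same$pre), voxels(m))
  expect_identical(voxels(same$post), voxels(m))
  # post is pre shifted by +3 slices
  v2 <- array(0L, c(8, 8, 12))
  v2[, , 4:12] <- v[, , 1:9]
  m2 <- LabeledMask3D(v2, c(1, 1, 5), c(`1` = "bone"))
  al <- alignStacksByLandmark(m, m2, 2, 5)
  expect_identical(voxels(al$pre), voxels(al$post))
  expect_error(alignStacksByLandmark(m, m2, 1, 40), "out of range")
  mBad <- LabeledMask3D(v, c(2, 2, 5), c(`1` = "bone"))
  expect_error(alignStacksByLandmark(m, mBad, 1, 1), "in-plane")
})

test_that("landmarks outside either stack are rejected", {
  # in-range landmarks always overlap on the landmark slice itself, so the
  # empty-overlap guard is only reachable through invalid indices
  v <- array(1L, c(4, 4, 3))
  a <- LabeledMask3D(v, c(1, 1, 5), c(`1` = "bone"))
  b <- LabeledMask3D(array(1L, c(4, 4, 8)), c(1, 1, 5), c(`1` = "bone"))
  expect_error(alignStacksByLandmark(a, b, 3, 12), "out of range")
  expect_error(alignStacksByLandmark(a, b, 0, 2), "out of range")
})

test_that("volumeReport renders losses and gains like printed tables", {
  v1 <- array(0L, c(10, 10, 4)); v1[1:10, 1:10, ] <- 1L
  v2 <- v1; v2[1:2, , ] <- 0L
  pre <- LabeledMask3D(v1, c(1, 1, 1), c(`1` = "femur"))
  post <- LabeledMask3D(v2, c(1, 1, 1), c(`1` = "femur"))
  rep <- volumeReport(pre, post)
  expect_equal(rep@labels$percent_change, -20)
  expect_match(rep@labels$change_label, "loss of 20.00%")
})
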
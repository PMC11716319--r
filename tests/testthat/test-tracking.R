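# Uniform field with principal direction z and muscle-typical anisotropy.
uniformZField <- function(dims = c(10, 10, 30), sp = c(2, 2, 2)) {
  comp <- c(1.6e-3, 1.4e-3, 2.1e-3, 0, 0, 0)
  new("TensorField", tensors = array(rep(comp, each = prod(dims)),
                                     c(dims, 6)),
      valid = array(TRUE, dims), spacing = sp)
}

test_that("tracts through a uniform field are straight box-spanning chords", {
  tf <- uniformZField()
  mask <- array(TRUE, c(10, 10, 30))            # 20 x 20 x 60 mm box
  ts <- trackFibers(tf, mask, trackingParams(targetCount = 50), seed = 1)
  expect_equal(nTracts(ts), 50)
  for (t in ts@tracts) {
    chord <- t$points[nrow(t$points), ] - t$points[1, ]
    expect_gt(abs(chord[3]) / sqrt(sum(chord^2)), 0.99999)
    expect_gte(t$raw_length, 57); expect_lte(t$raw_length, 60.01)
  }
  # analytic chord oracle: extrapolation lands each end on a z face
  ext <- extrapolateTracts(ts, LabeledMask3D(array(1L, c(10, 10, 30)),
                                             c(2, 2, 2)))
  for (t in ext@tracts) {
    expect_equal(t$status, "extrapolated")
    expect_lt(abs(t$extrapolated_length - 60), 0.5)
    zEnds <- sort(c(t$points[1, 3], t$points[nrow(t$points), 3]))
    expect_lt(zEnds[1], 0.3); expect_gt(zEnds[2], 59.7)
  }
})

test_that("masks thinner than the length floor accept no tracts", {
  tf <- uniformZField(dims = c(10, 10, 2))      # 4 mm along the field
  expect_warning(
    ts <- trackFibers(tf, array(TRUE, c(10, 10, 2)),
                      trackingParams(targetCount = 10, maxSeedAttempts = 50),
                      seed = 1),
    "0 of 10")
  expect_equal(nTracts(ts), 0)
})

test_that("tracking is bitwise deterministic under a fixed seed", {
  ph <- makePennatePhantom(30, boxDims = c(10, 20, 120))
  dwi <- simulateDWI(ph$tensors)
  tf <- fitTensors(dwi, ph$mask)
  p <- trackingParams(targetCount = 100)
  a <- trackFibers(tf, ph$mask, p, seed = 42)
  b <- trackFibers(tf, ph$mask, p, seed = 42)
  expect_identical(a@tracts, b@tracts)
})

test_that("extrapolation is idempotent on boundary-touching tracts", {
  mask <- LabeledMask3D(array(1L, c(10, 10, 30)), c(2, 2, 2))
  t0 <- straightTract(c(10, 10, 0.4), c(10, 10, 59.6), n = 40)
  out <- extrapolateTract(t0, mask, stepMm = 1)
  expect_equal(out$status, "extrapolated")
  expect_lt(abs(out$extrapolated_length - t0$raw_length), 1)
})

test_that("too-short tracts are rejected without an exception", {
  mask <- LabeledMask3D(array(1L, c(10, 10, 30)), c(2, 2, 2))
  t0 <- straightTract(c(10, 10, 20), c(10, 10, 22), n = 2)
  out <- extrapolateTract(t0, mask, polyOrder = 3, stepMm = 1)
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "short")
})

test_that("tracts that never reach the boundary are rejected as no-boundary", {
  mask <- LabeledMask3D(array(1L, c(50, 50, 50)), c(2, 2, 2))
  t0 <- straightTract(c(50, 50, 45), c(50, 50, 55), n = 11)
  out <- extrapolateTract(t0, mask, stepMm = 1)   # cap = 5 mm per end
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "no-boundary")
})

test_that("the inclusion filter applies the 1.3x and length-window rules", {
  keep <- straightTract(c(0, 0, 0), c(0, 0, 10), status = "extrapolated",
                        extrapolated = 12.9)
  drop <- straightTract(c(0, 0, 0), c(0, 0, 10), status = "extrapolated",
                        extrapolated = 13.1)
  ts <- filterTracts(newTractSet(list(keep, drop)))
  expect_equal(tractStatus(ts), c("extrapolated", "rejected"))
  expect_equal(ts@tracts[[2]]$reason, "overextended")
})

test_that("filtering equals brute-force predicates on 100 synthetic tracts", {
  set.seed(33)
  raw <- runif(100, 3, 180)
  ratio <- runif(100, 0.95, 1.6)
  ext <- raw * ratio
  tracts <- lapply(seq_len(100), function(i)
    straightTract(c(0, 0, 0), c(0, 0, raw[i]), status = "extrapolated",
                  extrapolated = ext[i]))
  out <- filterTracts(newTractSet(tracts))
  kept <- tractStatus(out) == "extrapolated"
  brute <- ext <= 1.3 * raw & ext >= 5 & ext <= 200
  expect_identical(kept, brute)
  reasons <- vapply(out@tracts, `[[`, character(1), "reason")
  expect_true(all(!is.na(reasons[!kept])))
  expect_true(all(is.na(reasons[kept])))
})

test_that("the tract ledger balances: tracked = accepted + rejected", {
  ph <- makePennatePhantom(30, boxDims = c(10, 20, 120))
  dwi <- simulateDWI(ph$tensors, noiseSigma = 1 / 40, seed = 3)
  res <- muscleArchitecture(dwi, ph$mask,
                            params = trackingParams(targetCount = 150),
                            seed = 3)
  st <- tractStatus(res$tracts)
  cnt <- tractCounts(res$tracts)
  expect_equal(unname(cnt["tracked"]),
               sum(st == "extrapolated") + sum(st == "rejected"))
  expect_equal(unname(cnt["accepted"]), sum(st == "extrapolated"))
  expect_gte(unname(cnt["seeded"]), unname(cnt["tracked"]))
})
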
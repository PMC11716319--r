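test_that("dual-echo subtraction clips, rescales and boosts sheet contrast", {
  te1 <- array(runif(64), c(4, 4, 4))
  expect_true(all(dualEchoSubtract(te1, te1) == 0))
  expect_equal(dualEchoSubtract(te1, array(0, dim(te1))), te1 / max(te1))
  expect_error(dualEchoSubtract(te1, array(0, c(4, 4, 2))), "shape")
  # fascia decays slowly between echoes, muscle hardly differs
  te1 <- array(0.05, c(8, 8, 1)); te2 <- array(0.04, c(8, 8, 1))
  te1[3:6, 3:6, 1] <- 0.8; te2[3:6, 3:6, 1] <- 0.75       # muscle
  te1[4:5, 4:5, 1] <- 1.0; te2[4:5, 4:5, 1] <- 0.2        # fascia
  sub <- dualEchoSubtract(te1, te2, rescale = FALSE)
  contrastBefore <- mean(te1[4:5, 4:5, 1]) / mean(te1[3, 3:6, 1])
  contrastAfter <- mean(sub[4:5, 4:5, 1]) / mean(sub[3, 3:6, 1])
  expect_gt(contrastAfter, contrastBefore)
})

test_that("centerline of a circular band approximates the mid-circle", {
  m <- ringMatrix(96, 40, 44)
  cl <- sliceCenterline(m, 0.3)
  expect_false(cl$empty)
  # every skeleton pixel close to radius 42 px
  r <- sqrt(rowSums((cl$pixels - 0.5 - 48)^2))
  expect_true(all(abs(r - 42) < 1.5))
  expect_lt(abs(cl$arclengthMm - 2 * pi * 42 * 0.3) / (2 * pi * 42 * 0.3),
            0.05)
})

test_that("a one-pixel-wide ring is its own centerline", {
  m <- ringMatrix(32, 9.5, 10.49)
  skelIn <- which(m == 1L, arr.ind = TRUE)
  cl <- sliceCenterline(m, 1)
  expect_true(cl$thin)
  expect_equal(nrow(cl$pixels), nrow(skelIn))
  expect_setequal(paste(cl$pixels[, 1], cl$pixels[, 2]),
                  paste(skelIn[, 1], skelIn[, 2]))
})

test_that("empty slices give an empty flagged centerline", {
  cl <- sliceCenterline(matrix(0L, 10, 10), 0.3)
  expect_true(cl$empty)
  expect_equal(cl$arclengthMm, 0)
  expect_equal(nrow(cl$pixels), 0)
})

test_that("thickness map recovers the constant annulus within one pixel", {
  ph <- makeFasciaPhantom(nSlices = 4)
  tm <- thicknessMap(ph$mask)
  expect_lt(abs(meanThickness(tm) - 1.2), 0.3)
  expect_true(all(thicknessSamples(tm)$thickness_mm > 0))
  expect_equal(meanThickness(tm), mean(thicknessSamples(tm)$thickness_mm),
               tolerance = 1e-12)
})

test_that("a 9% thicker irregular tube yields a mean ratio near 1.09", {
  prof <- fasciaProfile(thicknessMean = 1.2, thicknessAmp = 0.15,
                        radiusAmp = 0.8, twistPerSlice = 0.5,
                        phases = c(0.7, 2.1, 0))
  profPost <- prof
  profPost$thicknessMean <- prof$thicknessMean * 1.09
  profPost$thicknessAmp <- prof$thicknessAmp * 1.09
  pre <- makeFasciaPhantom(profile = prof, nSlices = 6)
  post <- makeFasciaPhantom(profile = profPost, nSlices = 6)
  ratio <- meanThickness(thicknessMap(post$mask)) /
    meanThickness(thicknessMap(pre$mask))
  expect_gte(ratio, 1.07); expect_lte(ratio, 1.11)
})

test_that("degenerate thickness-map inputs error out", {
  empty <- LabeledMask3D(array(0L, c(10, 10, 2)), c(0.3, 0.3, 3))
  expect_error(thicknessMap(empty), "empty mask")
  aniso <- LabeledMask3D(array(1L, c(10, 10, 2)), c(0.3, 0.4, 3))
  expect_error(thicknessMap(aniso), "isotropic")
  tiny <- makeFasciaPhantom(baseRadius = 6, spacing = c(0.6, 0.6, 3),
                            nSlices = 1)
  expect_error(thicknessMap(tiny$mask, minSamples = 1e5), "finer")
})

test_that("algebraic mean thickness cross-checks the medial-axis estimate", {
  ph <- makeFasciaPhantom(nSlices = 4)
  alg <- meanThicknessAlgebraic(ph$mask)
  expect_lt(abs(alg - 1.2) / 1.2, 0.10)
  tm <- thicknessMap(ph$mask)
  expect_lt(abs(meanThickness(tm) - alg) / alg, 0.15)
  expect_error(meanThicknessAlgebraic(
    LabeledMask3D(array(0L, c(8, 8, 2)), c(0.3, 0.3, 3))), "non-empty")
})

test_that("a one-pixel ribbon has algebraic thickness near one pitch", {
  v <- array(0L, c(60, 9, 1))
  v[6:55, 5, 1] <- 1L                       # 50 px straight ribbon
  m <- LabeledMask3D(v, c(0.4, 0.4, 3))
  alg <- meanThicknessAlgebraic(m, pruneLen = 0, weights = "chain")
  expect_lt(abs(alg - 0.4) / 0.4, 0.05)
})

test_that("thickness histograms conserve samples and expose bimodality", {
  tm <- mapFromSamples(c(rep(1.0, 4), rep(1.2, 6)))
  h <- thicknessHistogram(tm, binWidth = 0.05)
  expect_equal(sum(h@counts), 10)
  h1 <- thicknessHistogram(mapFromSamples(rep(0.87, 25)), binWidth = 0.05)
  expect_equal(sum(h1@counts > 0), 1)
  expect_error(thicknessHistogram(tm, binWidth = 0), "binWidth")
  # two-lobe angular profile: thickness concentrates at 1.2 +/- 0.35
  ph <- makeFasciaPhantom(profile = fasciaProfile(thicknessAmp = 0.35,
                                                  phases = c(0, 0, 0)),
                          nSlices = 2)
  h2 <- thicknessHistogram(thicknessMap(ph$mask), binWidth = 0.1)
  mids <- head(h2@breaks, -1) + 0.05
  lowPeak <- max(h2@counts[mids < 1.05])
  highPeak <- max(h2@counts[mids > 1.35])
  valley <- min(h2@counts[mids >= 1.05 & mids <= 1.35])
  expect_gt(lowPeak, 1.5 * valley)
  expect_gt(highPeak, 1.5 * valley)
})

test_that("thickness comparison reports exact shifts for scaled samples", {
  a <- mapFromSamples(runif(200, 0.8, 1.4))
  same <- compareThickness(a, a)
  expect_equal(same@meanShiftPct, 0)
  expect_equal(same@medianShiftPct, 0)
  b <- mapFromSamples(a@samples$thickness_mm * 1.10)
  sh <- compareThickness(a, b)
  expect_equal(sh@meanShiftPct, 10, tolerance = 1e-9)
  expect_equal(sh@medianShiftPct, 10, tolerance = 1e-9)
})

test_that("forward and reverse shifts obey the antisymmetry identity", {
  a <- mapFromSamples(runif(300, 0.7, 1.3))
  b <- mapFromSamples(runif(300, 0.8, 1.5))
  fwd <- compareThickness(a, b)@meanShiftPct
  rev <- compareThickness(b, a)@meanShiftPct
  expect_equal(rev, -fwd / (1 + fwd / 100), tolerance = 1e-9)
})

test_that("rotating the tube geometry barely changes the mean thickness", {
  prof <- fasciaProfile(thicknessAmp = 0.2, radiusAmp = 0.6,
                        phases = c(0.4, 1.3, 0))
  beta <- 37 * pi / 180
  profRot <- prof
  profRot$phases <- c(0.4 - prof$thicknessHarmonic * beta,
                      1.3 - prof$radiusHarmonic * beta, 0)
  m1 <- makeFasciaPhantom(profile = prof, nSlices = 2)$mask
  m2 <- makeFasciaPhantom(profile = profRot, nSlices = 2)$mask
  t1 <- meanThickness(thicknessMap(m1))
  t2 <- meanThickness(thicknessMap(m2))
  expect_lt(abs(t2 - t1) / t1, 0.05)
})
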
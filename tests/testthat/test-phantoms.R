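test_that("constant annulus phantom carries exact analytic truth", {
  ph <- makeFasciaPhantom(baseRadius = 12.6, nSlices = 10)
  expect_equal(ph$truth@meanThickness, 1.2)
  # thickness field constant 1.2: outer - inner = 13.2 - 12.0
  th <- seq(0, 2 * pi, length.out = 33)
  expect_equal(ph$truth@thicknessField(3, th), rep(1.2, 33))
})

test_that("truth mean equals the numerical mean of the thickness field", {
  ph <- makeFasciaPhantom(profile = fasciaProfile(thicknessAmp = 0.2,
                                                  axialAmp = 0.1,
                                                  twistPerSlice = 0.3),
                          nSlices = 7, seed = 11)
  nTheta <- 720
  th <- (seq_len(nTheta) - 0.5) / nTheta * 2 * pi
  num <- mean(vapply(1:7, function(k) mean(ph$truth@thicknessField(k, th)),
                     numeric(1)))
  expect_equal(num, ph$truth@meanThickness, tolerance = 1e-9)
})

test_that("degenerate fascia phantom inputs are rejected", {
  expect_error(makeFasciaPhantom(nSlices = 0), "nSlices")
  expect_error(makeFasciaPhantom(profile = fasciaProfile(thicknessMean = 0.2,
                                                         thicknessAmp = 0.3)),
               "non-positive thickness")
  expect_error(makeFasciaPhantom(baseRadius = 1), "baseRadius")
})

test_that("coarse grids set the resolution warning flag", {
  expect_warning(ph <- makeFasciaPhantom(spacing = c(0.8, 0.8, 3),
                                         nSlices = 2), "2 in-plane pixels")
  expect_true(ph$truth@coarse)
})

test_that("rasterized band area per slice tracks the analytic annulus area", {
  ph <- makeFasciaPhantom(profile = fasciaProfile(thicknessAmp = 0.2,
                                                  radiusAmp = 0.5),
                          nSlices = 6, seed = 7)
  areaAnalytic <- annulusAreaPerSlice(ph$truth)
  sp <- spacing(ph$mask)
  areaRaster <- apply(voxels(ph$mask), 3, sum) * sp[1] * sp[2]
  expect_true(all(abs(areaRaster - areaAnalytic) / areaAnalytic < 0.05))
})

test_that("halving the in-plane pitch about halves the area error", {
  prof <- fasciaProfile(thicknessAmp = 0.2, radiusAmp = 0.5,
                        phases = c(0.3, 1.1, 0))
  err <- vapply(c(0.3, 0.15), function(p) {
    ph <- makeFasciaPhantom(profile = prof, spacing = c(p, p, 3),
                            nSlices = 3)
    a <- annulusAreaPerSlice(ph$truth)
    r <- apply(voxels(ph$mask), 3, sum) * p^2
    mean(abs(r - a))
  }, numeric(1))
  expect_lt(err[2], 0.75 * err[1])
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- makeFasciaPhantom(profile = fasciaProfile(thicknessAmp = 0.2),
                         nSlices = 3, seed = 42)
  b <- makeFasciaPhantom(profile = fasciaProfile(thicknessAmp = 0.2),
                         nSlices = 3, seed = 42)
  expect_identical(voxels(a$mask), voxels(b$mask))
})

test_that("limb phantom volumes match their requested volumes within 2%", {
  spec <- list(cyl = list(center = c(25, 25, 55), volume_cm3 = 100,
                          height_mm = 100))
  m <- makeLimbPhantom(spec, spacing = c(0.5, 0.5, 5))
  v <- labelVolume(m, "cyl")
  expect_gte(v, 98); expect_lte(v, 102)
  # brute-force oracle: count voxel centers inside the analytic cylinder
  a <- sqrt(100e3 / (pi * 100))
  d <- dim(voxels(m))
  xs <- (seq_len(d[1]) - 0.5) * 0.5 - 25
  ys <- (seq_len(d[2]) - 0.5) * 0.5 - 25
  zs <- (seq_len(d[3]) - 0.5) * 5 - 55
  inPlane <- outer(xs^2, ys^2, `+`) <= a^2
  nBrute <- sum(inPlane) * sum(abs(zs) <= 50)
  expect_equal(sum(voxels(m) == 1L), nBrute)
})

test_that("empty label spec gives an all-background mask", {
  m <- makeLimbPhantom(list())
  expect_true(all(voxels(m) == 0L))
})

test_that("overlapping limb shapes are rejected with both names", {
  spec <- list(a = list(center = c(20, 20, 50), volume_cm3 = 50,
                        height_mm = 80),
               b = list(center = c(21, 20, 50), volume_cm3 = 50,
                        height_mm = 80))
  expect_error(makeLimbPhantom(spec), "'b' and 'a'")
})

test_that("pennate phantom geometry and tensors match the unipennate model", {
  ph <- makePennatePhantom(30, boxDims = c(20, 20, 60), spacing = c(2, 2, 2))
  expect_equal(ph$truth@fascicleLengthMm, 40)        # 20 / sin(30 deg)
  cmp <- ph$tensors@tensors[1, 1, 1, ]
  D <- matrix(c(cmp[1], cmp[4], cmp[5],
                cmp[4], cmp[2], cmp[6],
                cmp[5], cmp[6], cmp[3]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  v <- e$vectors[, 1] * sign(e$vectors[3, 1])
  expect_equal(v, c(sin(pi / 6), 0, cos(pi / 6)), tolerance = 1e-12)
  # same tensor in every voxel
  expect_equal(max(abs(sweep(matrix(ph$tensors@tensors, ncol = 6), 2, cmp))),
               0)
})

test_that("degenerate pennation angles are rejected", {
  expect_error(makePennatePhantom(90), "strictly inside")
  expect_error(makePennatePhantom(0), "strictly inside")
})

test_that("isotropic diffusion gives direction-independent signal", {
  d <- 1e-3
  tf <- new("TensorField",
            tensors = array(rep(c(d, d, d, 0, 0, 0), each = 8), c(2, 2, 2, 6)),
            valid = array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 1))
  dwi <- simulateDWI(tf, gradientTable(20), bValue = 500, S0 = 2)
  s <- dwi@signal[1, 1, 1, ]
  expect_equal(s[1], 2)                                # b = 0 volume
  expect_equal(unname(s[-1]), rep(2 * exp(-500 * d), 20), tolerance = 1e-12)
})

test_that("b = 0 acquisition returns S0 everywhere", {
  ph <- makePennatePhantom(30, boxDims = c(8, 8, 8), spacing = c(2, 2, 2))
  dwi <- simulateDWI(ph$tensors, bValue = 0, S0 = 3)
  expect_true(all(dwi@signal == 3))
})

test_that("non-unit gradients are normalized with a warning", {
  ph <- makePennatePhantom(30, boxDims = c(4, 4, 4), spacing = c(2, 2, 2))
  g <- gradientTable(20) * 2
  expect_warning(dwi <- simulateDWI(ph$tensors, g), "normalized")
  expect_equal(rowSums(dwi@gradients[-1, ]^2), rep(1, 20), tolerance = 1e-12)
})

test_that("noisy simulation is reproducible and S0 must be positive", {
  ph <- makePennatePhantom(30, boxDims = c(4, 4, 4), spacing = c(2, 2, 2))
  a <- simulateDWI(ph$tensors, noiseSigma = 0.05, seed = 9)
  b <- simulateDWI(ph$tensors, noiseSigma = 0.05, seed = 9)
  expect_identical(a@signal, b@signal)
  expect_error(simulateDWI(ph$tensors, S0 = -1), "S0")
})

test_that("pre/post pair reproduces the requested structural changes", {
  pair <- makePrePostPair(seed = 2)
  pre <- labelVolume(pair$pre$limb, "femur")
  post <- labelVolume(pair$post$limb, "femur")
  pct <- percentChange(pre, post)
  expect_gte(pct, -2.7); expect_lte(pct, -1.7)
  expect_equal(pair$post$fasciaTruth@meanThickness,
               1.2 * 1.09, tolerance = 1e-12)
})

test_that("identity fascia scale yields identical fascia masks", {
  pair <- makePrePostPair(list(volumeChanges = numeric(0), fasciaScale = 1),
                          seed = 4)
  expect_identical(voxels(pair$pre$fascia), voxels(pair$post$fascia))
})

test_that("non-positive change factors are rejected", {
  expect_error(makePrePostPair(list(fasciaScale = 0)), "fasciaScale")
  expect_error(makePrePostPair(list(volumeChanges = c(femur = -1.5))),
               "positive")
})
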
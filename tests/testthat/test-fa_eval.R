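test_that("small-tip prediction is exact for the uniform case and linear", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, roi)
  cfg <- fastCfg(nKt = 1L, lambda = 0)
  tp <- designTailored(maps, roi, cfg)
  fa <- predictFaSta(maps, tp)
  expect_equal(faArray(fa)[maskArray(roi)],
               rep(10, roiVoxelCount(roi)), tolerance = 1e-9)

  # linearity: doubling the weights doubles the flip angle everywhere
  tp2 <- tp
  tp2@weights <- tp@weights * 2
  expect_equal(faArray(predictFaSta(maps, tp2)), 2 * faArray(fa),
               tolerance = 1e-12)

  # channel mismatch is an error
  maps2 <- randomB1(g, roi, channels = 2L, seed = 1)
  expect_error(predictFaSta(maps2, tp), "channel mismatch")
})

test_that("small-tip prediction matches a direct summation oracle", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- randomB1(g, roi, channels = 2L, seed = 4)
  k <- rbind(c(0, 0, 0), c(30, -20, 10))
  w <- matrix(complex(real = c(0.3, -0.1, 0.2, 0.5),
                      imaginary = c(0.1, 0.4, -0.3, 0.2)), 2, 2)
  pulse <- new("KTPointsPulse", weights = w, kLocations = k,
               subpulseDuration = 100, blips = realizeGradientBlips(k),
               targetFa = 10, method = "TP", meta = list(),
               version = "ptx-pulse-1")
  fa <- faArray(predictFaSta(maps, pulse))
  # independent re-implementation: explicit loop over voxels
  coords <- voxelCoordinates(g) / 1000
  B <- matrix(b1Data(maps), ncol = 2)
  idx <- sample(seq_len(nrow(coords)), 40)
  for (r in idx) {
    acc <- 0 + 0i
    for (kk in 1:2) for (cc in 1:2)
      acc <- acc + B[r, cc] * w[cc, kk] *
        exp(1i * sum(k[kk, ] * coords[r, ]))
    expect_equal(fa[r], 10 * Mod(acc), tolerance = 1e-12)
  }
})

test_that("the hard-pulse Bloch simulator reproduces exact rotations", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, roi)
  pulse <- new("KTPointsPulse",
               weights = matrix(1 + 0i, 1, 1),
               kLocations = matrix(0, 1, 3), subpulseDuration = 100,
               blips = list(), targetFa = 10, method = "TP",
               meta = list(), version = "ptx-pulse-1")
  fa <- blochSimulate(maps, pulse)
  # a single on-resonance rectangular pulse of nominal 10 degrees
  expect_equal(faArray(fa)[maskArray(roi)],
               rep(10, roiVoxelCount(roi)), tolerance = 1e-6)
})

test_that("Bloch and small-tip agree at 10 degrees and diverge at 90", {
  e <- studyEntry(17, 23)
  tp <- designTailored(e$b1, e$roi, fastCfg())
  sta <- faArray(predictFaSta(e$b1, tp))[maskArray(e$roi)]
  bloch <- faArray(blochSimulate(e$b1, tp))[maskArray(e$roi)]
  expect_lt(max(abs(sta - bloch) / sta), 0.01)

  # at a 90-degree nominal angle the small-tip model overestimates
  tp90 <- tp
  tp90@weights <- tp@weights * 9
  sta90 <- faArray(predictFaSta(e$b1, tp90))[maskArray(e$roi)]
  bloch90 <- faArray(blochSimulate(e$b1, tp90))[maskArray(e$roi)]
  expect_gt(mean(sta90 - bloch90), 0)
  expect_true(all(sta90 - bloch90 > -1e-6))
})

test_that("the CV statistic matches its definition and invariances", {
  g <- tinyGrid()
  # connected 51-voxel ROI (8x6 slab plus a 3-voxel tab) so the voxel count
  # is a multiple of 3
  mask <- array(FALSE, gridShape(g))
  mask[1:8, 1:6, 1] <- TRUE
  mask[1:3, 7, 1] <- TRUE
  roi <- new("ROIMask", grid = g, mask = mask)
  n <- roiVoxelCount(roi)
  expect_equal(n %% 3, 0)
  mk <- function(vals) {
    fa <- array(0, gridShape(g))
    fa[maskArray(roi)] <- vals
    new("FAMap", grid = g, fa = fa, provenance = list())
  }
  expect_equal(computeCv(mk(rep(10, n)), roi), 0)
  # repeating {8, 10, 12}: population SD sqrt(8/3), mean 10 -> 16.33%
  vals <- rep_len(c(8, 10, 12), n)
  expect_equal(computeCv(mk(vals), roi), 100 * sqrt(8 / 3) / 10,
               tolerance = 1e-12)
  expect_equal(computeCv(mk(vals * 3.7), roi), computeCv(mk(vals), roi),
               tolerance = 1e-12)
  expect_error(computeCv(mk(rep(0, n)), roi), "mean")
})

test_that("the FA distribution summary uses midpoint medians", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  n <- roiVoxelCount(roi)
  fa <- array(0, gridShape(g))
  fa[maskArray(roi)] <- rep(10, n)
  f <- new("FAMap", grid = g, fa = fa, provenance = list())
  d <- faDistribution(f, roi)
  expect_equal(d$median, 10)
  expect_equal(d$q75 - d$q25, 0)

  # explicit even-count midpoint rule
  expect_equal(median(c(6, 8, 10, 12)), 9)
})

test_that("RF metrics scale linearly in voltage and quadratically in power", {
  w <- matrix(complex(modulus = c(1, 2, 3, 4), argument = c(0, 1, 2, 3)),
              2, 2)
  pulse <- new("KTPointsPulse", weights = w,
               kLocations = rbind(c(0, 0, 0), c(10, 0, 0)),
               subpulseDuration = 100,
               blips = realizeGradientBlips(rbind(c(0, 0, 0), c(10, 0, 0))),
               targetFa = 10, method = "TP", meta = list(),
               version = "ptx-pulse-1")
  m <- rfMetrics(pulse)
  expect_equal(m@peak, 4)
  expect_equal(m@meanPower, mean(c(1, 4, 9, 16)))
  expect_equal(m@channelPower, c(mean(c(1, 9)), mean(c(4, 16))))
  pulse2 <- pulse
  pulse2@weights <- 2 * w
  m2 <- rfMetrics(pulse2)
  expect_equal(m2@peak, 2 * m@peak)
  expect_equal(m2@meanPower, 4 * m@meanPower)
})
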
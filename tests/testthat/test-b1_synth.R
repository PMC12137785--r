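test_that("coil map simulation is deterministic and obeys the 1/(d+d0) law", {
  sub <- sampleSubject(5)
  ses <- sampleSession(1, "A", 7, zeroVariability())
  g <- defaultGrid()
  m1 <- simulateCoilMaps(sub, g, ses)
  m2 <- simulateCoilMaps(sub, g, ses)
  expect_identical(b1Data(m1), b1Data(m2))

  # magnitude law: with no tissue attenuation and no texture, |b1| along a
  # ray from an element follows 1/(d + d0); at distances 100 and 200 mm with
  # d0 = 50 the ratio is 250/150
  subClean <- new("SubjectParams", torsoSemiAxes = c(95, 122, 130),
                  heartCenter = c(25, -25, 8), heartSemiAxes = c(46, 40, 38),
                  attenuation = 0, phaseOffsets = rep(0, 8),
                  sessionSensitivity = 1,
                  textureFreqs = matrix(0, 1, 3), texturePhases = 0,
                  textureWeights = matrix(0, 1, 8), textureAmp = 0,
                  seed = 1L)
  maps <- simulateCoilMaps(subClean, g, ses, d0 = 50)
  elems <- ptxRepro:::.coilElements(subClean@torsoSemiAxes, ses)
  coords <- voxelCoordinates(g)
  d <- sqrt(rowSums(sweep(coords, 2, elems[1, ], "-")^2))
  nearVox <- which.min(abs(d - 100))
  farVox <- which.min(abs(d - 200))
  mag <- Mod(matrix(b1Data(maps), ncol = 8)[, 1])
  expected <- (d[farVox] + 50) / (d[nearVox] + 50)
  expect_equal(mag[nearVox] / mag[farVox], expected, tolerance = 1e-10)
})

test_that("a coil translation perturbs the field inside the ROI", {
  sub <- sampleSubject(5)
  g <- defaultGrid()
  s0 <- sampleSession(1, "A", 7, zeroVariability())
  s1 <- s0
  s1@translation <- c(20, 0, 0)
  roi <- heartMask(sub, g, s0)
  m0 <- Mod(matrix(b1Data(simulateCoilMaps(sub, g, s0)), ncol = 8))
  m1 <- Mod(matrix(b1Data(simulateCoilMaps(sub, g, s1)), ncol = 8))
  idx <- which(maskArray(roi))
  expect_gt(max(abs(m1[idx, ] - m0[idx, ]) / m0[idx, ]), 0)
  expect_lt(cor(as.vector(m0[idx, ]), as.vector(m1[idx, ])), 1)
})

test_that("simulateCoilMaps rejects grids too small for the torso", {
  sub <- sampleSubject(5)
  ses <- sampleSession(1, "A", 7, zeroVariability())
  small <- GridSpec(c(8L, 40L, 40L), 8)  # x FOV 64 mm < torso
  expect_error(simulateCoilMaps(sub, small, ses), "axis x")
})

test_that("normalizeB1 divides by the ROI mean sum of magnitudes", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, channels = 2L, value = 1)  # sum of magnitudes = 2
  norm <- normalizeB1(maps, roi)
  expect_true(isNormalized(norm))
  expect_equal(mean(ptxRepro:::.roiSumOfMagnitudes(norm, roi)), 1,
               tolerance = 1e-12)
  expect_equal(Mod(b1Data(norm)[1, 1, 1, 1]), 0.5, tolerance = 1e-12)

  # direct arithmetic: ROI magnitudes cycling {1, 2, 3} -> divisor = their
  # mean (2 when the count is a multiple of 3)
  vals <- c(1, 2, 3)
  data <- array(0 + 0i, c(gridShape(g), 1L))
  ballIdx <- which(maskArray(roi))
  data[ballIdx] <- complex(real = rep_len(vals, length(ballIdx)))
  maps3 <- new("B1MapSet", grid = g, data = data, normalized = FALSE,
               meta = list())
  divisor <- mean(rep_len(vals, length(ballIdx)))
  norm3 <- normalizeB1(maps3, roi)
  expect_equal(Mod(b1Data(norm3)[ballIdx[1]]), vals[1] / divisor,
               tolerance = 1e-12)

  # idempotence
  norm2 <- normalizeB1(norm, roi)
  expect_equal(b1Data(norm2), b1Data(norm), tolerance = 1e-12)

  # empty ROI errors
  emptyRoi <- roi
  expect_error({
    emptyRoi@mask[] <- FALSE
    normalizeB1(maps, emptyRoi)
  })
})

test_that("cohorts are reproducible, complete and seed-disjoint", {
  v <- sessionVariability()
  c1 <- generateCohort(2, 2, masterSeed = 101, variability = v)
  c2 <- generateCohort(2, 2, masterSeed = 101, variability = v)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(b1Data(cohortEntry(c1, 2, 2)$b1),
                   b1Data(cohortEntry(c2, 2, 2)$b1))
  expect_equal(nrow(c1$manifest), 4L)

  lib <- generateCohort(3, 1, masterSeed = 101, variability = v,
                        cohort = "library")
  expect_length(intersect(lib$manifest$subjectSeed,
                          c1$manifest$subjectSeed), 0)
  expect_length(intersect(lib$manifest$sessionSeed,
                          c1$manifest$sessionSeed), 0)

  # default operator map mirrors the four-scan protocol
  c4 <- generateCohort(1, 4, masterSeed = 5)
  expect_equal(c4$manifest$operator, c("A", "B", "A", "C"))
})

test_that("zero-amplitude session variability makes sessions identical", {
  coh <- generateCohort(1, 3, masterSeed = 31,
                        variability = zeroVariability())
  e1 <- cohortEntry(coh, 1, 1)
  e2 <- cohortEntry(coh, 1, 2)
  e3 <- cohortEntry(coh, 1, 3)
  expect_identical(b1Data(e1$b1), b1Data(e2$b1))
  expect_identical(b1Data(e1$b1), b1Data(e3$b1))
  expect_identical(maskArray(e1$roi), maskArray(e3$roi))
})

test_that("session-to-session decorrelation grows with perturbation", {
  decorr <- function(amp) {
    v <- zeroVariability()
    v$perturbAmp <- amp
    out <- numeric(0)
    for (seed in 1:3) {
      coh <- generateCohort(1, 2, masterSeed = seed, variability = v)
      a <- cohortEntry(coh, 1, 1); b <- cohortEntry(coh, 1, 2)
      idx <- which(maskArray(a$roi))
      ma <- rowSums(Mod(matrix(b1Data(a$b1), ncol = 8)[idx, ]))
      mb <- rowSums(Mod(matrix(b1Data(b$b1), ncol = 8)[idx, ]))
      out <- c(out, 1 - cor(ma, mb))
    }
    mean(out)
  }
  expect_gte(decorr(0.25), decorr(0.05) - 1e-12)
  expect_gte(decorr(0.05), decorr(0) - 1e-12)
})

test_that("parameter objects enforce their physical invariants", {
  expect_error(GridSpec(c(4, 8, 8), 8), "shape")
  expect_error(new("SessionParams", translation = c(50, 0, 0), rotation = 0,
                   scale = 1, perturbAmp = 0, standoff = 25,
                   perturbFreqs = matrix(0, 1, 3), perturbPhases = 0,
                   perturbWeights = matrix(0, 1, 8),
                   channelGainLog = rep(0, 8), channelPhase = rep(0, 8),
                   operator = "A", seed = 1L),
               "translation")
  sub <- sampleSubject(1)
  expect_error({
    sub@heartSemiAxes <- sub@torsoSemiAxes  # heart as big as the torso
    validObject(sub)
  }, "inside")
})
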
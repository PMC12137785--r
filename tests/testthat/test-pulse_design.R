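test_that("the STA system matrix realizes the small-tip model", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, roi)
  cfg <- fastCfg(nKt = 1L)
  sys <- buildSystem(maps, roi, matrix(0, 1, 3), cfg)
  # uniform unit sensitivity at k = 0: |A w| = targetFa * |w| at every voxel
  expect_equal(Mod(sys@A %*% (1 + 0i)), matrix(cfg@targetFa, nrow(sys@A)),
               tolerance = 1e-12)

  # a nonzero k imposes the phase ramp exp(i k . dr) between voxels
  k2 <- rbind(c(0, 0, 0), 2 * pi / (gridFov(g) / 1000))
  sys2 <- buildSystem(maps, roi, k2, fastCfg(nKt = 2L))
  pos <- ptxRepro:::.roiPositions(g, roi)
  ratio <- sys2@A[2, 2] / sys2@A[1, 2]
  expect_equal(Arg(ratio),
               as.numeric((pos[2, ] - pos[1, ]) %*% k2[2, ]),
               tolerance = 1e-10)

  # two opposed channels driven equally cancel exactly
  data <- array(0 + 0i, c(gridShape(g), 2L))
  data[, , , 1] <- 1 + 0i
  data[, , , 2] <- -1 + 0i
  opp <- normalizeB1(new("B1MapSet", grid = g, data = data,
                         normalized = FALSE, meta = list()), roi)
  sysOpp <- buildSystem(opp, roi, matrix(0, 1, 3), cfg)
  expect_lt(max(Mod(sysOpp@A %*% c(1 + 0i, 1 + 0i))), 1e-12)

  # unnormalized maps are rejected with a pointer to normalizeB1
  expect_error(buildSystem(uniformB1(g), roi, matrix(0, 1, 3), cfg),
               "normalizeB1")
})

test_that("variable exchange solves the uniform case exactly and is monotone", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, roi)
  cfg <- fastCfg(nKt = 1L, lambda = 0)
  sys <- buildSystem(maps, roi, matrix(0, 1, 3), cfg)
  fit <- mlsVariableExchange(sys, cfg)
  expect_lt(fit$cost, 1e-10)
  expect_equal(Mod(fit$weights[1, 1]), 1, tolerance = 1e-8)

  # cost trace is non-increasing on random instances
  for (seed in 1:5) {
    maps2 <- randomB1(g, roi, channels = 2L, seed = seed)
    sys2 <- buildSystem(maps2, roi, rbind(c(0, 0, 0), c(20, 0, 0)),
                        fastCfg(nKt = 2L))
    tr <- mlsVariableExchange(sys2, fastCfg(nKt = 2L))$costTrace
    expect_true(all(diff(tr) <= 1e-12 * pmax(tr[-length(tr)], 1)))
  }
  expect_error(mlsVariableExchange(sys, fastCfg(lambda = -1)), "lambda")
})

test_that("variable exchange matches a brute-force scan on a 2-voxel toy", {
  # single channel, rows with magnitudes {1, 2}, target theta, lambda 0:
  # optimal real w minimizes (w - theta)^2 + (2w - theta)^2 -> w = 3 theta / 5
  theta <- 10
  A <- matrix(c(1 + 0i, 2 + 0i), 2, 1)
  sys <- new("STASystem", A = A, c0 = theta, channels = 1L,
             kLocations = matrix(0, 1, 3))
  cfg <- fastCfg(nKt = 1L, lambda = 0, targetFa = theta)
  fit <- mlsVariableExchange(sys, cfg, init = 0.1 + 0i)
  ws <- seq(0, theta, length.out = 20001)
  bruteCost <- vapply(ws, function(w)
    sum((abs(A * w) - theta)^2), numeric(1))
  wBrute <- ws[which.min(bruteCost)]
  expect_equal(wBrute, 3 * theta / 5, tolerance = 1e-3)
  expect_equal(Mod(fit$weights[1, 1]), 3 * theta / 5, tolerance = 1e-6)
  expect_equal(fit$cost, min(bruteCost), tolerance = 1e-6)
})

test_that("greedy kT-point selection nests and handles the uniform case", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  maps <- uniformB1(g, roi)
  cfg <- fastCfg(nKt = 1L, ktExtent = 1, lambda = 0)
  k1 <- greedyKtSelection(maps, roi, cfg)
  expect_equal(as.numeric(k1), c(0, 0, 0))  # ties broken smallest-norm first
  expect_lt(attr(k1, "costs")[1], 1e-10)

  maps2 <- randomB1(g, roi, channels = 2L, seed = 3)
  cfg4 <- fastCfg(nKt = 4L, ktExtent = 1)
  k4 <- greedyKtSelection(maps2, roi, cfg4)
  costs <- attr(k4, "costs")
  expect_true(all(diff(costs) <= 1e-12 * pmax(costs[-length(costs)], 1)))
})

test_that("greedy K=2 matches exhaustive pair search on 2-channel toys", {
  g <- tinyGrid()
  roi <- ballRoi(g)
  cfg <- DesignConfig(nKt = 2L, maxIter = 300L, scanIter = 300L)
  # 4^3 candidate grid containing k = 0, enumerated smallest-norm first
  cyc <- as.matrix(expand.grid(kx = -1:2, ky = -1:2, kz = -1:2))
  cyc <- cyc[order(rowSums(cyc^2), cyc[, 3], cyc[, 2], cyc[, 1]), ]
  cand <- sweep(cyc, 2, 2 * pi / (gridFov(g) / 1000), "*")
  expect_equal(nrow(cand), 64L)
  for (seed in c(2, 9)) {
    maps <- randomB1(g, roi, channels = 2L, seed = seed)
    sel <- greedyKtSelection(maps, roi, cfg, candidates = cand)
    # exhaustive oracle: all unordered candidate pairs, full re-solve
    best <- NULL; bestCost <- Inf
    for (i in seq_len(nrow(cand) - 1)) for (j in (i + 1):nrow(cand)) {
      sys <- buildSystem(maps, roi, cand[c(i, j), ], cfg)
      cost <- mlsVariableExchange(sys, cfg)$cost
      if (cost < bestCost - 1e-10) {
        bestCost <- cost
        best <- cand[c(i, j), ]
      }
    }
    # the MLS cost only sees relative k-space displacements (a global
    # shift multiplies the excitation by a unit phase), so compare the
    # selected pair by its displacement class and its cost
    dSel <- abs(sel[2, ] - sel[1, ])
    dBest <- abs(best[2, ] - best[1, ])
    expect_equal(unname(sort(dSel)), unname(sort(dBest)),
                 tolerance = 1e-9)
    cSel <- mlsVariableExchange(buildSystem(maps, roi, sel, cfg), cfg)$cost
    expect_equal(cSel, bestCost, tolerance = 1e-5)
  }
})

test_that("tailored design beats the default shim on its own session", {
  e <- studyEntry(11, 22)
  cfg <- fastCfg()
  tp <- designTailored(e$b1, e$roi, cfg)
  def <- defaultShim(cfg, e)
  cvTp <- computeCv(predictFaSta(e$b1, tp), e$roi)
  cvDef <- computeCv(predictFaSta(e$b1, def), e$roi)
  expect_lt(cvTp, cvDef)
  # dynamic homogenization costs peak voltage (sign only)
  expect_gt(rfMetrics(tp)@peak, rfMetrics(def)@peak)
  expect_gt(min(faArray(predictFaSta(e$b1, tp))[maskArray(e$roi)]),
            min(faArray(predictFaSta(e$b1, def))[maskArray(e$roi)]))

  # byte-identical reproduction
  tp2 <- designTailored(e$b1, e$roi, cfg)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writePulse(tp, f1); writePulse(tp2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("universal design degenerates to tailored on an identical library", {
  e <- studyEntry(13, 29)
  cfg <- fastCfg()
  tp <- designTailored(e$b1, e$roi, cfg)
  up <- designUniversal(list(e, e, e), cfg)
  cvTp <- computeCv(predictFaSta(e$b1, tp), e$roi)
  cvUp <- computeCv(predictFaSta(e$b1, up), e$roi)
  expect_equal(cvUp, cvTp, tolerance = 1e-3)

  # the tailored pulse optimizes the individual objective
  e2 <- studyEntry(14, 31)
  up2 <- designUniversal(list(e, e2), cfg)
  for (m in list(e, e2)) {
    tpm <- designTailored(m$b1, m$roi, cfg)
    expect_gte(computeCv(predictFaSta(m$b1, up2), m$roi),
               computeCv(predictFaSta(m$b1, tpm), m$roi) - 1e-9)
  }

  expect_error(designUniversal(list(e), cfg), "at least 2")
  eBad <- e
  eBad$b1@data <- e$b1@data[, , , 1:4, drop = FALSE]
  expect_error(designUniversal(list(e, eBad), cfg), "channel")
})

test_that("the default shim is phase-only and frozen", {
  e <- studyEntry(11, 22)
  def <- defaultShim(fastCfg(), e)
  mags <- Mod(pulseWeights(def))
  expect_lt(diff(range(mags)), 1e-9 * max(mags))
  expect_equal(ncol(pulseWeights(def)), 1L)
  expect_equal(as.numeric(pulseKLocations(def)), c(0, 0, 0))
  # mean ROI FA hits the target on the reference
  expect_equal(mean(faArray(predictFaSta(e$b1, def))[maskArray(e$roi)]),
               10, tolerance = 1e-6)
  # applying elsewhere does not mutate the pulse
  e2 <- studyEntry(14, 31)
  invisible(predictFaSta(e2$b1, def))
  def2 <- defaultShim(fastCfg(), e)
  expect_identical(pulseWeights(def), pulseWeights(def2))
})

test_that("gradient blips reproduce the k-space displacements", {
  # zero displacement: no blip needed
  expect_equal(realizeGradientBlips(rbind(c(0, 0, 0), c(0, 0, 0)))[[1]]$
                 duration_us, 0)

  # derived example: 2 cycles over 0.25 m at slew 170 T/m/s, checked by
  # numeric integration of the triangular waveform
  dk <- 2 * 2 * pi / 0.25
  bl <- realizeGradientBlips(rbind(c(0, 0, 0), c(dk, 0, 0)),
                             maxSlew = 170)[[1]]
  gamma <- 2 * pi * 42.577478518e6
  amp <- bl$amplitude_mT_m[1] * 1e-3
  rampS <- bl$ramp_us[1] * 1e-6
  flatS <- bl$flat_us[1] * 1e-6
  tt <- seq(0, 2 * rampS + flatS, length.out = 100001)
  wave <- ifelse(tt < rampS, amp * tt / rampS,
                 ifelse(tt < rampS + flatS, amp,
                        amp * (2 * rampS + flatS - tt) / rampS))
  area <- sum((wave[-1] + wave[-length(wave)]) / 2 * diff(tt))
  expect_equal(gamma * area, dk, tolerance = 1e-4)
  # closed-form area identity used by the validity check
  expect_equal(gamma * amp * (rampS + flatS), dk, tolerance = 1e-9)
  # durations on the 10 us raster
  expect_equal(bl$ramp_us[1] %% 10, 0)
  expect_lte(abs(amp) * 1e3, 40)
  expect_lte(amp / rampS, 170 * (1 + 1e-9))

  # amplitude-limited displacement becomes a trapezoid
  big <- 40 * 2 * pi / 0.25
  bl2 <- realizeGradientBlips(rbind(c(0, 0, 0), c(0, 0, big)),
                              maxGrad = 10, maxSlew = 170)[[1]]
  expect_gt(bl2$flat_us[3], 0)
  expect_equal(gamma * bl2$amplitude_mT_m[3] * 1e-3 *
                 (bl2$ramp_us[3] + bl2$flat_us[3]) * 1e-6, big,
               tolerance = 1e-6)

  # unreachable within a duration budget
  expect_error(realizeGradientBlips(rbind(c(0, 0, 0), c(big, 0, 0)),
                                    maxGrad = 5, maxDuration = 100),
               "requires")
})

test_that("designs are invariant to the raw B1 scale", {
  e <- studyEntry(11, 22)
  cfg <- fastCfg()
  scaled <- e$b1
  scaled@data <- scaled@data * 7.3
  scaled@normalized <- FALSE
  scaled <- normalizeB1(scaled, e$roi)
  tp1 <- designTailored(e$b1, e$roi, cfg)
  tp2 <- designTailored(scaled, e$roi, cfg)
  fa1 <- faArray(predictFaSta(e$b1, tp1))
  fa2 <- faArray(predictFaSta(scaled, tp2))
  expect_equal(fa1, fa2, tolerance = 1e-9)
})
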
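# Small in-code fixtures shared across tests. Everything is generated at
# test time; nothing is read from disk.

# minimal grid (smallest legal shape)
tinyGrid <- function(n = 8L, spacing = 10) GridSpec(rep(n, 3), spacing)

# uniform single-channel map set: b1 == value everywhere, pre-normalized
# against the given ROI (so the ROI mean sum of magnitudes is 1)
uniformB1 <- function(grid, roi = NULL, channels = 1L, value = 1) {
  data <- array(complex(real = value, imaginary = 0),
                c(gridShape(grid), channels))
  maps <- new("B1MapSet", grid = grid, data = data, normalized = FALSE,
              meta = list())
  if (!is.null(roi)) maps <- normalizeB1(maps, roi) else maps
}

# ball ROI in the grid center with >= 50 voxels
ballRoi <- function(grid, radiusVox = 2.5) {
  shp <- gridShape(grid)
  coords <- voxelCoordinates(grid)
  r <- sqrt(rowSums(coords^2))
  mask <- array(r <= radiusVox * max(gridSpacing(grid)), shp)
  new("ROIMask", grid = grid, mask = mask)
}

# random multi-channel map set with smooth spatial structure (deterministic
# given seed), normalized on the given ROI
randomB1 <- function(grid, roi, channels = 2L, seed = 1) {
  coords <- voxelCoordinates(grid) / max(gridFov(grid))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data <- array(0 + 0i, c(gridShape(grid), channels))
  for (cc in seq_len(channels)) {
    f <- matrix(rnorm(9), 3, 3)
    ph <- coords %*% f[, 1] * 4 + rnorm(1)
    mag <- 1 + 0.5 * cos(coords %*% f[, 2] * 5 + rnorm(1))
    data[, , , cc] <- complex(modulus = as.vector(mag),
                              argument = as.vector(ph))
  }
  maps <- new("B1MapSet", grid = grid, data = data, normalized = FALSE,
              meta = list())
  normalizeB1(maps, roi)
}

# one normalized cohort entry on the default study grid
studyEntry <- function(subjectSeed = 11, sessionSeed = 22,
                       variability = sessionVariability(),
                       sessionIndex = 1, operator = "A") {
  sub <- sampleSubject(subjectSeed)
  ses <- sampleSession(sessionIndex, operator, sessionSeed, variability,
                       sensitivity = 1)
  g <- defaultGrid()
  roi <- heartMask(sub, g, ses)
  maps <- normalizeB1(simulateCoilMaps(sub, g, ses), roi)
  list(b1 = maps, roi = roi, subject = sub, session = ses)
}

# fast design configuration for small tests
fastCfg <- function(...) DesignConfig(maxIter = 100L, scanIter = 60L, ...)

# independent signed-rank enumeration oracle: all 2^n sign assignments via
# expand.grid (deliberately different machinery from the implementation)
enumSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
}
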
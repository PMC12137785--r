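## kT-points pulse design: magnitude least squares (MLS) in the small-tip
## regime, solved by variable exchange, with transmit k-space locations
## chosen by an interleaved greedy/local scheme over a small candidate grid.

#' Candidate transmit k-space grid
#'
#' Regular grid of candidate kT-point locations in cycles/FOV per axis,
#' converted to rad/m, enumerated smallest-norm first with lexicographic
#' (kz, ky, kx) tie-breaking. The grid always contains k = 0.
#'
#' @param grid A [GridSpec-class] (supplies the FOV).
#' @param cfg A [DesignConfig-class].
#' @return numeric matrix (nCandidates x 3), rad/m, with attribute
#'   `"cycles"` holding the integer grid.
#' @export
candidateKGrid <- function(grid, cfg = DesignConfig()) {
  cyc <- seq(-cfg@ktExtent, cfg@ktExtent, by = cfg@ktStep)
  if (!any(abs(cyc) < 1e-12))
    stop("candidate grid must contain k = 0")
  g <- as.matrix(expand.grid(kx = cyc, ky = cyc, kz = cyc))
  ord <- order(rowSums(g^2), g[, 3], g[, 2], g[, 1])
  g <- g[ord, , drop = FALSE]
  fov <- gridFov(grid) / 1000  # m
  k <- sweep(g, 2, 2 * pi / fov, "*")
  attr(k, "cycles") <- g
  k
}

#' Build the small-tip-angle system matrix
#'
#' Rows are ROI voxels (in column-major mask order); entry (r, (c,k)) is
#' c0 * b1_c(r) * exp(i k_k . r) with positions at voxel centers in meters.
#' c0 is chosen so that unit total drive at a voxel where the sum of channel
#' magnitudes is 1 yields the target flip angle, i.e. c0 = targetFa.
#'
#' @param maps A normalized [B1MapSet-class].
#' @param roi A [ROIMask-class] on the same grid.
#' @param kLocations numeric matrix (K x 3), rad/m.
#' @param cfg A [DesignConfig-class].
#' @return An [STASystem-class].
#' @export
buildSystem <- function(maps, roi, kLocations, cfg = DesignConfig()) {
  if (!maps@normalized)
    stop("maps are not normalized; run normalizeB1() first")
  if (!all(roi@grid@shape == maps@grid@shape))
    stop("maps and roi must share one grid")
  kLocations <- matrix(as.numeric(kLocations), ncol = 3)
  B <- cfg@targetFa * .roiB1Matrix(maps, roi)
  pos <- .roiPositions(maps@grid, roi)
  A <- cpp_sta_matrix(B, pos, kLocations)
  new("STASystem", A = A, c0 = cfg@targetFa,
      channels = channelCount(maps), kLocations = kLocations)
}

## deterministic initialization: per-channel phase matching of the column
## sums (a default-shim-like start), scaled to hit the mean target
.initWeights <- function(sys, cfg) {
  C <- sys@channels
  K <- nrow(sys@kLocations)
  colsum <- colSums(sys@A[, seq_len(C), drop = FALSE])
  u <- exp(-1i * Arg(colsum))
  w <- matrix(0 + 0i, C, K)
  w[, 1] <- u
  z <- abs(sys@A[, seq_len(C), drop = FALSE] %*% u)
  mz <- mean(z)
  if (mz > 0) w <- w * (cfg@targetFa / mz)
  as.vector(w)
}

#' Magnitude-least-squares variable exchange
#'
#' Minimizes sum_r (|A_r w| - theta)^2 + lambda ||w||^2 by alternating a
#' phase update (target phases set to arg(A w)) with a regularized linear
#' least-squares solve. The recorded MLS cost trace is non-increasing.
#'
#' @param sys An [STASystem-class].
#' @param cfg A [DesignConfig-class] (theta = `targetFa`, lambda, tol,
#'   maxIter).
#' @param init optional complex initial weights (C x K matrix or C*K
#'   vector); default is a phase-matched shim scaled to the mean target.
#' @return list with `weights` (complex C x K), `costTrace`, `cost`.
#' @export
mlsVariableExchange <- function(sys, cfg = DesignConfig(), init = NULL) {
  if (nrow(sys@A) == 0L) stop("system matrix has no rows (empty ROI)")
  if (cfg@lambda < 0) stop("lambda must be >= 0")
  K <- nrow(sys@kLocations)
  if (is.null(init)) init <- .initWeights(sys, cfg)
  init <- as.complex(as.vector(init))
  if (length(init) != sys@channels * K)
    stop("init must have C*K entries")
  r <- cpp_mls_ve(sys@A, cfg@targetFa, cfg@lambda, init, cfg@tol,
                  cfg@maxIter)
  list(weights = matrix(r$weights, sys@channels, K),
       costTrace = as.numeric(r$costTrace), cost = r$cost)
}

## normalize design inputs to parallel lists of maps and rois
.asDesignList <- function(maps, rois) {
  if (is(maps, "B1MapSet")) {
    maps <- list(maps)
    rois <- list(rois)
  }
  stopifnot(length(maps) == length(rois))
  for (i in seq_along(maps)) {
    if (!maps[[i]]@normalized)
      stop("maps are not normalized; run normalizeB1() first")
  }
  C <- vapply(maps, channelCount, integer(1))
  if (length(unique(C)) != 1L)
    stop("all map sets must have the same channel count")
  list(maps = maps, rois = rois)
}

#' Interleaved greedy/local selection of kT-point locations
#'
#' Starting from the best single candidate, repeatedly (greedy) adds the
#' candidate k-space location that minimizes the MLS cost after re-solving
#' the weights, then (local) re-solves the weights over all current
#' locations, until `nKt` points are selected. Deterministic: ties are
#' broken by the candidate enumeration order (smallest-norm first,
#' lexicographic (kz, ky, kx)). Accepts a single map set (tailored design)
#' or lists of map sets and ROIs (universal design over a library, rows
#' stacked with equal weighting per the plain summed cost).
#'
#' @param maps A [B1MapSet-class] or list thereof (normalized).
#' @param rois A [ROIMask-class] or list matching `maps`.
#' @param cfg A [DesignConfig-class].
#' @param candidates optional explicit candidate matrix (n x 3, rad/m) in
#'   enumeration order, overriding the regular grid from
#'   [candidateKGrid()].
#' @return numeric matrix (nKt x 3) of selected locations, rad/m, with
#'   attributes `"costs"` (cost after each addition) and `"weights"` (final
#'   local-solve weights).
#' @export
greedyKtSelection <- function(maps, rois, cfg = DesignConfig(),
                              candidates = NULL) {
  dl <- .asDesignList(maps, rois)
  grid <- dl$maps[[1]]@grid
  cand <- if (is.null(candidates)) candidateKGrid(grid, cfg) else
    matrix(as.numeric(candidates), ncol = 3)
  if (nrow(cand) == 0L) stop("candidate grid is empty")
  C <- channelCount(dl$maps[[1]])
  B <- do.call(rbind, lapply(seq_along(dl$maps), function(i)
    cfg@targetFa * .roiB1Matrix(dl$maps[[i]], dl$rois[[i]])))
  pos <- do.call(rbind, lapply(seq_along(dl$maps), function(i)
    .roiPositions(grid, dl$rois[[i]])))
  E <- exp(1i * (pos %*% t(cand)))
  selected <- integer(0)
  Abase <- matrix(0 + 0i, nrow(B), 0)
  wbase <- complex(0)
  stepCosts <- numeric(0)
  for (step in seq_len(cfg@nKt)) {
    avail <- setdiff(seq_len(nrow(cand)), selected)
    costs <- cpp_greedy_scan(Abase, B, E[, avail, drop = FALSE],
                             cfg@targetFa, cfg@lambda, wbase, cfg@tol,
                             cfg@scanIter)
    ## first candidate within numerical noise of the minimum: realizes the
    ## enumeration-order tie-break under floating-point round-off
    cmin <- min(costs)
    j <- avail[which(costs <= cmin + 1e-9 * max(cmin, 1e-12))[1]]
    selected <- c(selected, j)
    Abase <- cbind(Abase, B * as.vector(E[, j]))
    loc <- cpp_mls_ve(Abase, cfg@targetFa, cfg@lambda,
                      c(wbase, rep(0 + 0i, C)), cfg@tol, cfg@scanIter)
    wbase <- loc$weights
    stepCosts <- c(stepCosts, loc$cost)
  }
  k <- cand[selected, , drop = FALSE]
  if (!is.null(attr(cand, "cycles")))
    attr(k, "cycles") <- attr(cand, "cycles")[selected, , drop = FALSE]
  attr(k, "costs") <- stepCosts
  attr(k, "weights") <- matrix(wbase, C, cfg@nKt)
  k
}

.makePulse <- function(weights, kLocations, cfg, method, meta) {
  blips <- realizeGradientBlips(kLocations, maxGrad = cfg@maxGrad,
                                maxSlew = cfg@maxSlew, raster = cfg@raster)
  new("KTPointsPulse", weights = weights,
      kLocations = matrix(as.numeric(kLocations), ncol = 3),
      subpulseDuration = 100, blips = blips, targetFa = cfg@targetFa,
      method = method,
      meta = c(meta, list(lambda = cfg@lambda, seed = cfg@seed)),
      version = "ptx-pulse-1")
}

#' Design a subject-tailored kT-points pulse
#'
#' Greedy/local kT-point selection followed by a final variable-exchange
#' solve on this subject/session's maps only.
#'
#' @param maps A normalized [B1MapSet-class].
#' @param roi A [ROIMask-class].
#' @param cfg A [DesignConfig-class].
#' @return A [KTPointsPulse-class] with method `"TP"`.
#' @export
designTailored <- function(maps, roi, cfg = DesignConfig()) {
  k <- greedyKtSelection(maps, roi, cfg)
  sys <- buildSystem(maps, roi, k, cfg)
  fit <- mlsVariableExchange(sys, cfg, init = attr(k, "weights"))
  .makePulse(fit$weights, k, cfg, "TP",
             list(source = maps@meta[c("subject", "session")],
                  cost = fit$cost))
}

#' Design a universal kT-points pulse over a library
#'
#' One shared set of weights and k-space locations minimizing the summed MLS
#' cost over all library members (equal weighting of the stacked voxels).
#'
#' @param library list of `list(b1 = B1MapSet, roi = ROIMask)` entries, or a
#'   cohort from [generateCohort()].
#' @param cfg A [DesignConfig-class].
#' @return A [KTPointsPulse-class] with method `"UP"`.
#' @export
designUniversal <- function(library, cfg = DesignConfig()) {
  entries <- .libraryEntries(library)
  if (length(entries) < 2L)
    stop("a universal design needs at least 2 library entries")
  maps <- lapply(entries, `[[`, "b1")
  rois <- lapply(entries, `[[`, "roi")
  k <- greedyKtSelection(maps, rois, cfg)
  dl <- .asDesignList(maps, rois)
  A <- do.call(rbind, lapply(seq_along(maps), function(i)
    buildSystem(maps[[i]], rois[[i]], k, cfg)@A))
  sys <- new("STASystem", A = A, c0 = cfg@targetFa,
             channels = channelCount(maps[[1]]), kLocations = k)
  fit <- mlsVariableExchange(sys, cfg, init = attr(k, "weights"))
  .makePulse(fit$weights, k, cfg, "UP",
             list(source = list(library = length(entries)),
                  cost = fit$cost))
}

.libraryEntries <- function(library) {
  if (inherits(library, "ptxCohort")) {
    idx <- seq_len(nrow(library$manifest))
    return(lapply(idx, function(i)
      cohortEntry(library, library$manifest$subject[i],
                  library$manifest$session[i])))
  }
  library
}

#' Default phase-only RF shim
#'
#' Static shim with equal channel magnitudes, emulating a vendor-supplied
#' setting: the phases are optimized once by phase-only magnitude least
#' squares on a designated reference map set and then frozen. By default the
#' reference is the fixed vendor calibration model from
#' [vendorReference()], so the shim is one configuration across all studies;
#' any map set (e.g. a library member) can be designated instead. The common
#' magnitude is scaled so that the mean ROI flip angle equals the target on
#' the reference.
#'
#' @param cfg A [DesignConfig-class].
#' @param reference `list(b1 = B1MapSet, roi = ROIMask)` (the designated
#'   reference).
#' @return A [KTPointsPulse-class] with method `"default"`, K = 1, k = 0.
#' @export
defaultShim <- function(cfg = DesignConfig(), reference) {
  sys <- buildSystem(reference$b1, reference$roi,
                     matrix(0, 1, 3), cfg)
  A <- sys@A
  C <- sys@channels
  theta <- cfg@targetFa
  u <- exp(-1i * Arg(colSums(A)))
  AhA <- Conj(t(A)) %*% A + cfg@lambda * diag(C)
  for (it in seq_len(cfg@maxIter)) {
    z <- A %*% u
    b <- theta * exp(1i * Arg(z))
    wls <- solve(AhA, Conj(t(A)) %*% b)
    uNew <- exp(1i * Arg(wls))
    if (max(Mod(uNew - u)) < cfg@tol) {
      u <- uNew
      break
    }
    u <- uNew
  }
  v <- theta / mean(Mod(A %*% u))
  w <- matrix(v * u, C, 1)
  new("KTPointsPulse", weights = w, kLocations = matrix(0, 1, 3),
      subpulseDuration = 100, blips = list(), targetFa = theta,
      method = "default",
      meta = list(source = list(reference = "designated"),
                  lambda = cfg@lambda, seed = cfg@seed),
      version = "ptx-pulse-1")
}

#' Fixed vendor calibration reference
#'
#' The body model the vendor's default phase-only shim was set up on: a
#' fixed median-anatomy subject with the coil in its nominal position. It is
#' independent of any study seed, so the default shim is one configuration
#' across all studies.
#'
#' @param grid A [GridSpec-class].
#' @return `list(b1 = B1MapSet, roi = ROIMask)`.
#' @export
vendorReference <- function(grid = defaultGrid()) {
  subject <- sampleSubject(20210101L, cohort = "library")
  session <- sampleSession(1, "A", 1L, zeroVariability())
  roi <- heartMask(subject, grid, session)
  b1 <- normalizeB1(simulateCoilMaps(subject, grid, session), roi)
  list(b1 = b1, roi = roi)
}

#' Realize gradient blips between kT-points
#'
#' For each consecutive k-space displacement, per-axis triangular (or
#' trapezoidal when amplitude-limited) gradient blips whose area
#' gamma * integral(G dt) reproduces the displacement within 1e-6 rad/m.
#' Ramp and plateau durations are rounded up to the raster.
#'
#' @param kLocations numeric matrix (K x 3), rad/m.
#' @param maxGrad numeric, mT/m.
#' @param maxSlew numeric, T/m/s.
#' @param raster numeric, microseconds.
#' @param maxDuration numeric, microseconds; displacements needing longer
#'   blips raise an error stating the required duration.
#' @return list of K-1 blips: each `list(amplitude_mT_m, ramp_us, flat_us,
#'   duration_us)` with per-axis vectors and the gap duration (max over
#'   axes).
#' @examples
#' k <- rbind(c(0, 0, 0), c(50.27, 0, 0))
#' realizeGradientBlips(k)
#' @export
realizeGradientBlips <- function(kLocations, maxGrad = 40, maxSlew = 170,
                                 raster = 10, maxDuration = Inf) {
  kLocations <- matrix(as.numeric(kLocations), ncol = 3)
  K <- nrow(kLocations)
  if (K < 2L) return(list())
  Gmax <- maxGrad * 1e-3           # T/m
  rasterS <- raster * 1e-6         # s
  blips <- vector("list", K - 1L)
  for (j in seq_len(K - 1L)) {
    dk <- kLocations[j + 1L, ] - kLocations[j, ]
    amp <- numeric(3); rampUs <- numeric(3); flatUs <- numeric(3)
    for (ax in 1:3) {
      if (abs(dk[ax]) < 1e-12) next
      area <- abs(dk[ax]) / .gammaRad  # T s / m
      tauTri <- sqrt(area / maxSlew)
      if (maxSlew * tauTri <= Gmax) {
        ramp <- ceiling(tauTri / rasterS - 1e-12) * rasterS
        flat <- 0
      } else {
        ramp <- ceiling((Gmax / maxSlew) / rasterS - 1e-12) * rasterS
        flat <- max(0, area / Gmax - ramp)
        flat <- ceiling(flat / rasterS - 1e-12) * rasterS
      }
      g <- area / (ramp + flat)
      amp[ax] <- sign(dk[ax]) * g * 1e3  # mT/m
      rampUs[ax] <- ramp * 1e6
      flatUs[ax] <- flat * 1e6
    }
    dur <- max(2 * rampUs + flatUs)
    if (dur > maxDuration)
      stop(sprintf(
        "k-space displacement in gap %d unreachable within %g us; requires %g us",
        j, maxDuration, dur))
    blips[[j]] <- list(amplitude_mT_m = amp, ramp_us = rampUs,
                       flat_us = flatUs, duration_us = dur)
  }
  blips
}
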
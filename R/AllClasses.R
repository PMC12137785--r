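## Central S4 containers. All spatial objects share a GridSpec; pulses and
## field maps are deliberately plain (dense arrays) — the grids used here are
## desk-scale (tens of thousands of voxels).

#' Regular 3D sampling grid
#'
#' Isocenter-referenced regular grid: the grid center maps to (0, 0, 0) mm.
#'
#' @slot shape integer(3), voxels per axis (each >= 8).
#' @slot spacing numeric(3), voxel spacing in mm (each > 0).
#' @slot origin numeric(3), mm coordinates of the center of voxel (1, 1, 1).
#' @export
setClass("GridSpec", representation(
  shape = "integer", spacing = "numeric", origin = "numeric"
))

setValidity("GridSpec", function(object) {
  msg <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be 3 integers, all >= 8")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have 3 components (mm)")
  ctr <- object@origin + (object@shape - 1) / 2 * object@spacing
  if (length(msg) == 0L && any(abs(ctr) > 1e-6))
    msg <- c(msg, "grid must be isocenter-referenced (center at 0 mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param shape integer(3) voxels per axis.
#' @param spacing numeric voxel spacing in mm (scalar or length 3).
#' @return A [GridSpec-class] object centered on the isocenter.
#' @examples
#' g <- GridSpec(c(32L, 40L, 40L), 8)
#' gridFov(g)  # mm
#' @export
GridSpec <- function(shape, spacing) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- -(shape - 1) / 2 * spacing
  new("GridSpec", shape = shape, spacing = spacing, origin = origin)
}

#' Default study grid
#'
#' 32 x 40 x 40 voxels at 8 mm isotropic: a desk-scale stand-in for a torso
#' field of view of 256 x 320 x 320 mm.
#' @return A [GridSpec-class].
#' @export
defaultGrid <- function() GridSpec(c(32L, 40L, 40L), 8)

#' @rdname GridSpec
#' @param grid A [GridSpec-class].
#' @export
gridShape <- function(grid) grid@shape

#' @rdname GridSpec
#' @export
gridSpacing <- function(grid) grid@spacing

#' Field of view of a grid in mm
#' @param grid A [GridSpec-class].
#' @export
gridFov <- function(grid) grid@shape * grid@spacing

#' Voxel center coordinates
#'
#' @param grid A [GridSpec-class].
#' @return numeric matrix (nvox x 3) of mm coordinates, rows in column-major
#'   array order (x fastest).
#' @export
voxelCoordinates <- function(grid) {
  ax <- lapply(1:3, function(i)
    grid@origin[i] + (seq_len(grid@shape[i]) - 1) * grid@spacing[i])
  cbind(
    x = rep(ax[[1]], times = grid@shape[2] * grid@shape[3]),
    y = rep(rep(ax[[2]], each = grid@shape[1]), times = grid@shape[3]),
    z = rep(ax[[3]], each = grid@shape[1] * grid@shape[2])
  )
}

#' @export
setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels @ %s mm (FOV %s mm)\n",
              paste(object@shape, collapse = "x"),
              paste(signif(object@spacing, 3), collapse = "x"),
              paste(signif(gridFov(object), 4), collapse = "x")))
})

#' Multi-channel complex transmit sensitivity maps
#'
#' Per-channel complex B1+ sensitivities on a regular grid, in arbitrary
#' relative units until normalized to the heart-ROI mean sum of magnitudes
#' (see [normalizeB1()]).
#'
#' @slot grid [GridSpec-class].
#' @slot data complex array (Nx, Ny, Nz, C).
#' @slot normalized logical flag.
#' @slot meta list (subject/session/operator ids, seeds).
#' @export
setClass("B1MapSet", representation(
  grid = "GridSpec", data = "array", normalized = "logical", meta = "list"
))

setValidity("B1MapSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (Nx, Ny, Nz, C)")
  if (!all(d[1:3] == object@grid@shape))
    return("data dims do not match grid shape")
  if (!is.complex(object@data)) return("data must be complex")
  if (anyNA(object@data) || any(!is.finite(Mod(object@data))))
    return("data must be finite everywhere")
  TRUE
})

#' @rdname B1MapSet-class
#' @param object A `B1MapSet`.
#' @export
channelCount <- function(object) dim(object@data)[4]

#' @rdname B1MapSet-class
#' @export
b1Data <- function(object) object@data

#' @rdname B1MapSet-class
#' @export
isNormalized <- function(object) object@normalized

#' @rdname B1MapSet-class
#' @export
b1Grid <- function(object) object@grid

setMethod("show", "B1MapSet", function(object) {
  cat(sprintf("B1MapSet: %d channels on %s grid, %snormalized\n",
              channelCount(object),
              paste(object@grid@shape, collapse = "x"),
              if (object@normalized) "" else "not "))
})

#' Binary region-of-interest mask
#'
#' Heart ROI on the same grid as the B1+ maps. The mask must be a single
#' 6-connected component of at least 50 voxels.
#'
#' @slot grid [GridSpec-class].
#' @slot mask logical array (Nx, Ny, Nz).
#' @export
setClass("ROIMask", representation(grid = "GridSpec", mask = "array"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!all(dim(object@mask) == object@grid@shape))
    return("mask dims do not match grid shape")
  n <- sum(object@mask)
  if (n < 50L) return(sprintf("ROI has %d voxels; at least 50 required", n))
  if (!.roiConnected(object@mask))
    return("ROI must be a single 6-connected component")
  TRUE
})

#' @rdname ROIMask-class
#' @param object A `ROIMask`.
#' @export
roiVoxelCount <- function(object) sum(object@mask)

#' @rdname ROIMask-class
#' @export
maskArray <- function(object) object@mask

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d voxels on %s grid\n", sum(object@mask),
              paste(object@grid@shape, collapse = "x")))
})

## single 6-connected component check (BFS over the masked voxels)
.roiConnected <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  d <- dim(mask)
  seen <- array(FALSE, d)
  queue <- idx[1]
  seen[queue] <- TRUE
  strides <- c(1L, d[1], d[1] * d[2])
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    ci <- arrayInd(cur, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      ni <- ci
      ni[, ax] <- ni[, ax] + s
      ok <- ni[, ax] >= 1L & ni[, ax] <= d[ax]
      if (!any(ok)) next
      lin <- (ni[ok, 1] - 1L) + (ni[ok, 2] - 1L) * strides[2] +
        (ni[ok, 3] - 1L) * strides[3] + 1L
      keep <- lin[mask[lin] & !seen[lin]]
      if (length(keep)) {
        seen[keep] <- TRUE
        queue <- c(queue, keep)
      }
    }
    queue <- unique(queue)
  }
  sum(seen) == length(idx)
}

#' Subject anatomy parameters
#'
#' Torso and heart are coaxial ellipsoids; the heart must lie strictly inside
#' the torso. Attenuation is an exponential tissue damping rate (1/mm)
#' applied to channel magnitudes with depth.
#'
#' @slot torsoSemiAxes numeric(3) mm.
#' @slot heartCenter numeric(3) mm.
#' @slot heartSemiAxes numeric(3) mm.
#' @slot attenuation numeric, 1/mm.
#' @slot phaseOffsets numeric per channel, rad (hardware + subject coupling).
#' @slot sessionSensitivity numeric > 0: how strongly this subject expresses
#'   session-to-session variability (repositioning consistency, breathing
#'   state); multiplies the random parts of the session perturbations.
#' @slot textureFreqs numeric matrix (nHarmonics x 3), cycles per FOV, of the
#'   static subject-specific field texture (tissue structure the coil model
#'   cannot express; partially beyond the kT-point candidate bandwidth).
#' @slot texturePhases numeric, rad.
#' @slot textureWeights numeric matrix (nHarmonics x channels).
#' @slot textureAmp numeric in [0, 0.5], relative amplitude of the texture.
#' @slot seed integer.
#' @export
setClass("SubjectParams", representation(
  torsoSemiAxes = "numeric", heartCenter = "numeric",
  heartSemiAxes = "numeric", attenuation = "numeric",
  phaseOffsets = "numeric", sessionSensitivity = "numeric",
  textureFreqs = "matrix", texturePhases = "numeric",
  textureWeights = "matrix", textureAmp = "numeric", seed = "integer"
))

setValidity("SubjectParams", function(object) {
  if (any(object@torsoSemiAxes <= 0) || any(object@heartSemiAxes <= 0))
    return("semi-axes must be positive")
  if (object@attenuation < 0) return("attenuation must be >= 0")
  if (object@sessionSensitivity <= 0)
    return("sessionSensitivity must be > 0")
  if (object@textureAmp < 0 || object@textureAmp > 0.5)
    return("textureAmp must be in [0, 0.5]")
  ## sampled-surface containment check: heart surface points inside torso
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs %*% diag(object@heartSemiAxes), 2,
               object@heartCenter, "+")
  rho <- sqrt(rowSums(sweep(pts, 2, object@torsoSemiAxes, "/")^2))
  if (any(rho >= 1))
    return("heart ellipsoid must lie strictly inside the torso ellipsoid")
  TRUE
})

#' Scan-session perturbation parameters
#'
#' Coil placement (translation/rotation), anatomy scale drift and a smooth
#' multiplicative field perturbation, together with the operator who
#' positioned the coil. The perturbation field is parameterized here (drawn
#' once from the session seed) so that map simulation is a pure function.
#'
#' @slot translation numeric(3) mm, coil translation (|t| <= 40 mm).
#' @slot rotation numeric, deg about z (|rot| <= 15).
#' @slot scale numeric, isotropic anatomy scale in [0.9, 1.1].
#' @slot perturbAmp numeric in [0, 0.3], amplitude of the multiplicative
#'   smooth field perturbation.
#' @slot perturbFreqs numeric matrix (nHarmonics x 3), cycles per FOV.
#' @slot perturbPhases numeric, rad.
#' @slot perturbWeights numeric matrix (nHarmonics x channels): per-element
#'   harmonic weights of the multiplicative perturbation field.
#' @slot standoff numeric, mm distance between the coil elements and the
#'   torso surface for this session (operator-dependent).
#' @slot channelGainLog numeric per channel, log amplitude deviation of the
#'   element-wise coil-subject coupling for this session.
#' @slot channelPhase numeric per channel, rad, element-wise phase deviation.
#' @slot operator character id.
#' @slot seed integer.
#' @export
setClass("SessionParams", representation(
  translation = "numeric", rotation = "numeric", scale = "numeric",
  perturbAmp = "numeric", perturbFreqs = "matrix", perturbPhases = "numeric",
  perturbWeights = "matrix", standoff = "numeric",
  channelGainLog = "numeric",
  channelPhase = "numeric", operator = "character", seed = "integer"
))

setValidity("SessionParams", function(object) {
  if (sqrt(sum(object@translation^2)) > 40)
    return("|translation| must be <= 40 mm")
  if (abs(object@rotation) > 15) return("|rotation| must be <= 15 deg")
  if (object@scale < 0.9 || object@scale > 1.1)
    return("anatomy scale must be in [0.9, 1.1]")
  if (object@perturbAmp < 0 || object@perturbAmp > 0.3)
    return("perturbation amplitude must be in [0, 0.3]")
  if (object@standoff < 5)
    return("coil standoff must be at least 5 mm")
  TRUE
})

#' kT-points pulse
#'
#' Per-channel complex RF weights at each transmit k-space location, plus the
#' gradient blips realizing the k-space displacements between subpulses.
#'
#' @slot weights complex matrix (C x K), relative volts.
#' @slot kLocations numeric matrix (K x 3), rad/m.
#' @slot subpulseDuration numeric, microseconds per kT-point.
#' @slot blips list of K-1 realized gradient blips (per-axis amplitude mT/m,
#'   ramp/flat durations in microseconds).
#' @slot targetFa numeric, target flip angle in degrees.
#' @slot method character: "default", "TP" or "UP".
#' @slot meta list (source subject/session or library id, lambda, seed, cost).
#' @slot version character schema tag.
#' @export
setClass("KTPointsPulse", representation(
  weights = "matrix", kLocations = "matrix", subpulseDuration = "numeric",
  blips = "list", targetFa = "numeric", method = "character",
  meta = "list", version = "character"
))

setValidity("KTPointsPulse", function(object) {
  K <- nrow(object@kLocations)
  if (K < 1L) return("at least one kT-point required")
  if (!is.complex(object@weights)) return("weights must be complex")
  if (ncol(object@weights) != K)
    return("weights must have one column per kT-point")
  if (ncol(object@kLocations) != 3L)
    return("kLocations must be K x 3 (rad/m)")
  if (!object@method %in% c("default", "TP", "UP"))
    return("method must be one of default/TP/UP")
  if (object@method == "default") {
    if (K != 1L) return("default shim must have K = 1")
    if (any(abs(object@kLocations) > 0))
      return("default shim must sit at k = 0")
    mags <- Mod(object@weights[, 1])
    if (diff(range(mags)) > 1e-9 * max(mags, 1e-300))
      return("default shim weights must share one magnitude (phase-only)")
  }
  if (length(object@blips)) {
    if (length(object@blips) != K - 1L)
      return("blips must have one entry per inter-point gap (K - 1)")
    for (j in seq_along(object@blips)) {
      bl <- object@blips[[j]]
      dk <- object@kLocations[j + 1, ] - object@kLocations[j, ]
      area <- .gammaRad * bl$amplitude_mT_m * 1e-3 *
        (bl$ramp_us + bl$flat_us) * 1e-6
      if (any(abs(area - dk) > 1e-6))
        return(sprintf("blip %d does not reproduce its k-space displacement",
                       j))
    }
  }
  TRUE
})

#' @rdname KTPointsPulse-class
#' @param object A `KTPointsPulse`.
#' @export
pulseWeights <- function(object) object@weights

#' @rdname KTPointsPulse-class
#' @export
pulseKLocations <- function(object) object@kLocations

#' @rdname KTPointsPulse-class
#' @export
pulseMethod <- function(object) object@method

#' @rdname KTPointsPulse-class
#' @export
pulseChannels <- function(object) nrow(object@weights)

setMethod("show", "KTPointsPulse", function(object) {
  cat(sprintf(
    "KTPointsPulse [%s]: %d channels x %d kT-points, target FA %.3g deg\n",
    object@method, nrow(object@weights), ncol(object@weights),
    object@targetFa))
})

#' Pulse design configuration
#'
#' Parameters of the magnitude-least-squares kT-points design: target flip
#' angle, RF power regularization, transmit k-space candidate grid, and
#' variable-exchange controls.
#'
#' @slot nKt integer, number of kT-points (default 4).
#' @slot targetFa numeric, degrees (default 10).
#' @slot lambda numeric >= 0, Tikhonov weight on total RF power.
#' @slot ktExtent numeric, candidate grid half-extent in cycles/FOV.
#' @slot ktStep numeric, candidate grid step in cycles/FOV.
#' @slot maxIter integer, variable-exchange iteration cap (final solves).
#' @slot scanIter integer, iteration cap while scanning greedy candidates.
#' @slot tol numeric > 0, relative cost-change convergence tolerance.
#' @slot maxGrad numeric, mT/m gradient amplitude limit.
#' @slot maxSlew numeric, T/m/s gradient slew limit.
#' @slot raster numeric, gradient raster time in microseconds.
#' @slot seed integer, reserved for randomized initializations.
#' @export
setClass("DesignConfig", representation(
  nKt = "integer", targetFa = "numeric", lambda = "numeric",
  ktExtent = "numeric", ktStep = "numeric", maxIter = "integer",
  scanIter = "integer", tol = "numeric", maxGrad = "numeric",
  maxSlew = "numeric", raster = "numeric", seed = "integer"
))

setValidity("DesignConfig", function(object) {
  if (object@nKt < 1L) return("nKt must be >= 1")
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@tol <= 0) return("tol must be > 0")
  if (object@ktExtent < 0 || object@ktStep <= 0)
    return("candidate grid must contain k = 0 (ktExtent >= 0, ktStep > 0)")
  if (object@maxGrad <= 0 || object@maxSlew <= 0 || object@raster <= 0)
    return("gradient limits and raster must be positive")
  TRUE
})

#' @rdname DesignConfig-class
#' @param nKt,targetFa,lambda,ktExtent,ktStep,maxIter,scanIter,tol,maxGrad,maxSlew,raster,seed
#'   see slot documentation.
#' @return A `DesignConfig`.
#' @examples
#' DesignConfig(nKt = 2, targetFa = 10)
#' @export
DesignConfig <- function(nKt = 4L, targetFa = 10, lambda = 1e-3,
                         ktExtent = 2, ktStep = 1, maxIter = 200L,
                         scanIter = 12L, tol = 1e-6, maxGrad = 40,
                         maxSlew = 170, raster = 10, seed = 1L) {
  new("DesignConfig", nKt = as.integer(nKt), targetFa = targetFa,
      lambda = lambda, ktExtent = ktExtent, ktStep = ktStep,
      maxIter = as.integer(maxIter), scanIter = as.integer(scanIter),
      tol = tol, maxGrad = maxGrad, maxSlew = maxSlew, raster = raster,
      seed = as.integer(seed))
}

setMethod("show", "DesignConfig", function(object) {
  cat(sprintf(
    "DesignConfig: %d kT-points, target %.3g deg, lambda %.3g, grid +/-%g cyc/FOV step %g\n",
    object@nKt, object@targetFa, object@lambda, object@ktExtent,
    object@ktStep))
})

#' Small-tip-angle system matrix
#'
#' Linear map from stacked complex channel weights (C x K) to the complex
#' transverse excitation at each ROI voxel; entry (r, (c,k)) equals
#' c0 * b1_c(r) * exp(i k_k . r). Columns are grouped by kT-point with the
#' channel index fastest. c0 converts normalized-B1 drive to degrees.
#'
#' @slot A complex matrix (nROI x C*K).
#' @slot c0 numeric, degrees per unit normalized drive.
#' @slot channels integer.
#' @slot kLocations numeric matrix (K x 3), rad/m.
#' @export
setClass("STASystem", representation(
  A = "matrix", c0 = "numeric", channels = "integer", kLocations = "matrix"
))

setValidity("STASystem", function(object) {
  K <- nrow(object@kLocations)
  if (ncol(object@A) != object@channels * K)
    return("A must have C*K columns")
  if (!is.complex(object@A)) return("A must be complex")
  TRUE
})

setMethod("show", "STASystem", function(object) {
  cat(sprintf("STASystem: %d ROI voxels x (%d channels x %d kT-points)\n",
              nrow(object@A), object@channels, nrow(object@kLocations)))
})

#' Flip-angle map
#'
#' @slot grid [GridSpec-class].
#' @slot fa numeric array (Nx, Ny, Nz), degrees, non-negative.
#' @slot provenance list (pulse method, map ids, simulator tag).
#' @export
setClass("FAMap", representation(
  grid = "GridSpec", fa = "array", provenance = "list"
))

setValidity("FAMap", function(object) {
  if (!all(dim(object@fa) == object@grid@shape))
    return("fa dims do not match grid shape")
  if (anyNA(object@fa) || any(!is.finite(object@fa)))
    return("fa must be finite")
  if (any(object@fa < 0)) return("fa must be non-negative (degrees)")
  TRUE
})

#' @rdname FAMap-class
#' @param object A `FAMap`.
#' @export
faArray <- function(object) object@fa

setMethod("show", "FAMap", function(object) {
  cat(sprintf("FAMap [%s]: %s grid, range %.3g-%.3g deg\n",
              if (is.null(object@provenance$simulator)) "?" else
                object@provenance$simulator,
              paste(object@grid@shape, collapse = "x"),
              min(object@fa), max(object@fa)))
})

#' RF voltage and power metrics of a pulse
#'
#' @slot peak numeric, max over channels and kT-points of |w| (relative V).
#' @slot meanPower numeric, mean over channels and kT-points of |w|^2.
#' @slot channelPower numeric per channel, mean over kT-points of |w|^2.
#' @export
setClass("RFMetrics", representation(
  peak = "numeric", meanPower = "numeric", channelPower = "numeric"
))

setValidity("RFMetrics", function(object) {
  if (object@peak < 0 || object@meanPower < 0 || any(object@channelPower < 0))
    return("RF metrics must be non-negative")
  TRUE
})

setMethod("show", "RFMetrics", function(object) {
  cat(sprintf("RFMetrics: peak %.4g, mean power %.4g (%d channels)\n",
              object@peak, object@meanPower, length(object@channelPower)))
})

#' Subjects-by-scan-groups CV table
#'
#' The object the CV-space cluster statistics operate on: CV (percent) of the
#' flip angle within the ROI for one excitation method, for V subjects across
#' S scan groups.
#'
#' @slot method character tag.
#' @slot values numeric matrix (V x S), percent, complete and non-negative.
#' @export
setClass("CVTable", representation(method = "character", values = "matrix"))

setValidity("CVTable", function(object) {
  v <- object@values
  if (nrow(v) < 1L || ncol(v) < 1L) return("V >= 1 and S >= 1 required")
  if (anyNA(v)) return("CV table must have no missing cells")
  if (any(v < 0)) return("CV values must be >= 0")
  TRUE
})

#' @rdname CVTable-class
#' @param values numeric matrix (V subjects x S scan groups), percent.
#' @param method character tag.
#' @return A `CVTable`.
#' @examples
#' cvTable(rbind(c(10, 20), c(20, 30)), method = "demo")
#' @export
cvTable <- function(values, method = "unnamed") {
  new("CVTable", method = method, values = as.matrix(values))
}

#' @rdname CVTable-class
#' @param object A `CVTable`.
#' @export
cvValues <- function(object) object@values

setMethod("show", "CVTable", function(object) {
  cat(sprintf("CVTable [%s]: %d subjects x %d scan groups\n",
              object@method, nrow(object@values), ncol(object@values)))
})

#' CV-cluster summary statistics
#'
#' Inertia (spread of the CV cluster), centroid norm (overall CV magnitude)
#' and perpendicular distance from the centroid to the identity line
#' (inter-session consistency), plus the componentwise median point.
#'
#' @slot method character.
#' @slot centroid numeric(S), percent.
#' @slot icv numeric, squared-percent scale.
#' @slot icvRoot numeric, sqrt(icv), percent.
#' @slot centroidNorm numeric, percent.
#' @slot perpDistance numeric, percent.
#' @slot medianPoint numeric(S), percent.
#' @export
setClass("ClusterSummary", representation(
  method = "character", centroid = "numeric", icv = "numeric",
  icvRoot = "numeric", centroidNorm = "numeric", perpDistance = "numeric",
  medianPoint = "numeric"
))

setValidity("ClusterSummary", function(object) {
  if (object@icv < 0 || object@perpDistance < 0)
    return("icv and perpDistance must be >= 0")
  TRUE
})

setMethod("show", "ClusterSummary", function(object) {
  cat(sprintf(
    "ClusterSummary [%s]: ICV %.4g, |centroid| %.4g%%, d_perp %.4g%%\n",
    object@method, object@icv, object@centroidNorm, object@perpDistance))
})

#' Full cross-application study result
#'
#' @slot cvGrid data.frame with one row per (subject, session, method/config):
#'   CV percent, FA distribution summary, RF metrics, TSG flag.
#' @slot tables per-grouping lists of [CVTable-class] objects.
#' @slot summaries data.frame of per-grouping, per-method cluster statistics.
#' @slot tests per-grouping data.frames of pairwise signed-rank tests.
#' @slot pulses list: `default`, `up`, and `tp[[subject]][[session]]`.
#' @slot groupings named list of session index vectors.
#' @slot seed integer master seed.
#' @slot meta list (cohort sizes, config echo).
#' @export
setClass("StudyResult", representation(
  cvGrid = "data.frame", tables = "list", summaries = "data.frame",
  tests = "list", pulses = "list", groupings = "list", seed = "integer",
  meta = "list"
))

setMethod("show", "StudyResult", function(object) {
  cat(sprintf(
    "StudyResult: %d subjects x %d sessions, %d methods, seed %d\n",
    length(unique(object@cvGrid$subject)),
    length(unique(object@cvGrid$session)),
    length(unique(paste(object@cvGrid$method, object@cvGrid$config))),
    object@seed))
  cat(sprintf("  groupings: %s\n", paste(names(object@groupings),
                                         collapse = ", ")))
})

## gyromagnetic ratio of 1H, rad/s/T
.gammaRad <- 2 * pi * 42.577478518e6
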
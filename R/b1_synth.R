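## Synthetic multi-subject, multi-session, multi-operator B1+ maps.
##
## The generator emulates an 8-channel transmit body array around an
## ellipsoidal torso: point-like elements on two rings (4 anterior,
## 4 posterior), channel magnitude decaying as 1/(d + d0) with exponential
## tissue damping, phase as a per-channel offset plus linear propagation.
## Session-to-session variability enters through operator-dependent coil
## placement, anatomy scale drift and a smooth multiplicative perturbation.

## fixed hardware phase offsets per channel (rad); subjects add small
## deviations on top so a universal pulse remains meaningful
.hardwarePhases <- function(C) {
  c0 <- seq_len(C)
  2 * pi * (c0 - 1) / C + 0.5 * sin(2 * c0)
}

## run expr with a private RNG stream, restoring global state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## deterministic seed stream derived from a master seed, kept < 2^31
.seedStream <- function(masterSeed, offset, n) {
  base <- (as.numeric(masterSeed) + offset * 1000003) %% 2147483587 + 1
  .withSeed(as.integer(base), sample.int(2147483647L, n))
}

#' Session variability settings
#'
#' The frozen knobs of the synthetic longitudinal study: how strongly coil
#' placement, anatomy and the residual field differ between scan sessions.
#' Operator bias is a fixed translation/rotation per operator (each operator
#' follows the same positioning instructions but settles on a systematically
#' different placement); jitter is the per-session random part.
#'
#' @param operatorBias named list of numeric(3) mm translations per operator.
#' @param operatorRotBias named numeric, deg about z per operator.
#' @param operatorStandoff named numeric, mm deviation of the coil-to-torso
#'   standoff per operator (how snugly each operator straps the anterior
#'   section).
#' @param setupDriftPerYear numeric(3), mm/year systematic coil placement
#'   drift of the scanner setup (hardware/software state changes over the
#'   study, affecting every subject alike).
#' @param rotDriftPerYear numeric, deg/year systematic drift of the coil
#'   rotation about z (protocol execution drifts over the study).
#' @param jitterSd numeric, per-axis translation jitter SD in mm.
#' @param rotJitterSd numeric, rotation jitter SD in deg.
#' @param scaleMeanPerYear numeric, mean directional anatomy scale drift per
#'   elapsed year (subjects tend to grow slightly over the study).
#' @param scaleSdPerYear numeric, SD of anatomy scale drift per elapsed year.
#' @param perturbAmp numeric in [0, 0.3], base amplitude of the smooth
#'   multiplicative field perturbation.
#' @param operatorAmpFactor named numeric, operator-specific multiplier on
#'   the perturbation amplitude (how consistently each operator reproduces
#'   the positioning/breathing instructions).
#' @param perturbGrowthPerYear numeric, relative growth of the perturbation
#'   amplitude per elapsed year (physiological change accumulates).
#' @param channelGainSd numeric, SD of the per-session, per-element log
#'   amplitude deviation of the coil-subject coupling.
#' @param channelPhaseSd numeric, rad, SD of the per-session, per-element
#'   phase deviation.
#' @param sessionYears numeric, elapsed years of each session relative to the
#'   first (recycled to the number of sessions).
#' @return list of settings, used by [sampleSession()] and [generateCohort()].
#' @export
sessionVariability <- function(
    operatorBias = list(A = c(0, 0, 0), B = c(6, -4, 5),
                        C = c(-5, 4, -5)),
    operatorRotBias = c(A = 0, B = 8, C = -9),
    operatorStandoff = c(A = 0, B = 0, C = 0),
    setupDriftPerYear = c(1, 1, -2), rotDriftPerYear = 5,
    jitterSd = 5, rotJitterSd = 4, scaleMeanPerYear = 0.02,
    scaleSdPerYear = 0.018,
    perturbAmp = 0.03, operatorAmpFactor = c(A = 1, B = 1, C = 1),
    perturbGrowthPerYear = 0, channelGainSd = 0.03,
    channelPhaseSd = 0.05, sessionYears = c(0, 1, 2, 2)) {
  list(operatorBias = operatorBias, operatorRotBias = operatorRotBias,
       operatorStandoff = operatorStandoff,
       setupDriftPerYear = setupDriftPerYear,
       rotDriftPerYear = rotDriftPerYear,
       jitterSd = jitterSd, rotJitterSd = rotJitterSd,
       scaleMeanPerYear = scaleMeanPerYear,
       scaleSdPerYear = scaleSdPerYear, perturbAmp = perturbAmp,
       operatorAmpFactor = operatorAmpFactor,
       perturbGrowthPerYear = perturbGrowthPerYear,
       channelGainSd = channelGainSd, channelPhaseSd = channelPhaseSd,
       sessionYears = sessionYears)
}

#' Degenerate variability: identical sessions
#'
#' All placement, anatomy and field perturbations switched off; every session
#' of a subject is then bitwise identical.
#' @return list of settings as in [sessionVariability()].
#' @export
zeroVariability <- function() {
  sessionVariability(
    operatorBias = list(A = c(0, 0, 0), B = c(0, 0, 0), C = c(0, 0, 0)),
    operatorRotBias = c(A = 0, B = 0, C = 0),
    operatorStandoff = c(A = 0, B = 0, C = 0),
    setupDriftPerYear = c(0, 0, 0), rotDriftPerYear = 0,
    jitterSd = 0, rotJitterSd = 0, scaleMeanPerYear = 0,
    scaleSdPerYear = 0, perturbAmp = 0,
    operatorAmpFactor = c(A = 1, B = 1, C = 1), perturbGrowthPerYear = 0,
    channelGainSd = 0, channelPhaseSd = 0, sessionYears = c(0, 0, 0, 0))
}

#' Draw subject anatomy
#'
#' @param seed integer subject seed.
#' @param cohort "test" for the longitudinal cohort, "library" for the
#'   broader-anatomy pulse-design library.
#' @param channels transmit channel count.
#' @return A [SubjectParams-class].
#' @export
sampleSubject <- function(seed, cohort = c("test", "library"),
                          channels = 8L) {
  cohort <- match.arg(cohort)
  spread <- if (cohort == "library") 1.2 else 1.0
  .withSeed(seed, {
    torso <- c(95, 122, 130) * (1 + c(0.04, 0.04, 0.025) * spread *
                                  pmax(pmin(rnorm(3), 2.5), -2.5))
    heart <- c(46, 40, 38) * (1 + 0.06 * spread *
                                pmax(pmin(rnorm(3), 2.5), -2.5))
    center <- c(25, -25, 8) + c(4, 4, 5) *
      pmax(pmin(rnorm(3), 2.5), -2.5)
    ## keep the heart strictly inside the torso: shrink deterministically
    ## until every sampled heart-surface point sits well inside
    heart <- pmin(heart, 0.55 * torso)
    dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    dirs <- dirs[rowSums(abs(dirs)) > 0, ]
    dirs <- dirs / sqrt(rowSums(dirs^2))
    repeat {
      pts <- sweep(dirs %*% diag(heart), 2, center, "+")
      rho <- sqrt(rowSums(sweep(pts, 2, torso, "/")^2))
      if (max(rho) < 0.97) break
      center <- center * 0.93
      heart <- heart * 0.97
    }
    att <- 0.004 * exp(0.15 * spread * rnorm(1))
    ph <- .hardwarePhases(channels) + 0.05 * spread * rnorm(channels)
    sens <- exp(0.35 * pmax(pmin(rnorm(1), 2), -2))
    nt <- 10L
    tf <- matrix(runif(nt * 3, -10, 10), nt, 3)
    tp <- runif(nt, 0, 2 * pi)
    tw <- matrix(rnorm(nt * channels), nt, channels)
    new("SubjectParams", torsoSemiAxes = torso, heartCenter = center,
        heartSemiAxes = heart, attenuation = att, phaseOffsets = ph,
        sessionSensitivity = sens, textureFreqs = tf, texturePhases = tp,
        textureWeights = tw, textureAmp = 0.2, seed = as.integer(seed))
  })
}

#' Draw scan-session perturbations
#'
#' @param sessionIndex integer scan index (1-based).
#' @param operator character operator id ("A", "B", "C", ...).
#' @param seed integer session seed.
#' @param variability settings from [sessionVariability()].
#' @param channels transmit channel count.
#' @param sensitivity subject-level multiplier on the random perturbation
#'   magnitudes (see the `sessionSensitivity` slot of
#'   [SubjectParams-class]).
#' @param stateSeed integer seed of the scanner RF-chain state of the day:
#'   per-element gain/phase deviations are drawn from it, so sessions that
#'   share a `stateSeed` (all subjects scanned in one scan group) share the
#'   same deviations. Defaults to `seed`.
#' @return A [SessionParams-class].
#' @export
sampleSession <- function(sessionIndex, operator, seed,
                          variability = sessionVariability(),
                          channels = 8L, sensitivity = 1,
                          stateSeed = seed) {
  v <- variability
  yrs <- rep_len(v$sessionYears, max(sessionIndex, length(v$sessionYears)))
  bias <- v$operatorBias[[operator]]
  if (is.null(bias)) bias <- c(0, 0, 0)
  rotBias <- unname(v$operatorRotBias[operator])
  if (length(rotBias) != 1L || is.na(rotBias)) rotBias <- 0
  soBias <- unname(v$operatorStandoff[operator])
  if (length(soBias) != 1L || is.na(soBias)) soBias <- 0
  ampFac <- unname(v$operatorAmpFactor[operator])
  if (length(ampFac) != 1L || is.na(ampFac)) ampFac <- 1
  state <- .withSeed(stateSeed, {
    list(gl = v$channelGainSd * pmax(pmin(rnorm(channels), 3), -3),
         cp = v$channelPhaseSd * pmax(pmin(rnorm(channels), 3), -3))
  })
  .withSeed(seed, {
    ## placement is operator handling: not scaled by subject sensitivity
    tr <- bias + v$setupDriftPerYear * yrs[sessionIndex] +
      v$jitterSd * pmax(pmin(rnorm(3), 3), -3)
    tn <- sqrt(sum(tr^2))
    if (tn > 39.9) tr <- tr * (39.9 / tn)
    rot <- rotBias + v$rotDriftPerYear * yrs[sessionIndex] +
      v$rotJitterSd * pmax(pmin(rnorm(1), 3), -3)
    rot <- max(min(rot, 14.9), -14.9)
    sc <- 1 + v$scaleMeanPerYear * yrs[sessionIndex] +
      sensitivity * v$scaleSdPerYear * yrs[sessionIndex] *
      pmax(pmin(rnorm(1), 3), -3)
    sc <- max(min(sc, 1.1), 0.9)
    nh <- 6L
    freqs <- matrix(runif(nh * 3, -1.5, 1.5), nh, 3)
    phases <- runif(nh, 0, 2 * pi)
    wts <- matrix(rnorm(nh * channels), nh, channels)
    gl <- state$gl
    cp <- state$cp
    new("SessionParams", translation = tr, rotation = rot, scale = sc,
        perturbAmp = min(v$perturbAmp * ampFac *
                           (1 + v$perturbGrowthPerYear * yrs[sessionIndex]),
                         0.3),
        standoff = 25 + soBias, perturbFreqs = freqs,
        perturbPhases = phases, perturbWeights = wts,
        channelGainLog = gl, channelPhase = cp,
        operator = operator, seed = as.integer(seed))
  })
}

## coil element centers (mm): two rings offset in z, 4 anterior/4 posterior.
## The array has fixed geometry: it is sized on the subject's baseline torso
## (how the coil was strapped at the first fitting), so anatomy drift moves
## tissue relative to the elements; then rotated/translated per session.
.coilElements <- function(torsoSemiAxes, session, zRing = 40) {
  standoff <- session@standoff
  az <- c(-60, -20, 20, 60, 120, 160, 200, 240) * pi / 180
  zs <- rep(c(-zRing, zRing), 4)
  ux <- cos(az); uy <- sin(az)
  rad <- 1 / sqrt((ux / torsoSemiAxes[1])^2 + (uy / torsoSemiAxes[2])^2)
  p <- cbind((rad + standoff) * ux, (rad + standoff) * uy, zs)
  th <- session@rotation * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sweep(p %*% t(R), 2, session@translation, "+")
}

## static subject texture factors, one column per channel: smooth random
## fields up to ~3 cycles/FOV emulating tissue-driven B1 structure that the
## ellipsoid coil model cannot express
.textureField <- function(coords, grid, subject, channels, scale = 1) {
  if (subject@textureAmp <= 0)
    return(matrix(1, nrow(coords), channels))
  fov <- gridFov(grid)
  u <- sweep(coords, 2, fov * scale, "/")
  nh <- nrow(subject@textureFreqs)
  cosMat <- matrix(0, nrow(coords), nh)
  for (h in seq_len(nh))
    cosMat[, h] <- cos(2 * pi * (u %*% subject@textureFreqs[h, ]) +
                         subject@texturePhases[h])
  g <- cosMat %*% subject@textureWeights[, seq_len(channels), drop = FALSE]
  gmax <- apply(abs(g), 2, max)
  gmax[gmax == 0] <- 1
  1 + subject@textureAmp * sweep(g, 2, gmax, "/")
}

## smooth multiplicative perturbation factors, one column per channel
## (element-wise coil loading): 1 + amp * g_c with each g_c scaled to
## max |g_c| = 1
.perturbField <- function(coords, grid, session, channels) {
  if (session@perturbAmp <= 0)
    return(matrix(1, nrow(coords), channels))
  fov <- gridFov(grid)
  u <- sweep(coords, 2, fov, "/")  # normalized coordinates
  nh <- nrow(session@perturbFreqs)
  cosMat <- matrix(0, nrow(coords), nh)
  for (h in seq_len(nh))
    cosMat[, h] <- cos(2 * pi * (u %*% session@perturbFreqs[h, ]) +
                         session@perturbPhases[h])
  g <- cosMat %*% session@perturbWeights[, seq_len(channels), drop = FALSE]
  gmax <- apply(abs(g), 2, max)
  gmax[gmax == 0] <- 1
  1 + session@perturbAmp * sweep(g, 2, gmax, "/")
}

#' Simulate multi-channel B1+ maps for one subject and session
#'
#' Channel magnitude decays as 1/(d + d0) with distance d (mm) from the
#' element center, attenuated exponentially with depth inside the torso;
#' channel phase is a per-channel offset plus a linear propagation term
#' kProp * d. The result is deterministic given the subject and session
#' parameters and is not yet normalized.
#'
#' @param subject A [SubjectParams-class].
#' @param grid A [GridSpec-class]; must contain the (scaled) torso.
#' @param session A [SessionParams-class].
#' @param d0 numeric, mm softening of the 1/d decay.
#' @param kProp numeric, rad/mm propagation constant of the phase term.
#' @return An unnormalized [B1MapSet-class] with 8 channels (one per element).
#' @examples
#' sub <- sampleSubject(1)
#' ses <- sampleSession(1, "A", 2, zeroVariability())
#' maps <- simulateCoilMaps(sub, defaultGrid(), ses)
#' @export
simulateCoilMaps <- function(subject, grid, session, d0 = 40,
                             kProp = 0.065) {
  torso <- subject@torsoSemiAxes * session@scale
  half <- gridFov(grid) / 2
  bad <- which(torso > half)
  if (length(bad))
    stop(sprintf("grid too small to contain torso along axis %s (%.1f > %.1f mm)",
                 c("x", "y", "z")[bad[1]], torso[bad[1]], half[bad[1]]))
  coords <- voxelCoordinates(grid)
  elems <- .coilElements(subject@torsoSemiAxes, session)
  C <- nrow(elems)
  rho <- sqrt(rowSums(sweep(coords, 2, torso, "/")^2))
  depth <- pmax(0, 1 - rho) * min(torso)
  atten <- exp(-subject@attenuation * depth)
  f <- .perturbField(coords, grid, session, C) *
    .textureField(coords, grid, subject, C, scale = session@scale)
  data <- array(complex(real = 0), c(grid@shape, C))
  for (cc in seq_len(C)) {
    d <- sqrt((coords[, 1] - elems[cc, 1])^2 +
                (coords[, 2] - elems[cc, 2])^2 +
                (coords[, 3] - elems[cc, 3])^2)
    mag <- 1000 / (d + d0) * atten * f[, cc] *
      exp(session@channelGainLog[cc])
    ph <- subject@phaseOffsets[cc] + kProp * d + session@channelPhase[cc]
    data[, , , cc] <- complex(modulus = mag, argument = ph)
  }
  new("B1MapSet", grid = grid, data = data, normalized = FALSE,
      meta = list(subjectSeed = subject@seed, sessionSeed = session@seed,
                  operator = session@operator))
}

#' Heart ROI mask for a subject/session
#'
#' Ellipsoidal heart volume, scaled with the session anatomy factor.
#'
#' @param subject A [SubjectParams-class].
#' @param grid A [GridSpec-class].
#' @param session A [SessionParams-class] (identity scale if omitted).
#' @return A [ROIMask-class].
#' @export
heartMask <- function(subject, grid, session = NULL) {
  s <- if (is.null(session)) 1 else session@scale
  center <- subject@heartCenter * s
  axes <- subject@heartSemiAxes * s
  coords <- voxelCoordinates(grid)
  rho <- sqrt(rowSums(sweep(sweep(coords, 2, center, "-"), 2, axes, "/")^2))
  mask <- array(rho <= 1, grid@shape)
  new("ROIMask", grid = grid, mask = mask)
}

#' Normalize B1+ maps to the heart-ROI mean sum of magnitudes
#'
#' Divides every channel by s = mean over ROI voxels of the per-voxel sum of
#' channel magnitudes, so that this ROI mean equals 1 afterwards. Idempotent.
#'
#' @param maps A [B1MapSet-class].
#' @param roi A [ROIMask-class] on the same grid.
#' @return The normalized [B1MapSet-class].
#' @export
normalizeB1 <- function(maps, roi) {
  if (!all(roi@grid@shape == maps@grid@shape))
    stop("maps and roi must share one grid")
  n <- sum(roi@mask)
  if (n == 0L) stop("ROI is empty; cannot normalize")
  som <- .roiSumOfMagnitudes(maps, roi)
  s <- mean(som)
  if (!is.finite(s) || s <= 0) stop("ROI mean sum of magnitudes must be > 0")
  maps@data <- maps@data / s
  maps@normalized <- TRUE
  validObject(maps)
  maps
}

## per-ROI-voxel sum over channels of |b1|
.roiSumOfMagnitudes <- function(maps, roi) {
  idx <- which(roi@mask)
  C <- channelCount(maps)
  nvox <- prod(maps@grid@shape)
  m <- Mod(matrix(maps@data, nvox, C))
  rowSums(m[idx, , drop = FALSE])
}

## ROI-restricted complex b1 matrix (nROI x C) and positions (m)
.roiB1Matrix <- function(maps, roi) {
  idx <- which(roi@mask)
  C <- channelCount(maps)
  nvox <- prod(maps@grid@shape)
  matrix(maps@data, nvox, C)[idx, , drop = FALSE]
}

.roiPositions <- function(grid, roi) {
  voxelCoordinates(grid)[which(roi@mask), , drop = FALSE] / 1000
}

#' Generate a synthetic scan cohort
#'
#' Draws subjects and per-session perturbations, simulates and normalizes the
#' B1+ maps, and assembles a manifest. Subject anatomy is fixed across that
#' subject's sessions up to the session anatomy-scale factor; session
#' perturbations are drawn independently; the default operator assignment for
#' four sessions is sessions 1, 3 -> operator A, session 2 -> B, session 4
#' -> C. Fully reproducible from `masterSeed`.
#'
#' @param nSubjects,nSessions cohort layout (each >= 1).
#' @param nOperators number of distinct operators (default 3).
#' @param masterSeed integer.
#' @param grid A [GridSpec-class].
#' @param variability settings from [sessionVariability()].
#' @param cohort "test" or "library" (library: broader anatomy spread and a
#'   seed stream disjoint from the test cohort).
#' @param outDir optional directory; when given, each (subject, session) map
#'   pair is written as a container (see [writeB1Container()]) together with
#'   a `manifest.csv`, otherwise entries are kept in memory.
#' @return A list with elements `manifest` (data.frame: subject, session,
#'   operator, path, subjectSeed, sessionSeed), `entries` (in-memory list of
#'   `list(b1, roi)` or `NULL` when written to disk), `grid`, `variability`,
#'   `cohort`, `masterSeed`.
#' @examples
#' coh <- generateCohort(2, 2, masterSeed = 7)
#' coh$manifest
#' @export
generateCohort <- function(nSubjects = 6L, nSessions = 4L, nOperators = 3L,
                           masterSeed = 1L, grid = defaultGrid(),
                           variability = sessionVariability(),
                           cohort = c("test", "library"), outDir = NULL) {
  cohort <- match.arg(cohort)
  stopifnot(nSubjects >= 1L, nSessions >= 1L, nOperators >= 1L)
  streamOffset <- if (cohort == "library") 1L else 0L
  seeds <- .seedStream(masterSeed, streamOffset,
                       nSubjects + nSubjects * nSessions + nSessions)
  subjSeeds <- seeds[seq_len(nSubjects)]
  sessSeeds <- matrix(seeds[nSubjects + seq_len(nSubjects * nSessions)],
                      nSubjects, nSessions)
  ## scanner state of each scan group: shared by the test cohort's subjects
  ## (scanned in the same scan group); library members are one-off scans and
  ## each carries its own state
  stateSeeds <- seeds[nSubjects + nSubjects * nSessions + seq_len(nSessions)]
  ops <- .operatorAssignment(nSessions, nOperators)
  rows <- list()
  entries <- list()
  k <- 0L
  for (v in seq_len(nSubjects)) {
    subject <- sampleSubject(subjSeeds[v], cohort = cohort)
    for (s in seq_len(nSessions)) {
      k <- k + 1L
      ## library members each contribute one scan; cycle operators and
      ## study epochs over members so the universal design sees the full
      ## placement and drift spread the longitudinal sessions will express
      op <- if (cohort == "library")
        LETTERS[((v - 1L) %% nOperators) + 1L] else ops[s]
      sIdx <- if (cohort == "library")
        ((v - 1L) %% length(variability$sessionYears)) + 1L else s
      session <- sampleSession(sIdx, op, sessSeeds[v, s], variability,
                               sensitivity = subject@sessionSensitivity,
                               stateSeed = if (cohort == "library")
                                 sessSeeds[v, s] else stateSeeds[s])
      maps <- simulateCoilMaps(subject, grid, session)
      roi <- heartMask(subject, grid, session)
      maps <- normalizeB1(maps, roi)
      maps@meta$subject <- v
      maps@meta$session <- s
      path <- NA_character_
      if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        path <- file.path(outDir, sprintf("%s_sub%02d_ses%02d.rds",
                                          cohort, v, s))
        writeB1Container(maps, roi, path = path)
        entries[[k]] <- list(NULL)
      } else {
        entries[[k]] <- list(b1 = maps, roi = roi)
      }
      rows[[k]] <- data.frame(
        subject = v, session = s, operator = op, path = path,
        subjectSeed = subjSeeds[v], sessionSeed = sessSeeds[v, s],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    write.csv(manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
  structure(list(manifest = manifest, entries = entries, grid = grid,
                 variability = variability, cohort = cohort,
                 masterSeed = as.integer(masterSeed)),
            class = "ptxCohort")
}

.operatorAssignment <- function(nSessions, nOperators) {
  if (nSessions == 4L && nOperators >= 3L) return(c("A", "B", "A", "C"))
  LETTERS[((seq_len(nSessions) - 1L) %% nOperators) + 1L]
}

#' Fetch one cohort entry
#'
#' @param cohort result of [generateCohort()].
#' @param subject,session 1-based indices.
#' @return `list(b1 = B1MapSet, roi = ROIMask)`.
#' @export
cohortEntry <- function(cohort, subject, session = 1L) {
  i <- which(cohort$manifest$subject == subject &
               cohort$manifest$session == session)
  if (length(i) != 1L)
    stop(sprintf("no cohort entry for subject %d session %d",
                 subject, session))
  e <- cohort$entries[[i]]
  if (!is.null(e$b1)) return(e)
  path <- cohort$manifest$path[i]
  if (!file.exists(path))
    stop(sprintf("cohort file missing: %s", path))
  cont <- readB1Container(path)
  list(b1 = cont$b1, roi = cont$roi)
}
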
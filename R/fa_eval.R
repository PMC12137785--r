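## Flip-angle prediction (small-tip closed form and hard-pulse Bloch) and
## per-scan evaluation quantities: CV within the ROI, FA distribution
## summaries, RF voltage/power metrics.

## per-voxel complex drive of each subpulse: D (nvox x K) already including
## the k-space phase ramps
.pulseDrive <- function(maps, pulse) {
  if (channelCount(maps) != nrow(pulse@weights))
    stop(sprintf("channel mismatch: maps have %d channels, pulse has %d",
                 channelCount(maps), nrow(pulse@weights)))
  nvox <- prod(maps@grid@shape)
  B <- matrix(maps@data, nvox, channelCount(maps))
  D <- B %*% pulse@weights
  pos <- voxelCoordinates(maps@grid) / 1000
  E <- exp(1i * (pos %*% t(pulse@kLocations)))
  D * E
}

#' Small-tip-angle flip-angle prediction
#'
#' fa(r) = c0 * |sum_k sum_c b1_c(r) w_ck exp(i k_k . r)| in degrees,
#' computed over the full grid; c0 equals the pulse target flip angle per
#' unit normalized drive (matching [buildSystem()]).
#'
#' @param maps A normalized [B1MapSet-class].
#' @param pulse A [KTPointsPulse-class] with matching channel count.
#' @return An [FAMap-class] (simulator tag `"sta"`).
#' @export
predictFaSta <- function(maps, pulse) {
  if (!maps@normalized)
    stop("maps are not normalized; run normalizeB1() first")
  DE <- .pulseDrive(maps, pulse)
  fa <- pulse@targetFa * abs(rowSums(DE))
  new("FAMap", grid = maps@grid, fa = array(fa, maps@grid@shape),
      provenance = list(simulator = "sta", method = pulse@method,
                        map = maps@meta[c("subject", "session")]))
}

#' Hard-pulse Bloch simulation of the flip angle
#'
#' Each kT-point subpulse is a constant complex RF over its duration; the
#' gradient blips enter as position-dependent phase increments between
#' subpulses (exactly absorbed into the subpulse RF phases, which leaves the
#' final longitudinal magnetization unchanged). Relaxation is neglected, so
#' each subpulse is an exact axis-angle rotation and
#' fa(r) = arccos(Mz_final) for magnetization starting at equilibrium.
#'
#' @inheritParams predictFaSta
#' @return An [FAMap-class] (simulator tag `"bloch"`).
#' @export
blochSimulate <- function(maps, pulse) {
  if (!maps@normalized)
    stop("maps are not normalized; run normalizeB1() first")
  DE <- .pulseDrive(maps, pulse)
  nvox <- nrow(DE)
  K <- ncol(DE)
  mx <- rep(0, nvox); my <- rep(0, nvox); mz <- rep(1, nvox)
  for (j in seq_len(K)) {
    alpha <- pulse@targetFa * pi / 180 * abs(DE[, j])
    phi <- Arg(DE[, j])
    nx <- cos(phi); ny <- sin(phi)
    ca <- cos(alpha); sa <- sin(alpha)
    dot <- nx * mx + ny * my
    # Rodrigues rotation about the transverse axis (nx, ny, 0)
    cxn <- ny * mz          # (n x m)_x
    cyn <- -nx * mz         # (n x m)_y
    czn <- nx * my - ny * mx
    mx2 <- mx * ca + cxn * sa + nx * dot * (1 - ca)
    my2 <- my * ca + cyn * sa + ny * dot * (1 - ca)
    mz2 <- mz * ca + czn * sa
    mx <- mx2; my <- my2; mz <- mz2
  }
  fa <- acos(pmin(1, pmax(-1, mz))) * 180 / pi
  new("FAMap", grid = maps@grid, fa = array(fa, maps@grid@shape),
      provenance = list(simulator = "bloch", method = pulse@method,
                        map = maps@meta[c("subject", "session")]))
}

#' Coefficient of variation of the flip angle within the ROI
#'
#' CV = 100 * (population standard deviation / mean) of the flip angle over
#' the ROI voxels, in percent.
#'
#' @param fa An [FAMap-class].
#' @param roi A [ROIMask-class] on the same grid.
#' @return numeric, percent.
#' @examples
#' # a uniform map has CV 0
#' @export
computeCv <- function(fa, roi) {
  if (!all(roi@grid@shape == fa@grid@shape))
    stop("fa and roi must share one grid")
  x <- fa@fa[roi@mask]
  if (length(x) == 0L) stop("ROI is empty")
  m <- mean(x)
  if (m <= 0) stop("mean flip angle in ROI must be > 0")
  100 * sqrt(mean((x - m)^2)) / m
}

#' Flip-angle distribution summary within the ROI
#'
#' Order statistics of the ROI flip angles; for even counts the median is the
#' midpoint of the central pair.
#'
#' @inheritParams computeCv
#' @return data.frame with `median`, `q25`, `q75`, `min`, `max` (degrees).
#' @export
faDistribution <- function(fa, roi) {
  if (!all(roi@grid@shape == fa@grid@shape))
    stop("fa and roi must share one grid")
  x <- fa@fa[roi@mask]
  if (length(x) == 0L) stop("ROI is empty")
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  data.frame(median = median(x), q25 = q[1], q75 = q[2],
             min = min(x), max = max(x))
}

#' RF voltage and power metrics of a pulse
#'
#' Peak voltage is the maximum |w| over channels and kT-points; mean power is
#' the duty-weighted mean of |w|^2 (all subpulses share one duration, so a
#' plain mean); channel power is the per-channel mean over kT-points.
#'
#' @param pulse A [KTPointsPulse-class].
#' @return An [RFMetrics-class].
#' @export
rfMetrics <- function(pulse) {
  m <- Mod(pulse@weights)
  new("RFMetrics", peak = max(m), meanPower = mean(m^2),
      channelPower = rowMeans(m^2))
}
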
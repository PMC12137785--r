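## Readers/writers: schema-versioned map container (serialized R object with
## mandatory b1/roi layers and optional fa layers), human-auditable pulse
## JSON, and CSV tables. All round-trips are identities; validation failures
## raise errors rather than silently coercing.

.containerSchema <- "ptx-b1-container-1"
.pulseSchema <- "ptx-pulse-1"

#' Write a B1+/ROI/FA container
#'
#' @param maps A [B1MapSet-class].
#' @param roi A [ROIMask-class] on the same grid.
#' @param faLayers named list of [FAMap-class] objects (names = pulse ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeB1Container <- function(maps, roi, faLayers = list(), path) {
  if (!all(roi@grid@shape == maps@grid@shape))
    stop("grid inconsistency between datasets b1 and roi")
  for (nm in names(faLayers)) {
    if (!all(faLayers[[nm]]@grid@shape == maps@grid@shape))
      stop(sprintf("grid inconsistency between datasets b1 and fa/%s", nm))
  }
  obj <- list(
    schema = .containerSchema,
    grid = list(shape = maps@grid@shape, spacing = maps@grid@spacing,
                origin = maps@grid@origin),
    b1 = list(data = maps@data, normalized = maps@normalized,
              meta = maps@meta),
    roi = list(mask = roi@mask),
    fa = lapply(faLayers, function(f)
      list(fa = f@fa, provenance = f@provenance))
  )
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read a B1+/ROI/FA container
#'
#' @param path container file path.
#' @return list with `b1` ([B1MapSet-class]), `roi` ([ROIMask-class]) and
#'   `fa` (named list of [FAMap-class]).
#' @export
readB1Container <- function(path) {
  if (!file.exists(path)) stop(sprintf("container not found: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$schema) ||
      !identical(obj$schema, .containerSchema))
    stop(sprintf("unsupported container schema '%s' (expected '%s')",
                 if (is.list(obj)) obj$schema %||% "<missing>" else
                   "<not a container>", .containerSchema))
  for (layer in c("b1", "roi"))
    if (is.null(obj[[layer]]))
      stop(sprintf("container is missing required layer /%s", layer))
  grid <- new("GridSpec", shape = obj$grid$shape,
              spacing = obj$grid$spacing, origin = obj$grid$origin)
  b1 <- new("B1MapSet", grid = grid, data = obj$b1$data,
            normalized = obj$b1$normalized, meta = obj$b1$meta)
  roi <- new("ROIMask", grid = grid, mask = obj$roi$mask)
  fa <- lapply(obj$fa, function(f)
    new("FAMap", grid = grid, fa = f$fa, provenance = f$provenance))
  list(b1 = b1, roi = roi, fa = fa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Container inventory
#'
#' @param path container file path.
#' @return list with `schema`, `layers` and `faIds` (pulse ids of stored
#'   flip-angle layers).
#' @export
containerInventory <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$schema))
    stop("not a map container")
  list(schema = obj$schema,
       layers = intersect(c("b1", "roi", "fa"), names(obj)),
       faIds = names(obj$fa) %||% character(0))
}

#' Write a kT-points pulse to JSON
#'
#' Complex weights are stored as separate real/imaginary C x K matrices;
#' k-space locations as a K x 3 matrix in rad/m.
#'
#' @param pulse A [KTPointsPulse-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePulse <- function(pulse, path) {
  obj <- list(
    version = pulse@version,
    method = pulse@method,
    channels = nrow(pulse@weights),
    n_kt = ncol(pulse@weights),
    target_fa_deg = pulse@targetFa,
    weights_real = Re(pulse@weights),
    weights_imag = Im(pulse@weights),
    k_locations_rad_per_m = pulse@kLocations,
    subpulse_duration_us = pulse@subpulseDuration,
    blips = pulse@blips,
    design_meta = pulse@meta,
    lambda = pulse@meta$lambda %||% NA_real_,
    seed = pulse@meta$seed %||% NA_integer_
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a kT-points pulse from JSON
#'
#' Unknown fields are tolerated with a warning; shape mismatches between the
#' declared channel/kT-point counts and the stored arrays are errors.
#'
#' @param path pulse JSON path.
#' @return A [KTPointsPulse-class].
#' @export
readPulse <- function(path) {
  if (!file.exists(path)) stop(sprintf("pulse file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  known <- c("version", "method", "channels", "n_kt", "target_fa_deg",
             "weights_real", "weights_imag", "k_locations_rad_per_m",
             "subpulse_duration_us", "blips", "design_meta", "lambda",
             "seed")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning(sprintf("ignoring unknown pulse fields: %s",
                    paste(extra, collapse = ", ")))
  if (!identical(obj$version, .pulseSchema))
    stop(sprintf("unsupported pulse schema '%s' (expected '%s')",
                 obj$version %||% "<missing>", .pulseSchema))
  wr <- .asMatrix(obj$weights_real, obj$channels)
  wi <- .asMatrix(obj$weights_imag, obj$channels)
  if (!all(dim(wr) == c(obj$channels, obj$n_kt)))
    stop(sprintf("weights have shape %s; expected (%d, %d)",
                 paste(dim(wr), collapse = ", "), obj$channels, obj$n_kt))
  k <- .asMatrix(obj$k_locations_rad_per_m, obj$n_kt)
  if (is.null(dim(k)) || nrow(k) != obj$n_kt || ncol(k) != 3L)
    stop(sprintf("pulse declares n_kt = %d but stores %d k-space locations",
                 obj$n_kt, NROW(k)))
  blips <- list()
  if (length(obj$blips)) {
    blips <- lapply(seq_len(obj$n_kt - 1L), function(j) {
      bl <- if (is.data.frame(obj$blips)) lapply(obj$blips, `[[`, j)
        else obj$blips[[j]]
      list(amplitude_mT_m = as.numeric(unlist(bl$amplitude_mT_m)),
           ramp_us = as.numeric(unlist(bl$ramp_us)),
           flat_us = as.numeric(unlist(bl$flat_us)),
           duration_us = as.numeric(bl$duration_us))
    })
  }
  meta <- obj$design_meta
  if (is.null(meta)) meta <- list()
  new("KTPointsPulse",
      weights = matrix(complex(real = wr, imaginary = wi),
                       obj$channels, obj$n_kt),
      kLocations = matrix(as.numeric(k), obj$n_kt, 3),
      subpulseDuration = obj$subpulse_duration_us,
      blips = blips, targetFa = obj$target_fa_deg,
      method = obj$method, meta = meta, version = obj$version)
}

.asMatrix <- function(x, nrowExpect) {
  if (is.null(dim(x))) x <- matrix(x, nrow = nrowExpect)
  as.matrix(x)
}
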
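#' Write / read the array-container interchange format
#'
#' Stacks and compression series are stored as a single container file
#' (R serialization of the named arrays plus metadata, schema
#' `mmoct-container-1`) accompanied by a human-readable JSON metadata
#' sidecar (`<path>.json`) carrying the acquisition geometry (pitches,
#' wavelength, refractive index, seed). Complex-valued frames do not fit
#' standard bio-image formats cleanly, which is why one canonical container
#' is used; intensity-only data can additionally be exported as multi-page
#' TIFF ([export_tiff()]).
#'
#' @param x A [cpoct_stack()] or [compression_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  kind <- if (inherits(x, "cpoct_stack")) "cpoct_stack"
          else if (inherits(x, "compression_series")) "compression_series"
          else stopf("'x' must be a cpoct_stack or compression_series")
  payload <- list(schema = "mmoct-container-1", kind = kind, data = unclass(x))
  saveRDS(payload, path)
  meta <- x[setdiff(names(x), c("co", "cross", "frames", "tissue_mask"))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

container_required_fields <- list(
  cpoct_stack = c("co", "cross", "axial_pitch_air", "n_tissue"),
  compression_series = c("frames", "axial_pitch_air", "n_tissue", "wavelength",
                         "reference_region", "E_ref"))

#' @rdname write_container
#' @param path Path written by [write_container()].
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stopf("container file not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stopf("corrupt container '%s': %s", path, conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$schema, "mmoct-container-1")) {
    stopf("unrecognized container schema in '%s'", path)
  }
  kind <- payload$kind
  need <- container_required_fields[[kind]]
  missing <- need[!vapply(payload$data[need], function(f) !is.null(f), TRUE)]
  if (length(missing)) {
    stopf("container '%s' is missing required field(s): %s", path,
          paste(missing, collapse = ", "))
  }
  d <- payload$data
  if (kind == "cpoct_stack") {
    cpoct_stack(d$co, d$cross, d$axial_pitch_air, d$n_tissue,
                d$lateral_pitch %||% NA_real_, d$wavelength %||% 1.3,
                d$meta %||% list())
  } else {
    compression_series(d$frames, d$axial_pitch_air, d$n_tissue, d$wavelength,
                       d$reference_region, d$E_ref, d$tissue_mask,
                       d$meta %||% list())
  }
}

#' Export / import intensity channels as multi-page TIFF
#'
#' Each channel page is scaled into `[0, 1]` by its maximum before writing;
#' the scale factors and geometry are recorded in a JSON sidecar so that
#' [import_tiff()] restores the original values to 32-bit float precision.
#'
#' @param stack A [cpoct_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
export_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "cpoct_stack"))
  scales <- c(co = max(stack$co, 1e-300), cross = max(stack$cross, 1e-300))
  pages <- list(stack$co / scales[["co"]], stack$cross / scales[["cross"]])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = c("co", "cross"), scales = as.list(scales),
         axial_pitch_air = stack$axial_pitch_air, n_tissue = stack$n_tissue,
         lateral_pitch = stack$lateral_pitch, wavelength = stack$wavelength),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_tiff
#' @export
import_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("TIFF sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cpoct_stack(co = pages[[1]] * meta$scales$co,
              cross = pages[[2]] * meta$scales$cross,
              axial_pitch_air = meta$axial_pitch_air, n_tissue = meta$n_tissue,
              lateral_pitch = meta$lateral_pitch %||% NA_real_,
              wavelength = meta$wavelength %||% 1.3)
}
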
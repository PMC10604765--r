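#' Write a cine loop container
#'
#' Serializes a validated [cine_loop()] to a single-file container
#' (R serialization, version 3) holding the channel arrays under their
#' canonical names — `tissue`, `velocity`, `confidence`, `truth` — a
#' channel manifest, and the metadata attributes `pixel_pitch_mm`,
#' `prf_hz`, `period_s`, `frame_times_s`. The round trip through
#' [read_cine()] is lossless (bit-identical channels).
#'
#' @param cine A `cine_loop`.
#' @param path Output path (conventional extension `.rds`).
#' @return The path, invisibly.
#' @export
write_cine <- function(cine, path) {
  validate_cine(cine)
  present <- c("tissue",
               if (!is.null(cine$velocity)) "velocity",
               if (!is.null(cine$confidence)) "confidence",
               if (!is.null(cine$truth)) "truth")
  obj <- list(
    format = "bsiflow-cine", version = 1L, channels = present,
    tissue = cine$tissue, velocity = cine$velocity,
    confidence = cine$confidence, truth = cine$truth,
    pixel_pitch_mm = cine$meta$pixel_pitch,
    prf_hz = cine$meta$prf,
    period_s = cine$meta$period,
    frame_times_s = cine$meta$frame_times
  )
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read a cine loop container
#'
#' Reads a container written by [write_cine()] and validates its schema:
#' every channel listed in the manifest must be present (a missing one
#' raises a validation error naming it), and all cine invariants are
#' re-checked. Legacy containers lacking the cardiac period must be read
#' with an explicit `period`.
#'
#' @param path Container path.
#' @param period Cardiac period in seconds, required only when the file
#'   lacks a `period_s` attribute.
#' @return A `cine_loop`.
#' @export
read_cine <- function(path, period = NULL) {
  if (!file.exists(path)) {
    bsi_validation_error(paste0("file not found: ", path))
  }
  obj <- readRDS(path)
  if (!identical(obj$format, "bsiflow-cine")) {
    bsi_validation_error("not a bsiflow cine container")
  }
  for (ch in obj$channels) {
    if (is.null(obj[[ch]])) {
      bsi_validation_error(paste0(
        "container is missing channel '", ch, "' listed in its manifest"
      ))
    }
  }
  if (is.null(obj$tissue)) {
    bsi_validation_error("container is missing channel 'tissue'")
  }
  per <- obj$period_s %||% period
  if (is.null(per)) {
    bsi_validation_error(
      "container has no 'period_s' attribute; supply --period (the cardiac period in seconds)"
    )
  }
  cine_loop(tissue = obj$tissue, velocity = obj$velocity,
            confidence = obj$confidence,
            pixel_pitch = obj$pixel_pitch_mm, prf = obj$prf_hz,
            period = per, frame_times = obj$frame_times_s,
            truth = obj$truth)
}

#' Export tissue frames as a multi-page TIFF
#'
#' Writes the brightness channel (rescaled to [0, 1] over the whole loop)
#' for visual inspection. Requires the optional `tiff` package.
#'
#' @param cine A `cine_loop`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_tissue_tiff <- function(cine, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    bsi_validation_error("package 'tiff' is required for TIFF export")
  }
  validate_cine(cine)
  lo <- min(cine$tissue); hi <- max(cine$tissue)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(cine)), function(k) {
    (cine$tissue[k, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}
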
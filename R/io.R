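# Disk I/O: phantoms and reports are written as plain/multi-page TIFF, PNG,
# CSV and JSON. Volumes are stored one z-plane per TIFF page with a JSON
# sidecar carrying the voxel geometry, intensity scale and full phantom spec
# (including the seed), so a written phantom can be regenerated or reloaded
# exactly.

#' Write a specimen phantom to a directory
#'
#' Writes `oct.ome.tif` and `labels.ome.tif` as z-stacks (one page per
#' depth), `rcm.tif`, `fl.tif`, `photo.tif` as single images, and
#' `phantom.json` with the full spec (seed included) plus the intensity
#' scale used to map the OCT volume into TIFF range.
#'
#' @param phantom a [specimen_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "specimen_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(phantom$oct)
  oct_max <- max(phantom$oct)
  scale <- if (oct_max > 0) oct_max else 1
  pages <- lapply(seq_len(d[1]), function(z) phantom$oct[z, , ] / scale)
  tiff::writeTIFF(pages, file.path(dir, "oct.ome.tif"), bits.per.sample = 32L)
  lab_pages <- lapply(seq_len(d[1]), function(z) phantom$labels[z, , ] / 255)
  tiff::writeTIFF(lab_pages, file.path(dir, "labels.ome.tif"),
                  bits.per.sample = 8L)
  if (!is.null(phantom$fl)) {
    fmax <- max(phantom$fl)
    tiff::writeTIFF(pmax(phantom$fl, 0) / max(fmax, 1e-12),
                    file.path(dir, "fl.tif"), bits.per.sample = 32L)
  }
  if (!is.null(phantom$photo)) {
    tiff::writeTIFF(phantom$photo, file.path(dir, "photo.tif"),
                    bits.per.sample = 8L)
  }
  if (!is.null(phantom$rcm)) {
    r <- phantom$rcm
    tiff::writeTIFF(r / max(max(r), 1e-12), file.path(dir, "rcm.tif"),
                    bits.per.sample = 32L)
  }
  meta <- phantom$spec
  class(meta) <- NULL
  meta$class_params <- lapply(meta$class_params, as.list)
  jsonlite::write_json(list(spec = meta, oct_scale = scale,
                            dim_zxy = d, label_scale = 255),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an OCT volume from a multi-page TIFF
#'
#' Reads a z-stack written by [write_phantom()] (or any volume in the same
#' one-page-per-depth layout) back into a `(nz, nx, ny)` array, applying the
#' sidecar intensity scale when `phantom.json` sits next to the file.
#'
#' @param path TIFF file path.
#' @return numeric array `(nz, nx, ny)`.
#' @export
read_oct_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  sidecar <- file.path(dirname(path), "phantom.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (grepl("^oct", basename(path)) && !is.null(meta$oct_scale)) {
      arr <- arr * meta$oct_scale
    }
    if (grepl("^labels", basename(path)) && !is.null(meta$label_scale)) {
      arr <- round(arr * meta$label_scale)
      storage.mode(arr) <- "integer"
    }
  }
  arr
}

#' Write the artifacts of a margin report
#'
#' Writes the margin mask and overlay as PNG, the component areas and
#' surface class fractions as CSV, the stage log as text, and a JSON report
#' (specimen call, areas, configuration echo).
#'
#' @param report a `margin_report` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_margin_report <- function(report, dir) {
  stopifnot(inherits(report, "margin_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(report$margin$mask * 1, file.path(dir, "margin_mask.png"))
  png::writePNG(report$overlay, file.path(dir, "overlay.png"))
  areas <- report$margin$component_areas_mm2
  utils::write.csv(data.frame(component = seq_along(areas), area_mm2 = areas),
                   file.path(dir, "margin_components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(class = names(report$class_fractions),
                              surface_fraction = unname(report$class_fractions)),
                   file.path(dir, "class_fractions.csv"), row.names = FALSE)
  writeLines(report$log, file.path(dir, "pipeline.log"))
  cfg <- report$config
  class(cfg) <- NULL
  cfg$training$classifier <- NULL      # not serializable as JSON scalars
  cfg$phantom <- if (inherits(cfg$phantom, "specimen_phantom")) {
    list(note = "in-memory phantom supplied directly")
  } else cfg$phantom
  jsonlite::write_json(
    list(specimen_id = report$specimen_id,
         call = report$call,
         margin_area_mm2 = sum(areas),
         n_components = length(areas),
         class_fractions = as.list(report$class_fractions),
         thresholds = as.list(coef(report$classifier)),
         stitch_error_px = report$stitch_error_px,
         depth_decay_per_mm = report$depth_gain$rate_per_mm,
         config = cfg),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export an ROI feature table as CSV
#'
#' Header columns are the nine feature names (see [feature_names()]) plus
#' an optional class column.
#'
#' @param features data.frame of ROI features.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
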
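# Raster and table I/O for pipeline intermediates.
#
# Rasters go to multi-page 32-bit float TIFF (one page per band). TIFF
# float storage is defined on [0, 1], so values are divided by a scale
# factor recorded, together with the band set and image kind, in a JSON
# sidecar next to the raster.

#' Write a multiband image as a multi-page float TIFF
#'
#' @param image A [multiband_image()].
#' @param path Output `.tif` path; a `<path>.json` sidecar records the
#'   scale factor, kind and band set.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(image, path) {
  vals <- image$values
  lo <- min(vals, 0)
  scale <- max(vals - lo, 1e-12)
  pages <- lapply(seq_len(dim(vals)[3]), function(b) {
    (vals[, , b] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = image$kind, shift = lo, scale = scale,
               centers = image$bands$centers, width = image$bands$width)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multiband image written by [write_raster_tiff()]
#'
#' @param path `.tif` path with its JSON sidecar.
#' @return A [multiband_image()] (values carry float32 precision).
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- array(NA_real_, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                  length(pages)))
  for (b in seq_along(pages)) {
    vals[, , b] <- pages[[b]] * meta$scale + meta$shift
  }
  multiband_image(vals, band_set(meta$centers, meta$width), meta$kind)
}

#' Write an abundance map as a multi-page float TIFF
#'
#' One page per endmember plane plus a final residual-norm page; plane
#' names go to the JSON sidecar. An optional 8-bit export rescales each
#' abundance plane to 0-255 grey for visual inspection.
#'
#' @param abund An [abundance_map()].
#' @param path Output `.tif` path.
#' @param grey8 Optional path for an additional 8-bit grey export.
#' @return `path`, invisibly.
#' @export
write_abundance_tiff <- function(abund, path, grey8 = NULL) {
  resid <- abund$residual_norm
  rscale <- max(resid, 1e-12)
  pages <- c(lapply(seq_along(abund$names), function(k) abund$values[, , k]),
             list(resid / rscale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(names = abund$names, residual_scale = rscale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(grey8)) {
    tiff::writeTIFF(lapply(seq_along(abund$names),
                           function(k) abund$values[, , k]),
                    grey8, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read an abundance map written by [write_abundance_tiff()]
#'
#' @param path `.tif` path with its JSON sidecar.
#' @return An [abundance_map()].
#' @export
read_abundance_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nk <- length(meta$names)
  vals <- array(NA_real_, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), nk))
  for (k in seq_len(nk)) vals[, , k] <- pages[[k]]
  # float32 storage can leave per-pixel sums a hair off one; renormalise
  tot <- array(rowSums(matrix(vals, ncol = nk)), dim = dim(vals)[1:2])
  for (k in seq_len(nk)) vals[, , k] <- vals[, , k] / tot
  abundance_map(vals, pages[[nk + 1]] * meta$residual_scale, meta$names)
}

#' Write a plot layout as JSON
#' @param layout A [plot_layout()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(as.data.frame(layout), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a plot layout written by [write_layout_json()]
#' @param path `.json` path.
#' @return A [plot_layout()].
#' @export
read_layout_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  plot_layout(df$plot_id, df$nitrogen,
              lapply(seq_len(nrow(df)), function(i) {
                c(df$row0[i], df$col0[i], df$n_rows[i], df$n_cols[i])
              }))
}

#' Write calibration panels as JSON
#' @param panels A [calibration_target_set()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_panels_json <- function(panels, path) {
  jsonlite::write_json(list(nominals = panels$nominals,
                            regions = panels$regions),
                       path, digits = NA)
  invisible(path)
}

#' Read calibration panels written by [write_panels_json()]
#' @param path `.json` path.
#' @return A [calibration_target_set()].
#' @export
read_panels_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_target_set(x$nominals, asplit(x$regions, 1))
}
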
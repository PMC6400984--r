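#' Calibration panel set
#'
#' Ground panels of known ("nominal") reflectance placed in the camera's
#' field of view for empirical-line calibration. Each panel is a rectangle
#' of image pixels plus its nominal reflectance; the defaults correspond to
#' a four-panel ladder of 0.06, 0.24, 0.48 and 1.0, roughly constant across
#' the visible-NIR range.
#'
#' @param nominals Numeric vector of distinct nominal reflectances in
#'   (0, 1.2].
#' @param regions List of rectangles, one per panel, each
#'   `c(row0, col0, n_rows, n_cols)` with 0-based origin.
#' @return An object of class `calibration_target_set`.
#' @export
calibration_target_set <- function(nominals, regions) {
  nominals <- as.numeric(nominals)
  if (length(nominals) < 2) stop("at least 2 panels are required", call. = FALSE)
  if (anyDuplicated(nominals)) stop("nominal reflectances must be distinct", call. = FALSE)
  if (any(nominals <= 0 | nominals > 1.2)) {
    stop("nominal reflectances must lie in (0, 1.2]", call. = FALSE)
  }
  if (length(regions) != length(nominals)) {
    stop("one region per panel is required", call. = FALSE)
  }
  regions <- lapply(regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 4 || any(r[3:4] < 1) || any(r[1:2] < 0)) {
      stop("each region must be c(row0, col0, n_rows, n_cols)", call. = FALSE)
    }
    r
  })
  structure(list(nominals = nominals, regions = regions),
            class = "calibration_target_set")
}

# mean of each band over a 0-based rectangle
rect_band_means <- function(image, rect) {
  d <- dim(image$values)
  rows <- (rect[1] + 1):(rect[1] + rect[3])
  cols <- (rect[2] + 1):(rect[2] + rect[4])
  if (max(rows) > d[1] || max(cols) > d[2]) {
    stop("region exceeds the image bounds", call. = FALSE)
  }
  apply(image$values[rows, cols, , drop = FALSE], 3, mean)
}

#' Fit per-band empirical-line calibration
#'
#' Estimates, independently for every band, the affine digital-number to
#' reflectance model `reflectance = DN * gain + offset` by ordinary least
#' squares over the calibration panels: the panel statistic is the
#' arithmetic mean DN inside each panel rectangle, and (offset, gain) solve
#' the 2-parameter normal equations against the nominal reflectances.
#'
#' @param dn_image A [multiband_image()] of kind "dn" containing all panels.
#' @param targets A [calibration_target_set()].
#' @return An object of class `calibration_model` with per-band `gain` and
#'   `offset`, the `panel_dn` means (panels x bands), and per-panel,
#'   per-band `residuals` (fitted minus nominal reflectance).
#' @examples
#' # one-band image holding a DN ladder that is exactly reflectance / 0.001
#' v <- array(rep(c(60, 240, 480, 1000), each = 4), c(2, 8, 1))
#' img <- multiband_image(v, band_set(800), "dn")
#' panels <- calibration_target_set(
#'   c(0.06, 0.24, 0.48, 1.0),
#'   list(c(0, 0, 2, 2), c(0, 2, 2, 2), c(0, 4, 2, 2), c(0, 6, 2, 2)))
#' fit_empirical_line(img, panels)  # gain 0.001, offset 0
#' @export
fit_empirical_line <- function(dn_image, targets) {
  if (!inherits(dn_image, "multiband_image") || dn_image$kind != "dn") {
    stop("'dn_image' must be a multiband_image of kind 'dn'", call. = FALSE)
  }
  if (!inherits(targets, "calibration_target_set")) {
    stop("'targets' must be a calibration_target_set", call. = FALSE)
  }
  panel_dn <- do.call(rbind, lapply(targets$regions, rect_band_means,
                                    image = dn_image))
  nb <- n_bands(dn_image$bands)
  gain <- offset <- numeric(nb)
  residuals <- matrix(NA_real_, nrow = length(targets$nominals), ncol = nb)
  for (b in seq_len(nb)) {
    dn <- panel_dn[, b]
    if (max(dn) - min(dn) < .Machine$double.eps * max(1, max(abs(dn)))) {
      stop("panel-mean DNs are identical in band ",
           dn_image$bands$centers[b], " nm: singular design", call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, dn), targets$nominals)
    offset[b] <- fit$coefficients[1]
    gain[b] <- fit$coefficients[2]
    residuals[, b] <- (offset[b] + gain[b] * dn) - targets$nominals
  }
  structure(list(gain = gain, offset = offset, panel_dn = panel_dn,
                 residuals = residuals, bands = dn_image$bands,
                 nominals = targets$nominals),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> per-band empirical line\n")
  print(data.frame(center_nm = x$bands$centers, gain = signif(x$gain, 6),
                   offset = signif(x$offset, 6),
                   max_abs_residual = signif(apply(abs(x$residuals), 2, max), 3)))
  invisible(x)
}

#' Apply an empirical-line model to a DN image
#'
#' Per-pixel, per-band affine transform `reflectance = DN * gain + offset`.
#' Values are deliberately not clipped to the unit interval: clipping would
#' bias downstream vegetation indices and unmixing. The fraction of
#' out-of-range pixels is available via [calibration_qc()].
#'
#' @param dn_image A [multiband_image()] of kind "dn".
#' @param model A `calibration_model` fitted on the same band set.
#' @return A [multiband_image()] of kind "reflectance".
#' @export
apply_calibration <- function(dn_image, model) {
  if (!inherits(dn_image, "multiband_image") || dn_image$kind != "dn") {
    stop("'dn_image' must be a multiband_image of kind 'dn'", call. = FALSE)
  }
  nb <- dim(dn_image$values)[3]
  if (nb != length(model$gain)) {
    stop("band count of the image (", nb, ") does not match the model (",
         length(model$gain), ")", call. = FALSE)
  }
  refl <- dn_image$values
  for (b in seq_len(nb)) {
    refl[, , b] <- refl[, , b] * model$gain[b] + model$offset[b]
  }
  multiband_image(refl, dn_image$bands, "reflectance")
}

#' Out-of-range QC summary for a reflectance image
#'
#' Reports, per band, the fraction of pixels whose calibrated reflectance
#' falls outside the physical range 0 to 1.
#'
#' @param refl_image A [multiband_image()] of kind "reflectance".
#' @return Data frame with band centers and the below-zero / above-one
#'   fractions.
#' @export
calibration_qc <- function(refl_image) {
  if (!inherits(refl_image, "multiband_image") ||
      refl_image$kind != "reflectance") {
    stop("'refl_image' must be a reflectance multiband_image", call. = FALSE)
  }
  npx <- prod(dim(refl_image$values)[1:2])
  data.frame(
    center_nm = refl_image$bands$centers,
    frac_below_0 = apply(refl_image$values < 0, 3, sum) / npx,
    frac_above_1 = apply(refl_image$values > 1, 3, sum) / npx
  )
}
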
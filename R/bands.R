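#' Six-band camera band set
#'
#' Describes the spectral sampling of a multi-camera array: one narrow
#' band-pass filter per camera, given by its center wavelength and a common
#' full band width. The default matches a Mini-MCA-style six-camera rig with
#' 10 nm filters at 490, 550, 670, 720, 800 and 900 nm.
#'
#' @param centers Numeric vector of band center wavelengths in nm, strictly
#'   increasing.
#' @param width Full band width in nm (a single positive number); each band
#'   spans `center - width/2` to `center + width/2`.
#' @return An object of class `band_set` with elements `centers` and `width`.
#' @examples
#' band_set()
#' band_set(centers = c(550, 670, 800), width = 10)
#' @export
band_set <- function(centers = c(490, 550, 670, 720, 800, 900), width = 10) {
  centers <- as.numeric(centers)
  if (length(centers) < 1 || anyNA(centers)) {
    stop("'centers' must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("band centers must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0) {
    stop("'width' must be a single positive number", call. = FALSE)
  }
  structure(list(centers = centers, width = width), class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set> ", length(x$centers), " bands, width ", x$width, " nm\n",
      "  centers: ", paste(x$centers, collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

n_bands <- function(bands) length(bands$centers)

#' Multiband raster image
#'
#' A rows x cols x bands numeric array together with its [band_set()] and a
#' `kind` flag recording whether values are raw digital numbers ("dn") or
#' surface reflectance ("reflectance").
#'
#' @param values Numeric array of dimension rows x cols x bands, all finite.
#' @param bands A [band_set()]; its length must match `dim(values)[3]`.
#' @param kind Either "dn" or "reflectance".
#' @return An object of class `multiband_image`.
#' @export
multiband_image <- function(values, bands, kind = c("dn", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("'values' must be a 3-d array (rows x cols x bands)", call. = FALSE)
  }
  if (!inherits(bands, "band_set")) stop("'bands' must be a band_set", call. = FALSE)
  if (dim(values)[3] != n_bands(bands)) {
    stop("third dimension of 'values' (", dim(values)[3],
         ") does not match the band set (", n_bands(bands), ")", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("image values must all be finite", call. = FALSE)
  structure(list(values = values, bands = bands, kind = kind),
            class = "multiband_image")
}

#' @export
print.multiband_image <- function(x, ...) {
  d <- dim(x$values)
  cat("<multiband_image> ", d[1], " x ", d[2], " px, ", d[3], " bands [",
      x$kind, "]\n", sep = "")
  cat("  value range: ", signif(min(x$values), 4), " .. ",
      signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

band_index <- function(bands, center) {
  i <- match(center, bands$centers)
  if (is.na(i)) {
    stop("band centered at ", center, " nm not present in the band set",
         call. = FALSE)
  }
  i
}
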
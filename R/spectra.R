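#' Continuous endmember spectrum
#'
#' A continuous-wavelength reflectance spectrum for one paddy-field
#' endmember, as measured by a field spectroradiometer. The six endmembers
#' of a heading-stage rice canopy are top-layer leaf (TL), bottom-layer leaf
#' (BL), top-layer panicle (TP), bottom-layer panicle (BP), dry soil (DS)
#' and wet soil (WS).
#'
#' @param name Endmember label.
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param reflectance Non-negative reflectance fractions, same length as
#'   `wavelengths`.
#' @return An object of class `continuous_spectrum`.
#' @export
continuous_spectrum <- function(name, wavelengths, reflectance) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelength and reflectance grids differ in length", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
    stop("reflectance must be finite and non-negative", call. = FALSE)
  }
  structure(list(name = as.character(name), wavelengths = wavelengths,
                 reflectance = reflectance), class = "continuous_spectrum")
}

#' @export
print.continuous_spectrum <- function(x, ...) {
  cat("<continuous_spectrum> ", x$name, ": ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm (",
      length(x$wavelengths), " samples)\n", sep = "")
  invisible(x)
}

# Anchor points (wavelength nm -> reflectance) defining the deterministic
# shape of each endmember; smooth curves are interpolated through them.
# Top-layer leaf and panicle have the classic green-peak / red-absorption /
# red-edge / NIR-plateau shape; panicle has weaker NIR, stronger red.
# Bottom-layer spectra are shaded (scaled-down) copies; soils are gently
# increasing lines with wet soil darker than dry soil at all wavelengths.
.endmember_anchors <- function() {
  wl_veg <- c(450, 490, 520, 550, 600, 670, 700, 720, 750, 800, 850, 900, 950)
  tl <- c(0.055, 0.070, 0.090, 0.120, 0.090, 0.050, 0.120, 0.250, 0.420,
          0.450, 0.455, 0.460, 0.460)
  tp <- c(0.045, 0.050, 0.070, 0.100, 0.090, 0.080, 0.120, 0.180, 0.270,
          0.300, 0.310, 0.320, 0.320)
  # shading attenuates the NIR plateau more than the visible range, so the
  # bottom-layer spectra are not scalar copies of their top-layer versions
  shade_leaf <- 0.62 - 0.30 / (1 + exp(-(wl_veg - 700) / 25))
  shade_pan <- 0.48 - 0.12 / (1 + exp(-(wl_veg - 700) / 25))
  wl_soil <- c(450, 550, 670, 720, 800, 900, 950)
  ds <- c(0.090, 0.130, 0.180, 0.200, 0.230, 0.260, 0.270)
  list(
    TL = list(wl = wl_veg, r = tl),
    BL = list(wl = wl_veg, r = shade_leaf * tl),
    TP = list(wl = wl_veg, r = tp),
    BP = list(wl = wl_veg, r = shade_pan * tp),
    DS = list(wl = wl_soil, r = ds),
    WS = list(wl = wl_soil, r = 0.55 * ds)
  )
}

#' Generate the six-endmember paddy spectral library
#'
#' Produces smooth synthetic reflectance spectra for the six heading-stage
#' endmembers (TL, BL, TP, BP, DS, WS) on a 1 nm grid. The deterministic
#' shapes encode the qualitative contrasts seen in field-measured paddy
#' spectra: leaf slightly brighter than panicle in the blue (about 7% vs
#' 5%), much brighter in the NIR; panicle brighter in the red; bottom-layer
#' (shaded) spectra darker than their top-layer counterparts at all bands
#' while keeping leaf above panicle in the NIR; and wet soil darker than dry
#' soil at every wavelength. A seeded low-frequency multiplicative wiggle
#' (2% amplitude) individualises each draw without disturbing these
#' orderings.
#'
#' @param seed Integer seed; the same seed always returns identical spectra.
#' @param band_range Length-2 numeric, the wavelength interval (nm) the
#'   spectra must cover; must contain 480-910 nm so the default six bands
#'   can be resampled.
#' @return A named list of six [continuous_spectrum()] objects in the order
#'   TL, BL, TP, BP, DS, WS.
#' @examples
#' lib <- generate_endmember_library(seed = 1)
#' sapply(lib, function(s) s$reflectance[s$wavelengths == 490])
#' @export
generate_endmember_library <- function(seed = 1, band_range = c(450, 950)) {
  band_range <- as.numeric(band_range)
  if (length(band_range) != 2 || band_range[1] > 480 || band_range[2] < 910) {
    stop("'band_range' must cover at least 480-910 nm", call. = FALSE)
  }
  anchors <- .endmember_anchors()
  grid <- seq(band_range[1], band_range[2], by = 1)
  with_seed(seed, {
    out <- lapply(names(anchors), function(nm) {
      a <- anchors[[nm]]
      base <- stats::spline(a$wl, a$r, xout = grid, method = "fmm")$y
      # low-frequency seeded wiggle, bounded well inside the ordering margins
      ph <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(3, 0, 0.02 / 3)
      wig <- 1 + amp[1] * sin(2 * pi * grid / 400 + ph[1]) +
        amp[2] * sin(2 * pi * grid / 250 + ph[2]) +
        amp[3] * sin(2 * pi * grid / 150 + ph[3])
      continuous_spectrum(nm, grid, pmax(base * wig, 0))
    })
    names(out) <- names(anchors)
    out
  })
}

#' Average a continuous spectrum over a camera band
#'
#' Resamples a continuous spectrum to discrete camera bands by averaging the
#' reflectance over each closed band interval `center - width/2` to
#' `center + width/2`, matching how narrow-band camera reflectance is
#' emulated from spectroradiometer measurements. The average is the
#' trapezoid-rule integral of the piecewise-linear spectrum divided by the
#' band width, so it is exact for non-uniform wavelength grids.
#'
#' @param spectrum A [continuous_spectrum()].
#' @param bands A [band_set()]; the spectrum must cover every band interval.
#' @return Numeric vector of per-band reflectance, one value per band.
#' @examples
#' s <- continuous_spectrum("x", 400:1000, (400:1000) / 1000)
#' resample_to_bands(s, band_set())  # midpoint values of a linear spectrum
#' @export
resample_to_bands <- function(spectrum, bands) {
  if (!inherits(spectrum, "continuous_spectrum")) {
    stop("'spectrum' must be a continuous_spectrum", call. = FALSE)
  }
  if (!inherits(bands, "band_set")) stop("'bands' must be a band_set", call. = FALSE)
  wl <- spectrum$wavelengths
  rf <- spectrum$reflectance
  half <- bands$width / 2
  vapply(bands$centers, function(ctr) {
    lo <- ctr - half
    hi <- ctr + half
    if (lo < wl[1] || hi > wl[length(wl)]) {
      stop("spectrum '", spectrum$name, "' does not cover the band at ",
           ctr, " nm (", lo, "-", hi, " nm)", call. = FALSE)
    }
    inside <- wl > lo & wl < hi
    x <- c(lo, wl[inside], hi)
    y <- c(stats::approx(wl, rf, xout = lo)$y, rf[inside],
           stats::approx(wl, rf, xout = hi)$y)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2) / (hi - lo)
  }, numeric(1))
}

#' Endmember reference library
#'
#' The N endmembers x B bands reference reflectance matrix used by the
#' linear mixing model, with its band set and a fixed, recorded row order
#' (default TL, BL, TP, BP, DS, WS).
#'
#' @param names Character vector of unique endmember labels.
#' @param matrix N x B numeric matrix of non-negative reflectance.
#' @param bands The [band_set()] the columns refer to.
#' @return An object of class `endmember_library`.
#' @export
endmember_library <- function(names, matrix, bands) {
  matrix <- as.matrix(matrix)
  if (anyDuplicated(names)) stop("endmember names must be unique", call. = FALSE)
  if (nrow(matrix) != length(names)) {
    stop("row count does not match the number of names", call. = FALSE)
  }
  if (ncol(matrix) != n_bands(bands)) {
    stop("column count does not match the band set", call. = FALSE)
  }
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("library reflectance must be finite and non-negative", call. = FALSE)
  }
  dimnames(matrix) <- list(names, paste0("b", bands$centers))
  structure(list(names = as.character(names), matrix = matrix, bands = bands),
            class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat("<endmember_library> ", nrow(x$matrix), " endmembers x ",
      ncol(x$matrix), " bands\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Build an unmixing library from continuous spectra
#'
#' Resamples each continuous endmember spectrum to the camera bands with
#' [resample_to_bands()] and stacks the results into the N x B reference
#' matrix, preserving the input order.
#'
#' @param spectra A list of [continuous_spectrum()] objects with unique
#'   names.
#' @param bands A [band_set()].
#' @return An [endmember_library()].
#' @examples
#' lib <- build_library(generate_endmember_library(seed = 1), band_set())
#' lib$matrix["TL", ]
#' @export
build_library <- function(spectra, bands = band_set()) {
  nms <- vapply(spectra, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate endmember names", call. = FALSE)
  mat <- t(vapply(spectra, resample_to_bands, numeric(n_bands(bands)),
                  bands = bands))
  endmember_library(nms, mat, bands)
}

#' Write endmember spectra to CSV
#'
#' One `wavelength_nm` column followed by one reflectance column per
#' endmember; all spectra must share a wavelength grid.
#'
#' @param spectra List of [continuous_spectrum()] on a common grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (!identical(s$wavelengths, wl)) {
      stop("all spectra must share one wavelength grid", call. = FALSE)
    }
  }
  df <- data.frame(wavelength_nm = wl)
  for (s in spectra) df[[s$name]] <- s$reflectance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read endmember spectra from CSV
#'
#' Inverse of [write_spectra_csv()].
#'
#' @param path CSV path with a `wavelength_nm` column and one column per
#'   endmember.
#' @return Named list of [continuous_spectrum()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    stop("missing 'wavelength_nm' column in ", path, call. = FALSE)
  }
  nms <- setdiff(names(df), "wavelength_nm")
  out <- lapply(nms, function(nm) {
    continuous_spectrum(nm, df$wavelength_nm, df[[nm]])
  })
  names(out) <- nms
  out
}

#' Write an endmember library to CSV
#'
#' Rows are endmembers; the header records the band centers.
#'
#' @param library An [endmember_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  df <- data.frame(endmember = library$names, library$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an endmember library from CSV
#'
#' @param path CSV written by [write_library_csv()].
#' @param width Band width in nm for the reconstructed [band_set()].
#' @return An [endmember_library()].
#' @export
read_library_csv <- function(path, width = 10) {
  df <- utils::read.csv(path, check.names = FALSE)
  centers <- as.numeric(sub("^b", "", setdiff(names(df), "endmember")))
  endmember_library(df$endmember,
                    as.matrix(df[, setdiff(names(df), "endmember")]),
                    band_set(centers, width))
}
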
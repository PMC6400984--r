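# Registry of the ten tested vegetation indices. Each entry gives the bands
# (by center wavelength, nm) it needs and its numerator/denominator-style
# formula over per-pixel reflectance. VARI is used in its green-red
# two-band form, (rho550 - rho670) / (rho550 + rho670), without the blue
# term of some published variants; see the package vignette.
.vi_registry <- list(
  SR = list(bands = c(670, 800),
            fn = function(r) list(v = r[["800"]], d = r[["670"]])),
  CIrededge = list(bands = c(720, 800),
                   fn = function(r) list(v = r[["800"]], d = r[["720"]],
                                         post = function(q) q - 1)),
  CIgreen = list(bands = c(550, 800),
                 fn = function(r) list(v = r[["800"]], d = r[["550"]],
                                       post = function(q) q - 1)),
  NDVI = list(bands = c(670, 800),
              fn = function(r) list(v = r[["800"]] - r[["670"]],
                                    d = r[["800"]] + r[["670"]])),
  GNDVI = list(bands = c(550, 800),
               fn = function(r) list(v = r[["800"]] - r[["550"]],
                                     d = r[["800"]] + r[["550"]])),
  NDRE = list(bands = c(720, 800),
              fn = function(r) list(v = r[["800"]] - r[["720"]],
                                    d = r[["800"]] + r[["720"]])),
  VARI = list(bands = c(550, 670),
              fn = function(r) list(v = r[["550"]] - r[["670"]],
                                    d = r[["550"]] + r[["670"]])),
  MTCI = list(bands = c(670, 720, 800),
              fn = function(r) list(v = r[["800"]] - r[["720"]],
                                    d = r[["720"]] - r[["670"]])),
  EVI = list(bands = c(490, 670, 800),
             fn = function(r) list(v = 2.5 * (r[["800"]] - r[["670"]]),
                                   d = r[["800"]] + 6 * r[["670"]] -
                                     7.5 * r[["490"]] + 1)),
  EVI2 = list(bands = c(670, 800),
              fn = function(r) list(v = 2.5 * (r[["800"]] - r[["670"]]),
                                    d = r[["800"]] + 2.4 * r[["670"]] + 1))
)

#' Names of the available vegetation indices
#'
#' @return Character vector of the ten registered index names.
#' @export
vi_names <- function() names(.vi_registry)

#' Per-pixel vegetation index
#'
#' Evaluates one of the ten registered vegetation indices at every pixel of
#' a reflectance image. Pixels whose denominator magnitude falls below
#' `1e-9` (e.g. the MTCI denominator on soil pixels where the red-edge and
#' red reflectance coincide) are masked invalid rather than propagated as
#' huge ratios.
#'
#' @param image A [multiband_image()] of kind "reflectance" containing the
#'   bands the index requires.
#' @param vi Index name, one of [vi_names()].
#' @return List of class `vi_image`: `name`, `values` (rows x cols matrix,
#'   `NA` where masked) and `valid` (logical matrix).
#' @examples
#' img <- multiband_image(array(c(0.1, 0.5), c(1, 1, 2)),
#'                        band_set(c(670, 800)), "reflectance")
#' compute_vi(img, "NDVI")$values  # (0.5 - 0.1) / (0.5 + 0.1)
#' @export
compute_vi <- function(image, vi) {
  if (!inherits(image, "multiband_image") || image$kind != "reflectance") {
    stop("'image' must be a multiband_image of kind 'reflectance'", call. = FALSE)
  }
  def <- .vi_registry[[vi]]
  if (is.null(def)) {
    stop("unknown vegetation index '", vi, "'; see vi_names()", call. = FALSE)
  }
  missing <- setdiff(def$bands, image$bands$centers)
  if (length(missing)) {
    stop(vi, " needs band(s) at ", paste(missing, collapse = ", "),
         " nm, absent from the image", call. = FALSE)
  }
  r <- lapply(def$bands, function(ctr) {
    image$values[, , band_index(image$bands, ctr)]
  })
  names(r) <- as.character(def$bands)
  parts <- def$fn(r)
  valid <- abs(parts$d) >= 1e-9
  vals <- parts$v / parts$d
  if (!is.null(parts$post)) vals <- parts$post(vals)
  vals[!valid] <- NA_real_
  vals <- matrix(vals, nrow = dim(image$values)[1])
  structure(list(name = vi, values = vals,
                 valid = matrix(valid, nrow = dim(image$values)[1])),
            class = "vi_image")
}

#' Plot-level vegetation index means
#'
#' Averages a per-pixel vegetation index over each plot rectangle, using
#' only unmasked pixels (per-pixel index first, spatial mean second). The
#' fraction of invalid pixels is reported per plot.
#'
#' @param vi_image Output of [compute_vi()].
#' @param layout A [plot_layout()].
#' @return Data frame with `plot_id`, the mean index value (named after the
#'   index) and `invalid_frac`.
#' @export
aggregate_vi <- function(vi_image, layout) {
  if (!inherits(vi_image, "vi_image")) {
    stop("'vi_image' must come from compute_vi()", call. = FALSE)
  }
  d <- c(dim(vi_image$values), 1)
  out <- data.frame(plot_id = layout$plot_id,
                    value = NA_real_, invalid_frac = NA_real_)
  for (i in seq_len(nrow(layout))) {
    px <- layout_pixel_index(layout[i, ], d)
    vals <- vi_image$values[px$rows, px$cols]
    ok <- vi_image$valid[px$rows, px$cols]
    if (!any(ok)) {
      stop("plot '", layout$plot_id[i], "' has no valid ", vi_image$name,
           " pixels", call. = FALSE)
    }
    out$value[i] <- mean(vals[ok])
    out$invalid_frac[i] <- 1 - mean(ok)
  }
  names(out)[2] <- vi_image$name
  out
}
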
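#' Plot layout
#'
#' Rectangular regions of interest, one per field plot, with nitrogen-rate
#' labels. Rectangles are `c(row0, col0, n_rows, n_cols)` with a 0-based
#' origin and half-open extent, mirroring the "maximum rectangle that fits
#' the plot" convention used for plot-level averaging.
#'
#' @param plot_id Unique plot identifiers.
#' @param nitrogen Nitrogen application rate per plot (kg/ha).
#' @param rectangles List of `c(row0, col0, n_rows, n_cols)` integer
#'   vectors.
#' @return A data frame of class `plot_layout` with columns `plot_id`,
#'   `nitrogen`, `row0`, `col0`, `n_rows`, `n_cols`.
#' @export
plot_layout <- function(plot_id, nitrogen, rectangles) {
  if (anyDuplicated(plot_id)) stop("plot ids must be unique", call. = FALSE)
  if (length(plot_id) != length(rectangles) ||
      length(plot_id) != length(nitrogen)) {
    stop("plot_id, nitrogen and rectangles must have equal length", call. = FALSE)
  }
  rect <- do.call(rbind, lapply(rectangles, function(r) {
    r <- as.integer(r)
    if (length(r) != 4 || any(r[1:2] < 0) || any(r[3:4] < 1)) {
      stop("each rectangle must be c(row0, col0, n_rows, n_cols)", call. = FALSE)
    }
    r
  }))
  out <- data.frame(plot_id = plot_id, nitrogen = nitrogen,
                    row0 = rect[, 1], col0 = rect[, 2],
                    n_rows = rect[, 3], n_cols = rect[, 4])
  class(out) <- c("plot_layout", "data.frame")
  out
}

layout_pixel_index <- function(layout_row, image_dim) {
  rows <- (layout_row$row0 + 1):(layout_row$row0 + layout_row$n_rows)
  cols <- (layout_row$col0 + 1):(layout_row$col0 + layout_row$n_cols)
  if (max(rows) > image_dim[1] || max(cols) > image_dim[2]) {
    stop("plot '", layout_row$plot_id, "' exceeds the image bounds",
         call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Per-pixel abundance map
#'
#' Abundance fractions estimated by fully constrained unmixing: a
#' rows x cols x N array (one plane per endmember, in library order), the
#' per-pixel Euclidean residual norm of the linear mixing model, and the
#' endmember names. Every abundance lies in the unit interval and each
#' pixel's abundances sum to one.
#'
#' @param values rows x cols x N abundance array.
#' @param residual_norm rows x cols matrix of non-negative residual norms.
#' @param names Endmember labels, one per plane.
#' @return An object of class `abundance_map`.
#' @export
abundance_map <- function(values, residual_norm, names) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("'values' must be a 3-d array", call. = FALSE)
  }
  if (dim(values)[3] != length(names)) {
    stop("plane count does not match the endmember names", call. = FALSE)
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("abundances must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(matrix(values, ncol = dim(values)[3]))
  if (any(abs(sums - 1) > 1e-6)) {
    stop("per-pixel abundances must sum to 1", call. = FALSE)
  }
  if (any(residual_norm < 0)) stop("residual norms must be >= 0", call. = FALSE)
  structure(list(values = values, residual_norm = residual_norm,
                 names = as.character(names)), class = "abundance_map")
}

#' @export
print.abundance_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<abundance_map> ", d[1], " x ", d[2], " px, ", d[3],
      " endmembers (", paste(x$names, collapse = ", "), ")\n",
      "  mean residual norm: ", signif(mean(x$residual_norm), 4), "\n",
      sep = "")
  invisible(x)
}

fcls_delta <- function(library) 1e3 * max(abs(library$matrix))

#' Fully constrained unmixing of one spectrum
#'
#' Estimates the endmember abundances of a single mixed spectrum under the
#' linear mixing model with both the non-negativity and the sum-to-one
#' constraint: abundances minimise the Euclidean distance between the
#' observed spectrum and the abundance-weighted combination of library
#' spectra, subject to all abundances in the unit interval and summing to
#' one. An abundance of 1 marks a pure pixel of that endmember.
#'
#' @param spectrum Numeric vector of per-band reflectance (length B).
#' @param library An [endmember_library()] with N >= 2 endmembers.
#' @return List with `abundances` (named N-vector) and `residual_norm` (the
#'   attained Euclidean residual in band space).
#' @examples
#' lib <- build_library(generate_endmember_library(seed = 1))
#' fcls_pixel(lib$matrix["TL", ], lib)$abundances  # pure pixel: TL = 1
#' @export
fcls_pixel <- function(spectrum, library) {
  res <- unmix_matrix(matrix(as.numeric(spectrum), ncol = 1), library)
  list(abundances = stats::setNames(res$abundance[, 1], library$names),
       residual_norm = res$residual_norm[1])
}

# Shared core: spectra as a B x P matrix, one pixel per column.
unmix_matrix <- function(spectra, library) {
  if (!inherits(library, "endmember_library")) {
    stop("'library' must be an endmember_library", call. = FALSE)
  }
  N <- nrow(library$matrix)
  B <- ncol(library$matrix)
  if (N < 2) stop("unmixing requires at least 2 endmembers", call. = FALSE)
  if (nrow(spectra) != B) {
    stop("spectrum length (", nrow(spectra), ") does not match the library (",
         B, " bands)", call. = FALSE)
  }
  if (any(!is.finite(spectra))) stop("spectra must be finite", call. = FALSE)
  if (B < N - 1) {
    warning("fewer bands (", B, ") than endmembers - 1 (", N - 1,
            "); abundances may be poorly determined", call. = FALSE)
  }
  fcls_batch_cpp(spectra, library$matrix, fcls_delta(library))
}

#' Unmix a reflectance image
#'
#' Applies [fcls_pixel()] independently to every pixel of a reflectance
#' image (no spatial regularisation), returning one abundance plane per
#' endmember in library order plus the per-pixel residual norm.
#'
#' @param image A [multiband_image()] of kind "reflectance".
#' @param library An [endmember_library()] on the same band set.
#' @return An [abundance_map()].
#' @export
unmix_image <- function(image, library) {
  if (!inherits(image, "multiband_image") || image$kind != "reflectance") {
    stop("'image' must be a multiband_image of kind 'reflectance'", call. = FALSE)
  }
  d <- dim(image$values)
  spectra <- t(matrix(image$values, nrow = d[1] * d[2], ncol = d[3]))
  res <- unmix_matrix(spectra, library)
  N <- nrow(library$matrix)
  abundance_map(array(t(res$abundance), dim = c(d[1], d[2], N)),
                matrix(res$residual_norm, d[1], d[2]), library$names)
}

#' Plot-level abundance aggregation
#'
#' Averages per-pixel abundances over each plot rectangle and derives the
#' summary fractions used by the yield models: leaf abundance `Abd_L` is
#' the sum of the top- and bottom-layer leaf means, panicle abundance
#' `Abd_P` the sum of the two panicle means, and `Abd_LP` their difference.
#'
#' @param abund An [abundance_map()] whose names include TL, BL, TP and BP.
#' @param layout A [plot_layout()].
#' @return Data frame with one row per plot: `plot_id`, `nitrogen`, one
#'   mean-abundance column per endmember, `Abd_L`, `Abd_P` and `Abd_LP`.
#' @export
aggregate_abundance <- function(abund, layout) {
  if (!inherits(abund, "abundance_map")) {
    stop("'abund' must be an abundance_map", call. = FALSE)
  }
  d <- dim(abund$values)
  means <- matrix(NA_real_, nrow = nrow(layout), ncol = d[3],
                  dimnames = list(NULL, abund$names))
  for (i in seq_len(nrow(layout))) {
    px <- layout_pixel_index(layout[i, ], d)
    if (length(px$rows) * length(px$cols) == 0) {
      stop("plot '", layout$plot_id[i], "' has an empty region", call. = FALSE)
    }
    means[i, ] <- apply(abund$values[px$rows, px$cols, , drop = FALSE], 3, mean)
  }
  out <- data.frame(plot_id = layout$plot_id, nitrogen = layout$nitrogen,
                    means, check.names = FALSE)
  need <- c("TL", "BL", "TP", "BP")
  if (!all(need %in% abund$names)) {
    stop("leaf/panicle summaries need endmembers TL, BL, TP, BP", call. = FALSE)
  }
  out$Abd_L <- means[, "TL"] + means[, "BL"]
  out$Abd_P <- means[, "TP"] + means[, "BP"]
  out$Abd_LP <- out$Abd_L - out$Abd_P
  out
}
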
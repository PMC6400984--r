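#' Synthetic paddy-scene configuration
#'
#' Parameters of the seeded scene generator, which emulates a
#' nitrogen-gradient rice trial imaged by a six-band UAV camera at heading
#' stage: a grid of rectangular plot regions separated by soil ridges, four
#' calibration panels, per-plot abundance fields over the six endmembers,
#' and plot yields driven by a canopy-greenness latent.
#'
#' The defaults reproduce the study design the package targets: 8 nitrogen
#' levels x 3 replicates = 24 plots of 150 x 120 = 18000 pixels each;
#' plot-mean leaf abundance concentrated near 0.93 and panicle abundance
#' near 0.06, with panicle share rising with nitrogen; and a yield
#' population with mean about 3.61 and coefficient of variation about 12%
#' (yields are treated as unitless on that scale). Panicle emergence gets a
#' large plot-to-plot random component on top of its nitrogen trend — the
#' "uneven emergence" that confounds vegetation indices at heading stage.
#'
#' @param n_nitrogen_levels Number of nitrogen levels (default 8).
#' @param replicates Plots per level (default 3); plots = levels x
#'   replicates.
#' @param plot_rows,plot_cols Pixels per plot region (default 150 x 120).
#' @param ridge Width in pixels of the soil ridges separating plots.
#' @param panel_size Side length in pixels of each calibration panel.
#' @param noise_sd_dn Gaussian DN noise standard deviation (DN units).
#' @param gain,offset True per-band calibration (reflectance-per-DN and
#'   reflectance); DN is rendered as `(reflectance - offset) / gain` plus
#'   noise.
#' @param panel_nominals Nominal reflectances of the calibration panels.
#' @param nitrogen_rates Nitrogen application rates (kg/ha), one per level.
#' @param concentration Dirichlet concentration controlling within-plot
#'   abundance scatter (larger = more uniform plots).
#' @param smooth_half Half-width of the box filter giving the abundance
#'   fields their spatial coherence (0 disables smoothing).
#' @param greenness Length-3: intercept, nitrogen slope and plot-level sd
#'   of the canopy-greenness latent `C` (unitless).
#' @param greenness_coupling Slope of the top-layer leaf share on the
#'   greenness anomaly: vigorous canopies expose more sunlit top-layer
#'   leaf, which is how greenness reaches the vegetation indices while the
#'   pixel spectra stay exact endmember mixtures.
#' @param panicle Length-4: base fraction, nitrogen slope, and mean / sd of
#'   the skewed (gamma) plot-level emergence noise of panicle abundance;
#'   the large default sd makes emergence uneven across plots, the central
#'   confound of heading-stage yield estimation.
#' @param soil_in_plot Mean soil abundance inside plot regions (ridges are
#'   soil-dominated regardless).
#' @param tl_share,tp_share Top-layer share of leaf and panicle abundance.
#' @param yield_coefficients Length-2 `c(beta0, beta1)` of the yield model
#'   `yield = beta0 + beta1 * C * (Abd_L - Abd_P) + noise`.
#' @param yield_noise_sd Yield noise sd (yield units).
#' @param library_seed Seed of [generate_endmember_library()] used for the
#'   global endmember spectra.
#' @param seed Master seed; every stochastic draw in the scene derives
#'   from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_nitrogen_levels = 8,
                         replicates = 3,
                         plot_rows = 150,
                         plot_cols = 120,
                         ridge = 6,
                         panel_size = 20,
                         noise_sd_dn = 2,
                         gain = c(0.00095, 0.00100, 0.00105, 0.00100,
                                  0.00110, 0.00115),
                         offset = c(-0.020, -0.015, -0.010, 0.005,
                                    0.010, 0.020),
                         panel_nominals = c(0.06, 0.24, 0.48, 1.0),
                         nitrogen_rates = c(0, 3, 5.5, 8.5, 11, 14,
                                            16.5, 19.5),
                         concentration = 80,
                         smooth_half = 2,
                         greenness = c(0.725, 0.25, 0.03),
                         greenness_coupling = 1.4,
                         panicle = c(0.005, 0.02, 0.05, 0.07),
                         soil_in_plot = 0.01,
                         tl_share = 0.65,
                         tp_share = 0.7,
                         yield_coefficients = c(1.55, 2.8),
                         yield_noise_sd = 0.18,
                         library_seed = 1,
                         seed = 1) {
  cfg <- list(n_nitrogen_levels = as.integer(n_nitrogen_levels),
              replicates = as.integer(replicates),
              plot_rows = as.integer(plot_rows),
              plot_cols = as.integer(plot_cols),
              ridge = as.integer(ridge), panel_size = as.integer(panel_size),
              noise_sd_dn = noise_sd_dn, gain = gain, offset = offset,
              panel_nominals = panel_nominals,
              nitrogen_rates = nitrogen_rates,
              concentration = concentration, smooth_half = as.integer(smooth_half),
              greenness = greenness, greenness_coupling = greenness_coupling,
              panicle = panicle, soil_in_plot = soil_in_plot,
              tl_share = tl_share, tp_share = tp_share,
              yield_coefficients = yield_coefficients,
              yield_noise_sd = yield_noise_sd,
              library_seed = library_seed, seed = seed)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  counts <- c(cfg$n_nitrogen_levels, cfg$replicates, cfg$plot_rows,
              cfg$plot_cols)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (length(cfg$nitrogen_rates) != cfg$n_nitrogen_levels) {
    stop("one nitrogen rate per level is required", call. = FALSE)
  }
  if (cfg$noise_sd_dn < 0) stop("'noise_sd_dn' must be >= 0", call. = FALSE)
  if (any(cfg$gain <= 0)) stop("'gain' must be positive per band", call. = FALSE)
  if (length(cfg$gain) != 6 || length(cfg$offset) != 6) {
    stop("'gain' and 'offset' must have one entry per band (6)", call. = FALSE)
  }
  if (cfg$yield_noise_sd < 0) stop("'yield_noise_sd' must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Number of plots in a scene configuration
#' @param config A [scene_config()].
#' @return `n_nitrogen_levels * replicates`.
#' @export
n_plots <- function(config) config$n_nitrogen_levels * config$replicates

# near-square plot grid: pr rows x pc cols with pr * pc = n
plot_grid_shape <- function(n) {
  pr <- max(Filter(function(d) n %% d == 0, seq_len(floor(sqrt(n)))))
  c(pr, n %/% pr)
}

# windowed box mean with edge renormalisation, via cumulative sums
running_mean_rows <- function(m, half) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + half, n) + 1
  lo <- pmax(seq_len(n) - half, 1)
  (cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo)
}

box_smooth <- function(m, half) {
  if (half < 1) return(m)
  t(running_mean_rows(t(running_mean_rows(m, half)), half))
}

# top-layer leaf share of a plot as a function of its greenness anomaly:
# vigorous (high-nitrogen) canopies expose more sunlit top-layer leaf,
# which is what lifts canopy NDRE with nitrogen
top_leaf_share <- function(base, cprime, coupling) {
  pmin(pmax(base + coupling * cprime, 0.20), 0.95)
}

#' Generate a synthetic paddy scene with ground truth
#'
#' Draws a complete seeded scene: global endmember spectra resampled to the
#' six camera bands; a plot layout with randomly placed nitrogen levels;
#' per-pixel true abundance fields (spatially smoothed Dirichlet draws
#' around per-plot means, summing to one exactly, with the top-layer leaf
#' share rising with plot greenness); per-pixel true reflectance as the
#' exact abundance-weighted endmember mixture; the DN image obtained by
#' inverting the true per-band affine calibration and adding Gaussian DN
#' noise; four uniform calibration panels; and plot yields from the
#' greenness model `yield = beta0 + beta1 * C * (Abd_L - Abd_P) + noise`
#' evaluated on the realised plot-mean abundances.
#'
#' Soil is confined to the ridges between plots (plot regions get mean soil
#' abundance `soil_in_plot`); calibration panel pixels carry the panel's
#' nominal reflectance in every band and are marked pure dry soil in the
#' truth map by convention.
#'
#' @param config A [scene_config()].
#' @return A list of class `scene_truth`: `dn_image`, `true_reflectance`,
#'   `true_abundance`, `layout`, `panels`, `true_plot_table` (plot id,
#'   nitrogen, greenness, true plot-mean abundances, `Abd_L`, `Abd_P`,
#'   `Abd_LP`, `true_predictor`, `yield`), `true_gain`, `true_offset`,
#'   `library`, `spectra`, and the `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  validate_scene_config(config)
  spectra <- generate_endmember_library(seed = config$library_seed)
  library <- build_library(spectra, band_set())
  E <- library$matrix  # 6 x 6, rows TL BL TP BP DS WS
  nb <- ncol(E)
  np <- n_plots(config)
  gs <- plot_grid_shape(np)
  g <- config$ridge

  n_rows <- g + config$panel_size + g + gs[1] * (config$plot_rows + g)
  n_cols <- g + gs[2] * (config$plot_cols + g)

  with_seed(config$seed, {
    # ---- layout: levels randomly distributed over the plot grid ----
    level_of_plot <- sample(rep(seq_len(config$n_nitrogen_levels),
                                config$replicates))
    rects <- vector("list", np)
    for (i in seq_len(np)) {
      gr <- (i - 1) %/% gs[2]
      gc <- (i - 1) %% gs[2]
      rects[[i]] <- c(g + config$panel_size + g + gr * (config$plot_rows + g),
                      g + gc * (config$plot_cols + g),
                      config$plot_rows, config$plot_cols)
    }
    layout <- plot_layout(paste0("P", sprintf("%02d", seq_len(np))),
                          config$nitrogen_rates[level_of_plot], rects)

    # ---- calibration panels in the top strip ----
    n_pan <- length(config$panel_nominals)
    pan_gap <- config$panel_size + 2 * g
    if (g + n_pan * pan_gap > n_cols) {
      stop("image too narrow for the calibration panels", call. = FALSE)
    }
    pan_rects <- lapply(seq_len(n_pan) - 1, function(k) {
      c(g, g + k * pan_gap, config$panel_size, config$panel_size)
    })
    panels <- calibration_target_set(config$panel_nominals, pan_rects)

    # ---- per-plot latents ----
    u <- (level_of_plot - 1) / max(1, config$n_nitrogen_levels - 1)
    greenness <- config$greenness[1] + config$greenness[2] * u +
      stats::rnorm(np, 0, config$greenness[3])
    pan_shape <- (config$panicle[3] / config$panicle[4])^2
    pan_noise <- if (config$panicle[4] > 0) {
      stats::rgamma(np, shape = pan_shape,
                    rate = pan_shape / config$panicle[3])
    } else rep(config$panicle[3], np)
    p_mean <- pmin(pmax(config$panicle[1] + config$panicle[2] * u + pan_noise,
                        0.001), 0.30)
    l_mean <- 1 - config$soil_in_plot - p_mean

    # ---- Dirichlet-style abundance fields: smoothed gamma draws,
    # normalised across endmembers. Smoothing is applied per region (ridge
    # background and each plot separately) so plot means are not diluted by
    # the soil-dominated ridges. ----
    ridge_mean <- c(0.05, 0.03, 0.01, 0.01, 0.50, 0.40)  # soil-dominated
    fields <- array(NA_real_, dim = c(n_rows, n_cols, 6))
    for (k in 1:6) {
      gam <- stats::rgamma(n_rows * n_cols,
                           shape = config$concentration * ridge_mean[k],
                           rate = 1)
      fields[, , k] <- box_smooth(matrix(gam, n_rows, n_cols),
                                  config$smooth_half)
    }
    cbar <- config$greenness[1] + config$greenness[2] / 2
    tau <- top_leaf_share(config$tl_share, greenness - cbar,
                          config$greenness_coupling)
    for (i in seq_len(np)) {
      mu <- c(tau[i] * l_mean[i], (1 - tau[i]) * l_mean[i],
              config$tp_share * p_mean[i], (1 - config$tp_share) * p_mean[i],
              config$soil_in_plot / 2, config$soil_in_plot / 2)
      px <- layout_pixel_index(layout[i, ], c(n_rows, n_cols))
      npx <- length(px$rows) * length(px$cols)
      for (k in 1:6) {
        gam <- stats::rgamma(npx, shape = config$concentration * mu[k],
                             rate = 1)
        fields[px$rows, px$cols, k] <-
          box_smooth(matrix(gam, length(px$rows), length(px$cols)),
                     config$smooth_half)
      }
    }
    tot <- fields[, , 1] + fields[, , 2] + fields[, , 3] + fields[, , 4] +
      fields[, , 5] + fields[, , 6]
    for (k in 1:6) fields[, , k] <- fields[, , k] / tot

    # ---- true reflectance: exact abundance-weighted endmember mixture ----
    refl <- array(0, dim = c(n_rows, n_cols, nb))
    for (b in seq_len(nb)) {
      refl[, , b] <- fields[, , 1] * E["TL", b] + fields[, , 2] * E["BL", b] +
        fields[, , 3] * E["TP", b] + fields[, , 4] * E["BP", b] +
        fields[, , 5] * E["DS", b] + fields[, , 6] * E["WS", b]
    }

    # ---- panels: nominal reflectance in every band; pure dry soil in the
    # truth map by convention ----
    for (k in seq_len(n_pan)) {
      r <- pan_rects[[k]]
      rows <- (r[1] + 1):(r[1] + r[3])
      cols <- (r[2] + 1):(r[2] + r[4])
      refl[rows, cols, ] <- config$panel_nominals[k]
      fields[rows, cols, ] <- 0
      fields[rows, cols, 5] <- 1
    }

    # ---- DN image: invert the true affine calibration, add noise ----
    dn <- array(NA_real_, dim = dim(refl))
    for (b in seq_len(nb)) {
      dn[, , b] <- (refl[, , b] - config$offset[b]) / config$gain[b]
    }
    if (config$noise_sd_dn > 0) {
      dn <- dn + stats::rnorm(length(dn), 0, config$noise_sd_dn)
    }

    # ---- realised plot truth and yields ----
    tab <- data.frame(plot_id = layout$plot_id, nitrogen = layout$nitrogen,
                      level = level_of_plot, greenness = greenness)
    pm <- matrix(NA_real_, np, 6, dimnames = list(NULL, library$names))
    for (i in seq_len(np)) {
      px <- layout_pixel_index(layout[i, ], c(n_rows, n_cols))
      pm[i, ] <- apply(fields[px$rows, px$cols, , drop = FALSE], 3, mean)
    }
    tab <- cbind(tab, pm)
    tab$Abd_L <- pm[, "TL"] + pm[, "BL"]
    tab$Abd_P <- pm[, "TP"] + pm[, "BP"]
    tab$Abd_LP <- tab$Abd_L - tab$Abd_P
    tab$true_predictor <- tab$greenness * tab$Abd_LP
    tab$yield <- config$yield_coefficients[1] +
      config$yield_coefficients[2] * tab$true_predictor +
      (if (config$yield_noise_sd > 0) {
        stats::rnorm(np, 0, config$yield_noise_sd)
      } else 0)

    structure(list(
      dn_image = multiband_image(dn, library$bands, "dn"),
      true_reflectance = multiband_image(refl, library$bands, "reflectance"),
      true_abundance = abundance_map(fields,
                                     matrix(0, n_rows, n_cols),
                                     library$names),
      layout = layout, panels = panels, true_plot_table = tab,
      true_gain = config$gain, true_offset = config$offset,
      library = library, spectra = spectra, config = config),
      class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  d <- dim(x$dn_image$values)
  cat("<scene_truth> ", d[1], " x ", d[2], " px, ", d[3], " bands, ",
      nrow(x$layout), " plots\n", sep = "")
  cat(sprintf("  yield: mean %.3f, CV %.1f%%;  Abd_L mean %.3f;  Abd_P mean %.3f\n",
              mean(x$true_plot_table$yield),
              100 * stats::sd(x$true_plot_table$yield) /
                mean(x$true_plot_table$yield),
              mean(x$true_plot_table$Abd_L),
              mean(x$true_plot_table$Abd_P)))
  invisible(x)
}
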
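#!/usr/bin/env Rscript
# Stage 4: vegetation indices and the merged plot table.
#
# Computes the ten tested vegetation indices per pixel, averages each over
# the plot rectangles (per-pixel index first, spatial mean second), joins
# the plot-level abundance summaries and the yields, and writes the merged
# plot table that feeds the statistical stage.

suppressPackageStartupMessages(library(paddysma))

out <- "results/run"
refl <- read_raster_tiff(file.path(out, "reflectance.tif"))
abund <- read_abundance_tiff(file.path(out, "abundance.tif"))
layout <- read_layout_json(file.path(out, "layout.json"))
truth <- read.csv(file.path(out, "true_plot_table.csv"))

tab <- build_plot_table(refl, abund, layout, vi_names())
tab$yield <- truth$yield

write.csv(tab, file.path(out, "plot_table.csv"), row.names = FALSE)
cat("plot table with", length(vi_names()), "indices for", nrow(tab),
    "plots\n")
print(summary(tab[, c("NDVI", "NDRE", "GNDVI", "Abd_L", "Abd_P", "yield")]))
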
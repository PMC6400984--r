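#!/usr/bin/env Rscript
# Stage 1: simulate the nitrogen-gradient paddy trial.
#
# Generates the default synthetic scene -- 24 plots (8 nitrogen levels x 3
# replicates) of 150 x 120 pixels, six bands, four calibration panels,
# Gaussian DN noise -- and writes the raw DN raster plus every ground-truth
# table downstream stages will be checked against.

suppressPackageStartupMessages(library(paddysma))

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scene_config(seed = 42)
scene <- generate_scene(cfg)
print(scene)

write_raster_tiff(scene$dn_image, file.path(out, "dn.tif"))
write_layout_json(scene$layout, file.path(out, "layout.json"))
write_panels_json(scene$panels, file.path(out, "panels.json"))
write_spectra_csv(scene$spectra, file.path(out, "endmember_spectra.csv"))
write_library_csv(scene$library, file.path(out, "endmember_library.csv"))
write.csv(scene$true_plot_table, file.path(out, "true_plot_table.csv"),
          row.names = FALSE)
jsonlite::write_json(list(seed = cfg$seed, gain = cfg$gain,
                          offset = cfg$offset, noise_sd_dn = cfg$noise_sd_dn),
                     file.path(out, "scene_config.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote DN raster (%d x %d x 6) and truth tables to %s\n",
            dim(scene$dn_image$values)[1], dim(scene$dn_image$values)[2],
            out))
cat(sprintf("true yield: mean %.3f, CV %.1f%%\n",
            mean(scene$true_plot_table$yield),
            100 * sd(scene$true_plot_table$yield) /
              mean(scene$true_plot_table$yield)))
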
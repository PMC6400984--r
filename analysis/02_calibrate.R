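#!/usr/bin/env Rscript
# Stage 2: empirical-line radiometric calibration.
#
# Fits the per-band affine DN -> reflectance model from the four ground
# panels rendered in the image, applies it to the whole raster, and reports
# how well the fitted gains/offsets match the generating ones.

suppressPackageStartupMessages(library(paddysma))

out <- "results/run"
dn <- read_raster_tiff(file.path(out, "dn.tif"))
panels <- read_panels_json(file.path(out, "panels.json"))
truth <- jsonlite::read_json(file.path(out, "scene_config.json"),
                             simplifyVector = TRUE)

model <- fit_empirical_line(dn, panels)
print(model)
cat(sprintf("max |gain - true gain|:     %.3g\n",
            max(abs(model$gain - truth$gain))))
cat(sprintf("max |offset - true offset|: %.3g\n",
            max(abs(model$offset - truth$offset))))

refl <- apply_calibration(dn, model)
qc <- calibration_qc(refl)
print(qc)
write_raster_tiff(refl, file.path(out, "reflectance.tif"))
write.csv(qc, file.path(out, "calibration_qc.csv"), row.names = FALSE)
cat("wrote reflectance raster and QC table\n")
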
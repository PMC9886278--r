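#!/usr/bin/env Rscript
# Step 1: generate the synthetic flight-muscle datasets analysed by the
# following steps, and write them in the pipeline's on-disk formats
# (localization CSV + YAML sidecar, pick YAML, ground-truth JSON).
#
# Two experiments are simulated at the imaging conditions of the study
# system (3.5 um sarcomeres, 130 nm pixels, 5 nm precision, 300
# localizations per band, 10% background, 5% multi-emitter outliers):
#   a) "sls"  — dual-colour Sls geometry: epitopes at 50 and 98 nm.
#   b) "stag" — dual-colour staggered pair: 90 vs 98 nm across 44
#               sarcomeres, the configuration that probes band ordering.

library(sarcopaint)

seed <- 2026
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

experiments <- list(
  sls = list(offsets = c(50, 98), labels = c("Sls-Ig13/14", "Sls-Ig51/Fn2"),
             n_sarcomeres = 30, seed = seed),
  stag = list(offsets = c(90, 98), labels = c("Proj-Ig5-8", "Sls-Ig51/Fn2"),
              n_sarcomeres = 44, seed = seed + 1)
)

for (name in names(experiments)) {
  ex <- experiments[[name]]
  cfgs <- lapply(1:2, function(i) {
    sim_config(
      n_sarcomeres = ex$n_sarcomeres,
      epitopes = list(sim_epitope(ex$labels[i], ex$offsets[i],
                                  band_sigma_nm = 12, n_locs_per_band = 300,
                                  channel_label = paste0("ch", i))),
      loc_precision_nm = 5, background_per_um = 17, outlier_frac = 0.05,
      seed = ex$seed
    )
  })
  sim <- simulate_two_colour(cfgs[[1]], cfgs[[2]])
  for (side in c("a", "b")) {
    ch <- channel(sim[[side]]$locs)
    write_localizations(
      file.path(out_dir, sprintf("%s_%s_locs.csv", name, ch)),
      sim[[side]]$locs
    )
  }
  write_picks(file.path(out_dir, sprintf("%s_pick.yaml", name)), sim$a$pick)
  jsonlite::write_json(
    list(
      labels = ex$labels, offsets_nm = ex$offsets,
      zdisc_axis_nm = sim$a$truth$zdisc_axis_nm,
      realized_offsets = c(sim$a$truth$realized_offsets,
                           sim$b$truth$realized_offsets)
    ),
    file.path(out_dir, sprintf("%s_truth.json", name)),
    auto_unbox = TRUE, digits = NA
  )
  message(sprintf(
    "%s: wrote %d + %d localizations (%d Z-discs) to %s",
    name, nrow(sim$a$locs), nrow(sim$b$locs),
    length(sim$a$truth$zdisc_axis_nm), out_dir
  ))
}
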
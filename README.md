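# sarcopaint

Band-position analysis for DNA-PAINT single-molecule localization
imaging of sarcomeres.

Sarcomeric protein epitopes imaged along a myofibril form narrow band
pairs flanking each Z-disc. Given localization tables from a
reconstructed DNA-PAINT acquisition (per-molecule `x`, `y`, frame,
photons and PSF fit widths `sx`, `sy`, in camera pixels) and rectangular
picks selecting individual myofibrils, this package measures each
epitope's distance from the Z-disc center with nanometre precision:

1. **multi-emitter filter** — keep localizations within a 0.2 px disc
   around the mode of the `(sx, sy)` fit-width distribution;
2. **rotate + project** — rotate the pick horizontal and histogram the
   axial positions (130 nm bins, one camera pixel);
3. **Z-disc detection** — prominence-filtered peaks chained under the
   sarcomere-period constraint (≈3.5 µm in flight muscle);
4. **band refinement** — per Z-disc, a 13 nm histogram is smoothed
   (25 nm Gaussian) to find rough bands, then each band center µ is fit
   on the raw counts by least squares with
   `A·exp(−(u−µ)²/2σ²) + c`;
5. **statistics** — per-sarcomere half-distances
   (`half = (µ_right − µ_left)/2`), pooled means with bootstrap 95%
   percentile intervals (1000 replicates), dual-channel ordering counts,
   composite summed profiles and the separation-versus-sarcomere-length
   check.

A synthetic-data module (`simulate_myofibril()`,
`simulate_two_colour()`) generates localization tables with known
lattice and band geometry — including background, wide-fit outliers and
sarcomere-to-sarcomere offset variability — so every stage is testable
without microscope data.

## Worked example

Simulate a dual-colour acquisition of one myofibril with epitopes at 50
and 98 nm from the Z-disc (the Sls N-/C-terminal geometry), then run the
full pipeline:

```r
library(sarcopaint)

cfg_a <- sim_config(n_sarcomeres = 30,
                    epitopes = list(sim_epitope("Sls-Ig13/14", 50, channel_label = "ch1")),
                    seed = 7)
cfg_b <- sim_config(n_sarcomeres = 30,
                    epitopes = list(sim_epitope("Sls-Ig51/Fn2", 98, channel_label = "ch2")),
                    seed = 7)
sim <- simulate_two_colour(cfg_a, cfg_b)

res <- run_pipeline(pipeline_config(
  channels = list(ch1 = sim$a$locs, ch2 = sim$b$locs),
  picks = sim$a$pick,
  epitope_map = list(ch1 = "Sls-Ig13/14", ch2 = "Sls-Ig51/Fn2"),
  pairs = list(c("Sls-Ig13/14", "Sls-Ig51/Fn2")),
  seed = 1
))

res$summary[["Sls-Ig13/14"]]
#> <bootstrap_result> mean 50.35 nm, 95% CI [48.83, 51.96] nm (n = 30, 1000 replicates)
res$summary[["Sls-Ig51/Fn2"]]
#> <bootstrap_result> mean 98.01 nm, 95% CI [96.50, 99.71] nm (n = 31, 1000 replicates)
res$ordering[[1]]
#> <ordering_result> 'Sls-Ig13/14' closer than 'Sls-Ig51/Fn2' in 30 of 30 Z-discs (mean offset 47.68 nm)
```

The recovered pooled means sit within a nanometre of the configured
50/98 nm ground truth; interval widths of 2–3 nm reflect the
few-nanometre sarcomere-to-sarcomere variability at n ≈ 30. The
measurement table (`res$measurements`) holds one row per Z-disc and
epitope with both fitted band centers, the separation and the
half-distance; `res$report` and `res$skipped` record per-myofibril QC
counts and machine-readable skip reasons.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate_dataset.R` writes localization CSVs, picks and
ground truth under `results/data/`; `02_extract_band_positions.R` runs
the pipeline and stores band tables and measurements under
`results/runs/`; `03_epitope_statistics.R` builds the pooled epitope
position table, ordering statistic and composite profile under
`results/tables/`.

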
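# semgmap — spatial activation mapping for high-density surface EMG

`semgmap` analyses high-density surface electromyography (HD-sEMG) grid
recordings of forearm muscles — the kind used to map which compartments of
the extensor digitorum communis (EDC) drive individual finger extensions.
It is aimed at motor-control and rehabilitation researchers who record
multichannel EMG over a 7 × 9 electrode grid wrapped around the forearm
and want a tested, reproducible path from raw signals to group-level
statistics.

## What it computes

Channels live in *relative forearm coordinates*: row *j* of *R* rows sits
at `y_j = 100 (j − ½)/R` percent of forearm length (0% olecranon,
100% ulnar styloid), and the 9 columns of each row are equally spaced in
percent of circumference (0% at the medial seam, increasing over the
flexor then extensor side). The pipeline:

1. **Preprocessing** — zero-phase (double-pass) 2nd-order Butterworth
   band-pass, 20–400 Hz; per-channel RMS over each 5-s steady contraction
   minus RMS over the preceding 2-s rest (floored at 0); average of the
   three repetitions → one 7 × 9 activation map per condition.
2. **Centroid** — the amplitude-weighted barycenter of a map
   `RMS_ij`,

   `C_x = Σ_ij RMS_ij · x_i / Σ_ij RMS_ij`,  `C_y = Σ_ij RMS_ij · y_j / Σ_ij RMS_ij`,

   locating the active muscle region in % circumference / % length.
3. **SSD** — a normalized map contrast between two max-normalized maps:

   `SSD = 100 · Σ_ij (nRMS_A − nRMS_B)² / Σ_ij (nRMS_A² + nRMS_B²)`,

   0 for identical maps, exactly 100 for maps with disjoint support.
4. **Group statistics** — balanced repeated-measures ANOVA (1–3
   within-subject factors) with Mauchly's sphericity test and
   Greenhouse–Geisser correction, plus Tukey (studentized-range) pairwise
   comparisons.
5. **Synthetic generator** — compartmentalized multichannel EMG with
   Gaussian spatial territories, effort scaling, enslaving (co-activation
   of neighbouring compartments), band-limited stochastic carriers and
   baseline noise, with full ground truth — so the entire chain is
   testable with no recorded data.

## Worked example

Simulate one subject's index- and middle-finger extensions (high effort,
dynamic), run the standard chain, and compare the two maps:

```r
library(semgmap)

cfg   <- simulation_config(seed = 42)            # 7x9 grid, 2 kHz, 3 reps
sim_i <- simulate_recording(cfg, "index",  "high", "dynamic")
sim_m <- simulate_recording(cfg, "middle", "high", "dynamic")

map_of <- function(sim, lab) {
  rec <- emg_bandpass(sim$recording)             # 20-400 Hz, zero phase
  build_map(condition_rms(rec), cfg$grid, condition = lab)
}
mi <- map_of(sim_i, "index")
mm <- map_of(sim_m, "middle")

round(map_centroid(mi), 2)
#>    cx    cy
#> 58.50 54.66
round(map_centroid(mm), 2)
#>    cx    cy
#> 64.80 29.93
map_ssd(normalize_map(mi), normalize_map(mm))
#> SSD = 74.520% (index vs middle)
map_ssd(normalize_map(mi), normalize_map(mi))
#> SSD = 0.000% (index vs index)
```

The index-finger map centres distally (`cy` ≈ 55% of forearm length) and
the middle-finger map proximally (`cy` ≈ 30%), reproducing the default
compartment geography; their SSD of ≈ 75% says the two spatial patterns
overlap little. The generator's ground truth for the index condition is
`(58.82, 53.54)` — the recovered centroid is within ~1 percentage point.

A full cohort analysis (10 subjects × 20 conditions, maps, centroid/SSD
tables, ANOVAs) is one call, or one CLI command:

```r
res <- run_analysis(pipeline_config(seed = 1, out_dir = "report"))
```

```sh
Rscript -e 'semgmap::semg_cli()' report --seed 1 --out-dir report
```

Stages can also be run separately and chained:
`simulate | preprocess | map | stats | report` (see
`semg_cli` help; every output embeds the config hash and seed).

## Documentation

The methods vignette (`vignettes/semgmap-methods.Rmd`) describes the
coordinate conventions, the statistic definitions and their edge cases,
the synthetic-data model and what green tests do and do not establish,
and every numerically consequential design choice.
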
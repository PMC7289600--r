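# fretquant

Single-cell analysis of compartment-targeted FRET biosensor time courses.

Kinase activity reporters such as EKAR read out ERK activity as the
acceptor/donor (yellow/cyan, Y/C) emission ratio of a genetically encoded
FRET substrate. When the reporter is targeted to different subcellular
compartments, the same stimulus can produce strikingly different temporal
responses — a transient rise-and-return in the cytosol and nucleus versus a
sustained plateau at the plasma membrane. `fretquant` implements the full
quantitative workflow for such experiments, for imaging labs that extract
per-cell ratio traces from two-channel time-lapse stacks and need
reproducible, testable response metrics and QC:

- **Ratiometry** — per-frame background subtraction from a cell-free
  region, region-mean Y/C (or GFP/RFP, for TIRF translocation assays)
  ratio traces, baseline normalization R/R0.
- **Response metrics** — maximal response (both (Rmax−Rmin)/Rmin and the
  percent increase over baseline), time to half-maximal response,
  inhibitor-induced slope changes, and the **sustained activity metric at
  40 min**:

  SAM40 = (R40 − R0) / (Rmax − R0)

  where R0 is the ratio at the last pre-stimulus frame, Rmax the maximum
  ratio after stimulation, and R40 the (interpolated) ratio 40 min
  post-stimulus. SAM40 = 1 means fully sustained activity, 0 a full return
  to baseline; the statistic is invariant to affine rescaling of the trace.
- **Quality control** — FDR-controlled robust outlier flagging
  (median/MAD centring, Benjamini–Hochberg step-up at Q = 1%) and an
  iterative Pearson filter that removes cells whose extreme biosensor
  expression drives their apparent response, until every
  response-metric-versus-expression correlation is below 0.5.
- **Morphology and protrusions** — equivalent-ellipse minor:major axis
  ratios, kymographs along the cell's major axis, and protrusion events
  quantified as length (µm) and persistence (min) against 5 µm / 15 min
  classification thresholds.
- **Statistics** — mean ± SEM condition summaries with t-based confidence
  intervals, unpaired t-tests with automatic Welch correction, one-way
  ANOVA with Tukey HSD.
- **Synthetic data** — seeded generators for transient/sustained ratio
  traces, two-channel image stacks of disk-shaped cells, and mask movies
  with programmed protrusions, so every stage of the pipeline can be
  validated against known ground truth.

All user-facing functions take and return tibbles, so analyses compose with
the pipe; fitted comparison objects support `tidy()` and `glance()`, and
`plot_traces()`, `plot_population()` and `autoplot()` give quick ggplot2
views.

## Worked example

Simulate a plasma-membrane-like (sustained) and a cytosol-like (transient)
population at the standard acquisition settings (30-s frames, stimulus at
2.5 min, 45 min of post-stimulus imaging), compute per-cell metrics, and
compare SAM40 across conditions:

```r
library(fretquant)

pm  <- simulate_population(40, "sustained", seed = 7, condition = "plasma_membrane")
cyt <- simulate_population(40, "transient", seed = 8, condition = "cytosol")
traces <- rbind(pm$traces, cyt$traces)
traces$cell_id <- paste(traces$condition, traces$cell_id, sep = "_")

metrics <- trace_metrics(traces, stim_index = pm$stim_index)
summarize_population(metrics, "sam40")
#> # A tibble: 2 × 7
#>   condition       n_cells  mean     sd    sem ci_low ci_high
#>   <chr>             <int> <dbl>  <dbl>  <dbl>  <dbl>   <dbl>
#> 1 cytosol              40 0.375 0.128  0.0203  0.334   0.416
#> 2 plasma_membrane      40 0.828 0.0907 0.0143  0.799   0.857

glance(compare_many(metrics, "condition", "sam40"))
#> # A tibble: 1 × 4
#>   df_between df_within statistic  p_value
#>        <dbl>     <dbl>     <dbl>    <dbl>
#> 1          1        78      333. 7.16e-30
```

The membrane-like population retains ~83% of its maximal response at
40 min while the cytosol-like population has fallen back to ~38%, and the
two conditions separate decisively. On a single noiseless sustained trace
the metrics reduce to their closed forms:

```r
p  <- kinetic_params("sustained", amplitude = 0.745, k_act = 0.15,
                     k_dec = 0.005, noise_sd = 0)
tr <- normalize_trace(simulate_trace(p, n_frames = 96, stim_index = 6))
sam40(tr)             # 0.946
time_to_half_max(tr)  # 3.87 min
```

`run_pipeline(config)` chains the whole workflow (simulation or CSV/TIFF
input, metrics, QC, summaries, comparisons) from a YAML or list config and
writes every intermediate table as CSV, deterministically for a given
config and seed.

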
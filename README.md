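# spineclust

Quantitative analysis of experience-dependent cortical plasticity from two
kinds of longitudinal imaging data:

1. **Dendritic spine imaging** — shaft-normalized spine sizes,
   baseline-referenced size changes, density / addition / elimination /
   turnover rates, and a **nearest-neighbour statistic of spatially
   clustered plasticity** with a within-dendrite permutation (Monte Carlo)
   null. This is the analysis used to ask whether neighbouring spines on a
   dendrite weaken or strengthen *together* — for example after monocular
   deprivation — rather than independently.
2. **Intrinsic signal optical imaging (ISI)** — per-pixel response
   amplitude and phase at the stimulus frequency by Fourier analysis, a
   smoothed and thresholded binocular region of interest, and the **ocular
   dominance index** (ODI).

The package is aimed at experimenters analysing spine annotation exports
(one row per spine per session, with spine / shaft / background ROI
intensities) and periodic-stimulus ISI movies, and at methodologists who
want a fully synthetic, ground-truth-known replica of such an experiment:
`simulate_spine_dataset()` and `simulate_isi_recording()` generate data
with configurable clustering, turnover, noise and response maps so every
stage of the analysis is testable end to end.

## The statistics in brief

**Normalized size change.** A spine with raw shaft-normalized size `v_d`
on day `d` and mean baseline size `v̄_b` changes by

    Δ_d = (v_d − v̄_b) / (v_d + v̄_b)   ∈ [−1, +1]

with −1 exactly at elimination and +1 at formation. Spines are classified
from the window-averaged change Δ̄ (days 1–4 by default) as *increasing*
(Δ̄ > τ), *decreasing* (Δ̄ < −τ) or *stable*, with τ = 0.14 — one standard
deviation of control variability.

**Clustered plasticity.** For each persistent spine, its nearest neighbour
along the dendritic path is found; unordered pairs are kept once, at path
distances in [1.0, 3.5] µm. Of the retained pairs, the percentages where
both spines increase, both decrease, both change in the same direction, or
the two change in opposite directions are compared against `n_pools`
(default 10,000) shuffles of the change values along the spine positions
*within each dendrite*; the Monte Carlo p-value is the tail proportion of
shuffled fractions at or beyond the observed one.

**Ocular dominance.** Per-pixel score `(C − I)/(C + I)` over a binocular
ROI (ipsilateral map, 5×5 uniform smoothing, 40%-of-peak threshold), with
the ODI its ROI mean; `C` and `I` are response amplitudes at the stimulus
frequency for contralateral- and ipsilateral-eye stimulation.

## Worked example

Simulate a deprivation-like experiment in which spine weakening is
spatially clustered (neighbour correlation 0.8, mean change −0.1), run the
spine pipeline, and test for clustering:

```r
library(spineclust)

cko <- simulate_spine_dataset(
  spine_sim_config(neighbor_rho = 0.8, global_shift = -0.1, seed = 1))
cko
#> Spine dataset: 100 dendrites, 1082 spines, 8 sessions
#>   days: -3 -2 -1 0 1 2 3 4 (baseline: -3 -2 -1 0)

sct <- size_change_table(cko)          # per-spine Δ̄ and class at τ = 0.14
table(sct$class)
#> decreasing increasing     stable
#>        212         30        285

ct <- cluster_test(sct, clustering_config(n_pools = 10000, seed = 7,
                                          tail = "upper"))
ct
#> Nearest-neighbour clustered-plasticity test
#>   177 spine pairs on 77 dendrites (527 persistent spines)
#>   10000 permutation pools, tau = 0.14, distances [1.0, 3.5] um
#>                    observed_pct null_median_pct      p  tail
#> both_increase              3.95            2.82 0.0884 upper
#> both_decrease             29.38           24.29 0.0118 upper
#> same_direction            33.33           27.12 0.0028 upper
#> opposite_direction         0.00            0.00 1.0000 upper
```

29.4% of neighbouring pairs decreased together, against a shuffled median
of 24.3%: more coordinated weakening than position-shuffled chance
(p ≈ 0.01), and same-direction pairs are similarly in excess (p ≈ 0.003).
The same pipeline on a control-like dataset (`neighbor_rho = 0`,
`global_shift = 0`, same seed) shows no excess — both-decrease 1.1%
observed vs 1.7% shuffled median, p = 0.88. `plot(ct)` draws the four null
histograms with the observed values marked; `turnover_rates(cko)` and
`spine_density(cko)` give the per-dendrite structural metrics (mean
turnover 0.111/session and density 0.389 µm⁻¹ here).

The ISI side mirrors it:

```r
cfg <- isi_sim_config(seed = 1)              # contra map = 2 × ipsi map
contra <- fourier_response(simulate_isi_recording(cfg, "contra"))
ipsi   <- fourier_response(simulate_isi_recording(cfg, "ipsi"))
od <- ocular_dominance(contra$amplitude, ipsi$amplitude,
                       binocular_roi(ipsi$amplitude))
od
#> Ocular dominance: ODI = 0.3333 over 376 ROI pixels
#>   mean amplitudes: contra 1.299, ipsi 0.6498; 0 zero-response pixel(s) excluded
```

With the contralateral response twice the ipsilateral everywhere, each ROI
pixel scores (2−1)/(2+1) = 1/3 — recovered here to four decimals from a
noisy simulated movie.

`run_pipeline("out/")` chains simulate → metrics → cluster test into one
reproducible run with CSV/JSON outputs and a checksummed manifest, and
`inst/scripts/spineclust-cli.R` exposes the stages as shell subcommands.
See the vignette (`vignettes/spine-plasticity-methods.Rmd`) for the models,
conventions, calibration and limitations.

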
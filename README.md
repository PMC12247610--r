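# laminarfcs

Layer-specific functional connectivity analysis for VAPER fMRI, with a fully
synthetic test bed.

## Background

Blood-nulled (VAPER-style) fMRI interleaves *nulled* volumes, in which blood
signal is suppressed, with *control* volumes. The dynamic division

```
vaper_t = (C_t - N_t) / C_t
```

of each control/nulled pair cancels any multiplicative BOLD factor shared by
the two volumes of a pair, yielding a cerebral-blood-volume-weighted signal
whose laminar profile is not dominated by draining veins. Conventional BOLD
amplitude, by contrast, increases monotonically toward the pial surface,
where ascending veins pool the signal.

This package implements the full analysis chain on top of that contrast:

- **synthgen** — a generative model of a laminar fMRI session on a spherical
  cortex: equi-volume depth geometry, planted connectivity networks with
  depth-specific coupling profiles, a depth-increasing multiplicative BOLD
  (vein bias) factor, drift, motion, and thermal noise. Every downstream
  stage is testable against planted ground truth, with no external data.
- **contrast** — interleaved-series splitting, pairing, dynamic division,
  the paired BOLD companion series, and MT-weighted anatomical contrast.
  A pair of volumes acquired at TR 6.082 s gives an effective sampling
  interval of 12.164 s per contrast time point.
- **preprocess** — motion-derivative (enorm) and volume-outlier censoring,
  and nuisance regression: polynomial drift, six motion parameters and
  derivatives, mean CSF, and a per-voxel local white-matter regressor.
- **lamsurf** — icosphere meshes, equi-volume depth surfaces (18 depths by
  default, depth 1 deepest), volume-to-surface sampling (trilinear or
  project-after-5x-upsampling nearest neighbor), within-depth surface
  smoothing, and exact surface-to-template registration.
- **connstat** — functional connectivity strength (FCS): the mean of
  strictly positive Fisher-z correlations from a vertex-depth sample to a
  target set (network, seed, or whole-cortex columnar nodes for hubness),
  always excluding the source vertex's own column.
- **clusterel** — k-means on depth profiles with correlation distance,
  label anchoring by peak-depth band, Dice similarity, split-half
  reliability against a random-pattern null.
- **pipeline** — `run_session()` / `run_group()` drive the stages in order
  with a stage-tagged log; YAML round-trip for parameters.

## Worked example

```r
library(laminarfcs)

# simulate one VAPER session with two planted networks
cfg <- synthetic_config(seed = 42)
sess <- simulate_session(cfg)

# full session pipeline: contrast, censoring, nuisance regression,
# laminar projection, smoothing, network FCS
res <- run_session(sess)

# laminar connectivity profile of the middle-peak network
nm <- sess$model$network_masks
prof <- extract_profile(res$fcs$net_middle, nm[, 1])
print(prof, n = 5)

cat("peak depth:", which.max(prof$mean), "\n")
```

Output (the `compute_vaper` message counts background voxels outside the
head, where the control signal is zero):

```
[trim] 2 dummy volumes flagged
compute_vaper: 56.048% of voxel-time values had nonpositive control signal; set missing
[contrast] 60 pairs, effective TR 12.164 s
[censor] 4 of 60 pairs censored
[nuisance] 19 design columns, 56 kept pairs
[project] 0 vertex-depth points missing
[smooth] FWHM 3.0 mm within depth
[fcs] 2 network maps
# A tibble: 18 × 4
  depth  mean   sem     n
  <int> <dbl> <dbl> <int>
1     1 0.174     0     1
2     2 0.172     0     1
3     3 0.179     0     1
4     4 0.185     0     1
5     5 0.299     0     1
# ℹ 13 more rows
peak depth: 9
```

The recovered connectivity profile peaks at depth 9 of 18 — exactly the
planted middle-depth coupling peak — even though the session was generated
with a vein-bias BOLD factor that increases monotonically toward the pial
surface. Running the same profile extraction on the BOLD companion series
shows the superficial bias instead; see the vignette for the comparison and
for group-level reliability analysis.

Plot helpers (`plot_laminar_profile()`, `plot_parcellation_profiles()`,
ggplot2-based) and tidy methods (`tidy()`, `glance()` on parcellation and
reliability objects) are included.

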
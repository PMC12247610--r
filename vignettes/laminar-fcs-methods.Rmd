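---
title: "Methods: laminar functional connectivity with a blood-nulled contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar functional connectivity with a blood-nulled contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarfcs)
```

This vignette documents the signal model behind the synthetic generator, the
analysis pipeline it feeds, the numerical choices made along the way, and the
limits of what the synthetic data can stand in for.

## 1. The contrast

A blood-nulled acquisition interleaves *nulled* volumes $N_t$ (blood signal
suppressed) with *control* volumes $C_t$. Both volumes of a pair share any
multiplicative, slowly varying BOLD factor $(1 + b_t)$, drift, and baseline
$S_0$:

$$
C_t = S_0\,(1 + b_t)\,(1 + \delta_t)\,(1 + \varepsilon_t), \qquad
N_t = S_0\,(1 - v_t)\,(1 + b_t)\,(1 + \delta_t)\,(1 + \varepsilon_t).
$$

The dynamic division

$$
\mathrm{vaper}_t \;=\; \frac{C_t - N_t}{C_t} \;=\; v_t
$$

recovers the planted blood-volume signal $v_t$ *exactly* when noise is zero,
whatever the BOLD factor or drift does — this algebraic identity is asserted
at machine precision in the test suite. Because each contrast sample consumes
one nulled and one control volume, a volume TR of 6.082 s yields an effective
sampling interval of $2 \times 6.082 = 12.164$ s.

The companion BOLD series (paired control volumes, normalized per voxel)
retains the multiplicative vein-bias factor, whose amplitude the generator
makes increase linearly with equi-volume depth toward the pial surface.

## 2. Generator signal model

The cortex is a spherical shell: a white icosphere (subdivision chosen to
reach the requested vertex count) and a pial surface offset along the radial
normal by a spatially varying thickness. Gray-matter voxels are assigned to
the nearest vertex column, a depth bin, and a continuous equi-volume depth
fraction $\alpha \in [0, 1]$ (0 = white, 1 = pial).

The planted blood-volume signal of a GM voxel in column $i$ is

$$
v_t \;=\; v_0 \;+\; \sum_n \beta_n(\alpha)\, g_n(t) \;+\; \sigma_w\, w_i(t),
$$

where $v_0$ is the steady suppression baseline, $g_n$ are smoothed latent
network time courses, $\beta_n(\alpha)$ is the network's coupling profile
evaluated at the voxel's *continuous* depth fraction, and $w_i$ is a
spontaneous fluctuation private to each vertex column, flat across depth.
Values $v_t \ge 0.95$ (nulling overshoot) are clipped with a warning.

Key parameters of `synthetic_config()`:

| parameter           | default        | units    | role |
|---------------------|----------------|----------|------|
| `grid_shape`        | 44×44×44       | voxels   | volume matrix |
| `voxel_size`        | 0.7            | mm       | isotropic voxel edge |
| `n_vertices`        | 642            | —        | icosphere vertices |
| `n_depths`          | 18             | —        | equi-volume depth samples |
| `thickness_range`   | 2–3            | mm       | cortical thickness (varies over the sphere) |
| `white_radius`      | 10             | mm       | white-surface radius |
| `volume_tr`         | 6.082          | s        | per-volume TR (effective TR 12.164 s) |
| `n_pairs`           | 60             | —        | nulled/control pairs (plus 2 dummy volumes) |
| `vein_bias_slope`   | 1.5            | —        | BOLD gain increase from white to pial |
| `bold_amplitude`    | 0.02           | fraction | BOLD factor amplitude at the white surface |
| `vaper_baseline`    | 0.05           | fraction | steady suppression $v_0$ |
| `noise_sd`          | 0.02           | fraction | multiplicative thermal noise |
| `vertex_signal_sd`  | 0.01           | fraction | columnar spontaneous signal $\sigma_w$ |
| `drift_amplitude`   | 0.02           | fraction | slow drift, shared within a pair |
| `motion_rw_sd`      | 0.02           | mm/deg   | motion random-walk step |
| `motion_spikes`     | volumes 30, 80 | —        | spike times (also corrupt 20% of brain voxels) |

The two default networks are antipodal caps centered on the $\pm(1,1,1)/\sqrt3$
diagonals, one with a middle-peak coupling profile (peak depth 9 of 18), one
with a superficial-peak profile (peak depth 17). CSF voxels directly above
network columns carry the draining-vein BOLD response at full superficial
gain but no blood-volume signal, emulating pial veins.

## 3. Numerical and design choices

**Equi-volume depths.** On a sphere the equi-volume depth fraction has a
closed form; the package solves the general area-weighted quadratic
analytically and the tests check it against an independent root finder and
against the exact spherical-shell formula
$r(\alpha) = (r_w^3 + \alpha\,(r_p^3 - r_w^3))^{1/3}$.

**Continuous-depth coupling.** Coupling amplitudes are evaluated at each
voxel's continuous $\alpha$, not its depth bin, so the laminar response is
smooth in depth and binning artifacts cannot masquerade as laminar structure.

**Columnar spontaneous signal.** Without a per-column private signal, every
within-network correlation would saturate at $|r| \to 1$ in low-noise
regimes and FCS depth profiles would be flat; $\sigma_w$ grades correlations
by coupling amplitude. Its default (0.01) keeps peak within-network
correlations high but unsaturated.

**Depth resolution.** With 18 depths over a 2–3 mm ribbon, voxel size is the
binding constraint on laminar recovery: at 1 mm the sampled coupling profile
blurs across ~7 bins and sphere curvature skews it deep. The default 0.7 mm
voxels (~3.6 voxels across the ribbon) make bin-level peak recovery
well-conditioned while keeping a session fast to simulate on a laptop.

**Surface sampling.** The pipeline defaults to `upsample5_nearest`
(projection after a virtual 5× grid upsampling, nearest neighbor). Trilinear
interpolation averages across the pial boundary, diluting the columnar signal
faster than the coupling near the surface and biasing connectivity profiles
superficially; nearest-neighbor sampling from an upsampled grid never mixes
tissues. Trilinear sampling remains available (and is the default of the
lower-level `sample_volume_to_surface()`, where its exactness on linear
fields makes it the better-behaved general-purpose interpolant).

**Nuisance model.** Orthogonal polynomials (order 5), six motion parameters
plus derivatives, mean CSF, and a per-voxel local white-matter average
(15 mm sphere, FFT convolution, global-WM fallback where the sphere contains
too little WM). The local-WM term is handled by Frisch–Waugh partialling so
the returned residuals are exactly orthogonal to the shared design;
collinear columns are dropped by pivoted QR with a warning.

**Censoring.** A pair is censored if the motion-derivative Euclidean norm
exceeds 0.4 mm, if either volume's outlier fraction reaches 0.10
(inclusive), or if it contains a dummy volume. Outliers are counted against
a per-voxel 5th-order polynomial trend at 4.5 robust (MAD) units.

**FCS.** Connectivity strength is the mean of strictly positive Fisher-z
correlations; correlations are clipped to $1 - 10^{-7}$ in magnitude before
the z-transform so shared-latent duplicates cannot produce infinities. All
depths of the source vertex are excluded from its own target set.

**Problem sizes.** Desk-scale defaults (44³ voxels, 642 vertices, 60 pairs)
are package choices to keep the full test suite in minutes; the code paths
are dimension-generic and accept realistic matrix sizes.

## 4. Worked session

```{r session, eval = FALSE}
cfg <- synthetic_config(seed = 42)
sess <- simulate_session(cfg)
res <- run_session(sess)

nm <- sess$model$network_masks
prof_mid <- extract_profile(res$fcs$net_middle, nm[, 1])
prof_sup <- extract_profile(res$fcs$net_superficial, nm[, 2])
which.max(prof_mid$mean)   # 9  — planted middle-peak depth
which.max(prof_sup$mean)   # 17 — planted superficial-peak depth

plot_laminar_profile(prof_mid)
```

Group analysis registers each session's laminar maps to the template with
exact correspondence maps, clusters depth profiles with correlation-distance
k-means (labels anchored: the cluster peaking in depths 7–12 is class 1),
and quantifies reliability by split-half Dice against a random-pattern null:

```{r group, eval = FALSE}
grp <- make_group(synthetic_config(seed = 1), n_sessions = 4)
gres <- run_group(grp, pipeline_params())
gres$reliability$p_value
dice_parcellation(gres$parcellation$labels, grp$truth$labels)
```

## 5. Limitations

- Geometry is a sphere, not folded cortex: curvature enters only through the
  white/pial area ratio (exactly what equi-volume depths need), so gyral
  bias, sulcal partial-volume patterns, and surface-reconstruction error are
  out of scope.
- No k-space or EPI simulation: distortion, dropout, and T2*-blurring are
  not modeled; "motion" corrupts intensities and the motion trace but does
  not move the head.
- No physiological noise model (cardiac/respiratory aliasing).
- The BOLD factor is multiplicative and slow by default; `fast_bold = TRUE`
  breaks the within-pair assumption to exercise residual contamination, but
  no attempt is made to model the true hemodynamic response shape.
- Blood-nulling efficiency is a fixed baseline fraction, not a T1-based
  steady-state model.
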
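---
title: "From diffusion microstructure to low-frequency conductivity: models, choices, and what the phantom can and cannot show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diffusion microstructure to low-frequency conductivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctimaps)
```

## The conductivity model

Low-frequency tissue conductivity is dominated by ionic mobility, which — like
water diffusion — is shaped by the same cellular geometry. Conductivity tensor
imaging (CTI) exploits this: it scales the extracellular diffusivity by a
position-wise factor

$$\sigma_L = \eta\, d_e, \qquad
  \eta = \frac{\alpha\,\sigma_H}{\alpha d_e + \beta(1-\alpha) d_i},$$

where $\alpha$ is the extracellular volume fraction, $d_i$ and $d_e$ are
intra- and extracellular diffusivities (mm²/s), $\sigma_H$ the high-frequency
conductivity and $\beta$ the ratio of intra- to extracellular ionic
concentrations. Two consequences worth internalizing:

* $0 \le \sigma_L \le \sigma_H$ always, with equality at $\alpha = 1$ or
  $d_i = 0$. $\sigma_L$ rises with $\alpha$ and $d_e$, falls with $d_i$ and
  $\beta$. These are asserted as randomized property tests.
* $\beta$ is a pure scale knob on the intracellular penalty: it shifts
  absolute values but not the *ordering* of models or structures. It is not
  identifiable from diffusion data; the default 0.41 follows the CTI
  literature and is surfaced in every run manifest so nobody mistakes
  absolute values for measurements.

This package computes only the isotropic scalar $\sigma_L$. The tensor form
($\eta$ times the extracellular diffusion tensor) and the fitting of
multi-compartment signal models to raw diffusion data are out of scope:
the adapters consume *already fitted* parameter maps.

## The three adapters

Each microstructure model is reduced to the triplet $(\alpha, d_i, d_e)$.

**NODDI.** Neurite fraction $f_i$, orientation dispersion index ODI, and
isotropic fraction $f_{iso}$, with fixed stick diffusivity
$d_\parallel = 1.7\times10^{-3}$ and free-water diffusivity
$d_{iso} = 3.0\times10^{-3}$ mm²/s. ODI maps to the Watson concentration
$\kappa = 1/\tan(\pi\,\mathrm{ODI}/2)$ and then to the orientation coherence
$\tau(\kappa) = -\tfrac{1}{2\kappa} + \tfrac{1}{2\sqrt{\kappa}D(\sqrt{\kappa})}$
($D$ = Dawson function), which runs from 1/3 (fully dispersed) to 1 (parallel
sticks). The extracellular matrix gets the classic tortuosity scaling in its
parallel/perpendicular components, and free water is mixed in by volume
fraction. Two conventions exist for the diffusivity entering the tortuosity
expressions, and the package exposes both via `scaling`:

* `"paper"` (default): the parallel diffusivity is pre-scaled by
  $f_i(1-f_{iso})$, i.e. $d_{i\parallel} = f_i(1-f_{iso})d_\parallel$ appears
  on both the intracellular and extracellular side. This follows the
  conversion sequence this pipeline was built to reproduce.
* `"canonical"`: the unscaled intrinsic $d_\parallel$ enters the
  extracellular tortuosity expressions, the original NODDI convention.

Whether the pre-scaling is intended physics or a normalization convention is
not decidable from the source material; we implement it as published and keep
the switch. The same applies to two smaller readings, logged as interpretation
notices in every run manifest: the SANDI extracellular weight on $D_{ec}$ is
read as $f_e$, and the SMT extra-neurite mean diffusivity is carried through
unchanged as $d_e$ (its $d_e$ assignment is implied rather than printed in
the source conversion table).

**SANDI.** $\alpha = f_e$;
$d_i = (1-f_e)\,(f_{in} D_{in} + (1-f_{in}) D_{is})$ with soma diffusivity
fixed at $D_{is}=3\times10^{-3}$ mm²/s; $d_e = f_e D_{ec}$. Note the
$(1-f_e)$ pre-scaling of the intracellular mixture — again implemented as
published.

**SMT.** $\alpha = 1-f_{in}$, $d_i = f_{in} D_{in}$, $d_e = D_e$.

Out-of-range voxels (fractions slightly outside $[0,1]$, negative
diffusivities) are clipped to the physical range with a per-volume warning
count rather than an error, because fitted real-world maps routinely contain
small violations. `NA` voxels and degenerate voxels (the free-water mixing
denominator $f_{iso} + (1-f_i)(1-f_{iso}) = 0$, i.e. pure intracellular
voxels) propagate to a validity mask that every downstream statistic honors.

## High-frequency conductivity

$\sigma_H$ is assigned per tissue class from the Gabriel 4-term Cole–Cole
dispersion model,

$$\hat\varepsilon(\omega) = \varepsilon_\infty +
  \sum_{k=1}^{4}\frac{\Delta\varepsilon_k}{1+(i\omega\tau_k)^{1-a_k}} +
  \frac{\sigma_i}{i\omega\varepsilon_0}, \qquad
  \sigma(\omega) = -\omega\varepsilon_0\,\mathrm{Im}\,\hat\varepsilon(\omega).$$

At the default 128 MHz (the 3 T Larmor band, taken literally as 128.0 MHz)
the per-class values are fixed at the reference assignments GM 0.5864,
WM 0.3420, CSF 2.1429 S/m. Evaluating the packaged dispersion parameter sets
at exactly 128 MHz lands within $4\times10^{-4}$ S/m of each assignment —
the residual comes from rounding in the published dispersion parameter
tables — so the fixed values take precedence at 128 MHz while the dispersion
path serves every other frequency, and the test suite pins both facts.
Per-class overrides are available for sensitivity analyses.

## The synthetic phantom

The phantom exists to exercise the *procedure* — not to imitate anatomy. It
is a nested-ellipsoid head (CSF shell, cortical GM band, WM core) carrying 25
cuboid ROIs that mirror the study design: corpus-callosum genu/body/splenium,
inferior/superior cerebellar peduncle, left/right cingulum, five bilateral
subcortical pairs (amygdala, hippocampal CA1/CA2-3/CA4-DG subfields,
pallidum, putamen, thalamus), anterior/posterior cingulate, pre/postcentral
cortex. Paired regions are constructed by exact voxel-level mirroring or
translation of their partner, so partners have identical voxel counts at any
grid size and the null ("symmetric brain") is true *by construction*. Grids
too coarse to give every region at least two voxels per axis fail with a
sizing error naming the first region that did not fit.

Voxel values are i.i.d. truncated normals per tissue class. The defaults
(e.g. NODDI WM $f_i = 0.60\pm0.05$, ODI $0.20\pm0.05$; GM $f_i=0.40\pm0.05$,
ODI $0.55\pm0.10$; SMT WM $f_{in}=0.65\pm0.05$, GM $0.35\pm0.05$;
diffusivities around $1.1$–$2.8\times10^{-3}$ mm²/s) are plausible magnitudes
chosen once to keep WM/GM separable; they are *not* calibrated to any real
cohort, and results on the phantom must not be read as population estimates.
What the phantom deliberately lacks: anatomy, spatial correlation, scanner
noise, partial-volume mixing, registration error, EPI distortion. Passing
tests therefore demonstrate correctness of the computation and the operating
characteristics of the statistics under clean conditions — not robustness to
real-data artifacts.

Reproducibility contract: a master seed spawns one substream per subject
(subject index mixed into the stream key), so subject $k$ is bit-identical
regardless of cohort size, and the same (seed, spec) always regenerates the
same cohort. Asymmetry injections (ROI, parameter, additive offset) are
applied after sampling and re-clipped to the physical range;
`example_asymmetry()` provides per-model offsets strong enough to move a
putamen's $\sigma_L$ by well over 0.1 S/m, which is what the end-to-end
"flip only the injected pair" test uses.

## Statistics

Per subject and ROI we take the median and IQR of $\sigma_L$ over valid
voxels (quantile type 7 — linear interpolation between order statistics —
fixed and documented since conventions differ). Group summaries and tests
operate on the per-subject medians. CSF-class ROIs are excluded from tables:
the conversion is not meaningful for free fluid (the default phantom defines
no CSF ROIs in any case). Normality is screened per ROI and model with
Shapiro–Wilk at $\alpha=0.05$; zero-variance samples are flagged degenerate
and reported non-normal. Box-plot exports use Tukey 1.5×IQR whisker fences,
labelled as such, since "range excluding outliers" is not otherwise a number.

Equivalence between paired structures uses the Wilcoxon signed-rank TOST:
one-sided tests against bounds $\pm 0.05$ S/m at $\alpha=0.05$, plus a
two-sided difference test at shift 0. We treat the comparisons as paired
(within-subject) — that is what a *signed-rank* procedure implies — although
an independent-samples (rank-sum) mode is provided (`paired = FALSE`) since
the source description is ambiguous on this point. Zero differences are
dropped before ranking; ties are mid-ranked. For $n \le 25$ the exact
sign-flip permutation distribution of the rank sum is computed by dynamic
programming over the (possibly tied) mid-ranks — with distinct ranks this
reduces to the classical signed-rank distribution; beyond that a
tie-corrected normal approximation with continuity correction is used,
matching `stats::wilcox.test` conventions so the two can cross-check each
other. "Equivalent" ($\max(p_{lower}, p_{upper}) < \alpha$) and "different"
($p_{diff} < \alpha$) are deliberately not mutually exclusive: a tiny but
perfectly consistent offset is both. No multiple-testing correction is
applied across the roster; each comparison is reported at its own level.

## Numerical choices

* **Dawson function.** Maclaurin series below $|x| = 4.5$, asymptotic series
  truncated at its smallest term above; worst-case absolute error ~2e-9 at
  the branch point, below 1e-12 elsewhere, verified against a quadrature
  oracle. $\tau(\kappa)$ additionally uses the small-$\kappa$ expansion
  $1/3 + 4\kappa/45$ below $\kappa = 10^{-7}$ to avoid the
  $-1/(2\kappa)$ cancellation, and is clamped to $[1/3, 1]$.
* **$\kappa$ cap.** ODI $= 0$ maps to $\kappa = 10^6$ rather than infinity;
  $\tau(10^6)$ differs from 1 by well under $10^{-3}$, so the cap is
  invisible at display precision while keeping arithmetic finite.
* **Denominator floor.** Voxels with
  $\alpha d_e + \beta(1-\alpha)d_i < 10^{-12}$ mm²/s are masked instead of
  producing arbitrarily large $\eta$; this catches the $f_i = 1$ corner
  cases.
* **Degenerate normality samples** are reported, not raised, at the cohort
  level; per-vector `normality_screen()` keeps the strict $n \ge 3$ error.
* **Problem sizes in the test suite** (chosen as a sensible compromise for a
  routine check): 48³ grids for cohort mechanics, the default 64³ grid with
  30 subjects per model for the end-to-end equivalence checks, $10^5$ random
  voxels for the algebraic invariants, 200 replicates at $n = 199$ for the
  TOST operating characteristics, and 1000 replicates at $n = 50$ for the
  size-at-the-bound check.

## Known limitations

* $\beta$ and $\sigma_H$ are assumptions, not measurements; absolute
  $\sigma_L$ values inherit them linearly. Comparisons *between* models on
  identical inputs are the robust output.
* The NODDI `"paper"` scaling makes its $\sigma_L$ only weakly sensitive to
  $f_i$ in realistic ranges (the narrow NODDI distributions are visible on
  the phantom too); the `"canonical"` switch exists precisely so users can
  quantify that choice.
* The phantom's i.i.d. voxels make ROI medians extremely precise
  ($\mathrm{SE} \propto 1/\sqrt{n_{vox}}$), so equivalence power on the
  phantom is higher than on spatially correlated real data with comparable
  voxel counts.
* Exact TOST inference below $n = 5$ nonzero differences is refused rather
  than approximated.
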
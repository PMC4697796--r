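---
title: "Methods: spatial statistics of paired recombinase foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics of paired recombinase foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focipair)
```

# The problem

During meiosis the RecA-family recombinases Rad51 and Dmc1 load onto the
resected single-stranded ends of programmed DNA double-strand breaks
(DSBs) and appear as immunostaining foci on spread nuclei. Two spatial
questions drive the analyses in this package:

1. Are foci of one channel arranged non-randomly in **pairs** at
   separations up to ~400 nm, as expected if the two ends of one DSB
   drift apart but stay tethered?
2. What are widefield foci made of? Super-resolution (dSTORM) imaging
   resolves them into small **sr foci**, whose sizes translate into
   filament lengths in nucleotides and protomers.

Everything operates on planar point patterns: focus centroids in
continuous nanometres, image convention (x right, y down), one unit
throughout. The spread nucleus is treated as a bounded 2-D region; the
default is a disc of the measured area. Traced polygonal masks are
supported, but since the outline actually used for the original random
simulations is not recoverable, the disc is the default and the region
type is a parameter rather than an assumption baked into the code.

# Nearest-neighbour pairing against a matched null

For every focus, the distance to its nearest same-channel neighbour in
the same nucleus is recorded; distances are pooled across nuclei, so
nuclei are weighted by their focus counts. The null model is **complete
spatial randomness (CSR) matched per nucleus**: each replicate places
the observed number of foci uniformly in that nucleus's own region.
Pairing enrichment in a bin is the observed frequency minus the null
frequency, and the paired-fraction estimate

$$\hat p \;=\; \sum_{b:\ \mathrm{hi}(b)\le w} \max(0,\ f_b^{obs} - f_b^{null}),$$

sums positive excess over bins within the pairing window (default
$w = 400$ nm). Clipping at zero keeps CSR-like bins from cancelling
genuine excess; its cost is a small positive bias under the null, which
the null-calibration test bounds against the dataset-level Monte-Carlo
spread of the null replicates.

Two observation effects are modelled explicitly:

* **Resolution censoring.** Same-channel foci closer than ~150 nm are
  not separable by widefield microscopy. `apply_resolution_censor()`
  iteratively merges the closest sub-threshold pair into its
  intensity-weighted centroid (closest pair first; coordinate-
  lexicographic tie-break), conserving total intensity. The merge rule
  itself is a package choice — only the 150 nm floor is empirically
  grounded. Censoring is **on** by default for widefield-mode nulls, so
  the null embeds the same observation floor as the data, and off for
  dSTORM-mode distributions; whether the original simulations enforced
  the floor is not stated anywhere, so both modes exist.
* **Edge handling.** Points live strictly inside the bounded region; no
  toroidal wrap-around, because spreads are bounded physical objects.
  Closed-form calibration against the infinite-plane Poisson law
  $F(r) = 1 - e^{-\lambda \pi r^2}$ is therefore performed at low
  density in a large region (10^4 foci at 0.1 foci/µm² in a single
  disc), where the boundary band is a ~2% sliver and edge bias is far
  below the Dvoretzky–Kiefer–Wolfowitz band at $\alpha = 0.01$.

Binning uses 50 nm right-open bins over 0–2000 nm with an overflow
class. No bin width is documented for the original histograms; 50 nm
resolves both the ~100 nm dSTORM peak and the 200–400 nm widefield
band, and is exposed in `analysis_config()`.

## Crowding filters

Two focus filters reproduce the crowding controls: `filter_low_density()`
keeps nuclei with **strictly** fewer than 0.8 foci/µm² in a stated
channel, and `filter_locally_sparse()` keeps foci with **exactly one**
same-channel neighbour within a 1 µm closed ball (self excluded).
Boundary conventions (strict `<`, closed ball) are pinned by tests.

## How large a hidden subpopulation could hide?

`detectability_bound()` asks, by simulation: if a fraction *p* of foci
were arranged in pairs at some exact separation, would a chi-square
two-sample comparison of NN histograms against CSR have detected it?
One subtlety matters: NN distances within a nucleus are positively
correlated (mutual neighbours contribute near-duplicate distances), so
the nominal $\chi^2$ reference distribution is anti-conservative — at
these sample sizes its raw type-I rate is an order of magnitude above
the nominal level. The statistic is therefore calibrated against its
own Monte-Carlo CSR-vs-CSR null distribution, which restores type-I
control by construction; the test suite verifies calibration at
$p = 0$ within the binomial 99% interval and that power is monotone in
*p* and saturates at $p = 1$. The reported bound is the largest grid
fraction whose detection power stays below the target (default 0.8 at
$\alpha = 0.05$).

# Two-channel structure

Cross-channel colocalization uses the strict "< 200 nm to the nearest
other-channel focus" convention; because the channels carry different
fluorophores, these distances are meaningful below the single-channel
resolution limit. Co-focus **composites** are formed by greedily
merging the closest cross-channel partners under 200 nm into an
intensity-weighted centroid; the merge radius for classification is a
package choice exposed in `analysis_config()` (the colocalization
convention motivates 200 nm, but no merging radius is documented).

**Pairs** are mutual nearest neighbours among composites within the
400 nm window. Mutual-NN prevents chains: in a row of three composites
at 0, 300 and 700 nm, only (0, 300) pairs. Visual pair-picking in the
original scoring cannot be reproduced algorithmically; mutual-NN is the
deterministic stand-in, and the truth-tag test shows it recovers ≥ 95%
of generative DSB pairs at realistic densities when offsets are zero
and background is absent.

Per-pair **intensity shares** express a member's brightness in one
channel as a percentage of the pair's total in that channel; the
least-squares slope of DMC1 share on RAD51 share is ~0 when the two
co-foci assemble independently (the slope is defined as 0 when the
predictor is constant). Pairs with a zero channel total are excluded
and counted.

## The category classifier

Each nucleus is classified from its composites and their
single-linkage clusters ("cytological complexes") at 1 µm:

| complexes | composites | channel counts | category |
|---|---|---|---|
| — | 0 foci | — | NEGATIVE |
| 1 | 1 | — | I (single focus) |
| 1 | 2 | — | II (focus pair) |
| 1 | ≥ 3 | — | III |
| ≥ 2 | — | ≤ 2 per channel | IV |
| ≥ 2 | — | > 2 in some channel | V |

Two ambiguities had to be resolved. "Within 1 µm of one another" is
read as **single-linkage** (chain) connectivity, which is deterministic
and order-free; a maximum-diameter reading would make some
three-composite configurations ambiguous. And a one-complex nucleus
with ≥ 3 composites is always III, even in the degenerate case where
merging leaves ≤ 2 foci per channel (possible when a co-focus sits
beside two singletons); such nuclei are flagged in the output's `note`
column. An independent rule-table oracle (breadth-first-search
complexes, direct counting) cross-checks the classifier on randomized
configurations.

## Landmark selection

`landmark_filter_and_score()` reproduces the selection rules for
scoring foci at a cut-site locus flanked by fluorescent *lacO*/*tetO*
arrays: ≥ 1 and ≤ 2 spots of each landmark; anchor = midpoint of the
closest (tetO, lacO) spot pair; exactly one DMC1 focus within 300 nm
of the anchor; at most two further DMC1 foci within 1 µm of it. A
"resolvable pair" is not defined operationally in the source material;
the package calls **pair** when at least one additional DMC1 focus lies
within 1 µm of the anchor focus. The separation of doubled tetO spots
(sister-chromatid split) is reported whenever two are present.

# The synthetic generator

`simulate_dsb_pattern()` encodes the generative model under test: per
DSB a uniformly placed midpoint, two ends at ±sep/2 along a uniform
orientation (rejection-sampled inside the region), per-end channel
occupancy, and per-channel positional offsets:

| parameter | default | rationale |
|---|---|---|
| end separation | uniform on [150, 400] nm | the pairing band above the ~150 nm floor; no distribution is documented, uniform is least-committal |
| channel offset | uniform on [0, 150] nm | side-by-side co-foci sit within the 200 nm colocalization radius |
| occupancy (both / R-only / D-only / empty) | 0.7/0.1/0.1/0.1 | makes ~85% of foci carry a cross-channel partner, echoing the observed colocalization fractions |
| intensity | log-normal, median 100 a.u. | broad, strictly positive focus brightness |

These defaults are testing stand-ins, not biological inference; all are
config parameters. The generator tags every focus with its DSB, end and
background status, and stores the sampled end geometry, so downstream
operations can be scored against ground truth.

What the generator does **not** emulate: chromatin-axis constraints on
focus positions (foci are free points, not beads on an invisible
polymer), focus-intensity correlations, stage mixtures within one
dataset, chromatic offset between channels, or irregular spread
outlines (unless a polygon region is supplied). Passing tests therefore
demonstrate correctness of the *measurement machinery* under a known
model, not that real nuclei follow that model.

For parameter-recovery studies, `simulate_spiked_pattern()` plants an
exact fraction of foci as pairs at an exact separation and fills the
rest with CSR. The recovery study conditions are 200 nuclei of 150 µm²
with 30 foci each (0.2 foci/µm² — the low-density regime the pairing
analysis targets) and 50 null replicates; at higher densities $\hat p$
acquires a known negative bias of order $p\,F_{CSR}(w)$ because paired
foci whose partner is pre-empted by a random closer neighbour shift
into CSR-shared bins.

# The dSTORM arm

`simulate_blink_stack()` renders two-state blinking emitters: per frame
each emitter switches on independently with `p_on`, photons are Poisson
with the stated mean, and the pixel-integrated Gaussian PSF is added to
a Poisson background (per-pixel signal shot noise is optional; the
localization-precision test enables it). `localize_frames()` is a
deliberately minimal localizer — frame-median background, MAD noise
scale, lightly smoothed local-maximum detection, 7×7 window centroid,
second-moment width, SNR ≥ 5 — because the conclusions under study
depend only on two decision rules: the SNR threshold and the
**spot-width cutoff** (keep an event iff its fitted FWHM ≤ cutoff ×
pixel size, default 2 px at 100 nm pixels). Parity with any particular
GUI reconstruction plugin is untestable and not attempted.

## The mis-localization artifact

When two emitters several hundred nanometres apart fluoresce in the
same frame, the localizer can merge them into a single event near the
photon-weighted midpoint — the mechanism that draws artifactual threads
between adjacent structures. Such merged events carry an inflated
fitted width (second moment ≈ PSF² + (d/2)²), which is exactly what the
width cutoff rejects. `artifact_decay_curve()` quantifies this on a
two-cluster simulation: the fraction of localizations in a 50 nm disc
at the true midpoint decays as the cutoff tightens, while the two
clusters' own intensity ratio stays put. Because the fitted width does
not depend on the cutoff, the stack is localized once with the filter
open and the cutoffs are applied to the recorded widths — numerically
identical to re-running the localizer per cutoff.

Demonstration conditions (used by the acceptance checks and
`analysis/04_dstorm_artifact.R`): two clusters of 8 emitters, 40 nm
scatter truncated at 2σ, centres 300 nm apart; `p_on` 0.06 so that
cross-cluster co-blinks are frequent; 3000 photons per event;
background 1; 10^4 frames; cutoff grid {2, 2.5, 3, ∞} px. Three of
these choices are load-bearing and deliberate:

* **PSF σ = 75 nm** for the dSTORM arm. The width filter was active in
  the original reconstructions while tens of thousands of events were
  still called, so a single-emitter event must pass the 2 px (200 nm)
  cutoff; that premise requires a fitted single-emitter FWHM below
  200 nm, i.e. σ ≤ ~85 nm under this localizer's width definition. The
  generic `emitter_model()` default stays at σ = 130 nm.
* **Truncated clusters.** A labelled focus has a finite footprint; an
  unbounded Gaussian tail occasionally drops a real emitter at the
  midpoint between structures, which the geometry being modelled (two
  distinct structures with empty space between) excludes.
* **Cutoff grid {2, 2.5, 3, ∞}.** Merged-event widths concentrate
  below ~4 px here (the merge geometry caps the second moment), so a
  4 px step would compare nearly identical event sets and measure only
  Monte-Carlo jitter; the chosen grid places every step where the
  width distribution actually has mass.

## Shape scoring and filament geometry

`cluster_localizations()` groups localizations by density reachability
(connected components of the ≤ radius graph, small components counted
as noise) and `fit_ellipse()` scores each cluster by covariance
eigen-decomposition. Axis lengths use a **4σ full-axis convention**
(±2σ, ~95% of a Gaussian cluster's footprint); the manual elliptical
selections being emulated have no documented convention, so the
multiplier is exposed and real-data parity of absolute lengths is not
claimed.

`estimate_filament()` is exact arithmetic on fixed conversion
constants: indirect immunostaining plus finite resolution broaden every
dimension by ~60 nm (a 10 nm-wide filament images at 70 nm, the
apparent-width floor), filaments hold ~2 nt/nm, one protomer binds
3 nt, and 6.6 protomers make a helical turn (back-derived from
33 protomers ≈ 5 turns; the canonical RecA value ~6.2 is selectable).
Occupancy is expressed against an 800 nt reference tract. Inputs at or
below the 60 nm broadening floor are an error, not a zero.

## Congruence of the two modalities

`blur_congruence()` checks that the super-resolution view collapses to
the widefield view under a 6 px Gaussian blur at 20 nm reconstruction
pixels (σ = 120 nm): NN distributions are computed for sr-focus
centroids, for foci detected in the blurred reconstruction, and for
widefield foci, and compared by Kolmogorov–Smirnov distance. The
congruence study renders the widefield reference through the same
observation model (`render_widefield()`, PSF σ 110 nm at 100 nm pixels,
then local-maximum detection) rather than using true structure centres:
both imaged modalities pull the maxima of barely-resolved doublets
inward by the same mechanism, and comparing an imaged quantity with a
ground-truth quantity would mismeasure the congruence that is actually
at issue. Study geometry: 25 isolated units, each a pair of
diffraction-scale foci 300 nm apart whose members are themselves sr
pairs at 100 nm; localization scatter σ 10 nm, sr clustering radius
30 nm (50 nm would chain the 100 nm sr pairs into one cluster).

# Numerical conventions and problem sizes

* Histogram bins are right-open; a distance exactly at the range end
  goes to overflow. Percentages print with half-up integer rounding.
* All mergers and tie-breaks (censoring, composite formation, pairing)
  are deterministic with coordinate-lexicographic tie resolution, so
  identical inputs give byte-identical outputs.
* Every stochastic entry point takes a `seed`; the pipeline derives
  fixed per-stage offsets from one user seed.
* Test and acceptance problem sizes: 10^4 foci for the CSR law
  calibration; 200 nuclei × 30 foci × 3 fractions for recovery; 10^4
  frames for the artifact curve; 25 units for congruence; brute-force
  oracle comparisons at ≤ 200 foci. These sizes put Monte-Carlo noise
  well inside the stated tolerances while keeping the whole suite in a
  few minutes on one CPU.

# Known limitations

* The CSR null ignores chromatin-axis structure; a "random" placement
  along an invisible polymer would be a stricter null and is not
  implemented.
* $\hat p$ is a lower-bound-flavoured estimator at moderate densities
  (negative bias grows with $F_{CSR}(w)$), and clipping gives it a
  small positive bias under the exact null.
* The localizer is single-emitter; it diagnoses multi-emitter events by
  width and rejects them rather than fitting them.
* No drift correction, 3-D astigmatism, bleaching kinetics or camera
  gain modelling; the blink model is two-state.
* Real-data parity of absolute sr-focus dimensions depends on the
  undocumented manual ellipse convention and is deliberately out of
  scope; only the conversion arithmetic downstream of an apparent
  length is asserted.
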
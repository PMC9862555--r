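---
title: "Automated gating and diagnostic classification of sputum flow cytometry"
author: "sputumFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated gating and diagnostic classification of sputum flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sputumFlow)
```

# The problem

Sputum from a patient at risk of lung cancer contains cells shed from the
airways: leukocytes, lung macrophages, epithelial cells, debris, and dying
cells. A porphyrin dye (TCPP) is preferentially retained by cancer and
cancer-associated cells, a fixable viability stain (FVS510) marks dead and
dying cells, and a small antibody panel (CD45, pooled CD66b/CD3/CD19
"lineage", CD206, EpCAM, pan-cytokeratin) identifies the major populations.
Each patient sample is acquired as a set of tubes on a flow cytometer: a
NIST bead tube that anchors the size scale, per-fluorochrome single-stain
compensation controls, an unstained tube, an isotype control, a "blood"
tube (leukocyte/macrophage panel plus TCPP) and an "epithelial" tube.

sputumFlow implements the full desk side of such an assay: reading FCS
event data, deriving spillover compensation de novo, logicle
transformation, flow-rate quality control, a heuristics-guided automated
gating cascade that isolates viable single cells, extraction of the
classifier's per-10,000 quantized features, a logistic cancer/non-cancer
model with a training harness, and the diagnostic-accuracy statistics layer
(Wilson intervals, prevalence-adjusted predictive values, PDLR, bootstrap
AUC). A synthetic sample/cohort generator with per-event ground truth makes
every stage testable without instrument data.

# Preprocessing

**FCS input.** The reader handles FCS 3.0/3.1 list-mode files with float or
double data in either byte order. A file whose decoded event count differs
from the header-declared total is rejected outright ("incomplete data
matrix") — the pipeline's first QC diamond. Because no FCS codec is
available as an R dependency in this package's dependency set, the reader
and the FCS 3.1 writer used for synthetic fixtures are implemented here
directly; the writer stores float32 little-endian data, so write-read
roundtrips are bit-stable.

**Channel dialects.** Logical roles (FSC-A, SSC-A, FVS510, TCPP, ...) are
mapped to instrument channel names through a dialect table. Two dialects
ship built in (LSR II-style fluorochrome names, Navios-style FL numbering);
other instruments supply their own map. The same analysis code serves both
instruments.

**Compensation.** Spillover entry (i, j) is the background-subtracted
median signal in channel j of the channel-i-positive control events,
normalised to a unit diagonal. The positive/negative split of each control
uses a one-dimensional two-component Gaussian mixture; a control whose
positive and negative medians are indistinguishable (separation below five
robust deviations) is an "uninformative control" error. Compensated values
are deliberately not clipped at zero — the logicle transform is designed
for them.

**Logicle.** The biexponential display transform is implemented from its
defining equations: the scale function $S(x) = a e^{bx} - c e^{-dx} - f$
(mirrored below its zero point) is inverted by safeguarded bisection with a
Newton polish, giving forward-transform accuracy far below the $10^{-6}$
relative tolerance the tests assert. Defaults are $T = 262144$, $M = 4.5$,
$W = 0.5$, $A = 0$ — a common convention when the acquisition reports
18-bit data; they are configurable per call. Scatter channels stay linear:
the analysis axes that matter downstream (density ratios, grids) are
defined on logicle fluorescence over log10 raw scatter.

**Flow-rate QC.** Acquisition time is split into `bin_count` (default 100)
equal bins; a bin whose event count deviates from the median by more than
`k` (default 5) MADs is removed with all its events. When the bin counts
are so uniform that their MAD is zero, a Poisson floor (the square root of
the median count) stands in, so a perfectly steady acquisition is never
flagged. Re-running on a cleaned sample removes no further events; the
mask is invariant to affine changes of the time unit. Per-channel drift
detection is intentionally out of scope.

# The gating cascade

The cascade runs per assay tube, in this order:

1. **Bead anchor.** A cluster fit (Gaussian mixture, up to 3 components)
   on FSC-A vs SSC-A of the bead tube finds the dominant 5 µm bead peak;
   the lower edge of its 99% coverage interval becomes the sample's
   minimum FSC-A. A tube whose largest cluster holds under 20% of events,
   or whose "cluster" is as dispersed as noise (FSC-A standard deviation
   above 15% of full scale), fails bead QC.
2. **Bead size exclusion (BSE).** Keep events with FSC-A in
   [fsc_min, 2.5e5] and SSC-A at most 2.5e5; events above those limits are
   dead cells. All gate bounds are closed on the kept side — no boundary
   convention is standard here, so we fix one and test it.
3. **Corner artifacts.** A detached population occasionally appears at
   very high FSC-H and near-zero SSC-H. It is detected as a mixture
   component whose FSC-H centroid lies in the top quartile of the range
   while its SSC-H centroid is below the 5th percentile; its events are
   removed and the heuristic logged. The mixture here is allowed one
   component more than the core fits so the artifact can earn its own
   cluster. The result is the "non-debris" population.
4. **Core viable gate (temporary).** A mixture on FSC-H vs SSC-H of
   non-debris events; the component lowest in SSC-H (holding at least 5%
   of events) is taken as the likely-live subpopulation, gated at its 0.90
   Mahalanobis density contour. If that captures under 10% of non-debris
   events the contour is widened to 0.99 and the fallback logged.
5. **Provisional singlets (temporary)** and the **viability tail gate.**
   A kernel density (Silverman bandwidth) of logicle FVS510 over the core
   viable singlets; the threshold is the first point right of the dominant
   mode where density falls to 10% of the mode density. For a Gaussian
   signal this lands at $m + 2.146\,s$, which the tests verify to 0.05
   logicle units. Viable events lie at or below the threshold. Temporary
   gates are then discarded.
6. **Singlets polygon.** In FSC-A vs FSC-W (area vs height is the
   configurable alternative), single cells form a tight ridge through the
   origin while doublets carry twice the area at a single cell's width.
   The ridge slope is estimated as the median per-event width/area ratio —
   robust to the doublet cloud at half that ratio — with a band of ±5 MAD
   of the residuals; the top-right corner is forced to (2.5e5, 2.5e5) so
   the upper diagonal is included. A malformed polygon (lower-left corner
   below zero, or top-left above bottom-right) signals that an off-ridge
   population has skewed the fit; the gate is then refit on the subset
   with SSC-A ≤ 5e4 and applied to the full viable population
   ("ssc_temp_gate").
7. **Viability refinement.** If more than 10% of singlets carry logicle
   FVS510 between 2.5 and the tail-gate threshold and a two-component
   mixture confirms a distinct upper component, the threshold is reset to
   the natural cutoff 2.5 and the polygon refit on the restricted viable
   set ("viability_reset").

Masks nest strictly (viable singlets within viable within non-debris
within BSE), which is asserted on every run. All mixture fits operate on a
seeded subsample (at most 2000 events) and classify the full population
from the fitted model, so a `GatingResult` is bit-reproducible for a fixed
seed. The viability threshold is computed per tube; whether the original
assay shared it across tubes of one sample is not documented, and per-tube
is the conservative choice.

# Features and eligibility

Fluorescence density is fluorescence relative to cell size: per viable
singlet, logicle signal divided by log10 of raw scatter area, partitioned
at 0.25 and 0.6 into regions R1/R2/R3 (R2 closed at both bounds, matching
the printed "< 0.25, 0.25–0.6, > 0.6"). Grid features quantize logicle
intensity into low (< 1.5), low-mid [1.5, 2.5), mid [2.5, 3) and high
(≥ 3) windows — lower-closed, so printed boundary values fall
deterministically — and tabulate a 4×4 grid per 10,000 viable singlets.
Both feature families sum to exactly 10,000 per-10K units, a conservation
property the tests assert, and are invariant to duplicating every event.

The model's four flow variables come from the blood tube (both tubes carry
FVS510, CD45 and TCPP; the blood tube is the default source and the choice
is configurable): the TCPP/log10 SSC-A region-3 count, the FVS510/log10
FSC-A region-2 count, and the CD206-low × lineage-mid grid cell
(non-macrophage leukocytes). The lineage "mid" sector is the [2.5, 3)
window by default and config-exposed. The epithelial-tube EpCAM × pan-CK
grid is computed and reported but feeds no model term. A sample is
eligible only with at least 10,000 viable singlets and at least 10 events
in the lung-macrophage window (CD206 mid-or-high × lineage low-or-low-mid)
— the evidence that the sample actually sampled the lung.

# The classifier

The model is an ordinary maximum-likelihood logistic regression:

$$\mathrm{logit}\,P(\text{cancer}) = b_0 + b_1\,\text{age} +
b_2\,\text{tcpp}_{R3} + b_3\,\text{fvs}_{R2} + b_4\,\text{cd206}^{low}
\text{lin}^{mid} + b_5\,(\text{age}\times\text{fvs}_{R2})$$

Predictors are not normalised, so coefficients are interpretable on their
natural units. Complete separation — routine on cleanly separated
synthetic cohorts — is flagged and handled by a lightly ridge-penalised
IRLS refit (penalty $10^{-4}$ on standardised scale, intercept
unpenalised), with the flag carried in the model object. Samples without a
label are accepted in cohort tables but excluded from fitting.

The training harness mirrors the original design: repeated random
training subsets of 100 samples holding exactly 20 cancer samples (the
cohort's 20% ratio; with 28 cancer samples available there are
C(28, 20) = 3,108,105 distinct cancer strata alone), forward/backward
stepwise selection per split using Wald p-values (enter below 0.05, remove
at or above 0.05; an interaction is eligible only while both parents are
in), and per-variable selection frequencies. The published criterion for
"best performance" on the ROC is not printed; we operationalise the cutoff
as the maximiser of Youden's J over all distinct predicted probabilities,
and return the full cutoff grid so any other choice can be audited. A call
is "cancer" only when the probability strictly exceeds the cutoff.

The diagnostic layer reports sensitivity, specificity and accuracy with
Wilson score intervals, trapezoid AUC with a class-stratified percentile
bootstrap (2000 replicates by default, seeded), predictive values at the
dataset prevalence and at external prevalences via Bayes' theorem with
logit-scale (Mercaldo-style) intervals (0.5 continuity correction when a
cell is empty), the positive diagnostic likelihood ratio
sens/(1 − spec), and the ATS minimal-accuracy threshold
((1 − prevalence)/prevalence) × (R/(1 − R)).

# The synthetic generator

The generator defines the study conditions for every test. Scatter is
lognormal on the raw 18-bit scale; fluorescence is Gaussian on the logicle
scale and inverted to raw before a known spillover matrix (4–12% bleeds)
is applied, so compensation has an exact ground truth. Planted logicle
values are defined post-autofluorescence: the assay tubes' only distortion
is spillover, while unstained and single-stain control tubes carry an
explicit baseline so de-novo spillover derivation is honestly exercised.

Default structural fractions per assay tube: 8% debris, 15% dead cells
(FVS510 ≈ 3.3), 8% doublets, 20% lineage-mid leukocytes, 12% CD206-bright
macrophages, remainder other live cells. Two feature-carrying
subpopulations are planted at class-dependent per-10K targets: TCPP-bright
cells (60 per 10K non-cancer, 400 cancer — bright enough that their
TCPP/log10 SSC-A ratio clears 0.6 essentially always) and small
moderately-FVS510 "stressed" cells (150 vs 900 per 10K) whose
FVS510/log10 FSC-A ratio exceeds 0.25 through a small forward scatter
rather than a high stain, keeping them below the viability threshold. This
corridor — above the R2 bound, below the tail gate — is geometrically
narrow; the stressed population is therefore tight (logicle FVS510
1.165 ± 0.03 at FSC-A ≈ 2.7e4), and its effective capture depends slightly
on the per-sample threshold, which is why the fast feature-only cohort
mode draws from the *effective* rates the full pipeline recovers (about
55/390 per 10K for TCPP, 450/1050 for the FVS510 feature including its
live-cell tail baseline, 2850 for the grid cell) rather than the nominal
planted rates. Event counts default to 50,000 per assay tube; the test
suite scales samples to 15,000–25,000 events, which keeps every property
(mask nesting, recall ≥ 0.9, dead-cell leakage ≤ 0.05, per-10K
conservation) measurable in minutes on one core.

Optional planted pathologies drive the heuristics tests: a corner-artifact
population (FSC-A ≈ 2.2e5, SSC-H under 400), a high-SSC contaminant with
low, flat pulse width that demonstrably skews the naive singlets fit, and
doublets built by summing two singlet area draws.

What the generator does *not* emulate: instrument-specific noise floors
and PMT saturation artifacts, autofluorescence spectra (baseline is a
single lognormal), mucus/debris continuum between populations, day-to-day
staining drift, and any correlation between age and the flow features
within a class. Passing tests therefore demonstrate that the algorithms
recover what was planted under clean-but-nontrivial conditions, not that
the assay's clinical operating points reproduce; the published clinical
AUCs require the original patient cohorts and are out of desk scope.

# Numerical choices and degenerate inputs

* Mixture fits: model-based Gaussian clustering with hierarchical
  initialisation on a seeded subsample of at most 2000 events; component
  count defaults to 3 (4 where an artifact cluster is being hunted).
* Tail gate: KDE with Silverman's rule on 1024 grid points; if density
  never falls below tolerance the right edge of the support is returned.
* Tie-breaks: ROC cutoff ties on Youden's J resolve to the lowest (most
  sensitive) cutoff; quantization window edges are lower-closed; gate
  bounds are closed on the kept side; a probability exactly at the cutoff
  is non-cancer.
* Raising the tail-gate tolerance moves the threshold toward the mode
  (never away from it): at tolerance 1 the threshold *is* the mode.
* Zero-variance viability signal, empty masks, single-class label
  vectors, degenerate prevalences and singular spillover matrices are all
  explicit errors naming the failing quantity, not silent NAs.
* All randomness flows through explicit seeds; RNG state of the caller is
  saved and restored, and child streams are derived arithmetically (kept
  within 32-bit range) so results are reproducible across sessions.

# Known limitations

* The published model's coefficients were never printed; only their signs
  and the model structure are reproducible, and the package makes no
  attempt to match clinical operating points.
* The corner-artifact region and bead-cluster contour have no published
  numeric extent; both are config-exposed and our defaults are stated
  above.
* The per-channel flow-rate drift criterion hinted at by the original QC
  reference is not implemented; only event-rate anomalies are removed.
* The printed PDLR values of the source assay's performance table do not
  equal sens/(1 − spec) recomputed from its own printed counts (6.68 from
  the counts vs 6.31 printed); the package reports the quotient it
  defines and leaves the discrepancy to the reader.
* The ridge fallback for separated fits trades a small, fixed bias for
  finiteness; its standard errors are penalised-likelihood approximations.
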
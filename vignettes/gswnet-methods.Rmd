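---
title: "Methods: interictal EEG network analysis of generalized spike-wave discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interictal EEG network analysis of generalized spike-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gswnet)
```

## Scope and model

`gswnet` implements a complete interictal EEG network pipeline for
generalized spike-wave discharges (GSWDs), the hallmark of idiopathic
generalized epilepsies: from multichannel scalp recordings through
spike-event detection, source estimation, phase-lag-sensitive functional
connectivity, permutation-based network inference, and graph-theoretic
characterization (small-world propensity and influence fusion).  Because no
public patient cohort exists for this design, the package ships a
first-class synthetic cohort generator with known ground truth; every
claim the test suite makes about recovery rates refers to that generator.

The analysis contrasts two within-subject states: 4-s epochs centred on
spike-wave discharges (GSW) and equally many 4-s resting-state (RS) epochs
from the same recording.

## Preprocessing

Four third-order Butterworth stages are applied: high-pass 0.5 Hz,
low-pass 50 Hz, band-stop 47–53 Hz, band-stop 97–103 Hz (skipped below a
206 Hz sampling rate, where the band exceeds Nyquist).  All stages run
forward–backward: zero-phase filtering doubles the effective order but
leaves event latencies untouched, which matters because detected spike
times anchor both epoching and ROI selection.  Re-referencing is to the
common average, making the per-sample channel mean exactly zero.

Spike events are detected on the global field power (GFP), the spatial
standard deviation of the scalp field at each sample:
$\mathrm{GFP}(t) = \sqrt{\tfrac1N\sum_{i=1}^N (u_i(t) - \bar u(t))^2}$.
GFP is reference-independent, so the detection does not depend on the
montage.  A peak qualifies when its topographic prominence exceeds a
threshold (default: five times the median GFP — comfortably above
background fluctuation yet far below epileptiform peaks in the synthetic
cohort); the event is placed at the temporal midpoint of the ascending
limb, i.e. halfway between the preceding GFP local minimum and the peak,
rounding half down.  Peaks closer than a refractory period (default 2 s)
collapse to the largest one; because the generator's discharge trains wane
(per-cycle decay 0.75), the largest peak is the first spike of the train,
which therefore anchors the epoch.  Expert visual artifact rejection is
replaced by an amplitude-threshold rejector, the only practical stand-in
without a neurophysiologist in the loop.

RS epochs are drawn uniformly at random (seeded) over all windows whose
every sample lies at least 2 s from every detected event, falling back to
an earliest-first packing when random placement strands windows.

## Source estimation

The inverse solver is sLORETA on a user-supplied lead field: the
minimum-norm kernel $K = G^{\mathsf T}(G G^{\mathsf T} + \lambda C)^{-1}$
with noise covariance $C$ estimated from RS epochs (diagonal loading
$\varepsilon\,\mathrm{tr}(C)/N$ keeps the average-referenced covariance
invertible), followed by source-wise standardization by
$\sqrt{[KG]_{ii}}$, the resolution-matrix diagonal.  This classical
standardization is what gives sLORETA zero localization error for a single
noiseless source — the property the test suite verifies exhaustively over
every column of a 19×60 synthetic lead field.  Regularization follows the
SNR heuristic $\lambda = \mathrm{tr}(GG^{\mathsf T}) /
(\mathrm{tr}(C)\,\mathrm{SNR}^2)$ with SNR 3 by default; `lambda_rel`
overrides the $1/\mathrm{SNR}^2$ factor directly.  ROI selection takes,
per event, the source with maximal squared standardized activity in a
configurable window (default: the event sample alone, since the width of
"during the event" is an open choice).  Energy ties break to the lower
source index, logged.

## Connectivity

Functional connectivity is the imaginary part of coherency (ImCoh) at
integer frequencies 1–12 Hz.  Coherency is estimated by Welch averaging
with 1-s Hann segments and 50% overlap, so integer frequencies map to
integer bins at integer sampling rates; cross-spectra are pooled over all
segments of all epochs of a state *before* normalization (the consistent
pooled estimator — per-epoch coherency averaged afterwards is a biased
alternative the package deliberately avoids).  ImCoh is zero for any
instantaneous (real-valued) mixture of independent sources, which is the
reason it is the estimator of choice at the source level: volume
conduction and inverse-operator leakage are instantaneous and cannot
create it.  Graph weights downstream use $|\mathrm{ImCoh}|$, since the
path-length and clustering definitions assume non-negative weights; the
signed tensor is preserved for reporting.

## Network inference

Paired network-based statistics (NBS): edge-wise paired t statistics
(GSW − RS), a primary threshold $T$, connected components of the
suprathreshold graph scored by extent (edge count), and a family-wise null
distribution of the maximum extent built from within-subject condition
flips (5000 permutations by default; p-values use the
$(1 + \cdot)/(1 + n_{\mathrm{perm}})$ convention, so the smallest
attainable p with 5000 permutations is ≈ 0.0002).  The main adjacency uses
$T = 1$; a strict variant with $T = 3.5$ yields the low-density network on
which influential-node structure is examined.  The choice matters: extent-
based cluster inference at a liberal threshold has power only for broad,
distributed differences, while a focal effect of a few edges is resolved
only at the strict threshold — the validation suite demonstrates both
regimes.  Significant "1" entries are then replaced by the connectivity
magnitudes (the weighted modified network).

## Graph metrics

Weighted characteristic path length
$L^w = \tfrac1n \sum_i \tfrac{\sum_{j \ne i} d^w_{ij}}{n-1}$ uses shortest
paths on lengths $1/w$ (the package's explicit weight-to-length map; the
field has no single convention and this is the most common one).
Disconnected graphs fall back to the largest component with a warning.
The weighted clustering coefficient uses the geometric-mean triangle
intensity with weights rescaled by the maximum,
$t_i = \tfrac12\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$, node
term $2t_i/(k_i(k_i-1))$ with binary degree $k_i$ — the denominator is read
as $k_i(k_i - 1)$, the only reading under which $C \le 1$ and which matches
the cited clustering definition.

Small-world propensity compares the observed metrics with lattice and
random null networks that preserve the node count, edge count, and exact
weight multiset: the lattice null packs edges into the shortest ring
distances with larger weights nearer the diagonal band; the random null
scatters the weights uniformly.  With null means over `n_null`
realizations (default 10),
$\Delta_C = (C_{latt} - C_{obs})/(C_{latt} - C_{rand})$ and
$\Delta_L = (L_{obs} - L_{rand})/(L_{latt} - L_{rand})$, both clipped to
$[0,1]$, give $\phi = 1 - \sqrt{(\Delta_C^2 + \Delta_L^2)/2}$; values
above 0.6 are read as strong small-world propensity.  The contribution to
deviation is implemented as $\delta = (4/\pi)\arctan(\Delta_L/\Delta_C) - 1$
(with $\arctan(\infty) = \pi/2$ and $\delta = 0$ when both deltas vanish):
this is the only placement of the $-1$ under which the anchor cases
($\Delta_C = 0, \Delta_L = 1 \Rightarrow \delta = 1$;
$\Delta_L = \Delta_C \Rightarrow \delta = 0$) hold.  Degenerate null
spreads set the corresponding delta to 0 with a warning rather than
dividing by zero.

The canonical ensemble used for validation is a weighted Watts–Strogatz
construction: a ring lattice (n = 60, k = 6) with weights decaying
exponentially in ring distance (scale 10, a moderate decay that keeps
mid-range connections relevant) and 10% of edges rewired *keeping their
weights*, so shortcuts stay strong — rewiring that re-derived weights from
the new distance would produce weak, useless shortcuts and no small-world
regime.

## Influence fusion

Six per-node measures feed the integrated value of influence (IVI): degree
(DC), neighborhood connectivity (NC, mean neighbour degree), ClusterRank
($10^{-c_i}\sum_{j\in\Gamma(i)}(k_j+1)$ with local clustering $c_i$; the
out-degree term of the directed original becomes plain degree on
undirected graphs), local H-index (own h-index plus neighbours'),
betweenness (on weighted lengths $1/w$), and collective influence
($(k_i-1)\sum_{d(i,j)=\ell}(k_j-1)$, frontier radius $\ell = 2$).  All but
betweenness act on the binarized support by default; a weighted mode is
provided.  Each measure is range-normalized to $[1, 100]$ — the lower
anchor of 1 (not 0) prevents the fused products from vanishing, and
constant measures map to 1.  Then
$\mathrm{spreading} = (NC' + CR')(BC' + CI')$,
$\mathrm{hubness} = DC' + LH'$, and
$\mathrm{IVI} = \mathrm{hubness} \times \mathrm{spreading}$, normalized to
$[1,100]$.  Nodes with IVI strictly above the mean plus one standard
deviation form the influential set.

## Statistical protocol

Per frequency, per-subject GSW−RS differences pass a Shapiro–Wilk gate at
$\alpha = 0.05$: normal differences go to a two-sided paired t-test,
non-normal ones to the Wilcoxon signed-rank test (normal approximation
with continuity correction; zeros dropped — exact enumeration adds nothing
at n = 23).  Bonferroni adjustment uses the 12-frequency family.  Across
frequencies, a 2 (state) × 12 (frequency) repeated-measures ANOVA reports
main effects and the interaction with partial $\eta^2$; Mauchly's test
gates the Greenhouse–Geisser correction on frequency-involved effects.
Both branches are two-sided; the protocol's pairwise structure with two
states makes a separate post-hoc test redundant.

## The synthetic cohort

The generator emulates the validation conditions end to end: 23 subjects,
19 channels in the 10–20 montage, 256 Hz, ~5 GSWD trains per subject (115
cohort-wide, approximating an average interictal recording yield), each a
4-cycle 3 Hz spike-wave template (triangular spike, rise:fall 1:2, 20% of
the cycle; opposite-polarity half-sine slow wave, which places the
dominant spectral line at the repetition rate; per-cycle decay 0.75)
planted 10 s apart so GSW and RS epochs never collide.  Background is
per-source pink noise plus low-amplitude 10 Hz alpha.

Three deliberate design choices encode the biology:

* **Generator vs hub.**  The spiking (generator) source is distinct from
  the coupling hub: a source dominated by its own discharge has almost no
  normalized coherence with anything else, and discharge generators and
  network hubs are distinct roles.  The hub instead broadcasts one common
  3 Hz driver per burst; its partners receive it lagged by π/2.  Planting
  independent-phase couplings on a shared node would make them dilute each
  other.
* **Generalized discharge.**  All sources co-activate (zero-lag) during a
  burst at weak gain, and the generator's spike is scaled by
  $8\sqrt{n_{sources}}$ noise units so its scalp GFP is ~8× background
  regardless of dimensionality — discharges dominate the record, as in
  real EEG.  Zero-lag co-activation is invisible to ImCoh by construction,
  so it adds realism without contaminating the connectivity ground truth.
* **Source-space size.**  The default source space has 24 sources at 19
  sensors.  The nodes stand for ROI-level regions, and this near-determined
  regime is where a 19-channel inverse is informative: in experiments with
  much larger spaces (60 sources), template-operator leakage of the coupled
  signals produced spurious lagged "ghost" connectivity more consistent
  across subjects than the planted effect itself — a genuine limitation of
  low-density source connectivity worth knowing about, and the reason the
  per-subject forward models are additionally jittered around the template
  (column-renormalized Gaussian perturbation, weight 0.3) the way real
  anatomies scatter around a template head model.

What the generator does *not* emulate: real head geometry (the lead field
is random), ocular/muscle artifacts, inter-subject variation in discharge
morphology or rate, and medication effects.  Passing recovery tests on
this cohort therefore demonstrates the pipeline's internal correctness and
sensitivity under honest noise, not clinical performance.

## Validation scales and numerical choices

The test suite runs the pipeline at the scales the package documents:
event-detection sensitivity/precision ≥ 0.95 (±2 samples) over a 23-subject
cohort; FWER ≤ 0.075 over 200 null NBS replicates at 500 permutations;
planted component recovery in ≥ 90% of 20 seeds; path-length decrease and
hub recovery in ≥ 80% of 20 full cohort runs; type-I error within
[0.03, 0.07] for both inferential paths.  All randomness is seeded; every
generator routine is bit-reproducible under its seed.  Matrix
comparisons against brute-force oracles (per-sample GFP, exhaustive
shortest paths and triangle enumeration, path-counting betweenness) hold
to 1e-9 or better.

Known limitations: the NBS component statistic is extent only (intensity
is not implemented); path lengths on disconnected graphs depend on the
largest-component convention; ImCoh's insensitivity to zero-lag coupling
means genuinely instantaneous physiological interactions are invisible to
the whole pipeline by design.
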
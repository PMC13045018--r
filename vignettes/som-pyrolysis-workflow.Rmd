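---
title: "Characterizing soil organic matter by py-GC/MS and EGA/MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing soil organic matter by py-GC/MS and EGA/MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrosom)
```

# The problem

Soil organic matter is a mixture of biopolymers too complex to measure
intact. Analytical pyrolysis thermally cleaves it into volatile products
(pyrolysates) — phenols and methoxyphenols from lignin, furans and
anhydrosugars from carbohydrates, alkanes/alkenes from lipids and waxes,
N-heterocycles from proteins — which a GC column separates and an
electron-ionization quadrupole MS detects (m/z 29–850). A companion
evolved-gas mode (EGA/MS) skips the column and ramps the furnace
(100 °C → 900 °C), recording intensity against temperature instead of time
(m/z 29–650). This package turns those raw runs into compound tables, class
profiles, similarity networks and ecological statistics.

`pyrosom` represents data as S4 objects: `Spectrum` (one EI fragmentation
spectrum), `PyRun` (a scan series in pyrolysis or EGA mode), `Feature`
(one deconvoluted pyrolysate), `AlignedFeature` (a cross-sample group),
`MolecularNetwork`, and `EGACurve`. Validity methods enforce the invariants
the numerics rely on: strictly ascending m/z, non-negative intensities,
mode-dependent scan ranges, network degree and edge-threshold bounds.

# Deconvolution model

EI spectra from quadrupole instruments and the reference libraries used to
annotate them are nominal-mass data, so all spectral arithmetic happens on
the unit-mass (integer m/z) grid.

**EIC construction.** One extracted-ion chromatogram per integer m/z bin
that reaches the intensity threshold (default `1e5` counts) in at least one
scan. The threshold gates the *existence* of an EIC, not its points:
sub-threshold points within a kept trace are retained, since peak shape
matters for curve resolution.

**Peak detection.** Local maxima with height ≥ `1e5` counts and
signal-to-noise ≥ 5. Noise is estimated as `1.4826 × MAD(diff(trace)) / √2`:
differencing cancels the smooth chromatographic signal, the MAD resists the
peaks themselves, and the √2 removes the variance doubling that differencing
introduces. This estimator is used because peak-containing traces break
naive standard deviations.

**Curve resolution.** Detected peaks are grouped into retention-time windows
(single linkage; a gap > 0.05 min starts a new window). Within a window,
apexes are clustered by *height-anchored* assignment: tall peaks found
components and remaining peaks join the nearest anchor within ~2.5 scan
widths. Plain single-linkage was rejected here because fragment apexes of
two genuinely distinct components jitter by a scan or two and chain into one
cluster; anchoring at the tallest fragments prevents that while still
merging the jittered fragments of one compound. The window's scans × m/z
matrix `X` (restricted to bins with evidence in the window, and smoothed by
a 5-scan moving average — temporal smoothing is linear in time, so component
*spectra* are unchanged while the scan-to-scan noise floor the low-rank
model cannot fit is suppressed) is then factorized as `X ≈ C Sᵀ` with both
factors non-negative, by alternating least squares with negative parts
clipped after each unconstrained solve. The number of components is the
number of apex anchors; `S` is initialized from the apex-scan spectra, which
makes the procedure deterministic. Tails of neighboring compounds leaking
into the window edges are modeled by discardable edge components initialized
from the first/last scans. Iteration stops when the relative residual
changes by < 1e-6, at 200 iterations (with a warning), or as soon as an
update would increase the residual (the previous iterate is kept), so the
recorded residual trace is non-increasing. Each retained component becomes a
`Feature`: spectrum = its `S` column normalized to base peak 999; height =
the apex intensity of its base-peak ion; area = the trapezoidal integral of
that profile.

# Alignment, annotation, classification

Features are aligned across samples with the blended score
`w·max(0, 1 − |ΔRT|/rtTol) + (1−w)·cosine`, threshold 0.7, `rtTol = 0.05`
min and `w = 0.5`. Equal weighting is used because neither term alone
identifies a pyrolysate reliably: isomers share spectra but not RT, and
co-eluting compounds share RT but not spectra. Merging is greedy
best-pair-first with deterministic tie-breaking (lower mean RT, then sample
ids); a group never holds two features from one sample, and unmatched
features remain as singletons, so alignment is a partition of its input.
Consensus spectra are height-weighted means on the unit-mass grid.

Annotation is plain (unweighted) cosine against an MSP library with a 0.7
acceptance threshold; an optional intensity exponent is exposed for users
who want NIST-style weighted matching, but the default stays at 1 because
the plain form is transparent and directly checkable against a hand
computation. Classification is a pure lookup from compound name to one of
the 12 SOM pyrolysate classes, case-insensitive and whitespace-normalized
(library hit strings vary in casing and CAS-style suffixes); compounds
missing from the class library stay `"unclassified"`, and the operation is
idempotent.

# Molecular networking

All pairwise cosines between consensus spectra form the candidate graph;
edges need cosine ≥ 0.7 and must survive mutual-TopK pruning (each endpoint
ranks the other within its K = 10 most similar candidates). Mutual pruning
is used because it is the only variant that *guarantees* the advertised
"maximum number of neighboring nodes per node": keeping an edge when either
endpoint ranks the other highly can push degrees past K. Nodes without a
surviving edge are flagged singletons and excluded from cluster output;
clusters are connected components ordered by size.

Unannotated nodes take the class of their *most similar, connected, and
annotated* neighbor in a single pass: only originally library-annotated
nodes donate labels by default, so a propagated guess cannot seed further
guesses. Chained propagation (iterating until fixpoint) is available behind
`chain = TRUE` but off by default — with EI spectra, transitive similarity
decays quickly and chained labels inherit compounding error. Ties are broken
by neighbor abundance, then node id. Provenance (`"library"` vs
`"propagated"`) is stored per node, and a propagation never touches an
existing label, so the unclassified count is non-increasing.

# Ecological statistics

Class relative abundance is the classified-height share per sample
(integrated peak *heights*, not areas, are the default abundance measure —
heights are what the detector thresholds — with areas available from the
feature table; neither is a carbon mass). Diversity uses compound-level
shares: Shannon `H = −Σ p ln p` (natural log) and the Gini–Simpson form
`1 − Σ p²`, chosen over Simpson's `D` because on this scale larger values
mean more diverse, matching how soil diversity indices near 0.87 are usually
quoted. Bray–Curtis dissimilarities are computed from replicate-averaged
intensities; PERMANOVA uses the standard distance-based decomposition
(`SS_total = Σ d²/n`, within-group analogue per group) with pseudo-F and a
permutation p-value `(1 + #{F* ≥ F}) / (1 + n_perm)` over free label
permutations (no strata), 999 by default. Hierarchical clustering uses
`ln(x+1)` (the +1 handles structural zeros; the log base is a display
choice) and average linkage on Bray–Curtis distances. Pearson correlation
between ecosystem profiles is computed on the union of compounds with
absences as zeros.

# EGA profiling

Scan times map to furnace temperature piecewise-linearly (hold, then ramp,
capped at the end temperature). Class XICs sum the major m/z of the class's
marker compounds (e.g. m/z 105 for lignin markers, 94/107/108 for phenols,
44 for CO₂); the all-bin XIC equals the TIC exactly. Curves are smoothed
with a 5-scan moving average because the 2-second EGA scan time makes raw
curves coarse. Peak temperatures are local maxima filtered by topographic
prominence (≥ 10% of the curve maximum) and reported intensity-sorted.
Signal above 650 °C is flagged; the region is called inorganic-carbon-
consistent when CO₂ (m/z 44) contributes > 50% of its summed intensity,
stable-OM-consistent otherwise. The 0.5 dominance ratio operationalizes a
qualitative carbonate-vs-stable-OM distinction and is exposed as a
parameter rather than claimed as a measured constant.

# Synthetic data: what it emulates, what it does not

The generator provides ground truth for every stage. Compounds are built in
*structural families*: a family has a base fragment set (12–20 fragments,
m/z 30–300); members keep ≥ 60% of it (low-intensity fragments dropped
preferentially, log-normal intensity jitter) plus up to 3 private fragments.
That yields within-family cosines above 0.7 and cross-family cosines below
0.5 — the regime molecular networking assumes. Each family carries one
compound class, because classes *are* structure-based; this is what makes
neighbor propagation meaningful. Elution profiles are Gaussian with sd 0.02
min, chosen so the 0.05-min RT tolerance is genuinely stressed by the
forced co-elution pairs (apex separations drawn from 0.02–0.05 min);
baseline compounds sit on a jittered grid with ≥ 0.08 min spacing so
co-elution stress is controlled explicitly rather than by accident.
Abundances are log-normal (sd 1 on the log scale) for realistic
rank-abundance curves. The multi-ecosystem design plants a globally shared
core, per-ecosystem tails, and a wetland-exclusive set present only in the
two wetland ecosystems. All generators are deterministic under a seed and
restore the caller's RNG state.

What the synthetic benchmarks do **not** show: real pyrolysates have
correlated fragment structures (homologous series, isotope satellites),
retention drift between runs, heteroscedastic detector noise, column bleed
and matrix effects, none of which are simulated. Passing the benchmarks
demonstrates the algorithms are implemented correctly and behave as designed
under controlled difficulty — not that a given instrument's data will
annotate at the same rates.

# Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `intensityThreshold` | 1e5 | counts | EIC existence gate |
| `minSN` | 5 | — | peak signal-to-noise |
| `minHeight` | 1e5 | counts | minimum feature height |
| `rtTol` | 0.05 | min | curve-resolution window / alignment RT scale |
| `alignThreshold` | 0.7 | — | alignment score cutoff |
| `wRt` | 0.5 | — | RT weight in the alignment score |
| `annotateMinCosine` | 0.7 | — | library annotation cutoff |
| `networkMinCosine` | 0.7 | — | network edge cutoff |
| `topK` | 10 | — | max neighbors per node (mutual pruning) |
| `nPerm` | 999 | — | PERMANOVA permutations |
| EGA program | 100 °C, 1 min, 10 °C/min, 900 °C | — | furnace ramp |
| `icCutoff` | 650 | °C | high-temperature flag |

# Numerical choices and degenerate inputs

Cosines are clipped to [0, 1] against floating-point drift; an all-zero
spectrum is an error (undefined similarity), as are a zero-variance profile
in correlation, both-zero vectors in Bray–Curtis, and a PERMANOVA with
`n ≤` number of groups (no residual degrees of freedom). Share vectors that
do not sum to 1 are renormalized with a warning rather than silently. Ties
are broken deterministically everywhere (library order for annotation;
score, mean RT, then sample ids for alignment; cosine, abundance, then node
id for propagation), so identical inputs and seeds give identical outputs.
Retention times are normalized to minutes on load whatever the source units,
because every chromatographic tolerance is expressed in minutes.

Deconvolution quality is reported as the relative ALS reconstruction error:
per window, and pooled across windows norm-weighted (so abundant signal
dominates, as it does in the raw matrix). Under additive noise the pooled
residual approaches the noise floor; individual weak-compound windows sit
slightly above it because a low-rank model cannot absorb white noise.

# Problem sizes used in the checks

The test-suite and acceptance benchmarks run at desk scale: 20-compound runs
(~560 scans) with 5 forced co-elution pairs for deconvolution recovery;
100 library spectra under 5% multiplicative noise for annotation; 1000-node
networks for the degree/threshold bounds; 90-node three-family networks with
half the labels hidden for propagation; 500 null data sets (n = 12, 199
permutations) for PERMANOVA calibration; and a 5-ecosystem × 3-replicate
design (120-compound pool, 24 wetland-exclusive) for the end-to-end chain.

# Known limitations

* Unit-mass binning: high-resolution data are collapsed to nominal mass.
* No retention-time warping across runs; alignment assumes stable RT within
  the 0.05-min tolerance.
* No retention-index confirmation of annotations and no structure
  elucidation; annotation quality is bounded by the supplied library.
* MCR-ALS with clipping can, on heavily overlapped low-signal windows,
  converge to a local solution; initialization from apex spectra makes this
  deterministic but not globally optimal.
* EGA interpretation above 650 °C is a heuristic flag, not a carbonate
  measurement; acid-treatment experiments are out of scope.
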
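---
title: "Methods: the cencat dependence calculus, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cencat dependence calculus, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cencat)
```

## The assay model

Translation is among the most ATP-expensive activities of a cell, so the
short-term protein-synthesis rate is a proxy for ATP production. The
assay measures that rate by a pulse of a noncanonical amino acid (ncAA)
that is incorporated into nascent protein and click-labelled with a
fluorescent azide, under four inhibitor conditions: vehicle (DMSO),
2-deoxyglucose (2-DG), oligomycin, and both. Writing `MFI(c)` for the
geometric mean ncAA fluorescence of a gated population under condition
`c` and `ΔMFI = MFI(DMSO) − MFI(2DG+Oligo)`:

* glucose dependence (%) `= 100 (MFI(DMSO) − MFI(2DG)) / ΔMFI`
* mitochondrial dependence (%) `= 100 (MFI(DMSO) − MFI(Oligo)) / ΔMFI`
* glycolytic capacity `= 100 −` mitochondrial dependence
* FAO/AAO capacity `= 100 −` glucose dependence

`dependence_profile()` computes exactly these ratios. Three properties
follow from the algebra and are enforced by tests: the capacities are
exact complements; the metrics are invariant under a common affine
rescaling of the four MFIs (gain or offset changes of the cytometer
cancel, because each metric is a ratio of differences); and swapping the
2-DG and oligomycin inputs swaps the two dependences.

The interpretation leans on two assumptions the package cannot check:
the double inhibition fully abolishes ATP-linked translation (so
`MFI(2DG+Oligo)` is the background floor), and the ncAA signal is linear
in the amount of protein synthesised during the pulse. Deviations show
up as out-of-range metrics, which is why raw values are reported and
flagged rather than clamped.

### Degenerate inputs and flags

`ΔMFI ≤ 0` leaves every ratio undefined; the package refuses to divide
and raises an error. Above zero but below the *resolution floor*, the
profile is computed but flagged `LOW_RESOLUTION`: quiescent populations
incorporate so little ncAA that small fluctuations swing the ratios
wildly. The default floor is `3 ×` the pooled within-condition standard
error of the gMFI, where each condition's SE combines the per-replicate
delta-method SEs (`gMFI · sd(log x) / sqrt(n)`) and the pooled value is
the root-mean-square over the four conditions; an absolute floor in
fluorescence units can be configured instead. A negative mitochondrial
dependence — oligomycin *increasing* translation, a real phenomenon in
some lymphocytes termed MITA — raises the `MITA` flag; `OUT_OF_RANGE`
and `NEGATIVE_GLUCOSE_DEP` behave analogously. Clamping to [0, 100] is
available only at the reporting layer (`clamp_profile()`), never in the
fitted values, because out-of-range values carry QC information.

### Why the geometric mean

Cytometric fluorescence is close to lognormal; the geometric mean tracks
the distribution median and is stable against the heavy right tail that
dominates the arithmetic mean. Non-positive values (baseline-subtraction
artefacts) carry no log-scale information; they are dropped and counted.
An event floor guards the statistic: below 100 retained events the row
is marked low-n, below 25 it is an error. The arithmetic mean remains
available by option for comparison with instruments that export it.

### Replicate aggregation

Protocols run the four conditions in technical duplicate, but the order
of averaging is not fixed by the assay definition, so both policies are
implemented. The default averages replicate gMFIs per condition and then
applies the formulas once: the ratio of noisy differences is taken only
once, which is the numerically stabler path. The alternative
(`profile_per_replicate_then_mean`) computes per-replicate profiles and
averages the metrics; it is retained for sensitivity analysis, and the
two agree exactly for identical replicates.

## Barcode demultiplexing

The four conditions are stained with two amine-reactive dyes in four
combinations of two dilutions whose resulting intensities sit roughly
two decades apart, then pooled. Because the design is a 2×2 grid of
independent dyes, demultiplexing reduces to two one-dimensional
problems: on each barcode channel the log10 intensities are split into
two classes by exhaustively scanning every split point of the sorted
values for the minimum total within-class variance (the deterministic
1-D two-means partition; first minimum wins on ties, so the fit has no
random initialisation and no seed). The threshold is the midpoint of the
two class centres; a channel whose centres are separated by less than
twice the guard half-width has no usable hi/lo structure and errors.

Events within the guard corridor (default 0.1 log10 units on either
side of a threshold) are left unassigned and excluded from every MFI —
the software analogue of the conservative cluster gates an analyst would
draw by hand. An event exactly on a threshold goes to hi; the tie rule
is arbitrary but fixed and tested. Widening the guard can only remove
borderline events, so the misassignment rate among assigned events is
monotone non-increasing in the guard width (verified empirically on
seeded simulations). The combination-to-condition orientation (hi/hi =
DMSO, hi/lo = 2DG, lo/hi = Oligo, lo/lo = 2DG+Oligo) is a package
convention, overridable in `barcode_plan()`; unbarcoded acquisitions
bypass demultiplexing via per-file condition metadata.

## Gating

Gating in the real workflow is manual and external to this package;
`apply_gates()` provides axis-aligned threshold gates (conjunctions of
1-D predicates, nestable into a forest) sufficient to label synthetic
populations and simple marker panels. Gates operate on raw intensities,
consistent with the no-transform policy. Child membership is the
conjunction with the parent's; leaf gates are the reported populations;
an event matching several leaves is counted in each and its single label
is the first matching leaf in gate order.

## The forward simulator

The simulator is the package's verification instrument. Under condition
`c` a population translates at a factor `f(c)` of its baseline rate
`T0`: 1 for control, `1 − g/100` under 2-DG, `1 − m/100` under
oligomycin, 0 under double inhibition. Incorporation over a pulse of
length `t` follows saturating kinetics `I(t) = T0 f τ (1 − exp(−t/τ))`,
and the expected fluorescence is `B + k I(t)` with background `B` and
yield `k`. The factors are deliberately *linear* in (g, m): applying the
dependence formulas to the four expected signals returns (g, m)
identically, so the formulas are exact inverses of the forward model and
parameter recovery is a well-posed end-to-end check. MITA is simulated
as `m < 0` (oligomycin factor above 1); a homoharringtonine-style
translation block sets `f = 0` at all times, flattening the kinetics at
the background. A stimulation multiplier `s` scales `T0`; the
control-condition fold change recovers `s` exactly net of background
(an additive background attenuates measured fold changes toward 1, in
the simulator as in the bench assay, so fold-change recovery is
validated at `B = 0`).

Per event, the ncAA channel is the expected signal times
`exp(N(0, σ_log))` — multiplicative lognormal noise with zero-mean log,
so the geometric MFI is centred on the model signal. Marker channels are
lognormal a decade above (1e4) or below (1e3) the gate boundary;
barcode channels are lognormal around the plan's hi/lo centres (1e4 and
1e2, the ~100× dilution separation) with σ_log10 = 0.15. Defaults
describe a typical activated myeloid population on a conventional
cytometer: `T0 = 10 a.u./min`, `k = 4`, `τ = 120 min`, a 30-min pulse
(giving ≈ 1060 a.u. of condition-dependent signal, near-linear in `t`
at `t ≪ τ`), `B = 100 a.u.` (background about a tenth of the signal),
`σ_log = 0.25`, and 5000 events per condition.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: spectral spillover and compensation
artefacts, doublets and debris, acquisition drift, population-dependent
autofluorescence, the true (unknown) incorporation kinetics, secreted-
protein loss, and biological coupling between inhibitors beyond the
linear factor model. The saturating-exponential kinetics and the τ =
120 min default are modelling conventions chosen to reproduce the
qualitative accumulation behaviour over hours; they are exposed in the
spec rather than asserted as biology.

### Preset scenarios

`preset_scenarios()` ships the phenotypes the assay is known for:
classically activated macrophages (g = 80, m = 25: glycolytic) versus
alternatively activated ones (g = 80, m = 70: oxidative), chosen so both
are strongly glucose dependent while the capacity ordering reverses; a
MITA T-cell scenario (m = −25); a quiescent naive T cell whose `T0 =
0.05` yields ΔMFI ≈ 5 a.u., below the scenario's absolute resolution
floor of 15 a.u. so `LOW_RESOLUTION` is raised by construction; and a
tissue panel of 4 synthetic tissues × 3 donors sharing 5 populations,
whose per-tissue (g, m) bases spread widely for the myeloid populations
and little for the lymphoid ones (donor jitter SD 2 points), so that
myeloid features dominate the principal components and same-tissue
samples cluster.

## Statistics

Donor-level comparisons are paired by design, so the two-condition test
is the classical paired t on within-donor differences (all-zero
differences return statistic 0, p = 1 rather than failing). For several
treatments against a shared control, each contrast's paired |t| is
referred to the Monte-Carlo distribution of the *maximum* |t| over the
family under the joint null: the contrasts share the control arm and are
therefore equicorrelated, and simulating the maximum captures exactly
that dependence (the construction behind Dunnett's procedure) without
multivariate-t quadrature. The Monte-Carlo draw is seeded and its size
configurable (default 10,000); adjusted p-values are floored at the raw
p, and a family of one reduces identically to the paired t. Note the
procedure simulates the max over *per-contrast-variance* t statistics,
matching the paired tests actually performed, not the classic
common-variance Dunnett statistic; its null calibration is itself an
acceptance test. Two-factor layouts use cell-mean contrasts on the
pooled residual variance with the closed-form Šidák correction
`1 − (1 − p)^k`.

PCA of dependence profiles uses only the two dependence measures per
population as features — the capacities are affine complements and would
duplicate every axis of variance. Features are centred and, by default,
scaled to unit variance (an option disables scaling, since the original
analysis does not state it); the decomposition is the SVD via
`stats::prcomp`. Sign indeterminacy is resolved by requiring the
largest-|loading| feature of each component to load positively;
top-loading rankings break |loading| ties by feature name, ascending.
Zero-variance features are dropped with a warning; only complete-case
samples enter, and dropped rows are reported.

## Numerical and I/O choices

CSV event tables are written with 17 significant digits, so round trips
are bit exact. FCS support is a minimal, self-contained reader/writer
for FCS 3.0/3.1 list-mode files with `$DATATYPE F` (float32) or `I`
(uint16/32, uniform widths), either byte order — the envelope produced
by common benchtop cytometers and by the package's own writer; values
are used exactly as stored, with no compensation or display transform
anywhere in the pipeline. The float32 round trip preserves values to
relative error below 1e-6. Metadata travels in TEXT keywords
(`SAMPLE_ID`, `DONOR_ID`, `TISSUE`, `STIMULATION`, `REPLICATE_ID`,
`CONDITION`) or `meta_`-prefixed CSV columns.

## Problem sizes used in validation

The test-suite and acceptance computations run at the scale the
simulator defines as its study conditions: 5000 events per condition
(default noise σ_log = 0.25, background/signal ≈ 0.1) for recovery
across the 5×5 grid of true (g, m) — recovered dependences are required
within ±3 percentage points, and observed errors are ≈ 1 point;
consistency is checked at 500 / 5000 / 50,000 events per condition,
where the error shrinks approximately as n^(−1/2); noise-free round
trips use 200 events per condition and reproduce truth to ≤ 1e-9;
statistical calibration uses 2000 null simulations with 6 donors
(acceptance script: 1000), bounding the empirical type-I/FWER at ≤ 6.5%
against the nominal 5%; the tissue panel runs 12 samples × 5 populations
× 4 conditions × 1000 events.

## Known limitations

The dependence metrics are *relative* allocations of translation-
supporting ATP production, not absolute fluxes; a population can be
"highly glycolytic" at a tiny absolute rate, which is exactly the
situation the `LOW_RESOLUTION` flag marks. The ncAA readout misses
protein that is secreted during the pulse. The gating module is not a
substitute for expert manual gating of complex panels, and the
demultiplexer handles exactly two dyes at two levels. The Dunnett-style
adjustment is Monte-Carlo, so adjusted p-values carry simulation noise
of order `1/sqrt(n_mc)`; increase `n_mc` where p-values near a decision
boundary matter.
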
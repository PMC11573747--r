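# cencat

Metabolic dependence profiling from translation-inhibition flow cytometry.

## The problem

SCENITH-style assays infer the energetic wiring of single cells from their
protein-synthesis rate: cells are treated with metabolic inhibitors —
vehicle control (DMSO), 2-deoxyglucose (2-DG, blocking glucose metabolism),
oligomycin (blocking mitochondrial ATP synthase), or both — then pulsed
with a noncanonical amino acid (ncAA) that is click-labelled with a
fluorescent azide and read out by flow cytometry. With `MFI(c)` the
geometric mean ncAA fluorescence of a gated population under condition
`c`, and

```
ΔMFI = MFI(DMSO) − MFI(2DG+Oligo)
```

the assay's dynamic range, the dependence metrics are

```
glucose dependence (%)       = 100 · (MFI(DMSO) − MFI(2DG))   / ΔMFI
mitochondrial dependence (%) = 100 · (MFI(DMSO) − MFI(Oligo)) / ΔMFI
glycolytic capacity (%)      = 100 − mitochondrial dependence
FAO/AAO capacity (%)         = 100 − glucose dependence
```

`cencat` implements everything between the cytometer and those numbers:

* **events_io** — FCS 3.0/3.1 and CSV event tables, read as stored (no
  compensation or transforms);
* **demux** — the four inhibitor conditions are pooled into one tube after
  barcoding with two amine-reactive dyes at two dilutions (~100×
  intensity separation); a deterministic two-means split on each barcode
  channel recovers the condition of every event;
* **gating** — axis-aligned threshold gates labelling populations;
* **metrics** — geometric MFIs with event floors, the dependence calculus
  above, fold changes versus a medium control, QC flags (`MITA` for
  negative mitochondrial dependence, `LOW_RESOLUTION` for populations
  whose ΔMFI is within noise, `OUT_OF_RANGE`, `NEGATIVE_GLUCOSE_DEP`),
  and the Seahorse-style ECAR glycolytic capacity;
* **stats** — donor-level paired tests, Dunnett-style many-to-control
  comparisons (Monte-Carlo max-|t|), Šidák-corrected two-factor
  contrasts, and PCA of dependence profiles with ranked loadings;
* **sim** — a forward simulator of the complete assay (translation factors
  linear in the true (g, m), saturating incorporation kinetics,
  lognormal fluorescence noise, barcodes, markers) whose ground-truth
  ledger makes the whole pipeline verifiable by parameter recovery.

## Worked example

Simulate one barcoded tube of a monocyte-like population with true
glucose dependence 85% and mitochondrial dependence 35%, then fit:

```r
library(cencat)
sim <- simulate_experiment(simulation_spec(
  population_spec("monocyte", g = 85, m = 35, n_events = 5000),
  seed = 42, meta = list(sample_id = "donor1")))
fit <- cencat(sim$tables, sim$cmap, sim$gates)
summary(fit)
#> CENCAT metabolic dependence fit
#>   sample: sample_id=donor1, replicate_id=1
#>   events: 20000 read, 20000 quantified (0 unassigned, 0 ungated)
#>   populations: monocyte
#>
#>  population glucose_dependence mitochondrial_dependence glycolytic_capacity
#>    monocyte              84.87                    34.73               65.27
#>  faoaao_capacity delta_mfi flags
#>            15.13   1057.47
```

The 20,000 events are the four pooled conditions (5000 each); every event
was demultiplexed from the barcode channels and gated, and the fitted
dependences sit within a fraction of a percentage point of the simulated
truth (85, 35). `ΔMFI ≈ 1057 a.u.` is the population's dynamic range;
an empty `flags` column means no QC concern. `coef(fit)` returns the
metric matrix, `plot(fit)` a dependence barplot, and
`fit$profile_objects` the raw per-population profiles with flags.

Real acquisitions enter through `read_event_table()` (FCS or CSV) with a
`channel_map()` naming the ncAA, barcode and marker channels, or through
the `run_pipeline()` / command-line layer with a YAML config:

```sh
Rscript inst/scripts/cencat simulate --preset classical_macrophage --out sim/ --seed 4
Rscript inst/scripts/cencat run --config config.yaml --out results/ sim/*_rep1.csv
```

which writes `mfi_table.csv`, `profiles.csv`, PCA outputs for
multi-sample runs, and a `report.json` accounting for every event.

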
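# Example run configuration for a pooled, barcoded tube produced by
# `cencat simulate --preset classical_macrophage`.
seed: 1
pooled: true
channels:
  ncaa_signal: ncAA
  barcode_a: BC_A
  barcode_b: BC_B
  markers:
    Mk_macrophage: Mk_macrophage
barcode:
  hi_hi: DMSO
  hi_lo: 2DG
  lo_hi: Oligo
  lo_lo: 2DG+Oligo
  guard: 0.1
gates:
  - name: macrophage
    predicates:
      - {marker: Mk_macrophage, op: '>', cutoff: 3162.3}
metrics:
  statistic: geometric
  policy: mean_of_gmfi_before_formula
  clamp: false
stats:
  pca: true
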
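# Independent re-evaluation of the dependence formulas, kept deliberately
# separate from the package implementation: plain transcription of the
# published ratio definitions.
oracle_profile <- function(dmso, x2dg, oligo, both) {
  delta <- dmso - both
  g <- (dmso - x2dg) / delta * 100
  m <- (dmso - oligo) / delta * 100
  c(glucose = g, mito = m, glyco = 100 - m, faoaao = 100 - g)
}

# random MFI quadruples with a positive denominator
random_quadruples <- function(n, seed) {
  set.seed(seed)
  dmso <- exp(runif(n, log(50), log(5e4)))
  both <- dmso * runif(n, 0.01, 0.95)
  x2dg <- dmso * runif(n, 0.02, 1.5)
  oligo <- dmso * runif(n, 0.02, 1.5)
  data.frame(dmso = dmso, x2dg = x2dg, oligo = oligo, both = both)
}

# convenience: run a simulation through the full pipeline and return the
# fitted profile of one population
fit_simulation <- function(sim, ...) {
  floor_opt <- sim$spec$metric_options$resolution_floor
  cencat(sim$tables, sim$cmap, sim$gates,
         plan = sim$spec$barcode$plan,
         resolution_floor = floor_opt, ...)
}
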
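#' Ground-truth parameters of one simulated population
#'
#' The forward model reads the dependence metrics mechanistically: under
#' each inhibitor condition a population translates at a fraction of its
#' baseline rate — 1 under control, `1 - g/100` under glucose inhibition,
#' `1 - m/100` under ATP-synthase inhibition, and 0 under double
#' inhibition. Because these factors are linear in (g, m), the dependence
#' formulas are exact inverses of the forward model, which is what makes
#' parameter recovery a meaningful end-to-end check. MITA is simulated by
#' `m < 0` (oligomycin factor above 1).
#'
#' Defaults describe a typical activated myeloid population on a
#' conventional cytometer: baseline translation 10 a.u./min, fluorescence
#' yield 4 a.u. per incorporated a.u. (about 1060 a.u. of
#' condition-dependent signal after a 30-min pulse), additive background
#' about a tenth of that signal, multiplicative lognormal noise with
#' sigma 0.25 on the natural-log scale, and 5000 events per condition.
#'
#' @param name Population name.
#' @param g,m True glucose and mitochondrial dependence (%). `g` in
#'   \[0, 100\]; `m` may be negative to simulate MITA.
#' @param n_events Events per condition.
#' @param T0 Baseline translation rate (a.u./min).
#' @param B Additive fluorescence background (a.u.).
#' @param k Fluorescence yield per unit incorporation (a.u. per a.u.).
#' @param sigma_log Lognormal shape of multiplicative noise (log scale).
#' @param marker_means Named vector, marker role to mean intensity (a.u.).
#' @param stim_multiplier Stimulation factor on `T0` (>= 0).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(name, g, m, n_events = 5000L, T0 = 10, B = 100,
                            k = 4, sigma_log = 0.25, marker_means = NULL,
                            stim_multiplier = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            g >= 0, g <= 100, is.finite(m),
            n_events >= 1L, T0 >= 0, B >= 0, k > 0, sigma_log >= 0,
            stim_multiplier >= 0)
  structure(list(name = name, g = g, m = m, n_events = as.integer(n_events),
                 T0 = T0, B = B, k = k, sigma_log = sigma_log,
                 marker_means = marker_means, stim_multiplier = stim_multiplier),
            class = "population_spec")
}

#' Full simulation specification
#'
#' Bundles the populations with the assay schedule (30-min ncAA pulse by
#' default, matching the bench protocol), the incorporation kinetics time
#' constant, the barcode layout (hi/lo centres 100x apart, the intensity
#' separation produced by the 1:1000 vs 1:100,000 dye dilutions), and the
#' run seed. `pooled = TRUE` emits one tube per replicate with
#' barcode-encoded conditions; `pooled = FALSE` emits one table per
#' condition with the condition recorded in metadata (the unbarcoded
#' acquisition mode).
#'
#' @param populations List of [population_spec()]s (a single spec is
#'   wrapped).
#' @param incubation_time ncAA pulse length (min).
#' @param kinetics_tau Saturation time constant of incorporation (min).
#'   At the default 120 min the 30-min pulse sits in the near-linear
#'   regime.
#' @param barcode List: `plan` ([barcode_plan()]), `hi`/`lo` centre
#'   intensities (a.u.), `sigma_log10` spread of each barcode cluster.
#' @param seed Integer seed; a fixed seed makes the simulated tables
#'   byte-identical across runs.
#' @param pooled Barcoded single-tube mode (default) vs per-condition files.
#' @param n_replicates Technical replicates.
#' @param meta Sample metadata (see [event_table()]).
#' @param metric_options Optional list of metric options the scenario is
#'   meant to be analysed with (e.g. an absolute `resolution_floor`).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(populations, incubation_time = 30,
                            kinetics_tau = 120,
                            barcode = list(plan = barcode_plan(), hi = 1e4,
                                           lo = 1e2, sigma_log10 = 0.15),
                            seed = 1L, pooled = TRUE, n_replicates = 1L,
                            meta = list(), metric_options = list()) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, logical(1), "population_spec")),
            incubation_time >= 0, kinetics_tau > 0, n_replicates >= 1L)
  if (is.null(barcode$plan)) barcode$plan <- barcode_plan()
  stopifnot(barcode$hi > barcode$lo, barcode$lo > 0, barcode$sigma_log10 >= 0)
  structure(list(populations = populations,
                 incubation_time = incubation_time,
                 kinetics_tau = kinetics_tau, barcode = barcode,
                 seed = as.integer(seed), pooled = isTRUE(pooled),
                 n_replicates = as.integer(n_replicates),
                 meta = validate_meta(meta),
                 metric_options = metric_options),
            class = "simulation_spec")
}

condition_factor_of <- function(pop, condition) {
  switch(condition,
         "DMSO" = 1,
         "2DG" = 1 - pop$g / 100,
         "Oligo" = 1 - pop$m / 100,
         "2DG+Oligo" = 0,
         stop("unknown condition label '", condition, "'", call. = FALSE))
}

#' Expected ncAA fluorescence under one condition
#'
#' Mean (noise-free) model signal: incorporation follows saturating
#' kinetics `I(t) = T0 f tau (1 - exp(-t/tau))` with the
#' condition-specific translation factor `f`, and fluorescence is
#' `B + k I(t)`. Applying [dependence_profile()] to the four expected
#' signals returns the population's true (g, m) exactly.
#'
#' @param pop A [population_spec()].
#' @param condition A label from [condition_labels].
#' @param t Pulse length (min).
#' @param tau Kinetics time constant (min).
#' @return Expected fluorescence (a.u.).
#' @export
expected_signal <- function(pop, condition, t = 30, tau = 120) {
  stopifnot(inherits(pop, "population_spec"), t >= 0, tau > 0)
  f <- condition_factor_of(pop, condition)
  incorporation <- pop$T0 * pop$stim_multiplier * f * tau * (1 - exp(-t / tau))
  pop$B + pop$k * incorporation
}

#' Simulated incorporation kinetics
#'
#' Noise-free control-condition signal over a time course; with the
#' translation-elongation block (`homoharringtonine = TRUE`) incorporation
#' is abolished and the series stays flat at the background.
#'
#' @param pop A [population_spec()].
#' @param times Nonnegative, ascending time points (min).
#' @param homoharringtonine Apply the full translation block.
#' @param tau Kinetics time constant (min).
#' @return `data.frame(time, signal)`.
#' @export
simulate_kinetics <- function(pop, times, homoharringtonine = FALSE,
                              tau = 120) {
  stopifnot(all(times >= 0), !is.unsorted(times))
  f <- if (homoharringtonine) 0 else 1
  signal <- pop$B + pop$k * pop$T0 * pop$stim_multiplier * f * tau *
    (1 - exp(-times / tau))
  data.frame(time = times, signal = signal)
}

#' Forward-simulate a complete assay run
#'
#' Draws event tables from the generative model: per event, the ncAA
#' channel is the expected condition signal times lognormal noise
#' `exp(N(0, sigma_log))` (so the geometric MFI is centred on the model
#' signal); each population lights up its own marker channel
#' (`Mk_<name>`, mean 1e4) and sits a decade lower (1e3) on the others;
#' in pooled mode the two barcode channels are lognormal around the plan's
#' hi/lo centres. A ground-truth ledger records every event's population
#' and condition.
#'
#' @param spec A [simulation_spec()].
#' @return List of class `assay_simulation`: `tables` (list of
#'   [event_table()]s), `truth` (data.frame: table, event, population,
#'   condition, replicate_id), `cmap` (the matching [channel_map()]),
#'   `gates` (threshold gates separating the simulated populations at the
#'   geometric midpoint of the marker decades), and `spec`.
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  pops <- spec$populations
  pop_names <- vapply(pops, `[[`, character(1), "name")
  marker_channels <- paste0("Mk_", pop_names)
  extra_markers <- sort(unique(unlist(lapply(pops, function(p) names(p$marker_means)))))
  extra_markers <- setdiff(extra_markers, marker_channels)
  channels <- c("ncAA", if (spec$pooled) c("BC_A", "BC_B"),
                marker_channels, extra_markers)

  draw_block <- function(pop, cond, rep_id) {
    n <- pop$n_events
    mu <- expected_signal(pop, cond, t = spec$incubation_time,
                          tau = spec$kinetics_tau)
    vals <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    vals[, "ncAA"] <- mu * exp(stats::rnorm(n, 0, pop$sigma_log))
    for (ch in c(marker_channels, extra_markers)) {
      own <- identical(ch, paste0("Mk_", pop$name))
      base <- if (own) 1e4 else 1e3
      if (!is.null(pop$marker_means) && ch %in% names(pop$marker_means))
        base <- pop$marker_means[[ch]]
      vals[, ch] <- base * exp(stats::rnorm(n, 0, pop$sigma_log))
    }
    if (spec$pooled) {
      levels_ab <- strsplit(names(spec$barcode$plan$map)[
        match(cond, spec$barcode$plan$map)], "/", fixed = TRUE)[[1]]
      for (j in 1:2) {
        center <- if (levels_ab[j] == "hi") spec$barcode$hi else spec$barcode$lo
        vals[, c("BC_A", "BC_B")[j]] <-
          10^(log10(center) + stats::rnorm(n, 0, spec$barcode$sigma_log10))
      }
    }
    list(values = vals,
         truth = data.frame(population = rep(pop$name, n),
                            condition = rep(cond, n),
                            replicate_id = rep(as.character(rep_id), n),
                            stringsAsFactors = FALSE))
  }

  tables <- list()
  truth <- list()
  for (r in seq_len(spec$n_replicates)) {
    if (spec$pooled) {
      blocks <- list()
      for (pop in pops)
        for (cond in condition_labels)
          blocks[[length(blocks) + 1L]] <- draw_block(pop, cond, r)
      vals <- do.call(rbind, lapply(blocks, `[[`, "values"))
      tr <- do.call(rbind, lapply(blocks, `[[`, "truth"))
      meta <- spec$meta
      meta$replicate_id <- as.character(r)
      id <- paste0("rep", r)
      tables[[id]] <- event_table(vals, meta = meta)
      tr$table <- id
      tr$event <- seq_len(nrow(tr))
      truth[[id]] <- tr
    } else {
      for (cond in condition_labels) {
        blocks <- lapply(pops, draw_block, cond = cond, rep_id = r)
        vals <- do.call(rbind, lapply(blocks, `[[`, "values"))
        tr <- do.call(rbind, lapply(blocks, `[[`, "truth"))
        meta <- spec$meta
        meta$replicate_id <- as.character(r)
        meta$condition <- cond
        id <- paste0("rep", r, "_", cond)
        tables[[id]] <- event_table(vals, meta = meta)
        tr$table <- id
        tr$event <- seq_len(nrow(tr))
        truth[[id]] <- tr
      }
    }
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))

  markers <- stats::setNames(marker_channels, marker_channels)
  cmap <- channel_map("ncAA",
                      barcode_a = if (spec$pooled) "BC_A",
                      barcode_b = if (spec$pooled) "BC_B",
                      markers = markers)
  # own-channel decade (1e4) vs off-channel decade (1e3): gate at the
  # geometric midpoint
  gates <- lapply(pop_names, function(p)
    population_gate(p, list(list(marker = paste0("Mk_", p), op = ">",
                                 cutoff = 10^3.5))))
  structure(list(tables = tables, truth = truth, cmap = cmap, gates = gates,
                 spec = spec),
            class = "assay_simulation")
}

#' Preset simulation scenarios
#'
#' Named, ready-to-run scenarios spanning the assay's characteristic
#' phenotypes:
#' \describe{
#'   \item{classical_macrophage}{LPS+IFNg-style activation: highly glucose
#'     dependent with low mitochondrial dependence, hence high glycolytic
#'     capacity.}
#'   \item{alternative_macrophage}{IL-4-style activation: equally glucose
#'     dependent but strongly mitochondrial, hence low glycolytic
#'     capacity.}
#'   \item{naive_T_quiescent}{Near-quiescent lymphocyte: translation so low
#'     that the dynamic range sits below the scenario's absolute
#'     resolution floor (15 a.u., carried in `metric_options`), raising
#'     `LOW_RESOLUTION`.}
#'   \item{T_MITA}{Oligomycin paradoxically increases translation
#'     (true m = -25), producing a negative mitochondrial dependence and
#'     the `MITA` flag.}
#'   \item{tissue_panel}{A list of specs — 4 synthetic tissues x 3 donors
#'     sharing 5 populations with tissue-distinct (g, m), myeloid
#'     populations most variable across tissues — for exercising PCA and
#'     clustering.}
#' }
#'
#' @param seed Base seed; per-scenario seeds and the tissue panel's
#'   donor-level (g, m) jitter derive from it.
#' @param n_events Events per condition for the single-population presets.
#' @return Named list; each element is a [simulation_spec()] except
#'   `tissue_panel`, which is a list of specs with tissue/donor metadata.
#' @export
preset_scenarios <- function(seed = 1L, n_events = 5000L) {
  seed <- as.integer(seed)
  out <- list(
    classical_macrophage = simulation_spec(
      population_spec("macrophage", g = 80, m = 25, n_events = n_events),
      seed = seed + 1L,
      meta = list(sample_id = "classical", stimulation = "LPS+IFNg")),
    alternative_macrophage = simulation_spec(
      population_spec("macrophage", g = 80, m = 70, n_events = n_events),
      seed = seed + 2L,
      meta = list(sample_id = "alternative", stimulation = "IL-4")),
    naive_T_quiescent = simulation_spec(
      population_spec("naive_T", g = 60, m = 40, n_events = 1000L,
                      T0 = 0.05, B = 100),
      seed = seed + 3L,
      meta = list(sample_id = "naive_T"),
      metric_options = list(resolution_floor = 15)),
    T_MITA = simulation_spec(
      population_spec("T_cell", g = 60, m = -25, n_events = n_events),
      seed = seed + 4L,
      meta = list(sample_id = "T_MITA")))

  tissues <- c("spleen", "liver", "lung", "kidney")
  pops <- c("macrophage", "cDC2", "B_cell", "CD4_T", "NK")
  # per-tissue base (g, m): myeloid populations spread widely across
  # tissues, lymphoid ones little — so myeloid features dominate the
  # principal components
  base_g <- rbind(macrophage = c(90, 45, 70, 25),
                  cDC2       = c(85, 30, 55, 20),
                  B_cell     = c(60, 55, 58, 52),
                  CD4_T      = c(55, 50, 53, 49),
                  NK         = c(50, 47, 52, 45))
  base_m <- rbind(macrophage = c(80, 30, 55, 20),
                  cDC2       = c(75, 25, 45, 15),
                  B_cell     = c(45, 42, 46, 40),
                  CD4_T      = c(40, 38, 42, 36),
                  NK         = c(38, 35, 40, 33))
  colnames(base_g) <- colnames(base_m) <- tissues
  set.seed(seed + 5L)
  panel <- list()
  for (ti in tissues) {
    for (d in 1:3) {
      jit_g <- pmin(100, pmax(0, base_g[, ti] + stats::rnorm(length(pops), 0, 2)))
      jit_m <- pmin(100, pmax(0, base_m[, ti] + stats::rnorm(length(pops), 0, 2)))
      plist <- lapply(seq_along(pops), function(i)
        population_spec(pops[i], g = jit_g[i], m = jit_m[i], n_events = 1000L))
      panel[[paste0(ti, "_d", d)]] <- simulation_spec(
        plist, seed = seed + 10L + length(panel),
        meta = list(sample_id = paste0(ti, "_d", d), tissue = ti,
                    donor_id = paste0("d", d)))
    }
  }
  out$tissue_panel <- panel
  out
}
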
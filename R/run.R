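#' Read and validate a run configuration
#'
#' The structured configuration wires the whole pipeline: channel roles,
#' barcode plan and guard, gates, per-file condition mapping for unpooled
#' runs, metric options, stats options and the run seed. The schema is
#' validated before any computation; unknown keys at any level are
#' rejected so that typos fail loudly instead of silently using defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (parsed YAML or built in code).
#' @export
validate_run_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("config error: unknown key(s) in ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(cfg, c("seed", "pooled", "channels", "barcode", "gates",
                    "conditions", "metrics", "stats"), "config")
  if (is.null(cfg$channels) || is.null(cfg$channels$ncaa_signal))
    stop("config error: channels.ncaa_signal is required", call. = FALSE)
  check_keys(cfg$channels, c("ncaa_signal", "barcode_a", "barcode_b",
                             "markers", "viability"), "channels")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  pooled <- cfg$pooled %||% (!is.null(cfg$channels$barcode_a) &&
                               !is.null(cfg$channels$barcode_b))
  if (pooled && (is.null(cfg$channels$barcode_a) ||
                 is.null(cfg$channels$barcode_b)))
    stop("config error: pooled input needs channels.barcode_a and ",
         "channels.barcode_b (a barcode plan cannot be applied otherwise)",
         call. = FALSE)
  cfg$pooled <- pooled
  if (!is.null(cfg$barcode))
    check_keys(cfg$barcode, c("hi_hi", "hi_lo", "lo_hi", "lo_lo",
                              "expected_ratio", "guard"), "barcode")
  if (!is.null(cfg$metrics))
    check_keys(cfg$metrics, c("statistic", "policy", "clamp", "min_events",
                              "error_events", "resolution_floor"), "metrics")
  if (!is.null(cfg$stats))
    check_keys(cfg$stats, c("pca", "scale", "n_components"), "stats")
  if (!is.null(cfg$gates)) {
    for (g in cfg$gates) {
      check_keys(g, c("name", "parent", "predicates"), "gate")
      if (is.null(g$name) || is.null(g$predicates))
        stop("config error: every gate needs a name and predicates",
             call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

config_channel_map <- function(cfg) {
  ch <- cfg$channels
  channel_map(ch$ncaa_signal, barcode_a = ch$barcode_a,
              barcode_b = ch$barcode_b,
              markers = unlist(ch$markers) %||% character(),
              viability = ch$viability)
}

config_gates <- function(cfg) {
  if (is.null(cfg$gates)) return(NULL)
  lapply(cfg$gates, function(g)
    population_gate(g$name, g$predicates, parent = g$parent))
}

config_plan <- function(cfg) {
  b <- cfg$barcode
  if (is.null(b)) return(barcode_plan())
  barcode_plan(hi_hi = b$hi_hi %||% "DMSO", hi_lo = b$hi_lo %||% "2DG",
               lo_hi = b$lo_hi %||% "Oligo",
               lo_lo = b$lo_lo %||% "2DG+Oligo",
               expected_ratio = b$expected_ratio %||% 100)
}

#' Run the full pipeline to an output directory
#'
#' Reads the input event tables, fits [cencat()] per sample (tables are
#' grouped by `meta$sample_id`; unpooled files get their condition from
#' the config's `conditions` file-to-label mapping or their own
#' metadata), and writes tidy outputs: `mfi_table.csv` (one row per
#' population x condition x replicate), `profiles.csv` (one row per
#' sample x population), `pca_scores.csv`/`pca_loadings.csv` when at
#' least two samples are present and stats are enabled, and `report.json`
#' with versions, seed, options, per-stage event accounting and QC flags.
#' Deterministic for fixed config, inputs and seed; on any stage error
#' the partially written outputs are removed.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to one.
#' @param inputs Character paths to event files, or a list of
#'   [event_table()]s.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-sample fits and the output
#'   paths.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    tables <- if (is.character(inputs)) {
      lapply(inputs, read_event_table)
    } else {
      if (inherits(inputs, "event_table")) inputs <- list(inputs)
      inputs
    }
    if (is.character(inputs) && !is.null(config$conditions)) {
      for (i in seq_along(inputs)) {
        key <- basename(inputs[[i]])
        if (!is.null(config$conditions[[key]]))
          tables[[i]]$meta$condition <- config$conditions[[key]]
      }
    }
    cmap <- config_channel_map(config)
    gates <- config_gates(config)
    mx <- config$metrics %||% list()
    sample_ids <- vapply(tables, function(tb) tb$meta$sample_id %||% "sample",
                         character(1))
    fits <- list()
    for (sid in unique(sample_ids)) {
      fits[[sid]] <- cencat(tables[sample_ids == sid], cmap, gates = gates,
                            plan = config_plan(config),
                            pooled = config$pooled,
                            guard = config$barcode$guard %||% 0.1,
                            policy = mx$policy %||% "mean_of_gmfi_before_formula",
                            statistic = mx$statistic %||% "geometric",
                            min_events = mx$min_events %||% 100L,
                            error_events = mx$error_events %||% 25L,
                            resolution_floor = mx$resolution_floor,
                            clamp = isTRUE(mx$clamp))
    }

    mfi_all <- do.call(rbind, lapply(names(fits), function(sid)
      cbind(sample_id = sid, fits[[sid]]$mfi)))
    profiles_all <- do.call(rbind, lapply(names(fits), function(sid)
      cbind(sample_id = sid, fits[[sid]]$profiles)))
    p_mfi <- file.path(out_dir, "mfi_table.csv")
    p_prof <- file.path(out_dir, "profiles.csv")
    utils::write.csv(mfi_all, p_mfi, row.names = FALSE)
    utils::write.csv(profiles_all, p_prof, row.names = FALSE)
    written <- c(written, p_mfi, p_prof)

    pca <- NULL
    if (length(fits) >= 2L && isTRUE((config$stats %||% list(pca = TRUE))$pca)) {
      pm <- profile_matrix(profiles_all)
      pca <- pca_profiles(pm, n_components = config$stats$n_components,
                          scale = config$stats$scale %||% TRUE)
      p_sc <- file.path(out_dir, "pca_scores.csv")
      p_ld <- file.path(out_dir, "pca_loadings.csv")
      utils::write.csv(data.frame(sample_id = rownames(pca$scores),
                                  pca$scores, check.names = FALSE),
                       p_sc, row.names = FALSE)
      utils::write.csv(data.frame(feature = rownames(pca$loadings),
                                  pca$loadings, check.names = FALSE),
                       p_ld, row.names = FALSE)
      written <- c(written, p_sc, p_ld)
    }

    report <- list(
      package = "cencat",
      version = as.character(utils::packageVersion("cencat")),
      seed = config$seed,
      options = config[c("pooled", "barcode", "metrics", "stats")],
      samples = lapply(fits, function(f) list(
        accounting = as.list(f$accounting),
        gate_counts = as.list(f$gate_counts),
        demux_counts = if (length(f$demux)) as.list(f$demux[[1L]]$counts),
        flags = stats::setNames(as.list(f$profiles$flags),
                                f$profiles$population))),
      pca_explained = if (!is.null(pca)) pca$explained_variance_fraction)
    p_rep <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, p_rep, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    written <- c(written, p_rep)
    invisible(list(fits = fits, pca = pca, files = written))
  }, error = on_fail)
}
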
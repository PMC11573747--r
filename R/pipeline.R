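#' Fit metabolic dependence profiles from event data
#'
#' The package's central entry point: takes the event tables of one
#' sample — either a pooled, barcoded tube per technical replicate, or
#' one table per inhibitor condition with the condition recorded in
#' metadata — and carries them through demultiplexing, population gating,
#' geometric-MFI quantification and the dependence calculus, returning a
#' classed fit with `print`, `summary`, `coef` and `plot` methods.
#'
#' @param tables An [event_table()] or list of them. In pooled mode each
#'   table is one replicate tube; in unpooled mode each table must carry
#'   `meta$condition` (one of [condition_labels]) and tables of the same
#'   `meta$replicate_id` form a replicate.
#' @param cmap A [channel_map()].
#' @param gates List of [population_gate()]s. If omitted the whole table
#'   is treated as a single population `"all"`.
#' @param plan A [barcode_plan()] (pooled mode).
#' @param pooled Demultiplex conditions from barcode channels (default:
#'   `TRUE` when the map has barcode roles).
#' @param guard Demultiplexing guard half-width, log10 units.
#' @param policy Replicate aggregation policy, see
#'   [aggregate_replicates()].
#' @param statistic `"geometric"` or `"arithmetic"` MFI.
#' @param min_events,error_events Event floors for the MFI statistic.
#' @param resolution_floor Absolute a.u. floor for the `LOW_RESOLUTION`
#'   flag; `NULL` for the SE-based default, `NA` to disable.
#' @param clamp Clamp reported metrics to \[0, 100\] (raw values are
#'   always kept in the per-population profile objects).
#' @return Object of class `cencat`: `profiles` (data.frame, one row per
#'   population), `profile_objects`, `mfi` (the MFI table), `demux`,
#'   `gate_counts`, `accounting` (events read / assigned / unassigned /
#'   ungated), `options`, `call`.
#' @examples
#' sim <- simulate_experiment(simulation_spec(
#'   population_spec("mono", g = 75, m = 40, n_events = 300), seed = 7))
#' fit <- cencat(sim$tables, sim$cmap, sim$gates)
#' coef(fit)
#' @export
cencat <- function(tables, cmap, gates = NULL, plan = barcode_plan(),
                   pooled = NULL, guard = 0.1,
                   policy = "mean_of_gmfi_before_formula",
                   statistic = "geometric", min_events = 100L,
                   error_events = 25L, resolution_floor = NULL,
                   clamp = FALSE) {
  cl <- match.call()
  if (inherits(tables, "event_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "event_table")))
  if (is.null(pooled))
    pooled <- !is.null(cmap$barcode_a) && !is.null(cmap$barcode_b)

  ncaa_all <- population_all <- condition_all <- replicate_all <- list()
  demux_results <- list()
  gate_counts <- NULL
  n_read <- n_unassigned <- n_ungated <- 0L

  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    idx <- validate_channels(tb, cmap)
    n_read <- n_read + nrow(tb$values)
    if (pooled) {
      dm <- assign_conditions(tb, cmap, plan = plan, guard = guard)
      condition <- dm$condition
      demux_results[[length(demux_results) + 1L]] <- dm
      n_unassigned <- n_unassigned + sum(is.na(condition))
      rep_id <- tb$meta$replicate_id %||% as.character(ti)
    } else {
      cond <- tb$meta$condition
      if (is.null(cond) || !cond %in% condition_labels)
        stop("config error: unpooled table ", ti,
             " lacks a valid meta$condition (one of ",
             paste(condition_labels, collapse = ", "), ")", call. = FALSE)
      condition <- rep(cond, nrow(tb$values))
      rep_id <- tb$meta$replicate_id %||% "1"
    }
    if (is.null(gates)) {
      label <- rep("all", nrow(tb$values))
      counts <- c(all = nrow(tb$values), ungated = 0L)
    } else {
      g <- apply_gates(tb, cmap, gates)
      label <- g$label
      counts <- g$counts
    }
    n_ungated <- n_ungated + sum(label == "ungated")
    gate_counts <- if (is.null(gate_counts)) counts else gate_counts + counts
    ncaa_all[[ti]] <- tb$values[, idx$ncaa_signal]
    population_all[[ti]] <- label
    condition_all[[ti]] <- condition
    replicate_all[[ti]] <- rep(rep_id, nrow(tb$values))
  }

  mfi <- mfi_table(unlist(ncaa_all),
                   population = ifelse(unlist(population_all) == "ungated",
                                       NA, unlist(population_all)),
                   condition = unlist(condition_all),
                   replicate = unlist(replicate_all),
                   min_events = min_events, error_events = error_events,
                   statistic = statistic)
  profs <- aggregate_replicates(mfi, policy = policy,
                                resolution_floor = resolution_floor)
  report <- if (clamp) lapply(profs, clamp_profile) else profs
  profiles <- do.call(rbind, lapply(names(report), function(p) {
    pr <- report[[p]]
    data.frame(population = p,
               glucose_dependence = pr$glucose_dependence,
               mitochondrial_dependence = pr$mitochondrial_dependence,
               glycolytic_capacity = pr$glycolytic_capacity,
               faoaao_capacity = pr$faoaao_capacity,
               delta_mfi = pr$delta_mfi,
               flags = paste(pr$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  meta <- tables[[1L]]$meta

  structure(list(profiles = profiles, profile_objects = profs, mfi = mfi,
                 demux = demux_results, gate_counts = gate_counts,
                 accounting = c(read = n_read, unassigned = n_unassigned,
                                ungated = n_ungated,
                                quantified = n_read - n_unassigned - n_ungated),
                 meta = meta,
                 options = list(pooled = pooled, guard = guard, policy = policy,
                                statistic = statistic, clamp = clamp,
                                min_events = min_events,
                                error_events = error_events,
                                resolution_floor = resolution_floor),
                 call = cl),
            class = "cencat")
}

#' @export
print.cencat <- function(x, ...) {
  cat("CENCAT metabolic dependence fit\n")
  if (length(x$meta))
    cat("  sample: ", paste(names(x$meta), unlist(x$meta), sep = "=",
                            collapse = ", "), "\n", sep = "")
  cat("  events: ", x$accounting["read"], " read, ",
      x$accounting["quantified"], " quantified (",
      x$accounting["unassigned"], " unassigned, ",
      x$accounting["ungated"], " ungated)\n", sep = "")
  cat("  populations:", paste(x$profiles$population, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cencat <- function(object, ...) {
  structure(list(fit = object), class = "summary.cencat")
}

#' @export
print.summary.cencat <- function(x, ...) {
  print(x$fit)
  df <- x$fit$profiles
  num <- c("glucose_dependence", "mitochondrial_dependence",
           "glycolytic_capacity", "faoaao_capacity", "delta_mfi")
  df[num] <- lapply(df[num], function(v) round(v, 2))
  cat("\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cencat <- function(object, ...) {
  df <- object$profiles
  m <- as.matrix(df[c("glucose_dependence", "mitochondrial_dependence",
                      "glycolytic_capacity", "faoaao_capacity")])
  rownames(m) <- df$population
  m
}

#' @export
plot.cencat <- function(x, ...) {
  df <- x$profiles
  m <- t(as.matrix(df[c("glucose_dependence", "mitochondrial_dependence")]))
  colnames(m) <- df$population
  graphics::barplot(m, beside = TRUE, ylab = "dependence (%)",
                    legend.text = c("glucose", "mitochondrial"),
                    col = c("steelblue", "firebrick"), ...)
  invisible(x)
}
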
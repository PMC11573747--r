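#' Geometric mean fluorescence intensity
#'
#' The assay's primary summary statistic for a gated population:
#' `exp(mean(log(x)))` over strictly positive values. Fluorescence is
#' log-normally distributed to good approximation, so the geometric mean
#' tracks the distribution median and is robust to the heavy right tail
#' that distorts the arithmetic mean. Non-positive values (baseline
#' subtraction artefacts) carry no log-scale information and are dropped
#' and counted.
#'
#' @param values Numeric vector of fluorescence intensities (a.u.).
#' @param min_events Warn-level minimum retained events (default 100):
#'   fewer events sets `low_n = TRUE`.
#' @param error_events Error-level minimum (default 25): fewer is an error.
#' @param statistic `"geometric"` (default) or `"arithmetic"`.
#' @param context Optional string (population/condition) used in error
#'   messages.
#' @return List: `gmfi`, `gmfi_se` (delta-method standard error of the
#'   geometric mean), `n_events` (retained), `n_dropped`, `low_n`.
#' @examples
#' geometric_mfi(c(1, 100))$gmfi  # 10
#' @export
geometric_mfi <- function(values, min_events = 100L, error_events = 25L,
                          statistic = c("geometric", "arithmetic"),
                          context = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(values))
  keep <- values > 0
  x <- values[keep]
  n <- length(x)
  if (n < error_events)
    stop("metric error: only ", n, " positive events (< ", error_events, ")",
         if (!is.null(context)) paste0(" for ", context), call. = FALSE)
  if (statistic == "geometric") {
    lx <- log(x)
    g <- exp(mean(lx))
    se <- if (n > 1L) g * stats::sd(lx) / sqrt(n) else NA_real_
  } else {
    g <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
  }
  list(gmfi = g, gmfi_se = se, n_events = n,
       n_dropped = length(values) - n, low_n = n < min_events)
}

#' Metabolic dependence profile from the four condition MFIs
#'
#' The core calculus of the assay. With MFI denoting the (geometric) mean
#' ncAA fluorescence of one population under each inhibitor condition, and
#' `dMFI = MFI(DMSO) - MFI(2DG+Oligo)` the assay's dynamic range:
#'
#' \deqn{glucose\ dependence = 100 (MFI_{DMSO} - MFI_{2DG}) / \Delta MFI}
#' \deqn{mitochondrial\ dependence = 100 (MFI_{DMSO} - MFI_{Oligo}) / \Delta MFI}
#' \deqn{glycolytic\ capacity = 100 - mitochondrial\ dependence}
#' \deqn{FAO/AAO\ capacity = 100 - glucose\ dependence}
#'
#' Values are returned raw, never clamped: dependences outside \[0, 100\]
#' are biologically meaningful QC signals. A negative mitochondrial
#' dependence (oligomycin *increasing* translation) is flagged `MITA`
#' (mitochondrial inhibition translation activation). `dMFI <= 0` leaves
#' every ratio undefined and is an error, not a division.
#'
#' @param mfi_dmso,mfi_2dg,mfi_oligo,mfi_both Condition MFIs (a.u.).
#' @param resolution_floor Optional a.u. floor below which `dMFI` flags the
#'   profile `LOW_RESOLUTION` (populations with tiny dynamic range have
#'   unstable ratios). `NA` disables the check.
#' @return Object of class `dependence_profile`: the four metrics (%),
#'   `delta_mfi`, and `flags` (subset of `MITA`,
#'   `NEGATIVE_GLUCOSE_DEP`, `OUT_OF_RANGE`, `LOW_RESOLUTION`).
#' @examples
#' dependence_profile(1000, 400, 700, 200)  # glucose 75, mito 37.5
#' @export
dependence_profile <- function(mfi_dmso, mfi_2dg, mfi_oligo, mfi_both,
                               resolution_floor = NA_real_) {
  for (v in list(mfi_dmso, mfi_2dg, mfi_oligo, mfi_both))
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  mfi_dmso <- unname(mfi_dmso); mfi_2dg <- unname(mfi_2dg)
  mfi_oligo <- unname(mfi_oligo); mfi_both <- unname(mfi_both)
  delta <- mfi_dmso - mfi_both
  if (delta <= 0)
    stop("undefined profile: dMFI = MFI(DMSO) - MFI(2DG+Oligo) = ",
         signif(delta, 4), " <= 0; dependence ratios have no denominator",
         call. = FALSE)
  glucose <- 100 * (mfi_dmso - mfi_2dg) / delta
  mito <- 100 * (mfi_dmso - mfi_oligo) / delta
  metrics <- c(glucose_dependence = glucose,
               mitochondrial_dependence = mito,
               glycolytic_capacity = 100 - mito,
               faoaao_capacity = 100 - glucose)
  flags <- character()
  if (mito < 0) flags <- c(flags, "MITA")
  if (glucose < 0) flags <- c(flags, "NEGATIVE_GLUCOSE_DEP")
  if (any(metrics < 0 | metrics > 100)) flags <- c(flags, "OUT_OF_RANGE")
  if (!is.na(resolution_floor) && delta < resolution_floor)
    flags <- c(flags, "LOW_RESOLUTION")
  structure(c(as.list(metrics), list(delta_mfi = delta, flags = flags)),
            class = "dependence_profile")
}

#' @export
print.dependence_profile <- function(x, ...) {
  cat(sprintf(paste0("<dependence_profile>\n",
                     "  glucose dependence:       %8.2f %%\n",
                     "  mitochondrial dependence: %8.2f %%\n",
                     "  glycolytic capacity:      %8.2f %%\n",
                     "  FAO/AAO capacity:         %8.2f %%\n",
                     "  dMFI:                     %8.2f a.u.\n"),
              x$glucose_dependence, x$mitochondrial_dependence,
              x$glycolytic_capacity, x$faoaao_capacity, x$delta_mfi))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Clamp a profile's metrics to [0, 100] for reporting
#'
#' Reporting-layer convenience only; the fitted values keep their raw,
#' possibly out-of-range metrics together with the QC flags explaining
#' them.
#'
#' @param profile A [dependence_profile()].
#' @return The profile with the four metrics clamped to \[0, 100\]; flags
#'   untouched.
#' @export
clamp_profile <- function(profile) {
  stopifnot(inherits(profile, "dependence_profile"))
  for (m in c("glucose_dependence", "mitochondrial_dependence",
              "glycolytic_capacity", "faoaao_capacity"))
    profile[[m]] <- min(100, max(0, profile[[m]]))
  profile
}

#' Fold change of ncAA incorporation versus the medium control
#'
#' Ratio of control-condition (DMSO) MFIs: stimulated over unstimulated
#' medium, within one population and donor. Donor-level fold changes are
#' averaged downstream.
#'
#' @param mfi_stimulated,mfi_medium Control-condition gMFIs (a.u., > 0).
#' @param population,stimulation Optional annotations carried through.
#' @return List (`fold_change_record`): `population`, `stimulation`,
#'   `fold_change`.
#' @export
fold_change <- function(mfi_stimulated, mfi_medium, population = NA_character_,
                        stimulation = NA_character_) {
  if (!is.finite(mfi_stimulated) || mfi_stimulated <= 0 ||
      !is.finite(mfi_medium) || mfi_medium <= 0)
    stop("metric error: fold change needs positive MFIs", call. = FALSE)
  structure(list(population = population, stimulation = stimulation,
                 fold_change = mfi_stimulated / mfi_medium),
            class = "fold_change_record")
}

#' Seahorse-style glycolytic capacity from ECAR
#'
#' Extracellular-flux counterpart of the cytometric glycolytic capacity:
#' the difference between the oligomycin-induced and basal extracellular
#' acidification rates. A negative difference is reported as-is with a
#' warning flag.
#'
#' @param ecar_basal,ecar_oligo ECAR before and after oligomycin (mpH/min).
#' @return List: `capacity` (mpH/min) and `flags`.
#' @export
seahorse_glycolytic_capacity <- function(ecar_basal, ecar_oligo) {
  stopifnot(is.finite(ecar_basal), is.finite(ecar_oligo))
  cap <- ecar_oligo - ecar_basal
  list(capacity = cap,
       flags = if (cap < 0) "NEGATIVE_CAPACITY" else character())
}

#' Tabulate per-group geometric MFIs
#'
#' Builds the MFI table — one row per population x condition x replicate —
#' from event-level ncAA intensities and their group labels. Rows that
#' fail the error-level event floor raise an error naming the group.
#'
#' @param ncaa Numeric vector of ncAA-channel intensities, one per event.
#' @param population,condition Character vectors parallel to `ncaa`; events
#'   with `NA` in either (unassigned or ungated) are excluded.
#' @param replicate Replicate id (single string or per-event vector).
#' @param min_events,error_events,statistic Passed to [geometric_mfi()].
#' @return `data.frame` with columns population, condition, replicate_id,
#'   gmfi, gmfi_se, n_events, n_dropped, low_n.
#' @export
mfi_table <- function(ncaa, population, condition, replicate = "1",
                      min_events = 100L, error_events = 25L,
                      statistic = "geometric") {
  stopifnot(length(population) == length(ncaa),
            length(condition) == length(ncaa))
  replicate <- rep_len(as.character(replicate), length(ncaa))
  keep <- !is.na(population) & !is.na(condition) & population != "ungated"
  df <- data.frame(ncaa = ncaa[keep], population = population[keep],
                   condition = condition[keep], replicate = replicate[keep],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("metric error: no assigned, gated events", call. = FALSE)
  groups <- unique(df[c("population", "condition", "replicate")])
  groups <- groups[order(groups$population, groups$condition, groups$replicate), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- df$population == g$population & df$condition == g$condition &
      df$replicate == g$replicate
    m <- geometric_mfi(df$ncaa[sel], min_events = min_events,
                       error_events = error_events, statistic = statistic,
                       context = paste0(g$population, "/", g$condition,
                                        "/rep", g$replicate))
    data.frame(population = g$population, condition = g$condition,
               replicate_id = g$replicate, gmfi = m$gmfi, gmfi_se = m$gmfi_se,
               n_events = m$n_events, n_dropped = m$n_dropped, low_n = m$low_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate technical replicates into dependence profiles
#'
#' Two aggregation policies are supported, because protocols with technical
#' duplicates leave the order of averaging open:
#' `"mean_of_gmfi_before_formula"` (default) averages the replicate gMFIs
#' per condition and computes one profile from the averaged MFIs — this
#' keeps the noisy difference-of-differences ratio out of the average.
#' `"profile_per_replicate_then_mean"` computes a profile per replicate and
#' averages the metrics; retained for sensitivity analysis. The two agree
#' exactly when replicates are identical.
#'
#' When `resolution_floor` is `NULL` it defaults to 3x the pooled
#' within-condition standard error of the (replicate-averaged) gMFIs,
#' so populations whose dynamic range is within noise are flagged
#' `LOW_RESOLUTION`.
#'
#' @param mfi A data frame from [mfi_table()] (columns population,
#'   condition, replicate_id, gmfi; optionally gmfi_se).
#' @param policy Aggregation policy (see above).
#' @param resolution_floor Absolute a.u. floor, `NA` to disable, or `NULL`
#'   for the SE-based default.
#' @return Named list of [dependence_profile()]s, one per population.
#' @export
aggregate_replicates <- function(mfi,
                                 policy = c("mean_of_gmfi_before_formula",
                                            "profile_per_replicate_then_mean"),
                                 resolution_floor = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(mfi),
            all(c("population", "condition", "replicate_id", "gmfi") %in% names(mfi)))
  out <- list()
  for (pop in unique(mfi$population)) {
    sub <- mfi[mfi$population == pop, ]
    missing <- setdiff(condition_labels, sub$condition)
    if (length(missing))
      stop("undefined profile for '", pop, "': missing condition(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    cond_mean <- vapply(condition_labels,
                        function(cl) mean(sub$gmfi[sub$condition == cl]),
                        numeric(1))
    floor_pop <- resolution_floor
    if (is.null(floor_pop)) {
      floor_pop <- if ("gmfi_se" %in% names(sub) && all(is.finite(sub$gmfi_se))) {
        se_cond <- vapply(condition_labels, function(cl) {
          s <- sub[sub$condition == cl, ]
          sqrt(sum(s$gmfi_se^2)) / nrow(s)  # SE of the replicate mean
        }, numeric(1))
        3 * sqrt(mean(se_cond^2))
      } else NA_real_
    }
    if (policy == "mean_of_gmfi_before_formula") {
      out[[pop]] <- dependence_profile(cond_mean["DMSO"], cond_mean["2DG"],
                                       cond_mean["Oligo"], cond_mean["2DG+Oligo"],
                                       resolution_floor = floor_pop)
    } else {
      reps <- unique(sub$replicate_id)
      profs <- lapply(reps, function(r) {
        s <- sub[sub$replicate_id == r, ]
        g <- stats::setNames(s$gmfi, s$condition)
        if (!all(condition_labels %in% names(g)))
          stop("undefined profile for '", pop, "' replicate ", r,
               ": missing condition(s) ",
               paste(setdiff(condition_labels, names(g)), collapse = ", "),
               call. = FALSE)
        dependence_profile(g["DMSO"], g["2DG"], g["Oligo"], g["2DG+Oligo"],
                           resolution_floor = floor_pop)
      })
      mmean <- function(f) mean(vapply(profs, `[[`, numeric(1), f))
      metrics <- vapply(c("glucose_dependence", "mitochondrial_dependence",
                          "glycolytic_capacity", "faoaao_capacity",
                          "delta_mfi"), mmean, numeric(1))
      flags <- character()
      if (metrics["mitochondrial_dependence"] < 0) flags <- c(flags, "MITA")
      if (metrics["glucose_dependence"] < 0) flags <- c(flags, "NEGATIVE_GLUCOSE_DEP")
      if (any(metrics[1:4] < 0 | metrics[1:4] > 100)) flags <- c(flags, "OUT_OF_RANGE")
      if (!is.na(floor_pop) && metrics["delta_mfi"] < floor_pop)
        flags <- c(flags, "LOW_RESOLUTION")
      out[[pop]] <- structure(c(as.list(metrics[1:4]),
                                list(delta_mfi = unname(metrics["delta_mfi"]),
                                     flags = flags)),
                              class = "dependence_profile")
    }
  }
  out
}
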
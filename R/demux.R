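#' Inhibitor condition labels
#'
#' The four treatment arms of the assay, in canonical order: vehicle
#' control (DMSO), glucose-metabolism inhibition (2-deoxyglucose),
#' mitochondrial ATP-synthase inhibition (oligomycin), and the double
#' inhibition that abolishes ATP production.
#'
#' @format Character vector of length 4: `"DMSO"`, `"2DG"`, `"Oligo"`,
#'   `"2DG+Oligo"`.
#' @export
condition_labels <- c("DMSO", "2DG", "Oligo", "2DG+Oligo")

#' Barcode plan: dye-level combinations to conditions
#'
#' The four conditions are pooled into one tube after labelling each with a
#' combination of two amine-reactive dyes, each applied at one of two
#' dilutions roughly 100-fold apart in resulting intensity (the 1:1000 vs
#' 1:100,000 staining scheme). A plan is a bijection from the four
#' (level A, level B) combinations onto the four condition labels.
#'
#' The default orientation (hi/hi = DMSO, hi/lo = 2DG, lo/hi = Oligo,
#' lo/lo = 2DG+Oligo) is a package convention — the combination-to-condition
#' assignment is an experiment-design choice and can be overridden.
#'
#' @param hi_hi,hi_lo,lo_hi,lo_lo Condition label for each level combination
#'   (dye A level / dye B level).
#' @param expected_ratio Expected hi:lo intensity ratio (default 100).
#' @return An object of class `barcode_plan`.
#' @export
barcode_plan <- function(hi_hi = "DMSO", hi_lo = "2DG", lo_hi = "Oligo",
                         lo_lo = "2DG+Oligo", expected_ratio = 100) {
  map <- c("hi/hi" = hi_hi, "hi/lo" = hi_lo, "lo/hi" = lo_hi, "lo/lo" = lo_lo)
  if (!setequal(map, condition_labels) || anyDuplicated(map))
    stop("barcode plan must be a bijection onto the four condition labels: ",
         paste(condition_labels, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(expected_ratio), expected_ratio > 1)
  structure(list(map = map, expected_ratio = expected_ratio),
            class = "barcode_plan")
}

#' Fit the hi/lo threshold of one barcode channel
#'
#' Splits the log10 intensities of a barcode-dye channel into two classes
#' by exhaustively scanning all split points of the sorted values and
#' choosing the one minimising total within-class variance (the 1-D
#' two-means partition; deterministic, no random initialisation). The
#' threshold is the midpoint of the two class centres on the log10 scale.
#'
#' Non-positive intensities carry no barcode information and are dropped
#' before fitting; it is an error if they exceed half the events. A channel
#' whose two centres are separated by no more than `2 * guard` log10 units
#' has no usable hi/lo structure and raises a demultiplexing error.
#'
#' @param intensities Numeric vector of raw barcode-channel intensities.
#' @param guard Half-width of the guard band in log10 units (default 0.1).
#' @param min_events Minimum events required per putative class.
#' @return List with `log10_threshold`, `threshold` (linear scale),
#'   `log10_centers` (length 2, increasing) and `n_dropped`.
#' @export
fit_barcode_threshold <- function(intensities, guard = 0.1, min_events = 25L) {
  stopifnot(is.numeric(intensities), guard >= 0)
  pos <- intensities[intensities > 0]
  n_dropped <- length(intensities) - length(pos)
  if (n_dropped > length(intensities) / 2)
    stop("demux error: more than 50% of barcode intensities are non-positive",
         call. = FALSE)
  if (length(pos) < 2L * min_events)
    stop("demux error: need at least ", 2L * min_events,
         " positive barcode events, got ", length(pos), call. = FALSE)
  x <- sort(log10(pos))
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1L)
  # within-class sum of squares for split after position k, via prefix sums
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ss_lo + ss_hi)  # first minimum on ties
  c_lo <- cs[best] / best
  c_hi <- (cs[n] - cs[best]) / (n - best)
  if (c_hi - c_lo <= 2 * guard)
    stop("demux error: no hi/lo structure in barcode channel (centers ",
         signif(c_lo, 4), " and ", signif(c_hi, 4),
         " log10 units, separation <= 2*guard)", call. = FALSE)
  mid <- (c_lo + c_hi) / 2
  list(log10_threshold = mid, threshold = 10^mid,
       log10_centers = c(c_lo, c_hi), n_dropped = n_dropped)
}

# level decision for one barcode channel: hi iff log10 intensity >= the
# threshold (ties go to hi by convention); NA inside the guard corridor or
# for non-positive intensities
barcode_level <- function(x, log10_threshold, guard) {
  lx <- ifelse(x > 0, log10(x), NA_real_)
  lev <- ifelse(lx >= log10_threshold, "hi", "lo")
  lev[is.na(lx) | abs(lx - log10_threshold) < guard] <- NA_character_
  as.character(lev)
}

#' Demultiplex pooled inhibitor conditions from barcode channels
#'
#' Fits a hi/lo threshold independently on each of the two barcode
#' channels ([fit_barcode_threshold()]), classifies each event into a
#' (level A, level B) combination, and maps combinations to condition
#' labels via the plan. Events whose log10 intensity falls strictly within
#' `guard` of either threshold — or with a non-positive barcode value —
#' are left unassigned and excluded from all downstream MFI computation,
#' mimicking the conservative cluster gates that would be drawn by hand.
#' An event exactly on a threshold is assigned hi.
#'
#' @param table An [event_table()] of a pooled tube.
#' @param cmap A [channel_map()] with both barcode roles set.
#' @param plan A [barcode_plan()].
#' @param guard Guard half-width in log10 units (default 0.1).
#' @param min_events_condition Conditions with fewer assigned events are
#'   flagged (default 100); below `hard_floor` (default 25) it is an error.
#' @param hard_floor See above.
#' @return Object of class `demux_result`: `condition` (character vector,
#'   `NA` for unassigned), `thresholds` (per-channel fits), `counts`
#'   (named, four conditions plus `unassigned`), `unassigned_fraction`,
#'   and `flags` (names of under-populated conditions).
#' @export
assign_conditions <- function(table, cmap, plan = barcode_plan(), guard = 0.1,
                              min_events_condition = 100L, hard_floor = 25L) {
  stopifnot(inherits(plan, "barcode_plan"))
  idx <- validate_channels(table, cmap)
  if (is.null(idx$barcode_a) || is.null(idx$barcode_b))
    stop("both barcode channels must be mapped to demultiplex a pooled tube",
         call. = FALSE)
  a <- table$values[, idx$barcode_a]
  b <- table$values[, idx$barcode_b]
  fit_a <- fit_barcode_threshold(a, guard = guard)
  fit_b <- fit_barcode_threshold(b, guard = guard)

  la <- barcode_level(a, fit_a$log10_threshold, guard)
  lb <- barcode_level(b, fit_b$log10_threshold, guard)
  combo <- ifelse(is.na(la) | is.na(lb), NA, paste(la, lb, sep = "/"))
  condition <- unname(plan$map[combo])

  counts <- vapply(condition_labels,
                   function(cl) sum(condition == cl, na.rm = TRUE), integer(1))
  counts <- c(counts, unassigned = sum(is.na(condition)))
  low <- condition_labels[counts[condition_labels] < min_events_condition]
  if (any(counts[condition_labels] < hard_floor))
    stop("demux error: condition(s) below the hard event floor (",
         hard_floor, "): ",
         paste(condition_labels[counts[condition_labels] < hard_floor],
               collapse = ", "), call. = FALSE)
  structure(list(condition = condition,
                 thresholds = list(barcode_a = fit_a, barcode_b = fit_b),
                 counts = counts,
                 unassigned_fraction = unname(counts["unassigned"]) / length(condition),
                 flags = if (length(low)) paste0("LOW_EVENTS:", low) else character()),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n  counts: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n",
      "  unassigned fraction: ", signif(x$unassigned_fraction, 3), "\n",
      "  log10 thresholds: A=", signif(x$thresholds$barcode_a$log10_threshold, 4),
      ", B=", signif(x$thresholds$barcode_b$log10_threshold, 4), "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
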
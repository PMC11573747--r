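#' Define a population gate
#'
#' Axis-aligned threshold gate: a conjunction of 1-D predicates on marker
#' roles, optionally nested under a parent gate. Cutoffs are in raw
#' fluorescence a.u. (no transform is applied, consistent with the rest of
#' the pipeline). Gates form a forest; an event belongs to a gate iff it
#' satisfies every predicate and belongs to the parent gate.
#'
#' @param name Population name.
#' @param predicates List of predicates, each `list(marker=, op=, cutoff=)`
#'   with `op` one of `">"`, `"<"`, `">="`, `"<="`; `marker` is a role
#'   resolved through the channel map.
#' @param parent Optional parent gate name.
#' @return Object of class `population_gate`.
#' @export
population_gate <- function(name, predicates, parent = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!length(predicates)) stop("a gate needs at least one predicate", call. = FALSE)
  for (p in predicates) {
    if (!all(c("marker", "op", "cutoff") %in% names(p)))
      stop("each predicate needs marker, op and cutoff", call. = FALSE)
    if (!p$op %in% c(">", "<", ">=", "<="))
      stop("unsupported comparator '", p$op, "' in gate '", name, "'",
           call. = FALSE)
    stopifnot(is.numeric(p$cutoff))
  }
  structure(list(name = name, predicates = predicates, parent = parent),
            class = "population_gate")
}

#' Apply threshold gates to an event table
#'
#' Evaluates a forest of [population_gate()]s against an event table and
#' returns per-gate membership, per-event leaf labels and per-population
#' counts. Leaf gates (gates with no children) are the reported
#' populations; an event matching no leaf is labelled `"ungated"`. If an
#' event satisfies several leaf gates it is counted in each gate's
#' membership; its single `label` is the first matching leaf in gate
#' order.
#'
#' @param table An [event_table()].
#' @param cmap A [channel_map()] resolving the marker roles.
#' @param gates List of [population_gate()]s (forest: no cycles, parents
#'   defined in the list).
#' @return List with `membership` (logical matrix events x gates), `label`
#'   (character vector, `"ungated"` where no leaf matched), `counts`
#'   (named integer vector over leaf populations plus `ungated`), and
#'   `flags` (empty-gate warnings).
#' @export
apply_gates <- function(table, cmap, gates) {
  if (inherits(gates, "population_gate")) gates <- list(gates)
  stopifnot(length(gates) >= 1L)
  idx <- validate_channels(table, cmap)
  gnames <- vapply(gates, `[[`, character(1), "name")
  if (anyDuplicated(gnames))
    stop("duplicate gate names: ",
         paste(unique(gnames[duplicated(gnames)]), collapse = ", "),
         call. = FALSE)
  parents <- vapply(gates, function(g) g$parent %||% NA_character_, character(1))
  unknown <- setdiff(stats::na.omit(parents), gnames)
  if (length(unknown))
    stop("config error: unknown parent gate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  marker_col <- function(role) {
    if (!is.null(idx$markers) && role %in% names(idx$markers))
      return(idx$markers[[role]])
    j <- match(role, table$channel_names)  # allow direct channel names too
    if (is.na(j))
      stop("gate predicate refers to unknown marker role '", role, "'",
           call. = FALSE)
    j
  }

  own <- matrix(TRUE, nrow(table$values), length(gates),
                dimnames = list(NULL, gnames))
  for (gi in seq_along(gates)) {
    for (p in gates[[gi]]$predicates) {
      v <- table$values[, marker_col(p$marker)]
      own[, gi] <- own[, gi] & switch(p$op,
                                      ">" = v > p$cutoff, "<" = v < p$cutoff,
                                      ">=" = v >= p$cutoff, "<=" = v <= p$cutoff)
    }
  }
  # propagate parent membership; parents may appear in any order, and the
  # forest is acyclic, so iterate to a fixed point over depths
  membership <- own
  depth <- rep(0L, length(gates))
  repeat {
    changed <- FALSE
    for (gi in seq_along(gates)) {
      pa <- parents[gi]
      if (!is.na(pa)) {
        d <- depth[match(pa, gnames)] + 1L
        if (d != depth[gi]) { depth[gi] <- d; changed <- TRUE }
        if (d > length(gates))
          stop("config error: cycle in gate graph at '", gnames[gi], "'",
               call. = FALSE)
      }
    }
    if (!changed) break
  }
  for (gi in order(depth)) {
    pa <- parents[gi]
    if (!is.na(pa))
      membership[, gi] <- membership[, gi] & membership[, match(pa, gnames)]
  }

  leaves <- gnames[!gnames %in% stats::na.omit(parents)]
  label <- rep("ungated", nrow(table$values))
  for (g in rev(leaves)) label[membership[, g]] <- g  # first leaf wins
  counts <- c(vapply(leaves, function(g) sum(membership[, g]), integer(1)),
              ungated = sum(label == "ungated"))
  flags <- paste0("EMPTY_GATE:", gnames[colSums(membership) == 0L])
  if (!length(gnames[colSums(membership) == 0L])) flags <- character()
  list(membership = membership, label = label, counts = counts, flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
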
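#' Construct an event table
#'
#' An `event_table` is the universal currency between pipeline stages: a
#' numeric matrix of cytometry events (rows) by fluorescence channels
#' (columns), in arbitrary units as exported by the instrument, plus optional
#' sample-level metadata. No transformation (compensation, logicle, arcsinh)
#' is ever applied; values are taken as stored.
#'
#' @param values Numeric matrix, one row per event, one column per channel.
#'   A data frame of numeric columns is accepted and coerced.
#' @param channel_names Character vector of unique channel names; defaults to
#'   the column names of `values`.
#' @param meta Named list of sample-level metadata. Recognised keys:
#'   `sample_id`, `donor_id`, `tissue`, `stimulation`, `replicate_id`, and
#'   `condition` (for unpooled, one-file-per-condition acquisitions).
#' @return An object of class `event_table`.
#' @examples
#' tb <- event_table(matrix(c(100, 200, 5, 7), 2, 2,
#'                          dimnames = list(NULL, c("ncAA", "CD14"))))
#' n_events(tb)
#' @export
event_table <- function(values, channel_names = colnames(values), meta = list()) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix of events x channels", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("event table must have at least 1 event and 1 channel", call. = FALSE)
  if (is.null(channel_names))
    stop("channel names are required (column names or `channel_names`)", call. = FALSE)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(values))
    stop("length of `channel_names` (", length(channel_names),
         ") does not match number of columns (", ncol(values), ")", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("event values must be finite", call. = FALSE)
  colnames(values) <- channel_names
  meta <- validate_meta(meta)
  structure(list(values = values, channel_names = channel_names, meta = meta),
            class = "event_table")
}

meta_keys <- c("sample_id", "donor_id", "tissue", "stimulation",
               "replicate_id", "condition")

validate_meta <- function(meta) {
  if (length(meta) == 0L) return(list())
  if (is.null(names(meta)) || any(names(meta) == ""))
    stop("`meta` must be a fully named list", call. = FALSE)
  bad <- setdiff(names(meta), meta_keys)
  if (length(bad))
    stop("unknown metadata keys: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(meta_keys, collapse = ", "), call. = FALSE)
  lapply(meta, function(x) as.character(x)[1L])
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x$values), " events x ", ncol(x$values),
      " channels\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  if (length(x$meta))
    cat("  meta: ", paste(names(x$meta), unlist(x$meta), sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname event_table
#' @param x An `event_table`.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$values)
}

#' Declare channel roles
#'
#' Binds the assay roles to instrument channel names: the clicked
#' ncAA-azide signal channel (the protein-synthesis readout), the two
#' amine-reactive barcoding dye channels used to encode inhibitor
#' conditions, lineage marker channels for population gating, and an
#' optional viability channel.
#'
#' @param ncaa_signal Channel carrying the click-labelled ncAA fluorescence.
#' @param barcode_a,barcode_b Channels of the two barcoding dyes (e.g. the
#'   CF700-SE and CF750-SE roles). May be `NULL` for unpooled acquisitions.
#' @param markers Named character vector mapping marker roles to channel
#'   names, e.g. `c(CD14 = "APC-A")`.
#' @param viability Optional viability-dye channel.
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(ncaa_signal, barcode_a = NULL, barcode_b = NULL,
                        markers = character(), viability = NULL) {
  stopifnot(is.character(ncaa_signal), length(ncaa_signal) == 1L)
  markers <- unlist(markers)
  if (length(markers) && (is.null(names(markers)) || any(names(markers) == "")))
    stop("`markers` must be a named character vector (role = channel)", call. = FALSE)
  bc <- c(barcode_a, barcode_b)
  if (any(duplicated(c(ncaa_signal, bc))))
    stop("ncaa_signal, barcode_a and barcode_b must be mutually distinct channels",
         call. = FALSE)
  structure(list(ncaa_signal = ncaa_signal,
                 barcode_a = if (is.null(barcode_a)) NULL else as.character(barcode_a),
                 barcode_b = if (is.null(barcode_b)) NULL else as.character(barcode_b),
                 markers = markers,
                 viability = if (is.null(viability)) NULL else as.character(viability)),
            class = "channel_map")
}

#' Resolve a channel map against an event table
#'
#' Checks every role in the map against the table's channels and returns
#' the resolved column indices. Fails atomically: if any role is missing,
#' nothing is returned and the error names both the role and the absent
#' channel.
#'
#' @param table An [event_table()].
#' @param cmap A [channel_map()].
#' @return Named list of column indices: `ncaa_signal`, optionally
#'   `barcode_a`, `barcode_b`, `viability`, and `markers` (named integer
#'   vector).
#' @export
validate_channels <- function(table, cmap) {
  stopifnot(inherits(table, "event_table"), inherits(cmap, "channel_map"))
  nm <- table$channel_names
  resolve <- function(role, channel) {
    idx <- match(channel, nm)
    if (is.na(idx))
      stop("channel map role '", role, "' refers to channel '", channel,
           "' which is not in the event table", call. = FALSE)
    idx
  }
  out <- list(ncaa_signal = resolve("ncaa_signal", cmap$ncaa_signal))
  for (role in c("barcode_a", "barcode_b", "viability"))
    if (!is.null(cmap[[role]])) out[[role]] <- resolve(role, cmap[[role]])
  if (length(cmap$markers)) {
    midx <- vapply(seq_along(cmap$markers), function(i)
      resolve(paste0("marker '", names(cmap$markers)[i], "'"), cmap$markers[[i]]),
      integer(1))
    names(midx) <- names(cmap$markers)
    out$markers <- midx
  }
  out
}
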
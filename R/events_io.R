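#' Read an event table from disk
#'
#' Reads raw cytometry event data from an FCS 3.0/3.1 file or from the
#' package's CSV event-table dialect (comma separated, `.` decimal, UTF-8,
#' mandatory header row of channel names; metadata in constant columns
#' prefixed `meta_`). Values are returned exactly as stored: no
#' compensation or display transform is applied and event order is
#' preserved.
#'
#' @param path Path to the file.
#' @param format `"fcs"` or `"csv"`; guessed from the file extension when
#'   missing.
#' @return An [event_table()].
#' @seealso [write_event_table()]
#' @export
read_event_table <- function(path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  switch(format, fcs = read_fcs(path), csv = read_events_csv(path))
}

#' Write an event table to disk
#'
#' The inverse of [read_event_table()]. CSV round-trips are value exact
#' (17 significant digits); FCS is written as little-endian float32 list
#' mode, preserving values to within single-precision rounding (relative
#' error below 1e-6).
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param format `"fcs"` or `"csv"`; guessed from the extension when missing.
#' @return Invisibly, `path`.
#' @export
write_event_table <- function(table, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(table, "event_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  switch(format,
         fcs = write_fcs(table, path),
         csv = write_events_csv(table, path))
  invisible(path)
}

read_events_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("CSV event table must have a header row and at least one event: ",
         path, call. = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm))
    stop("duplicate channel names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  is_meta <- startsWith(nm, "meta_")
  meta <- list()
  for (col in nm[is_meta]) {
    key <- sub("^meta_", "", col)
    meta[[key]] <- as.character(df[[col]][1L])
  }
  values <- as.matrix(df[!is_meta])
  if (!is.numeric(values))
    stop("non-numeric channel column(s) in ", path, call. = FALSE)
  event_table(values, meta = meta)
}

write_events_csv <- function(table, path) {
  vals <- table$values
  # %.17g keeps doubles bit-exact through the text round-trip
  txt <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  header <- table$channel_names
  if (length(table$meta)) {
    for (key in names(table$meta)) {
      txt <- cbind(txt, rep(table$meta[[key]], nrow(txt)))
      header <- c(header, paste0("meta_", key))
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
}
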
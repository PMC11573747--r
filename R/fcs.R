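# Minimal FCS 3.0/3.1 support: list-mode data segments with $DATATYPE F
# (float32) or I (uint16/uint32), uniform parameter widths, little- or
# big-endian. Covers CytoFLEX-style exports and the package's own writer;
# anything else is rejected with a format error. Spillover/compensation
# keywords are ignored on purpose: values are used as stored.

fcs_meta_keywords <- c(sample_id = "SAMPLE_ID", donor_id = "DONOR_ID",
                       tissue = "TISSUE", stimulation = "STIMULATION",
                       replicate_id = "REPLICATE_ID", condition = "CONDITION")

read_fcs <- function(path) {
  size <- file.size(path)
  raw <- readBin(path, "raw", n = size)
  if (size < 58L)
    stop("not an FCS file (truncated header): ", path, call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' in ", path,
         " (only FCS3.0/3.1)", call. = FALSE)
  off <- function(i) {
    s <- trimws(rawToChar(raw[(11L + 8L * (i - 1L)):(10L + 8L * i)]))
    if (s == "") 0 else as.numeric(s)
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (text_beg <= 0 || text_end <= text_beg)
    stop("invalid TEXT segment offsets in ", path, call. = FALSE)

  text <- rawToChar(raw[(text_beg + 1L):(text_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  kw <- stats::setNames(parts[seq(2L, length(parts), 2L)],
                        toupper(trimws(parts[seq(1L, length(parts), 2L)])))

  need <- function(key) {
    if (is.na(kw[key]))
      stop("FCS file ", path, " lacks required keyword ", key, call. = FALSE)
    kw[[key]]
  }
  datatype <- toupper(need("$DATATYPE"))
  if (!datatype %in% c("F", "I"))
    stop("unsupported $DATATYPE '", datatype, "' in ", path,
         " (only F and I)", call. = FALSE)
  if (toupper(need("$MODE")) != "L")
    stop("unsupported $MODE '", kw[["$MODE"]], "' in ", path,
         " (list mode only)", call. = FALSE)
  byteord <- need("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD '", byteord, "' in ", path,
                        call. = FALSE))
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  bits <- unique(vapply(seq_len(p),
                        function(i) as.integer(need(sprintf("$P%dB", i))),
                        integer(1)))
  if (length(bits) != 1L)
    stop("mixed parameter bit widths are not supported: ", path, call. = FALSE)
  if (datatype == "F" && bits != 32L)
    stop("$DATATYPE F requires $PnB 32 (got ", bits, "): ", path, call. = FALSE)
  if (datatype == "I" && !bits %in% c(16L, 32L))
    stop("$DATATYPE I supports $PnB 16/32 (got ", bits, "): ", path,
         call. = FALSE)

  if (data_beg == 0) data_beg <- as.numeric(need("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  nbytes <- bits / 8L * as.numeric(n) * p
  if (data_end - data_beg + 1 < nbytes)
    stop("DATA segment shorter than $TOT x $PAR values: ", path, call. = FALSE)

  con <- rawConnection(raw[(data_beg + 1L):(data_beg + nbytes)])
  on.exit(close(con))
  vals <- if (datatype == "F") {
    readBin(con, "numeric", n = n * p, size = 4L, endian = endian)
  } else if (bits == 16L) {
    readBin(con, "integer", n = n * p, size = 2L, signed = FALSE,
            endian = endian)
  } else {
    v <- readBin(con, "integer", n = n * p, size = 4L, endian = endian)
    ifelse(v < 0, v + 2^32, as.numeric(v))  # stored unsigned
  }
  values <- matrix(as.numeric(vals), nrow = n, ncol = p, byrow = TRUE)
  channels <- vapply(seq_len(p), function(i) need(sprintf("$P%dN", i)),
                     character(1))
  meta <- list()
  for (key in names(fcs_meta_keywords)) {
    v <- kw[fcs_meta_keywords[[key]]]
    if (!is.na(v) && nzchar(v)) meta[[key]] <- v
  }
  event_table(values, channel_names = channels, meta = meta)
}

write_fcs <- function(table, path) {
  vals <- table$values
  n <- nrow(vals); p <- ncol(vals)
  if (any(grepl("/", table$channel_names, fixed = TRUE)))
    stop("channel names may not contain the FCS delimiter '/'", call. = FALSE)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          # fixed-width placeholders so the TEXT length is offset-independent
          "$BEGINDATA" = sprintf("%012d", 0), "$ENDDATA" = sprintf("%012d", 0),
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n))
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- table$channel_names[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(2^ceiling(log2(max(vals[, i], 1) + 1)),
                                      scientific = FALSE)
  }
  for (key in names(fcs_meta_keywords))
    if (!is.null(table$meta[[key]]))
      kw[fcs_meta_keywords[[key]]] <- gsub("/", "_", table$meta[[key]])

  text <- paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))
  text_beg <- 58L
  text_end <- text_beg + nchar(text, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n * p - 1L
  kw["$BEGINDATA"] <- sprintf("%012d", data_beg)
  kw["$ENDDATA"] <- sprintf("%012d", data_end)
  text <- paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))

  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(vals)), con, size = 4L, endian = "little")
  invisible(path)
}
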
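#' Read a spectrum from a JCAMP-DX or CSV file
#'
#' Supported JCAMP-DX subset: single-block files with
#' `##XYDATA=(X++(Y..Y))` in AFFN or simple SQZ (squeezed-digit) encoding,
#' or `##XYPOINTS=(XY..XY)`; `##XFACTOR`/`##YFACTOR` scaling is applied and
#' X units must be 1/CM. Compound (multi-block) files are rejected. CSV files
#' carry two numeric columns (wavenumber, intensity), an optional single
#' header line, and optional `# key: value` comment lines for channel
#' metadata.
#'
#' The returned axis is always ascending; descending instrument order is
#' reversed together with the intensities.
#'
#' @param path Path to the file.
#' @param format `"jcamp"`, `"csv"` or `"auto"` (decide from the extension,
#'   falling back to content sniffing).
#' @param channel Override for the intensity channel when the file carries no
#'   channel metadata; default `"transmittance_pct"` (the usual instrument
#'   export mode).
#' @param csv_dialect `"period"` for comma-separated columns with `.` decimal
#'   (default), `"comma"` for semicolon-separated columns with `,` decimal.
#' @return An [ftir_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp", "csv"),
                          channel = NULL,
                          csv_dialect = c("period", "comma")) {
  format <- match.arg(format)
  csv_dialect <- match.arg(csv_dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcm", "jcamp")) "jcamp"
              else if (ext %in% c("csv", "txt", "tsv")) "csv"
              else if (startsWith(readLines(path, n = 1L, warn = FALSE), "##"))
                "jcamp" else "csv"
  }
  if (format == "jcamp") read_jcamp(path, channel)
  else read_spectrum_csv(path, channel, csv_dialect)
}

#' Write a spectrum to a JCAMP-DX or CSV file
#'
#' Round-trips through [read_spectrum()] within 1e-9. The channel and
#' derivative order are recorded in file metadata (`##$CHANNEL` /
#' `##$DERIVATIVEORDER` for JCAMP, `# key: value` comments for CSV) and
#' restored on read. Uniform axes are written as `##XYDATA=(X++(Y..Y))`,
#' non-uniform axes as `##XYPOINTS=(XY..XY)`.
#'
#' @inheritParams read_spectrum
#' @param s An [ftir_spectrum()].
#' @return The path, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("jcamp", "csv"),
                           csv_dialect = c("period", "comma")) {
  stopifnot(inherits(s, "ftir_spectrum"))
  format <- match.arg(format)
  csv_dialect <- match.arg(csv_dialect)
  out <- tryCatch({
    if (format == "jcamp") write_jcamp(s, path) else
      write_spectrum_csv(s, path, csv_dialect)
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

# plain decimal rendering: SQZ/AFFN data may not contain exponent letters,
# and 'e'/'E' are squeezed digits in ASDF, so exponents are banned outright
num_fmt <- function(x) {
  out <- formatC(x, digits = 15, format = "fg", flag = "-")
  trimws(out)
}

write_jcamp <- function(s, path) {
  w <- s$wavenumbers
  y <- s$intensities
  yunits <- switch(s$channel,
                   transmittance_pct = "TRANSMITTANCE",
                   absorbance = "ABSORBANCE",
                   derivative = "ARBITRARY UNITS")
  hdr <- c(
    paste0("##TITLE= ", if (!is.null(s$meta$title)) s$meta$title else
      basename(path)),
    "##JCAMP-DX= 4.24",
    "##DATA TYPE= INFRARED SPECTRUM",
    "##ORIGIN= ftirquant",
    "##XUNITS= 1/CM",
    paste0("##YUNITS= ", yunits),
    paste0("##$CHANNEL= ", s$channel),
    paste0("##$DERIVATIVEORDER= ", s$derivative_order),
    "##XFACTOR= 1",
    "##YFACTOR= 1",
    paste0("##FIRSTX= ", num_fmt(w[1L])),
    paste0("##LASTX= ", num_fmt(w[length(w)])),
    paste0("##NPOINTS= ", length(w)),
    paste0("##FIRSTY= ", num_fmt(y[1L])))
  if (is_uniform_axis(w, rtol = 1e-9)) {
    idx <- split(seq_along(y), ceiling(seq_along(y) / 6))
    body <- vapply(idx, function(i)
      paste(num_fmt(w[i[1L]]), paste(num_fmt(y[i]), collapse = " ")),
      character(1))
    lines <- c(hdr, "##XYDATA= (X++(Y..Y))", body, "##END=")
  } else {
    idx <- split(seq_along(y), ceiling(seq_along(y) / 3))
    body <- vapply(idx, function(i)
      paste(paste0(num_fmt(w[i]), ",", num_fmt(y[i])), collapse = " "),
      character(1))
    lines <- c(hdr, "##XYPOINTS= (XY..XY)", body, "##END=")
  }
  writeLines(lines, path)
}

# one ASDF token -> numeric values; SQZ pseudo-digits: @=0, A..I=1..9,
# a..i=-1..-9; plain +/- starts an AFFN value
decode_asdf_token <- function(tok, lineno) {
  pieces <- strsplit(gsub("([@A-Ia-i+-])", " \\1", tok), " +")[[1L]]
  pieces <- pieces[nzchar(pieces)]
  vapply(pieces, function(p) {
    c1 <- substr(p, 1L, 1L)
    rest <- substring(p, 2L)
    v <- if (c1 == "@") as.numeric(paste0("0", rest))
    else if (c1 %in% LETTERS[1:9])
      as.numeric(paste0(match(c1, LETTERS), rest))
    else if (c1 %in% letters[1:9])
      -as.numeric(paste0(match(c1, letters), rest))
    else suppressWarnings(as.numeric(p))
    if (is.na(v))
      stop("unparseable JCAMP data at line ", lineno, ": '", tok, "'",
           call. = FALSE)
    v
  }, numeric(1), USE.NAMES = FALSE)
}

parse_asdf_line <- function(line, lineno) {
  toks <- strsplit(trimws(line), "[,;[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  unlist(lapply(toks, function(tok) {
    v <- suppressWarnings(as.numeric(tok))     # AFFN fast path
    if (!is.na(v)) v else decode_asdf_token(tok, lineno)
  }))
}

read_jcamp <- function(path, channel_override = NULL) {
  lines <- readLines(path, warn = FALSE)
  is_ldr <- grepl("^\\s*##", lines)
  ldr_idx <- which(is_ldr)
  keys <- toupper(gsub(" ", "", sub("^\\s*##([^=]*)=.*$", "\\1",
                                    lines[ldr_idx])))
  vals <- trimws(sub("^\\s*##[^=]*=", "", lines[ldr_idx]))
  if (sum(keys == "TITLE") > 1L || any(keys == "BLOCKS"))
    stop("compound (multi-block) JCAMP files are not supported: ", path,
         call. = FALSE)
  if (!any(keys == "TITLE"))
    stop("unparseable file (no ##TITLE record) at line 1: ",
         lines[1L], call. = FALSE)
  get1 <- function(key, default = NA_character_) {
    i <- which(keys == key)
    if (length(i)) vals[i[1L]] else default
  }
  xunits <- toupper(get1("XUNITS", "1/CM"))
  if (!grepl("1/CM|CM-1|WAVENUMBER", xunits))
    stop("unsupported XUNITS '", xunits, "' (need 1/CM)", call. = FALSE)
  xfactor <- as.numeric(get1("XFACTOR", "1"))
  yfactor <- as.numeric(get1("YFACTOR", "1"))
  npoints <- as.numeric(get1("NPOINTS", NA))

  data_i <- which(keys %in% c("XYDATA", "XYPOINTS"))
  if (!length(data_i))
    stop("no ##XYDATA or ##XYPOINTS record in ", path, call. = FALSE)
  data_kind <- keys[data_i[1L]]
  start <- ldr_idx[data_i[1L]] + 1L
  after <- ldr_idx[ldr_idx >= start]
  end <- if (length(after)) min(after) - 1L else length(lines)
  body <- start:end
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body))
    stop("empty data table in ", path, call. = FALSE)

  if (data_kind == "XYDATA") {
    firstx <- as.numeric(get1("FIRSTX"))
    lastx <- as.numeric(get1("LASTX"))
    if (is.na(firstx) || is.na(lastx) || is.na(npoints))
      stop("XYDATA requires FIRSTX, LASTX and NPOINTS in ", path,
           call. = FALSE)
    ys <- numeric(0)
    xs_line <- numeric(0)
    pos_line <- integer(0)
    for (ln in body) {
      v <- parse_asdf_line(lines[ln], ln)
      if (length(v) < 2L)
        stop("unparseable JCAMP data at line ", ln, ": '", lines[ln], "'",
             call. = FALSE)
      xs_line <- c(xs_line, v[1L] * xfactor)
      pos_line <- c(pos_line, length(ys) + 1L)
      ys <- c(ys, v[-1L])
    }
    if (length(ys) != npoints)
      stop("NPOINTS is ", npoints, " but data table holds ", length(ys),
           " ordinates in ", path, call. = FALSE)
    w <- seq(firstx, lastx, length.out = npoints)
    dx <- if (npoints > 1) (lastx - firstx) / (npoints - 1) else 0
    off <- abs(xs_line - w[pos_line])
    if (any(off > abs(dx) + 1e-6))
      stop("line-start abscissa inconsistent with FIRSTX/LASTX/NPOINTS at ",
           "line ", body[which(off > abs(dx) + 1e-6)[1L]], " in ", path,
           call. = FALSE)
    y <- ys * yfactor
  } else {                                    # XYPOINTS: flat x,y stream
    v <- unlist(lapply(body, function(ln) parse_asdf_line(lines[ln], ln)))
    if (length(v) %% 2L != 0L)
      stop("odd number of values in XY table of ", path, call. = FALSE)
    w <- v[seq(1L, length(v), by = 2L)] * xfactor
    y <- v[seq(2L, length(v), by = 2L)] * yfactor
    if (!is.na(npoints) && length(w) != npoints)
      stop("NPOINTS is ", npoints, " but data table holds ", length(w),
           " points in ", path, call. = FALSE)
  }

  chan <- get1("$CHANNEL")
  dord <- as.integer(as.numeric(get1("$DERIVATIVEORDER", "0")))
  if (is.na(chan)) {
    yunits <- toupper(get1("YUNITS", ""))
    chan <- if (grepl("ABSORBANCE", yunits)) "absorbance"
    else if (grepl("TRANSMIT", yunits)) "transmittance_pct"
    else if (!is.null(channel_override)) channel_override
    else "transmittance_pct"
    if (is.na(dord)) dord <- 0L
  }
  meta <- list(source = path, title = get1("TITLE"))
  ftir_spectrum(w, y, channel = chan,
                derivative_order = if (chan == "derivative")
                  max(dord, 1L) else 0L,
                meta = meta)
}

write_spectrum_csv <- function(s, path, csv_dialect) {
  sep <- if (csv_dialect == "comma") ";" else ","
  dec <- if (csv_dialect == "comma") "," else "."
  fmt1 <- function(x) {
    out <- num_fmt(x)
    if (dec != ".") gsub(".", dec, out, fixed = TRUE) else out
  }
  lines <- c(paste0("# channel: ", s$channel),
             paste0("# derivative_order: ", s$derivative_order),
             paste("wavenumber", "intensity", sep = sep),
             paste(fmt1(s$wavenumbers), fmt1(s$intensities), sep = sep))
  writeLines(lines, path)
}

read_spectrum_csv <- function(path, channel_override, csv_dialect) {
  sep <- if (csv_dialect == "comma") ";" else ","
  dec <- if (csv_dialect == "comma") "," else "."
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines)
  chan <- channel_override
  dord <- NA_integer_
  for (ln in meta_lines) {
    m <- regmatches(lines[ln],
                    regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", lines[ln]))[[1L]]
    if (length(m) == 3L) {
      if (m[2L] == "channel") chan <- m[3L]
      if (m[2L] == "derivative_order") dord <- as.integer(m[3L])
    }
  }
  data_lines <- setdiff(seq_along(lines), meta_lines)
  data_lines <- data_lines[nzchar(trimws(lines[data_lines]))]
  if (!length(data_lines))
    stop("no data rows in ", path, call. = FALSE)
  parse_row <- function(ln) {
    f <- strsplit(trimws(lines[ln]), sep, fixed = TRUE)[[1L]]
    if (dec != ".") f <- gsub(dec, ".", f, fixed = TRUE)
    suppressWarnings(as.numeric(f))
  }
  first <- parse_row(data_lines[1L])
  if (anyNA(first)) data_lines <- data_lines[-1L]     # single header line
  if (!length(data_lines))
    stop("no numeric rows in ", path, call. = FALSE)
  rows <- lapply(data_lines, parse_row)
  bad <- which(vapply(rows, function(r) length(r) < 2L || anyNA(r[1:2]),
                      logical(1)))
  if (length(bad))
    stop("unparseable CSV row at line ", data_lines[bad[1L]], ": '",
         lines[data_lines[bad[1L]]], "'", call. = FALSE)
  w <- vapply(rows, `[`, numeric(1), 1L)
  y <- vapply(rows, `[`, numeric(1), 2L)
  if (is.null(chan)) chan <- "transmittance_pct"
  ftir_spectrum(w, y, channel = chan,
                derivative_order = if (chan == "derivative")
                  max(dord, 1L, na.rm = TRUE) else 0L,
                meta = list(source = path))
}
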
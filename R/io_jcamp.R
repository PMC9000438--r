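#' Read a single spectrum from a minimal JCAMP-DX file
#'
#' Supports the uncompressed AFFN subset of JCAMP-DX 4.24: tabular
#' `##XYDATA=(X++(Y..Y))` records (axis reconstructed from
#' FIRSTX/LASTX/NPOINTS, or DELTAX when given) and `##XYPOINTS=(XY..XY)`
#' records. XFACTOR and YFACTOR are honored. ASDF-compressed records
#' (SQZ/DIF/DUP digit letters) are rejected with an explicit error, as are
#' files whose point count disagrees with `##NPOINTS`.
#'
#' @param path JCAMP-DX file path.
#' @return An [ir_spectrum()]; its id is the `##TITLE` record.
#' @seealso [write_jcamp()]
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path))
    ir_stop(sprintf("cannot read '%s'", path), "ir_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", sub("\\$\\$.*$", "", lines))  # strip comments

  labels <- list()
  data_start <- NA_integer_
  data_kind <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, "##")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- toupper(gsub("[ _-]", "", substr(ln, 3L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (key %in% c("XYDATA", "XYPOINTS")) {
      data_start <- i + 1L
      data_kind <- key
      if (key == "XYDATA" && !grepl("X\\+\\+\\(Y\\.\\.Y\\)", val))
        ir_stop(sprintf("unsupported XYDATA form '%s'", val),
                "ir_parse_error")
      break
    }
    labels[[key]] <- val
  }
  if (is.na(data_start))
    ir_stop(sprintf("no XYDATA/XYPOINTS table in '%s'", path),
            "ir_parse_error")

  end <- grep("^\\s*##END", lines)
  end <- if (length(end)) min(end[end >= data_start]) - 1L else length(lines)
  body <- trimws(lines[seq(data_start, end)])
  body <- body[nzchar(body)]
  if (any(grepl("[A-DF-Za-df-z@%]", body)))
    ir_stop("ASDF-compressed (SQZ/DIF/DUP) JCAMP data is not supported; export uncompressed AFFN tables",
            "ir_parse_error")

  num <- function(key, default = NULL) {
    v <- labels[[key]]
    if (is.null(v)) return(default)
    suppressWarnings(as.numeric(v))
  }
  xfac <- num("XFACTOR", 1)
  yfac <- num("YFACTOR", 1)
  title <- labels[["TITLE"]]
  if (is.null(title)) title <- basename(path)

  if (data_kind == "XYPOINTS") {
    tok <- as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                      "[,;[:space:]]+")))
    if (anyNA(tok) || length(tok) %% 2L != 0L)
      ir_stop(sprintf("malformed XYPOINTS table in '%s'", path),
              "ir_parse_error")
    x <- tok[seq(1L, length(tok), 2L)] * xfac
    y <- tok[seq(2L, length(tok), 2L)] * yfac
  } else {
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); np <- num("NPOINTS")
    if (is.null(firstx) || is.null(np))
      ir_stop(sprintf("XYDATA in '%s' needs FIRSTX and NPOINTS", path),
              "ir_parse_error")
    y <- numeric(0)
    for (ln in body) {
      tok <- as.numeric(strsplit(ln, "[,;[:space:]]+")[[1L]])
      if (anyNA(tok))
        ir_stop(sprintf("non-numeric token in XYDATA of '%s'", path),
                "ir_parse_error")
      y <- c(y, tok[-1L])           # first token per line is the line's X
    }
    if (!is.null(np) && length(y) != np)
      ir_stop(sprintf("NPOINTS=%d but %d Y values found in '%s'",
                      np, length(y), path), "ir_integrity_error")
    deltax <- num("DELTAX")
    if (is.null(deltax)) {
      if (is.null(lastx))
        ir_stop(sprintf("XYDATA in '%s' needs DELTAX or LASTX", path),
                "ir_parse_error")
      deltax <- (lastx - firstx) / (np - 1)
    }
    x <- (firstx + (seq_len(np) - 1L) * deltax) * xfac
    y <- y * yfac
  }
  ir_spectrum(x, y, id = title)
}

#' Write a spectrum as a minimal JCAMP-DX file
#'
#' Emits an uncompressed AFFN `##XYDATA=(X++(Y..Y))` record with
#' XFACTOR = YFACTOR = 1 and full-precision values, readable by
#' [read_jcamp()] and by standard JCAMP-DX software. Requires a uniformly
#' spaced axis (the X++(Y..Y) form encodes the axis arithmetically).
#'
#' @param spectrum An `ir_spectrum` on a uniformly spaced axis.
#' @param path Output file path.
#' @param per_line Y values per data line.
#' @return Invisibly, `path`.
#' @export
write_jcamp <- function(spectrum, path, per_line = 6L) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  wn <- spectrum$wavenumbers
  n <- length(wn)
  if (n < 2L)
    ir_stop("JCAMP XYDATA needs at least two channels", "ir_contract_error")
  d <- diff(wn)
  if (max(d) - min(d) > 1e-6 * mean(d))
    ir_stop("X++(Y..Y) JCAMP output requires a uniformly spaced axis",
            "ir_contract_error")
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  hdr <- c(paste0("##TITLE=", spectrum$id),
           "##JCAMP-DX=4.24",
           "##DATA TYPE=INFRARED SPECTRUM",
           "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
           "##XFACTOR=1", "##YFACTOR=1",
           paste0("##FIRSTX=", fmt(wn[1L])),
           paste0("##LASTX=", fmt(wn[n])),
           paste0("##DELTAX=", fmt((wn[n] - wn[1L]) / (n - 1))),
           paste0("##NPOINTS=", n),
           "##XYDATA=(X++(Y..Y))")
  starts <- seq(1L, n, by = per_line)
  rows <- vapply(starts, function(s) {
    e <- min(s + per_line - 1L, n)
    paste(c(fmt(wn[s]), fmt(spectrum$absorbance[s:e])), collapse = " ")
  }, character(1L))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) ir_stop(
                    sprintf("cannot write '%s'", path), "ir_io_error"))
  on.exit(close(con))
  writeLines(c(hdr, rows, "##END="), con)
  invisible(path)
}
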
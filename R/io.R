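# CSV dialect shared by all text inputs/outputs:
#   header line, comma-separated numeric columns, '.' decimal, UTF-8;
#   comment lines begin '#' and may carry metadata as '# key=value'.
# Values are serialized with 17 significant digits so a write/read round
# trip reproduces doubles exactly and re-writing reproduces the text.

fmt_num <- function(x) sprintf("%.17g", x)

write_table_csv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v) || length(v) != 1L || is.list(v)) next
    writeLines(sprintf("# %s=%s", k, if (is.numeric(v)) fmt_num(v) else as.character(v)), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(col)
    if (is.numeric(col)) fmt_num(col) else as.character(col)), sep = ","))
  writeLines(rows, con)
}

read_table_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      k <- sub("=.*$", "", body)
      v <- sub("^[^=]*=", "", body)
      num <- suppressWarnings(as.numeric(v))
      meta[[trimws(k)]] <- if (!is.na(num)) num else trimws(v)
    }
  }
  body <- lines[!is_comment & nzchar(lines)]
  if (length(body) < 1L) stop_data(sprintf("no data in %s", path))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Read / write spectra as CSV
#'
#' Emission spectra use columns `wavelength_nm,intensity`; absorbance
#' spectra use `wavelength_nm,od`. Metadata travel as `# key=value` comment
#' lines. A write/read round trip reproduces the numeric values exactly.
#'
#' @param spec spectrum object to write.
#' @param path file path.
#' @return `read_spectrum_csv` / `read_absorbance_csv` return the parsed
#'   object; the writers return `path` invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "anap_spectrum"))
  write_table_csv(as.data.frame(spec), path, meta = spec$meta)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read_table_csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop_data(sprintf("%s: expected columns wavelength_nm,intensity", path))
  spectrum(df$wavelength_nm, df$intensity, meta = attr(df, "meta"),
           allow_negative = TRUE)
}

#' @rdname write_spectrum_csv
#' @export
write_absorbance_csv <- function(spec, path) {
  stopifnot(inherits(spec, "anap_absorbance"))
  write_table_csv(as.data.frame(spec), path, meta = spec$meta)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_absorbance_csv <- function(path) {
  df <- read_table_csv(path)
  if (!all(c("wavelength_nm", "od") %in% names(df)))
    stop_data(sprintf("%s: expected columns wavelength_nm,od", path))
  absorbance_spectrum(df$wavelength_nm, df$od, meta = attr(df, "meta"))
}

#' Read / write time-resolved traces as CSV
#'
#' Traces use columns `time_ns,signal` with `# kind=trpl|tas` and
#' `# averages=N` metadata; IRFs use the same layout with `# kind=irf`.
#'
#' @param x a `decay_trace` or `anap_irf` to write.
#' @param path file path.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "anap_irf")) {
    write_table_csv(data.frame(time_ns = x$time, signal = x$response), path,
                    meta = c(list(kind = "irf"), x$meta))
  } else {
    stopifnot(inherits(x, "decay_trace"))
    write_table_csv(data.frame(time_ns = x$time, signal = x$signal), path,
                    meta = c(list(kind = x$kind, averages = x$averages), x$meta))
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read_table_csv(path)
  if (!all(c("time_ns", "signal") %in% names(df)))
    stop_data(sprintf("%s: expected columns time_ns,signal", path))
  meta <- attr(df, "meta")
  kind <- if (!is.null(meta$kind)) meta$kind else "trpl"
  if (identical(kind, "irf"))
    return(irf(df$time_ns, df$signal, meta = meta[setdiff(names(meta), "kind")]))
  averages <- if (!is.null(meta$averages)) meta$averages else 1
  decay_trace(df$time_ns, df$signal, kind = kind, averages = averages,
              meta = meta[setdiff(names(meta), c("kind", "averages"))])
}
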
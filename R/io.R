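#' Load a rate-parameter file
#'
#' Parameter files are tab-separated text with a commented header
#' (\code{# scheme:}, \code{# isoform:}, \code{# temperature:}) and columns
#' \code{transition}, \code{alpha}, \code{beta} (optionally \code{corr_a},
#' \code{corr_b}). The shipped fixtures transcribe the published rate
#' tables for \code{mmodel1}/\code{mmodel2} x \code{hERG1a}/\code{hERG1b}.
#'
#' @param source Path to a parameter file.
#' @param resolve Resolve reversibility-constrained transitions (default
#'   TRUE).
#' @return A validated \code{\link{herg_params}} object.
#' @export
load_parameters <- function(source, resolve = TRUE) {
  if (!file.exists(source)) stop("load_parameters: no such file: ", source)
  lines <- readLines(source)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default = NA_character_) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  scheme <- get_field("scheme")
  if (is.na(scheme)) stop("load_parameters: header line '# scheme: ...' missing")
  if (!scheme %in% c("mmodel1", "mmodel2")) {
    stop("load_parameters: unknown scheme '", scheme, "'")
  }
  isoform <- get_field("isoform", "unknown")
  temperature <- suppressWarnings(as.numeric(get_field("temperature", "296.15")))
  tab <- utils::read.delim(source, comment.char = "#",
                           stringsAsFactors = FALSE)
  herg_params(scheme, tab, isoform = isoform, temperature = temperature,
              resolve = resolve)
}

#' Shipped rate parameters for a scheme and isoform
#'
#' Convenience loader for the fixtures under \code{inst/extdata/params}.
#'
#' @param scheme \code{"mmodel1"} or \code{"mmodel2"}.
#' @param isoform \code{"hERG1a"} or \code{"hERG1b"}.
#' @param resolve Resolve constrained transitions (default TRUE).
#' @return A \code{\link{herg_params}} object.
#' @export
herg_parameters <- function(scheme = c("mmodel1", "mmodel2"),
                            isoform = c("hERG1a", "hERG1b"),
                            resolve = TRUE) {
  scheme <- match.arg(scheme)
  isoform <- match.arg(isoform)
  path <- system.file("extdata", "params",
                      paste0(scheme, "_", isoform, ".tsv"),
                      package = "hergmarkov", mustWork = TRUE)
  load_parameters(path, resolve = resolve)
}

#' Export a current trace to delimited text
#'
#' Writes a two-column (\code{time_ms}, \code{current}) tab-separated file
#' with a commented header block carrying the recording conditions (protocol
#' name, sweep value, segment boundaries, temperature, potassium levels).
#' Values are written with 17 significant digits so a round trip through
#' \code{\link{import_trace}} is lossless to double precision.
#'
#' @param trace A \code{current_trace} (see \code{\link{simulate_sweeps}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attributes(trace)
  writeLines(c(
    "# hergmarkov current trace",
    paste0("# protocol: ", meta$protocol %||% "unknown"),
    paste0("# sweep_value: ", format(meta$sweep_value %||% NA, digits = 17)),
    paste0("# segment_starts_ms: ",
           paste(format(meta$segment_starts %||% 0, digits = 17), collapse = ",")),
    paste0("# segment_voltages_mV: ",
           paste(format(meta$segment_voltages %||% NA, digits = 17), collapse = ",")),
    paste0("# measurement_segment: ", format(meta$measurement_segment %||% NA)),
    paste0("# EK_mV: ", format(meta$EK %||% NA, digits = 17)),
    paste0("# temperature_K: ", format(meta$temperature %||% NA, digits = 17)),
    paste0("# Ko_mM: ", format(meta$Ko %||% NA, digits = 17)),
    paste0("# isoform: ", meta$isoform %||% "unknown"),
    paste0("# scheme: ", meta$scheme %||% "unknown"),
    "time_ms\tcurrent"
  ), con)
  utils::write.table(
    data.frame(time_ms = format(trace$time, digits = 17, trim = TRUE),
               current = format(trace$current, digits = 17, trim = TRUE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a current trace written by \code{\link{export_trace}}
#'
#' @param path File path.
#' @return A \code{current_trace} object.
#' @export
import_trace <- function(path) {
  if (!file.exists(path)) stop("import_trace: no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("current trace", hdr[1])) {
    stop("import_trace: missing header block (line 1)")
  }
  body_start <- which(!grepl("^#", lines))[1]
  if (is.na(body_start) || !grepl("^time_ms\tcurrent", lines[body_start])) {
    stop("import_trace: missing 'time_ms\\tcurrent' column header (line ",
         body_start %||% length(lines), ")")
  }
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  tab <- utils::read.delim(path, comment.char = "#")
  if (ncol(tab) != 2L) stop("import_trace: expected 2 columns, got ", ncol(tab))
  if (any(diff(tab$time_ms) <= 0)) {
    stop("import_trace: time column not strictly increasing (row ",
         which(diff(tab$time_ms) <= 0)[1] + 1L, ")")
  }
  num_list <- function(key) {
    v <- get_field(key)
    if (is.na(v)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
  }
  structure(list(time = tab$time_ms, current = tab$current),
            class = "current_trace",
            protocol = get_field("protocol"),
            sweep_value = suppressWarnings(as.numeric(get_field("sweep_value"))),
            segment_starts = num_list("segment_starts_ms"),
            segment_voltages = num_list("segment_voltages_mV"),
            measurement_segment = suppressWarnings(as.integer(get_field("measurement_segment"))),
            EK = suppressWarnings(as.numeric(get_field("EK_mV"))),
            temperature = suppressWarnings(as.numeric(get_field("temperature_K"))),
            Ko = suppressWarnings(as.numeric(get_field("Ko_mM"))),
            isoform = get_field("isoform"),
            scheme = get_field("scheme"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
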
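#' Read a 3-pulse ESEEM trace from a two-column ASCII file
#'
#' The format is two whitespace- or comma-separated numeric columns (delay T
#' in ns, echo amplitude in arbitrary units), preceded by optional metadata
#' header lines of the form `# key: value` carrying `tau_ns`, `nu_MHz`,
#' `field_mT` and `label`.
#'
#' @param path file path.
#' @param dialect column separator: `"whitespace"` (default) or `"csv"`.
#' @return An [echo_trace()].
#' @export
load_trace <- function(path, dialect = c("whitespace", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  data_lines <- which(!is_meta & nzchar(trimws(lines)))
  if (length(data_lines) < 2)
    stop("trace file has fewer than 2 data rows: ", path, call. = FALSE)
  split_re <- if (dialect == "csv") "\\s*,\\s*" else "\\s+"
  vals <- lapply(data_lines, function(i) {
    parts <- strsplit(trimws(lines[i]), split_re)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop(sprintf("non-numeric trace row at line %d of %s", i, path),
           call. = FALSE)
    v[1:2]
  })
  m <- do.call(rbind, vals)
  T_ns <- m[, 1]
  if (any(diff(T_ns) <= 0))
    stop(sprintf("T column not strictly increasing (line %d of %s)",
                 data_lines[which(diff(T_ns) <= 0)[1] + 1], path),
         call. = FALSE)
  steps <- diff(T_ns)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop(sprintf("non-uniform T step at line %d of %s",
                 data_lines[which.max(abs(steps - stats::median(steps))) + 1],
                 path),
         call. = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  echo_trace(T_ns, m[, 2],
             tau = num_or_na(meta$tau_ns),
             nu = num_or_na(meta$nu_MHz),
             field = num_or_na(meta$field_mT),
             label = if (is.null(meta$label)) NA_character_ else meta$label,
             meta = meta)
}

#' Write an ESEEM trace as two-column ASCII
#'
#' Inverse of [load_trace()]: metadata as `# key: value` header lines, then
#' `T amplitude` rows at full double precision.
#'
#' @param trace an [echo_trace()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "echo_trace"))
  hdr <- c(
    if (!is.na(trace$tau)) sprintf("# tau_ns: %.17g", trace$tau),
    if (!is.na(trace$nu)) sprintf("# nu_MHz: %.17g", trace$nu),
    if (!is.na(trace$field)) sprintf("# field_mT: %.17g", trace$field),
    if (!is.na(trace$label)) sprintf("# label: %s", trace$label))
  rows <- sprintf("%.17g %.17g", trace$T, trace$amplitude)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Load all traces from a directory
#'
#' @param dir directory containing `.dat` / `.txt` / `.csv` trace files.
#' @param pattern filename regular expression.
#' @return A named list of [echo_trace()] objects, keyed by label (falling
#'   back to the file name).
#' @export
load_trace_dir <- function(dir, pattern = "\\.(dat|txt|csv)$") {
  if (!dir.exists(dir)) stop("no such trace directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no trace files in ", dir, call. = FALSE)
  traces <- lapply(files, function(f)
    load_trace(f, dialect = if (grepl("\\.csv$", f)) "csv" else "whitespace"))
  nm <- vapply(seq_along(traces), function(i) {
    lb <- traces[[i]]$label
    if (is.na(lb)) sub("\\.[^.]+$", "", basename(files[i])) else lb
  }, character(1))
  names(traces) <- nm
  traces
}
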
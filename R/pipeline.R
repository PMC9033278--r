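#' Run the configured analysis arms and write all artifacts
#'
#' Config-driven orchestration of the three analysis arms. The config is a
#' YAML file or an equivalent nested list with an `output_dir`, an optional
#' `seed`, and one section per enabled arm:
#'
#' \describe{
#'   \item{eseem}{`traces` (directory of two-column ASCII traces for the
#'     reference state), optional `traces_b` (second state), `method`
#'     (`fit`/`ft`), `reference` (`max` or a label).}
#'   \item{hdx}{`a` and `b` (uptake CSVs), `alpha`, optional `consensus`.}
#'   \item{md}{`structure` (PDB), optional `parameter_table` (CSV),
#'     `thickness` (logical), `helix_range` (+ optional `helix_chain`),
#'     `pore` (list: `z_min`, `z_max`, optional `step`).}
#' }
#'
#' Each arm runs independently; a failing arm is recorded in the manifest
#' with its error message while the other arms still complete. Outputs are
#' CSV/JSON files under `output_dir` plus `manifest.json` listing every
#' artifact with an MD5 checksum, the seed, and per-arm status. Runs are
#' deterministic for a fixed config and seed.
#'
#' @param config path to a YAML config, or a list.
#' @return The manifest list (invisibly). Attribute `any_failed` reports
#'   whether an arm errored.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  arms <- intersect(c("eseem", "hdx", "md"), names(config))
  if (length(arms) == 0)
    stop("config enables no analysis arm", call. = FALSE)
  if (is.null(config$output_dir))
    stop("config needs an output_dir", call. = FALSE)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  set.seed(seed)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    writeLines(msg, log_con)
    message(msg)
  }

  manifest <- list(seed = seed, arms = list(), files = list())
  record <- function(path) {
    manifest$files[[length(manifest$files) + 1]] <<- list(
      path = sub(paste0("^", out_dir, "/?"), "", path),
      md5 = unname(tools::md5sum(path)))
    path
  }
  run_arm <- function(name, fun) {
    logmsg("arm %s: start", name)
    res <- tryCatch(list(status = "ok", files = fun()),
                    error = function(e)
                      list(status = "error", message = conditionMessage(e)))
    if (res$status == "ok") {
      for (f in res$files) record(f)
      logmsg("arm %s: ok (%d artifact(s))", name, length(res$files))
    } else {
      logmsg("arm %s: ERROR %s", name, res$message)
    }
    manifest$arms[[name]] <<- res[setdiff(names(res), "files")]
  }

  if ("eseem" %in% arms) run_arm("eseem", function() {
    cf <- config$eseem
    method <- if (is.null(cf$method)) "fit" else cf$method
    reference <- if (is.null(cf$reference)) "max" else cf$reference
    traces <- load_trace_dir(cf$traces)
    panel <- analyze_panel(traces, method = method, reference = reference)
    f1 <- file.path(out_dir, "eseem_panel.csv")
    write.csv(as.data.frame(panel), f1, row.names = FALSE, quote = FALSE)
    files <- f1
    if (!is.null(cf$traces_b)) {
      panel_b <- analyze_panel(load_trace_dir(cf$traces_b), method = method,
                               reference = reference)
      f2 <- file.path(out_dir, "eseem_panel_b.csv")
      write.csv(as.data.frame(panel_b), f2, row.names = FALSE, quote = FALSE)
      cmp <- compare_states(panel, panel_b)
      f3 <- file.path(out_dir, "eseem_comparison.csv")
      write.csv(cmp, f3, row.names = FALSE, quote = FALSE)
      files <- c(files, f2, f3)
    }
    files
  })

  if ("hdx" %in% arms) run_arm("hdx", function() {
    cf <- config$hdx
    alpha <- if (is.null(cf$alpha)) 0.01 else cf$alpha
    consensus <- if (is.null(cf$consensus)) "strict" else cf$consensus
    ta <- load_uptake_table(cf$a)
    tb <- load_uptake_table(cf$b)
    dr <- differential_uptake(ta, tb, alpha = alpha)
    f1 <- file.path(out_dir, "hdx_differential.csv")
    write.csv(as.data.frame(dr), f1, row.names = FALSE, quote = FALSE)
    mr <- map_regions(dr, consensus = consensus)
    f2 <- file.path(out_dir, "hdx_regions.csv")
    write.csv(mr$regions, f2, row.names = FALSE, quote = FALSE)
    f3 <- file.path(out_dir, "hdx_residues.csv")
    write.csv(mr$residues, f3, row.names = FALSE, quote = FALSE)
    f4 <- file.path(out_dir, "hdx_woods.json")
    jsonlite::write_json(list(alpha = alpha,
                              threshold = attr(dr, "threshold"),
                              segments = mr$woods),
                         f4, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    c(f1, f2, f3, f4)
  })

  if ("md" %in% arms) run_arm("md", function() {
    cf <- config$md
    sys <- load_system(cf$structure, parameter_table = cf$parameter_table)
    files <- character(0)
    summary <- list()
    if (isTRUE(cf$thickness)) {
      th <- membrane_thickness(sys)
      summary$thickness_nm <- th
      f <- file.path(out_dir, "md_thickness.csv")
      write.csv(data.frame(frame = seq_along(th), thickness_nm = th), f,
                row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    if (!is.null(cf$helix_range)) {
      tl <- helix_tilt(sys, unlist(cf$helix_range), chain = cf$helix_chain)
      summary$helix_tilt_deg <- tl
      f <- file.path(out_dir, "md_helix_tilt.csv")
      write.csv(data.frame(frame = seq_along(tl), tilt_deg = tl), f,
                row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    if (!is.null(cf$pore)) {
      pp <- pore_profile(sys,
                         z_range = c(cf$pore$z_min, cf$pore$z_max),
                         step = if (is.null(cf$pore$step)) 0.25
                                else cf$pore$step)
      summary$pore_min_radius <- min(pp$radius)
      f <- file.path(out_dir, "md_pore_profile.csv")
      write.csv(as.data.frame(pp), f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "md_summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    c(files, f)
  })

  manifest$any_failed <- any(vapply(manifest$arms, function(a)
    a$status == "error", logical(1)))
  record(log_path)
  jsonlite::write_json(manifest[c("seed", "arms", "files", "any_failed")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(invisible(manifest), any_failed = manifest$any_failed)
}

#' Merge per-arm artifacts into a per-residue state report
#'
#' Joins the single-residue ESEEM classification and the residue-level HDX
#' classification on residue number (parsed from the ESEEM labels, e.g.
#' `V71`), attaches the MD summary, and flags residues where the two
#' experimental arms disagree in sign (one protected, the other
#' deprotected) — conflicts are reported, never resolved. Residues absent
#' from every arm are not invented.
#'
#' @param manifest path to a pipeline `manifest.json`, or the manifest
#'   list returned by [run_pipeline()] (with an `output_dir` attribute or
#'   alongside the artifacts).
#' @param output_dir directory holding the artifacts; defaults to the
#'   manifest's directory.
#' @param write write `state_report.json` and `state_report.csv` into
#'   `output_dir`.
#' @return A `state_report` list: `residues` (data frame), `md_summary`,
#'   `sources`.
#' @export
build_state_report <- function(manifest, output_dir = NULL, write = TRUE) {
  if (is.character(manifest)) {
    if (is.null(output_dir)) output_dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (is.null(output_dir))
    stop("output_dir must be given when passing a manifest list",
         call. = FALSE)
  paths <- if (is.data.frame(manifest$files)) manifest$files$path
           else vapply(manifest$files, `[[`, character(1), "path")
  if (length(paths) == 0) stop("manifest lists no artifacts", call. = FALSE)
  have <- function(f) f %in% paths && file.exists(file.path(output_dir, f))

  eseem <- NULL
  if (have("eseem_comparison.csv")) {
    ec <- read.csv(file.path(output_dir, "eseem_comparison.csv"),
                   stringsAsFactors = FALSE)
    res_no <- suppressWarnings(as.integer(gsub("[^0-9]", "", ec$label)))
    eseem <- data.frame(residue = res_no, eseem_label = ec$label,
                        eseem_delta_pct = ec$delta_pct,
                        eseem_class = ec$class, stringsAsFactors = FALSE)
    eseem <- eseem[!is.na(eseem$residue), ]
  }
  hdx <- NULL
  if (have("hdx_residues.csv")) {
    hr <- read.csv(file.path(output_dir, "hdx_residues.csv"),
                   stringsAsFactors = FALSE)
    hdx <- data.frame(residue = hr$residue, hdx_class = hr$class,
                      stringsAsFactors = FALSE)
  }
  md_summary <- NULL
  if (have("md_summary.json"))
    md_summary <- jsonlite::read_json(file.path(output_dir, "md_summary.json"),
                                      simplifyVector = TRUE)
  if (is.null(eseem) && is.null(hdx) && is.null(md_summary))
    stop("no arm artifacts found in manifest", call. = FALSE)

  residues <- NULL
  if (!is.null(eseem) && !is.null(hdx)) {
    residues <- merge(hdx, eseem, by = "residue", all = TRUE)
  } else if (!is.null(eseem)) {
    residues <- eseem
  } else if (!is.null(hdx)) {
    residues <- hdx
  }
  if (!is.null(residues) && all(c("eseem_class", "hdx_class") %in%
                                names(residues))) {
    sig <- c("protected", "deprotected")
    residues$conflict <- !is.na(residues$eseem_class) &
      !is.na(residues$hdx_class) &
      residues$eseem_class %in% sig & residues$hdx_class %in% sig &
      residues$eseem_class != residues$hdx_class
    agree <- !is.na(residues$eseem_class) & !is.na(residues$hdx_class) &
      residues$eseem_class %in% sig &
      residues$eseem_class == residues$hdx_class
    residues$concordant <- ifelse(agree,
                                  paste0("concordant-", residues$eseem_class),
                                  NA_character_)
  }
  report <- structure(list(residues = residues, md_summary = md_summary,
                           sources = paths),
                      class = "state_report")
  if (write) {
    jsonlite::write_json(
      list(residues = residues, md_summary = md_summary, sources = paths),
      file.path(output_dir, "state_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(residues))
      write.csv(residues, file.path(output_dir, "state_report.csv"),
                row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.state_report <- function(x, ...) {
  n <- if (is.null(x$residues)) 0 else nrow(x$residues)
  cat(sprintf("<state_report> %d residue row(s); MD summary: %s\n", n,
              if (is.null(x$md_summary)) "none"
              else paste(names(x$md_summary), collapse = ", ")))
  invisible(x)
}
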
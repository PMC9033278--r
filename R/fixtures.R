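#' Write a bundle of synthetic objects as plain-text fixtures
#'
#' Traces become two-column ASCII files, uptake tables CSV, molecular
#' systems (multi-model) PDB. A JSON manifest recording every file, its
#' MD5 checksum and the ground-truth parameters/seeds is written alongside,
#' so a fixture set can be regenerated and verified byte-for-byte.
#'
#' @param bundle named list with any of: `traces` (list of [echo_trace()]),
#'   `uptake` (named list of `peptide_uptake_table`s), `systems` (named
#'   list of `molecular_system`s), `params` (free-form ground truth).
#' @param out_dir output directory (created if needed).
#' @return The manifest (invisibly); also written as `manifest.json`.
#' @export
write_fixtures <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  if (!is.null(bundle$traces)) {
    tdir <- file.path(out_dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(bundle$traces)) {
      tr <- bundle$traces[[i]]
      nm <- if (!is.null(names(bundle$traces)) &&
                nzchar(names(bundle$traces)[i])) names(bundle$traces)[i]
            else if (!is.na(tr$label)) tr$label else sprintf("trace%03d", i)
      f <- file.path(tdir, paste0(nm, ".dat"))
      write_trace(tr, f)
      files <- c(files, f)
    }
  }
  if (!is.null(bundle$uptake)) {
    hdir <- file.path(out_dir, "hdx")
    dir.create(hdir, showWarnings = FALSE)
    for (nm in names(bundle$uptake)) {
      f <- file.path(hdir, paste0(nm, ".csv"))
      write_uptake_table(bundle$uptake[[nm]], f)
      files <- c(files, f)
    }
  }
  if (!is.null(bundle$systems)) {
    sdir <- file.path(out_dir, "structures")
    dir.create(sdir, showWarnings = FALSE)
    for (nm in names(bundle$systems)) {
      f <- file.path(sdir, paste0(nm, ".pdb"))
      write_system_pdb(bundle$systems[[nm]], f)
      files <- c(files, f)
    }
  }
  manifest <- list(
    files = lapply(files, function(f)
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))),
    params = bundle$params,
    seeds = bundle$seeds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
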
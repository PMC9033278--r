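#' Load a peptide-level deuterium uptake table
#'
#' Reads a CSV with columns `peptide`, `start`, `end`, `state`,
#' `exposure_min`, `replicate`, `uptake_Da` (residue numbering 1-based
#' inclusive), validates it, and sorts by (start, end, exposure, replicate).
#'
#' @param path CSV file path.
#' @param protein_length protein length; defaults to the maximum peptide end.
#' @return A `peptide_uptake_table` data frame with attribute
#'   `protein_length`.
#' @export
load_uptake_table <- function(path, protein_length = NULL) {
  if (!file.exists(path)) stop("no such uptake table: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("peptide", "start", "end", "state", "exposure_min",
                "replicate", "uptake_Da")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("uptake table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_uptake_table(tab, protein_length)
}

#' Validate and finalise an uptake table
#'
#' @param tab data frame with the uptake-table columns.
#' @param protein_length protein length; defaults to `max(end)`.
#' @return A sorted `peptide_uptake_table`.
#' @export
validate_uptake_table <- function(tab, protein_length = NULL) {
  if (nrow(tab) == 0) stop("uptake table is empty", call. = FALSE)
  if (any(tab$start < 1))
    stop("peptide start < 1: residue numbering is 1-based", call. = FALSE)
  if (any(tab$end < tab$start))
    stop("peptide end before start", call. = FALSE)
  if (is.null(protein_length)) protein_length <- max(tab$end)
  if (any(tab$end > protein_length))
    stop("peptide extends beyond protein length", call. = FALSE)
  if (any(!is.finite(tab$uptake_Da)) || any(tab$uptake_Da < 0))
    stop("uptake values must be finite and >= 0", call. = FALSE)
  key <- paste(tab$start, tab$end, tab$peptide, tab$state, tab$exposure_min,
               tab$replicate)
  if (anyDuplicated(key))
    stop("duplicate replicate IDs for the same peptide/state/exposure",
         call. = FALSE)
  tab <- tab[order(tab$start, tab$end, tab$exposure_min, tab$replicate), ]
  rownames(tab) <- NULL
  structure(tab, class = c("peptide_uptake_table", "data.frame"),
            protein_length = as.integer(protein_length))
}

#' Write an uptake table as CSV
#' @param tab a `peptide_uptake_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_uptake_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peptide coverage statistics
#'
#' A residue counts as covered when at least one peptide spans it;
#' redundancy is the mean per-residue depth of coverage over the stated
#' range (uncovered residues count as depth zero).
#'
#' @param table a `peptide_uptake_table`.
#' @param residue_range length-2 vector, 1-based inclusive.
#' @return A `coverage_stats` list: `depth` (named integer vector),
#'   `coverage_percent`, `redundancy`, `uncovered` (residue numbers),
#'   `residue_range`.
#' @export
coverage_stats <- function(table, residue_range = c(1, attr(table, "protein_length"))) {
  if (nrow(table) == 0) stop("empty uptake table", call. = FALSE)
  protein_length <- attr(table, "protein_length")
  if (is.null(protein_length)) protein_length <- max(table$end)
  if (residue_range[1] < 1 || residue_range[2] > protein_length ||
      residue_range[2] < residue_range[1])
    stop("residue_range outside protein", call. = FALSE)
  peps <- unique(table[, c("start", "end")])
  res <- residue_range[1]:residue_range[2]
  depth <- vapply(res, function(r) sum(peps$start <= r & peps$end >= r),
                  integer(1))
  names(depth) <- res
  covered <- depth >= 1
  structure(list(depth = depth,
                 coverage_percent = 100 * mean(covered),
                 redundancy = mean(depth),
                 uncovered = res[!covered],
                 residue_range = residue_range),
            class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("<coverage_stats> residues %d-%d: %.1f%% covered (%d uncovered), redundancy %.2f\n",
              x$residue_range[1], x$residue_range[2], x$coverage_percent,
              length(x$uncovered), x$redundancy))
  invisible(x)
}

## per (start,end,peptide,exposure) replicate summary for one state
.uptake_summary <- function(tab) {
  key <- interaction(tab$start, tab$end, tab$peptide, tab$exposure_min,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(tab, key), function(d)
    data.frame(peptide = d$peptide[1], start = d$start[1], end = d$end[1],
               exposure_min = d$exposure_min[1], n = nrow(d),
               mean = mean(d$uptake_Da),
               var = if (nrow(d) > 1) var(d$uptake_Da) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Differential deuterium uptake between two states
#'
#' For every peptide present in both states, computes the per-timepoint
#' uptake difference `delta_t = mean_B(t) - mean_A(t)` and their sum over
#' the time course, then classifies each peptide against a single global
#' significance threshold at confidence level `1 - alpha` (99% by default):
#'
#' `threshold = t_crit(1 - alpha/2, df) * sqrt(sum_t (s2_A,t/n_A + s2_B,t/n_B))`
#'
#' with per-timepoint variances pooled across all peptides (a global
#' estimate of the replicate noise, as in Wood's-plot significance
#' testing) and `df` the per-peptide replicate degrees of freedom summed
#' over timepoints. `method = "hybrid"` additionally requires at least one
#' individually significant timepoint (per-peptide Welch test).
#'
#' Peptides observed in only one state are excluded from statistics and
#' listed in the `unmatched` attribute.
#'
#' @param table_a state-A `peptide_uptake_table` (reference).
#' @param table_b state-B table.
#' @param alpha significance level (0.01 gives the 99% CI threshold).
#' @param method `"summed"` (default) or `"hybrid"`.
#' @return A `differential_result` data frame (`peptide`, `start`, `end`,
#'   `summed_delta`, `threshold`, `class`) with attributes `alpha`,
#'   `threshold`, `deltas` (peptide x timepoint matrix), `timepoints`,
#'   `protein_length`, `unmatched`.
#' @export
differential_uptake <- function(table_a, table_b, alpha = 0.01,
                                method = c("summed", "hybrid")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  sa <- .uptake_summary(table_a)
  sb <- .uptake_summary(table_b)
  key_a <- paste(sa$start, sa$end, sa$peptide)
  key_b <- paste(sb$start, sb$end, sb$peptide)
  shared <- intersect(unique(key_a), unique(key_b))
  unmatched <- c(setdiff(unique(key_a), shared), setdiff(unique(key_b), shared))
  if (length(shared) == 0)
    stop("no peptides shared between the two states; unmatched: ",
         paste(head(unmatched, 10), collapse = "; "), call. = FALSE)
  if (length(unmatched) > 0)
    warning(length(unmatched),
            " peptide(s) present in only one state excluded from statistics")

  tps <- sort(unique(c(sa$exposure_min, sb$exposure_min)))
  common_tps <- intersect(unique(sa$exposure_min), unique(sb$exposure_min))
  if (!setequal(tps, common_tps))
    stop("exposure time courses differ between states", call. = FALSE)

  ## pooled per-timepoint replicate variances across all shared peptides
  pool_var <- function(s) {
    vapply(tps, function(tp) {
      v <- s$var[s$exposure_min == tp & paste(s$start, s$end, s$peptide) %in% shared]
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  va <- pool_var(sa)
  vb <- pool_var(sb)
  na <- vapply(tps, function(tp) round(mean(sa$n[sa$exposure_min == tp])),
               numeric(1))
  nb <- vapply(tps, function(tp) round(mean(sb$n[sb$exposure_min == tp])),
               numeric(1))
  if (any(na < 2) || any(nb < 2))
    stop("at least 2 replicates per state/timepoint are required", call. = FALSE)
  se_sum <- sqrt(sum(va / na + vb / nb))
  df <- sum(na - 1) + sum(nb - 1)
  threshold <- qt(1 - alpha / 2, df) * se_sum

  rows <- lapply(shared, function(k) {
    da <- sa[key_a == k, ]
    db <- sb[key_b == k, ]
    ord_a <- match(tps, da$exposure_min)
    ord_b <- match(tps, db$exposure_min)
    deltas <- db$mean[ord_b] - da$mean[ord_a]
    hybrid_ok <- TRUE
    if (method == "hybrid") {
      per_tp <- abs(deltas) > qt(1 - alpha / 2, pmax(da$n[ord_a] + db$n[ord_b] - 2, 1)) *
        sqrt(da$var[ord_a] / da$n[ord_a] + db$var[ord_b] / db$n[ord_b])
      hybrid_ok <- any(per_tp, na.rm = TRUE)
    }
    list(peptide = da$peptide[1], start = da$start[1], end = da$end[1],
         deltas = deltas, summed = sum(deltas), hybrid_ok = hybrid_ok)
  })
  summed <- vapply(rows, `[[`, numeric(1), "summed")
  sig <- abs(summed) > threshold &
    vapply(rows, `[[`, logical(1), "hybrid_ok")
  cls <- ifelse(!sig, "not_significant",
                ifelse(summed > 0, "deprotected", "protected"))
  out <- data.frame(
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    start = vapply(rows, function(r) r$start, numeric(1)),
    end = vapply(rows, function(r) r$end, numeric(1)),
    summed_delta = summed, threshold = threshold, class = cls,
    stringsAsFactors = FALSE)
  ord <- order(out$start, out$end)
  out <- out[ord, ]
  rownames(out) <- NULL
  deltas <- do.call(rbind, lapply(rows, `[[`, "deltas"))[ord, , drop = FALSE]
  colnames(deltas) <- as.character(tps)
  pl <- max(attr(table_a, "protein_length"), attr(table_b, "protein_length"),
            out$end)
  structure(out, class = c("differential_result", "data.frame"),
            alpha = alpha, threshold = threshold, deltas = deltas,
            timepoints = tps, df = df, protein_length = as.integer(pl),
            unmatched = unmatched, method = method)
}

#' Per-exposure uptake curve of one peptide
#'
#' @param table a `peptide_uptake_table`.
#' @param peptide peptide sequence, or `c(start, end)`.
#' @return Data frame of `state`, `exposure_min`, `mean`, `sd`, `n`.
#' @export
uptake_curves <- function(table, peptide) {
  if (is.numeric(peptide) && length(peptide) == 2) {
    sel <- table$start == peptide[1] & table$end == peptide[2]
  } else {
    sel <- table$peptide == peptide
  }
  if (!any(sel))
    stop("peptide not found in table: ", paste(peptide, collapse = "-"),
         call. = FALSE)
  d <- table[sel, ]
  key <- interaction(d$state, d$exposure_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g)
    data.frame(state = g$state[1], exposure_min = g$exposure_min[1],
               mean = mean(g$uptake_Da), sd = sd(g$uptake_Da), n = nrow(g),
               stringsAsFactors = FALSE)))
  out <- out[order(out$state, out$exposure_min), ]
  rownames(out) <- NULL
  out
}

#' Map peptide-level classifications onto residues and regions
#'
#' Projects the differential classification onto the sequence. With the
#' default `consensus = "strict"` a residue takes a significant class only
#' when *every* peptide covering it is significant with that same sign —
#' the conservative rule: any covering peptide that failed significance, or
#' a sign contradiction, vetoes the call. `consensus = "majority"` instead
#' takes the majority class over the covering significant peptides (ties
#' become `not_significant`). Contiguous runs of classified residues are
#' reported as regions, and the per-peptide summed differences are returned
#' as Wood's-plot segments.
#'
#' @param result a `differential_result`.
#' @param consensus `"strict"` (default) or `"majority"`.
#' @return A list: `residues` (data frame `residue`, `class`, `n_peptides`,
#'   `n_significant`), `regions` (data frame `start`, `end`, `class`),
#'   `woods` (data frame `start`, `end`, `summed_delta`, `threshold`,
#'   `class`).
#' @export
map_regions <- function(result, consensus = c("strict", "majority")) {
  consensus <- match.arg(consensus)
  pl <- attr(result, "protein_length")
  n_pep <- integer(pl)
  n_sig <- integer(pl)
  cls <- rep("not_significant", pl)
  if (nrow(result) > 0) {
    for (r in seq_len(pl)) {
      cover <- result$start <= r & result$end >= r
      n_pep[r] <- sum(cover)
      if (n_pep[r] == 0) {
        cls[r] <- "uncovered"
        next
      }
      cc <- result$class[cover]
      n_sig[r] <- sum(cc != "not_significant")
      if (consensus == "strict") {
        u <- unique(cc)
        if (length(u) == 1 && u != "not_significant") cls[r] <- u
      } else {
        sigc <- cc[cc != "not_significant"]
        if (length(sigc) > 0) {
          votes <- table(sigc)
          top <- names(votes)[votes == max(votes)]
          if (length(top) == 1) cls[r] <- top
        }
      }
    }
  } else {
    cls <- rep("uncovered", pl)
  }
  residues <- data.frame(residue = seq_len(pl), class = cls,
                         n_peptides = n_pep, n_significant = n_sig,
                         stringsAsFactors = FALSE)
  sig_res <- cls %in% c("deprotected", "protected")
  regions <- data.frame(start = integer(0), end = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
  if (any(sig_res)) {
    r <- rle(cls)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values %in% c("deprotected", "protected")
    regions <- data.frame(start = starts[keep], end = ends[keep],
                          class = r$values[keep], stringsAsFactors = FALSE)
  }
  woods <- result[result$class != "not_significant",
                  c("start", "end", "summed_delta", "threshold", "class")]
  rownames(woods) <- NULL
  list(residues = residues, regions = regions, woods = woods)
}
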
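#' Parameters for a synthetic differential HDX-MS experiment
#'
#' Describes a two-state peptide-level hydrogen-deuterium exchange dataset:
#' a protein of `sequence_length` residues digested into a peptide map, a
#' labelling time course, replicate structure, a uniform baseline protection
#' factor, and a set of regions whose protection is reduced in the second
#' state (deprotection, i.e. increased uptake), each by a fold change.
#'
#' The default peptide map tiles the protein with 11-residue peptides every
#' 3 residues (redundancy about 3.7, typical of a well-digested membrane
#' protein), and the default time course is 0.5, 1, 2, 10 and 60 min with
#' three replicates.
#'
#' @param sequence_length protein length, residues.
#' @param peptide_set data frame or two-column matrix of 1-based inclusive
#'   peptide boundaries (`start`, `end`); `NULL` for the default tiling.
#' @param timepoints labelling times, minutes, strictly increasing.
#' @param n_replicates replicate measurements per peptide/timepoint/state.
#' @param base_protection uniform residue protection factor of state A.
#' @param deprotected_regions list of `c(start, end, fold_change)` vectors;
#'   in state B the protection of those residues is divided by
#'   `fold_change`.
#' @param intrinsic_rate intrinsic amide exchange rate, per minute
#'   (residue-independent; sequence-dependent rates are out of scope).
#' @param noise_sd replicate measurement noise, Da.
#' @param sequence optional protein sequence (one-letter); generated without
#'   prolines by default. The first residue of each peptide and prolines do
#'   not exchange.
#' @param seed integer seed.
#' @return An object of class `hdx_sim_params`.
#' @export
hdx_sim_params <- function(sequence_length = 125, peptide_set = NULL,
                           timepoints = c(0.5, 1, 2, 10, 60),
                           n_replicates = 3, base_protection = 100,
                           deprotected_regions = list(),
                           intrinsic_rate = 10, noise_sd = 0.05,
                           sequence = NULL, seed = NULL) {
  if (is.null(peptide_set))
    peptide_set <- default_peptide_map(sequence_length)
  peptide_set <- as.data.frame(peptide_set)
  names(peptide_set)[1:2] <- c("start", "end")
  if (any(peptide_set$start < 1) || any(peptide_set$end > sequence_length) ||
      any(peptide_set$end < peptide_set$start))
    stop("peptides must lie within [1, sequence_length]", call. = FALSE)
  if (any(diff(timepoints) <= 0) || any(timepoints <= 0))
    stop("timepoints must be positive and strictly increasing", call. = FALSE)
  if (n_replicates < 1) stop("need at least 1 replicate", call. = FALSE)
  if (base_protection <= 0 || intrinsic_rate <= 0)
    stop("protection and intrinsic rate must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (r in deprotected_regions) {
    if (length(r) != 3 || r[1] < 1 || r[2] > sequence_length || r[2] < r[1] ||
        r[3] <= 0)
      stop("each deprotected region must be c(start, end, fold_change > 0)",
           call. = FALSE)
  }
  ## overlapping regions with contradictory fold changes are ambiguous
  if (length(deprotected_regions) > 1) {
    fold_at <- rep(NA_real_, sequence_length)
    for (r in deprotected_regions) {
      idx <- r[1]:r[2]
      clash <- !is.na(fold_at[idx]) & fold_at[idx] != r[3]
      if (any(clash))
        stop("overlapping deprotected regions with contradictory fold changes",
             call. = FALSE)
      fold_at[idx] <- r[3]
    }
  }
  if (is.null(sequence)) {
    ## deterministic proline-free sequence; exchange bookkeeping stays exact
    aa <- c("A", "S", "T", "V", "L", "I", "F", "Y", "W", "N", "Q", "D", "E",
            "K", "R", "G", "M", "H")
    sequence <- paste(rep(aa, length.out = sequence_length), collapse = "")
  }
  if (nchar(sequence) != sequence_length)
    stop("`sequence` length must equal `sequence_length`", call. = FALSE)
  structure(list(sequence_length = as.integer(sequence_length),
                 peptide_set = peptide_set, timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 base_protection = base_protection,
                 deprotected_regions = deprotected_regions,
                 intrinsic_rate = intrinsic_rate, noise_sd = noise_sd,
                 sequence = sequence, seed = seed),
            class = "hdx_sim_params")
}

#' Default peptide tiling of a protein
#'
#' @param sequence_length protein length, residues.
#' @param length peptide length, residues.
#' @param stride offset between consecutive peptide starts, residues.
#' @return Data frame of `start`, `end` (1-based inclusive); the final
#'   peptide is anchored to the C terminus so the whole protein is covered.
#' @export
tile_peptides <- function(sequence_length, length = 11, stride = 3) {
  starts <- seq(1, max(1, sequence_length - length + 1), by = stride)
  if (starts[base::length(starts)] + length - 1 < sequence_length)
    starts <- c(starts, sequence_length - length + 1)
  data.frame(start = starts,
             end = pmin(starts + length - 1, sequence_length))
}

#' Default synthetic peptide map
#'
#' Union of a long tiling (11-mers every 3 residues) and a dense short
#' tiling (4-mers every residue). The short fragments mimic the small
#' pepsin products that give real HDX maps their redundancy; they are what
#' allows region boundaries to be localised to within a couple of residues
#' when peptide classifications are projected back onto the sequence.
#'
#' @param sequence_length protein length, residues.
#' @return Data frame of `start`, `end`, sorted, without duplicates.
#' @export
default_peptide_map <- function(sequence_length) {
  m <- rbind(tile_peptides(sequence_length, length = 11, stride = 3),
             tile_peptides(sequence_length, length = 4, stride = 1))
  m <- unique(m)
  m <- m[order(m$start, m$end), ]
  rownames(m) <- NULL
  m
}

#' Closed-form expected deuterium uptake of a peptide
#'
#' Residue-level kinetics `1 - exp(-k_int t / P)` summed over the
#' exchangeable residues of the peptide.
#'
#' @param n_exchangeable number of exchanging amides.
#' @param protection protection factor `P` (scalar or per-residue vector of
#'   length `n_exchangeable`).
#' @param rate intrinsic exchange rate, per minute.
#' @param t labelling time, minutes (vectorised).
#' @return Expected uptake, Da.
#' @export
expected_uptake <- function(n_exchangeable, protection, rate, t) {
  if (length(protection) == 1) protection <- rep(protection, n_exchangeable)
  stopifnot(length(protection) == n_exchangeable)
  vapply(t, function(ti) sum(1 - exp(-rate * ti / protection)), numeric(1))
}

## exchangeable residue positions of a peptide: everything after the first
## residue, minus prolines
.exchangeable_positions <- function(start, end, sequence) {
  if (end <= start) return(integer(0))
  pos <- (start + 1):end
  pos[substring(sequence, pos, pos) != "P"]
}

#' Simulate a matched pair of peptide uptake tables
#'
#' State A uses the uniform baseline protection; state B divides the
#' protection of residues inside the deprotected regions by the region's
#' fold change, so those peptides take up more deuterium. Replicate noise is
#' i.i.d. Gaussian (truncated at zero uptake).
#'
#' @param params an [hdx_sim_params()] object.
#' @param states labels of the two states in the output tables.
#' @return A list of two `peptide_uptake_table` data frames, `A` and `B`,
#'   with columns `peptide`, `start`, `end`, `state`, `exposure_min`,
#'   `replicate`, `uptake_Da` and attribute `protein_length`.
#' @export
simulate_hdx_dataset <- function(params, states = c("A", "B")) {
  stopifnot(inherits(params, "hdx_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(as.integer(p$seed %% .Machine$integer.max))
  prot_A <- rep(p$base_protection, p$sequence_length)
  prot_B <- prot_A
  for (r in p$deprotected_regions)
    prot_B[r[1]:r[2]] <- p$base_protection / r[3]

  one_state <- function(prot, state_label) {
    rows <- lapply(seq_len(nrow(p$peptide_set)), function(i) {
      s <- p$peptide_set$start[i]
      e <- p$peptide_set$end[i]
      ex <- .exchangeable_positions(s, e, p$sequence)
      mu <- vapply(p$timepoints, function(ti)
        sum(1 - exp(-p$intrinsic_rate * ti / prot[ex])), numeric(1))
      data.frame(
        peptide = substring(p$sequence, s, e),
        start = s, end = e, state = state_label,
        exposure_min = rep(p$timepoints, each = p$n_replicates),
        replicate = rep(seq_len(p$n_replicates), length(p$timepoints)),
        uptake_Da = pmax(0, rep(mu, each = p$n_replicates) +
                           rnorm(length(mu) * p$n_replicates, 0, p$noise_sd)),
        stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    structure(tab, class = c("peptide_uptake_table", "data.frame"),
              protein_length = p$sequence_length)
  }
  ## draw state A fully before state B so each state's noise stream is
  ## reproducible independent of the other's region specification
  list(A = one_state(prot_A, states[1]), B = one_state(prot_B, states[2]))
}
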
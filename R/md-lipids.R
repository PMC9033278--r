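#' Per-residue lipid contact counts
#'
#' A contact is any heavy-atom pair (one protein atom, one lipid atom)
#' within the cutoff; pairs are counted per protein residue and per frame,
#' then averaged over frames.
#'
#' @param system a `molecular_system`.
#' @param protein_selection,lipid_selection atom index vectors (e.g. from
#'   [select_atoms()]); hydrogens are dropped automatically.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param frames frame numbers (default all).
#' @return A `contact_map` data frame: `resid`, `chain`, `mean_contacts`.
#' @export
lipid_contacts <- function(system, protein_selection, lipid_selection,
                           cutoff = 4.0, frames = NULL) {
  a <- system$atoms
  heavy <- !grepl("^H", a$name)
  prot <- intersect(protein_selection, which(heavy))
  lip <- intersect(lipid_selection, which(heavy))
  if (length(prot) == 0 || length(lip) == 0)
    stop("empty protein or lipid selection", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(system$frames)
  key <- paste(a$chain[prot], a$resid[prot])
  res_keys <- unique(key)
  counts <- matrix(0, length(res_keys), length(frames),
                   dimnames = list(res_keys, NULL))
  cut2 <- cutoff^2
  for (fi in seq_along(frames)) {
    xyz <- system$frames[[frames[fi]]]
    pm <- xyz[prot, , drop = FALSE]
    lm <- xyz[lip, , drop = FALSE]
    ## squared distances protein x lipid
    d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
    n_in <- rowSums(d2 <= cut2)
    counts[, fi] <- vapply(res_keys, function(k) sum(n_in[key == k]),
                           numeric(1))
  }
  mean_ct <- rowMeans(counts)
  parts <- strsplit(res_keys, " ")
  structure(data.frame(resid = as.integer(vapply(parts, `[`, character(1), 2)),
                       chain = vapply(parts, `[`, character(1), 1),
                       mean_contacts = mean_ct, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("contact_map", "data.frame"), cutoff = cutoff)
}

#' Relative difference of lipid contacts between two conditions
#'
#' `(C_t - C_r) / max(C_r, 1)` per residue, plus an alternative
#' normalisation by the maximum reference contact count. Residues with a
#' zero reference count are flagged (their relative difference is reported
#' against the floor of 1 contact).
#'
#' @param map_tension contact map of the perturbed condition.
#' @param map_ref contact map of the reference condition.
#' @return A `contact_map` data frame: `resid`, `chain`, `contacts_ref`,
#'   `contacts_tension`, `abs_diff`, `rel_diff`, `rel_diff_maxnorm`,
#'   `zero_reference`.
#' @export
contact_relative_difference <- function(map_tension, map_ref) {
  key_t <- paste(map_tension$chain, map_tension$resid)
  key_r <- paste(map_ref$chain, map_ref$resid)
  shared <- intersect(key_t, key_r)
  if (length(shared) == 0) stop("no shared residues", call. = FALSE)
  t_ <- map_tension[match(shared, key_t), ]
  r_ <- map_ref[match(shared, key_r), ]
  d <- t_$mean_contacts - r_$mean_contacts
  cmax <- max(r_$mean_contacts)
  structure(data.frame(resid = r_$resid, chain = r_$chain,
                       contacts_ref = r_$mean_contacts,
                       contacts_tension = t_$mean_contacts,
                       abs_diff = d,
                       rel_diff = d / pmax(r_$mean_contacts, 1),
                       rel_diff_maxnorm = if (cmax > 0) d / cmax else NA_real_,
                       zero_reference = r_$mean_contacts == 0,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("contact_map", "data.frame"))
}

#' Acyl-chain deuterium order parameters
#'
#' `S_CD = <(3 cos^2 theta - 1) / 2>` with theta the angle between each
#' C-H bond and the bilayer normal, averaged over hydrogens, lipids and
#' frames, reported per carbon index. `-0.5` corresponds to C-H bonds
#' perpendicular to the normal (all-trans chains along it), `0` to
#' isotropic orientations.
#'
#' @param system a `molecular_system` with explicit chain hydrogens.
#' @param chain_atom_map data frame `carbon`, `carbon_name`, `h_name` (one
#'   row per C-H bond); defaults to the toy-lipid naming `Ck`/`Hk1`,`Hk2`.
#' @param selection `"all"` or a vector of lipid residue ids (e.g. pocket
#'   vs bulk lipids).
#' @param lipid_resname lipid residue name.
#' @param normal bilayer normal.
#' @param frames frame numbers (default all).
#' @return An `order_parameters` data frame: `carbon`, `S_CD`, `n_samples`.
#' @export
order_parameters <- function(system, chain_atom_map = NULL, selection = "all",
                             lipid_resname = "LIP", normal = c(0, 0, 1),
                             frames = NULL) {
  a <- system$atoms
  if (is.null(chain_atom_map)) {
    cn <- unique(a$name[a$resname == lipid_resname & grepl("^C[0-9]+$", a$name)])
    if (length(cn) == 0)
      stop("no lipid chain carbons found for the default atom map",
           call. = FALSE)
    k <- as.integer(sub("^C", "", cn))
    chain_atom_map <- data.frame(
      carbon = rep(k, each = 2), carbon_name = rep(cn, each = 2),
      h_name = as.vector(rbind(sprintf("H%d1", k), sprintf("H%d2", k))),
      stringsAsFactors = FALSE)
  }
  lip_res <- unique(a$resid[a$resname == lipid_resname])
  if (!identical(selection, "all")) lip_res <- intersect(lip_res, selection)
  if (length(lip_res) == 0) stop("no lipids selected", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(system$frames)
  n <- normal / sqrt(sum(normal^2))

  carbons <- unique(chain_atom_map$carbon)
  out <- lapply(carbons, function(ci) {
    rowsmap <- chain_atom_map[chain_atom_map$carbon == ci, ]
    vals <- c()
    for (f in frames) {
      xyz <- system$frames[[f]]
      for (j in seq_len(nrow(rowsmap))) {
        ci_idx <- which(a$resname == lipid_resname & a$resid %in% lip_res &
                          a$name == rowsmap$carbon_name[j])
        hi_idx <- which(a$resname == lipid_resname & a$resid %in% lip_res &
                          a$name == rowsmap$h_name[j])
        if (length(hi_idx) == 0) next
        ord_c <- a$resid[ci_idx]
        ord_h <- a$resid[hi_idx]
        m <- match(ord_h, ord_c)
        ok <- !is.na(m)
        if (!any(ok)) next
        v <- xyz[hi_idx[ok], , drop = FALSE] - xyz[ci_idx[m[ok]], , drop = FALSE]
        ct <- (v %*% n) / sqrt(rowSums(v^2))
        vals <- c(vals, (3 * ct^2 - 1) / 2)
      }
    }
    if (length(vals) == 0) {
      warning("no hydrogens for carbon ", ci, "; omitted")
      return(NULL)
    }
    data.frame(carbon = ci, S_CD = mean(vals), n_samples = length(vals))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  structure(out[order(out$carbon), ],
            class = c("order_parameters", "data.frame"))
}
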
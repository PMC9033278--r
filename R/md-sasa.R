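#' Shrake-Rupley solvent-accessible surface area of a pocket
#'
#' Classic probe-rolling approximation: each atom's sphere is expanded by
#' the probe radius and sampled with a deterministic golden-spiral point
#' set; the accessible fraction (points not buried inside any neighbour's
#' expanded sphere) scales the expanded-sphere area. The total over the
#' pocket residues is returned per frame. All atoms of the system occlude,
#' so pocket burial by surrounding structure is counted.
#'
#' @param system a `molecular_system` with vdW radii.
#' @param pocket_residues residue numbers defining the pocket.
#' @param chain restrict the pocket to a chain (optional).
#' @param probe probe radius, Angstrom.
#' @param n_points sample points per atom.
#' @param frames frame numbers (default all).
#' @return Numeric vector of areas (Angstrom^2), one per frame.
#' @export
pocket_sasa <- function(system, pocket_residues, chain = NULL, probe = 1.4,
                        n_points = 960, frames = NULL) {
  if (length(pocket_residues) == 0)
    stop("empty pocket residue list", call. = FALSE)
  a <- system$atoms
  vdw <- a$vdw
  if (is.null(vdw)) vdw <- .default_vdw(a$name)
  vdw[is.na(vdw)] <- .default_vdw(a$name[is.na(vdw)])
  sel <- select_atoms(system, resid = pocket_residues, chain = chain)
  if (length(sel) == 0) stop("pocket selection matches no atoms", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(system$frames)
  pts <- .golden_spiral(n_points)
  vapply(frames, function(f) {
    xyz <- system$frames[[f]]
    total <- 0
    for (i in sel) {
      ri <- vdw[i] + probe
      cand <- which(abs(xyz[, 1] - xyz[i, 1]) < ri + max(vdw) + probe)
      cand <- setdiff(cand[
        rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2) <
          (ri + vdw[cand] + probe)^2], i)
      sphere <- sweep(pts * ri, 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in cand) {
        rj2 <- (vdw[j] + probe)^2
        acc <- acc & rowSums(sweep(sphere, 2, xyz[j, ])^2) > rj2
        if (!any(acc)) break
      }
      total <- total + 4 * pi * ri^2 * mean(acc)
    }
    total
  }, numeric(1))
}

## deterministic quasi-uniform points on the unit sphere
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
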
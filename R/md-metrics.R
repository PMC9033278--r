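## coordinates of a frame restricted to selected atom indices
.frame_coords <- function(system, frame = 1, selection = NULL) {
  xyz <- system$frames[[frame]]
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  xyz
}

#' Kabsch-superposed RMSD between two coordinate sets
#'
#' Optimal rigid-body superposition (rotation + translation) by the Kabsch
#' SVD construction, then root-mean-square deviation over the paired atoms.
#'
#' @param a,b n x 3 coordinate matrices, or `molecular_system`s (whose
#'   frame and selection are taken from `frame_a`/`frame_b` and
#'   `selection`).
#' @param selection atom indices used for both systems (optional).
#' @param frame_a,frame_b frame numbers when systems are given.
#' @return RMSD in Angstrom.
#' @export
rmsd_kabsch <- function(a, b, selection = NULL, frame_a = 1, frame_b = 1) {
  if (inherits(a, "molecular_system")) a <- .frame_coords(a, frame_a, selection)
  if (inherits(b, "molecular_system")) b <- .frame_coords(b, frame_b, selection)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in size", call. = FALSE)
  if (nrow(a) < 3) stop("need at least 3 atoms for superposition", call. = FALSE)
  pa <- sweep(a, 2, colMeans(a))
  pb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(pa, pb))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  pa_rot <- pa %*% t(rot)
  sqrt(mean(rowSums((pa_rot - pb)^2)))
}

#' Helix tilt relative to the membrane normal
#'
#' Fits the principal axis of the C-alpha trace of a residue range and
#' returns its angle to the normal, folded into [0, 90] degrees, per frame.
#'
#' @param system a `molecular_system`.
#' @param residue_range `c(first, last)` residue numbers.
#' @param chain chain identifier (optional).
#' @param normal membrane normal vector (default z).
#' @param frames frame numbers (default all).
#' @return Numeric vector of tilt angles, degrees, one per frame.
#' @export
helix_tilt <- function(system, residue_range, chain = NULL,
                       normal = c(0, 0, 1), frames = NULL) {
  sel <- select_atoms(system, name = "CA", chain = chain,
                      resid = residue_range[1]:residue_range[2])
  if (length(sel) == 0)
    stop("no C-alpha atoms in residue range", call. = FALSE)
  if (length(sel) < 6)
    stop("need at least 6 C-alpha atoms for an axis fit", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(system$frames)
  n <- normal / sqrt(sum(normal^2))
  vapply(frames, function(f) {
    xyz <- .frame_coords(system, f, sel)
    ax <- svd(sweep(xyz, 2, colMeans(xyz)))$v[, 1]
    acos(min(1, abs(sum(ax * n)))) * 180 / pi
  }, numeric(1))
}

#' Phosphate-to-phosphate membrane thickness
#'
#' Mean z of the upper-leaflet phosphates minus mean z of the lower
#' leaflet (leaflets split at the phosphate midplane), reported in nm per
#' frame.
#'
#' @param system a `molecular_system`.
#' @param phosphate_name atom name of the phosphate marker.
#' @param resname restrict to a lipid residue name (optional).
#' @param frames frame numbers (default all).
#' @return Numeric vector, nm, one value per frame.
#' @export
membrane_thickness <- function(system, phosphate_name = "P", resname = NULL,
                               frames = NULL) {
  sel <- select_atoms(system, name = phosphate_name, resname = resname)
  if (length(sel) < 2) stop("no phosphate atoms found", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(system$frames)
  vapply(frames, function(f) {
    z <- .frame_coords(system, f, sel)[, 3]
    mid <- mean(z)
    up <- z[z > mid]
    lo <- z[z <= mid]
    if (length(up) == 0 || length(lo) == 0)
      stop("all phosphates in one leaflet", call. = FALSE)
    (mean(up) - mean(lo)) / 10
  }, numeric(1))
}
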
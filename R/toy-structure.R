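#' Parameters for a toy membrane/pore/helix/water system
#'
#' Defines a fully synthetic molecular system with known geometric ground
#' truth: a phosphate bilayer of stated thickness carrying tilted all-trans
#' acyl pseudo-chains with explicit hydrogens, a channel pore lined with
#' spheres realising a cylinder, cone or hourglass free-radius profile, an
#' ideal alpha-helix at a stated tilt, and water oxygens filling the pore
#' axis. Thickness and box are nm (reported units); everything is stored in
#' Angstrom internally.
#'
#' @param bilayer_thickness phosphate-to-phosphate distance, nm.
#' @param n_lipids_per_leaflet lipid count per leaflet.
#' @param chain_tilt acyl-chain tilt from the membrane normal, degrees
#'   (0-90).
#' @param pore_shape `"cylinder"`, `"cone"` or `"hourglass"`.
#' @param pore_radius lining-sphere centreline radius, Angstrom: a scalar
#'   for a cylinder, `c(min, max)` for cone (min at low z) and hourglass
#'   (min at the waist). The free pore radius is `pore_radius - lining_vdw`.
#' @param helix_tilt helix principal-axis tilt from the normal, degrees
#'   (0-90).
#' @param n_waters_in_pore water oxygens placed in the pore cylinder
#'   (spanning the whole box so bulk bins exist outside the membrane).
#' @param box simulation box, nm (length 3).
#' @param lining_vdw vdW radius of pore-lining spheres, Angstrom.
#' @param ring_spacing axial spacing of lining rings, Angstrom.
#' @param n_per_ring lining spheres per ring.
#' @param chain_length carbons per acyl pseudo-chain.
#' @param helix_residues residues in the ideal helix.
#' @param dewet_band optional `c(zmin, zmax)` (Angstrom) from which waters
#'   are excluded, emulating a vapor lock.
#' @param seed integer seed for water placement.
#' @return An object of class `toy_system_params`.
#' @export
toy_system_params <- function(bilayer_thickness = 3.8,
                              n_lipids_per_leaflet = 36, chain_tilt = 0,
                              pore_shape = c("cylinder", "cone", "hourglass"),
                              pore_radius = 5, helix_tilt = 0,
                              n_waters_in_pore = 200, box = c(12, 12, 12),
                              lining_vdw = 1.5, ring_spacing = 0.5,
                              n_per_ring = 36, chain_length = 8,
                              helix_residues = 30, dewet_band = NULL,
                              seed = NULL) {
  pore_shape <- match.arg(pore_shape)
  if (bilayer_thickness <= 0) stop("thickness must be positive", call. = FALSE)
  if (any(pore_radius <= 0)) stop("pore radius must be positive", call. = FALSE)
  if (chain_tilt < 0 || chain_tilt > 90 || helix_tilt < 0 || helix_tilt > 90)
    stop("tilts must lie in [0, 90] degrees", call. = FALSE)
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive lengths (nm)", call. = FALSE)
  if (pore_shape == "cylinder") {
    if (length(pore_radius) != 1)
      stop("cylinder takes a single pore radius", call. = FALSE)
  } else if (length(pore_radius) != 2 || pore_radius[1] >= pore_radius[2]) {
    stop("cone/hourglass take c(min, max) pore radii", call. = FALSE)
  }
  if (max(pore_radius) + lining_vdw >= min(box[1:2]) * 10 / 2)
    stop("pore wider than the box", call. = FALSE)
  if (bilayer_thickness >= box[3])
    stop("bilayer thicker than the box", call. = FALSE)
  structure(list(bilayer_thickness = bilayer_thickness,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 chain_tilt = chain_tilt, pore_shape = pore_shape,
                 pore_radius = pore_radius, helix_tilt = helix_tilt,
                 n_waters_in_pore = as.integer(n_waters_in_pore), box = box,
                 lining_vdw = lining_vdw, ring_spacing = ring_spacing,
                 n_per_ring = as.integer(n_per_ring),
                 chain_length = as.integer(chain_length),
                 helix_residues = as.integer(helix_residues),
                 dewet_band = dewet_band, seed = seed),
            class = "toy_system_params")
}

.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
         byrow = TRUE)
}

#' Ideal alpha-helix C-alpha coordinates
#'
#' 2.3 Angstrom radius, 1.5 Angstrom rise and 100 degrees per residue,
#' centred on the origin with its axis along z.
#'
#' @param n_residues number of residues.
#' @return n x 3 matrix of coordinates (Angstrom).
#' @export
ideal_helix <- function(n_residues) {
  i <- seq_len(n_residues) - 1
  ang <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  sweep(xyz, 2, colMeans(xyz))
}

## centreline radius of the pore lining at height z
.pore_lining_radius <- function(z, shape, radius, z_half) {
  switch(shape,
         cylinder = rep(radius[1], length(z)),
         cone = radius[1] + (radius[2] - radius[1]) * (z + z_half) /
           (2 * z_half),
         hourglass = radius[1] + (radius[2] - radius[1]) * abs(z) / z_half)
}

#' Build a toy molecular system with known ground truth
#'
#' Pseudo-atoms emitted per component: leaflet phosphates (`LIP`/`P`) at
#' z = +-thickness/2; acyl chains (`LIP`/`C1..Cn` with hydrogens
#' `Hn1`/`Hn2` perpendicular to the chain director) tilted by `chain_tilt`
#' from the normal; pore-lining spheres (`POR`/`PL`) in rings realising the
#' requested shape; an ideal helix (`ALA`/`CA`, chain `H`) rotated by
#' `helix_tilt` about x; water oxygens (`HOH`/`OW`) quasi-uniform in the
#' pore cylinder over the full box height.
#'
#' @param params a [toy_system_params()] object.
#' @return A `molecular_system`; `ground_truth` holds the parameters.
#' @export
build_toy_structure <- function(params) {
  stopifnot(inherits(params, "toy_system_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(as.integer(p$seed %% .Machine$integer.max))
  thick <- p$bilayer_thickness * 10
  box <- p$box * 10
  rows <- list()
  add <- function(name, resname, resid, chain, xyz, vdw = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = chain,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = vdw,
      stringsAsFactors = FALSE)
  }

  ## lipids: phosphate grid per leaflet, avoiding the pore mouth
  n_side <- ceiling(sqrt(p$n_lipids_per_leaflet))
  gx <- seq(-box[1] / 2 + 4, box[1] / 2 - 4, length.out = n_side)
  grid <- expand.grid(x = gx, y = gx)
  rmax_pore <- max(p$pore_radius) + p$lining_vdw + 2
  grid <- grid[sqrt(grid$x^2 + grid$y^2) > rmax_pore, , drop = FALSE]
  grid <- grid[seq_len(min(nrow(grid), p$n_lipids_per_leaflet)), , drop = FALSE]
  resid_ctr <- 0
  director <- .rot_x(p$chain_tilt) %*% c(0, 0, -1)
  u1 <- c(director[3], 0, -director[1])    # perpendicular to director, in xz
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(director[2] * u1[3] - director[3] * u1[2],
          director[3] * u1[1] - director[1] * u1[3],
          director[1] * u1[2] - director[2] * u1[1])
  for (leaflet in c(1, -1)) {
    d <- director * leaflet   # chains point toward the midplane
    for (i in seq_len(nrow(grid))) {
      resid_ctr <- resid_ctr + 1
      pz <- leaflet * thick / 2
      base <- c(grid$x[i], grid$y[i], pz)
      add("P", "LIP", resid_ctr, "L", matrix(base, 1, 3), vdw = 1.8)
      for (k in seq_len(p$chain_length)) {
        cpos <- base + as.vector(d) * 1.27 * k
        add(sprintf("C%d", k), "LIP", resid_ctr, "L", matrix(cpos, 1, 3),
            vdw = 1.7)
        add(sprintf("H%d1", k), "LIP", resid_ctr, "L",
            matrix(cpos + u1 * 1.09, 1, 3), vdw = 1.2)
        add(sprintf("H%d2", k), "LIP", resid_ctr, "L",
            matrix(cpos + u2 * 1.09, 1, 3), vdw = 1.2)
      }
    }
  }

  ## pore lining rings spanning the membrane plus a small margin
  z_half <- thick / 2 + 5
  zs <- seq(-z_half, z_half, by = p$ring_spacing)
  ang <- seq(0, 2 * pi, length.out = p$n_per_ring + 1)[-(p$n_per_ring + 1)]
  pore_resid <- resid_ctr
  for (z in zs) {
    pore_resid <- pore_resid + 1
    r <- .pore_lining_radius(z, p$pore_shape, p$pore_radius, z_half)
    xyz <- cbind(r * cos(ang), r * sin(ang), z)
    add("PL", "POR", pore_resid, "P", xyz, vdw = p$lining_vdw)
  }

  ## ideal helix, tilted about x, displaced from the pore in x
  hx <- ideal_helix(p$helix_residues) %*% t(.rot_x(p$helix_tilt))
  hx[, 1] <- hx[, 1] + box[1] / 2 - 8
  for (i in seq_len(nrow(hx)))
    add("CA", "ALA", i, "H", hx[i, , drop = FALSE], vdw = 1.7)

  ## waters: quasi-uniform in the free pore cylinder over the full box height
  if (p$n_waters_in_pore > 0) {
    rfree <- max(0.5, (min(p$pore_radius) - p$lining_vdw) * 0.8)
    wz <- runif(p$n_waters_in_pore, -box[3] / 2, box[3] / 2)
    wr <- rfree * sqrt(runif(p$n_waters_in_pore))
    wa <- runif(p$n_waters_in_pore, 0, 2 * pi)
    w <- cbind(wr * cos(wa), wr * sin(wa), wz)
    if (!is.null(p$dewet_band))
      w <- w[w[, 3] < p$dewet_band[1] | w[, 3] > p$dewet_band[2], ,
             drop = FALSE]
    if (nrow(w) > 0) {
      wid <- seq_len(nrow(w))
      rows[[length(rows) + 1]] <- data.frame(
        name = "OW", resname = "HOH", resid = 9000 + wid, chain = "W",
        x = w[, 1], y = w[, 2], z = w[, 3], vdw = 1.52,
        stringsAsFactors = FALSE)
    }
  }

  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "name", "resname", "resid", "chain",
                     "x", "y", "z", "vdw")]
  molecular_system(atoms, box = box, ground_truth = unclass(p))
}
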
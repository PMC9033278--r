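#' HOLE-style pore radius profile
#'
#' At each height z along the pore axis, the pore radius is the largest
#' sphere that fits without overlapping any atom's van der Waals sphere:
#' `r(z) = max over (x, y) of min_i (|p - a_i| - R_i)`, with the in-plane
#' maximisation done by a local search seeded from the previous slice's
#' centre. Slices are classified against the water-passage thresholds:
#' below 1.15 Angstrom water cannot pass (`sub_water`), above 2.3 Angstrom
#' it passes freely (`open`), otherwise `intermediate`.
#'
#' @param system a `molecular_system` with vdW radii.
#' @param frame frame number.
#' @param z_range `c(zmin, zmax)` along the axis; defaults to the z extent
#'   of the non-water atoms.
#' @param step slice spacing, Angstrom.
#' @param center_xy starting in-plane centre; defaults to the centroid of
#'   the non-water atoms.
#' @param exclude_resname residue names ignored as pore-blocking atoms
#'   (waters and bulk lipids by default are kept; pass e.g. `"HOH"`).
#' @param search_radius only atoms within this axial distance of a slice
#'   are considered, Angstrom.
#' @param thresholds classification radii, Angstrom.
#' @return A `pore_profile` data frame: `z`, `radius`, `x`, `y`, `class`,
#'   with attribute `thresholds`.
#' @export
pore_profile <- function(system, frame = 1, z_range = NULL, step = 0.25,
                         center_xy = NULL, exclude_resname = "HOH",
                         search_radius = 12, thresholds = c(1.15, 2.3)) {
  a <- system$atoms
  if (is.null(a$vdw) || all(is.na(a$vdw)))
    stop("pore profiling needs vdW radii", call. = FALSE)
  keep <- !(a$resname %in% exclude_resname)
  xyz <- .frame_coords(system, frame)[keep, , drop = FALSE]
  vdw <- a$vdw[keep]
  vdw[is.na(vdw)] <- .default_vdw(a$name[keep][is.na(vdw)])
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  if (is.null(center_xy)) center_xy <- colMeans(xyz[, 1:2, drop = FALSE])
  zs <- seq(z_range[1], z_range[2], by = step)
  centre <- center_xy
  res <- lapply(zs, function(z) {
    near <- abs(xyz[, 3] - z) <= search_radius + max(vdw)
    if (!any(near))
      return(list(z = z, radius = Inf, x = centre[1], y = centre[2],
                  flagged = TRUE))
    ax <- xyz[near, , drop = FALSE]
    av <- vdw[near]
    objective <- function(par) {
      d <- sqrt((ax[, 1] - par[1])^2 + (ax[, 2] - par[2])^2 + (ax[, 3] - z)^2)
      -min(d - av)
    }
    opt <- optim(centre, objective, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 400))
    centre <<- opt$par
    list(z = z, radius = max(-opt$value, 0), x = opt$par[1], y = opt$par[2],
         flagged = FALSE)
  })
  out <- data.frame(z = vapply(res, `[[`, numeric(1), "z"),
                    radius = vapply(res, `[[`, numeric(1), "radius"),
                    x = vapply(res, `[[`, numeric(1), "x"),
                    y = vapply(res, `[[`, numeric(1), "y"),
                    open_flag = vapply(res, `[[`, logical(1), "flagged"))
  out$class <- ifelse(out$radius < thresholds[1], "sub_water",
                      ifelse(out$radius > thresholds[2], "open",
                             "intermediate"))
  structure(out, class = c("pore_profile", "data.frame"),
            thresholds = thresholds, step = step)
}

#' Axial solvent (water) density profile
#'
#' Counts water oxygens inside a cylinder around the pore axis in z bins
#' and converts to number density (nm^-3). Bulk density is estimated from
#' the bins fully outside the stated membrane span; the pore counts as
#' hydrated when the minimum in-membrane density stays above
#' `hydration_fraction` of bulk (a dewetted/vapor-locked pore fails this).
#'
#' @param system a `molecular_system`.
#' @param cylinder_radius cylinder radius, Angstrom.
#' @param bin z bin width, Angstrom.
#' @param membrane_span `c(zmin, zmax)` of the membrane, Angstrom; defaults
#'   to the phosphate leaflet planes.
#' @param water_resname,water_name water selection.
#' @param center_xy axis position; defaults to the centroid of non-water
#'   atoms.
#' @param z_range profile extent; defaults to the water z extent.
#' @param hydration_fraction fraction of bulk density below which a bin
#'   counts as dewetted.
#' @param frame frame number.
#' @return A `density_profile` data frame: `z` (bin centre), `count`,
#'   `density` (nm^-3), `in_membrane`, `hydrated`; attributes
#'   `bulk_density`, `hydrated` (overall), `membrane_span`.
#' @export
solvent_density_profile <- function(system, cylinder_radius, bin = 0.5,
                                    membrane_span = NULL,
                                    water_resname = "HOH", water_name = "OW",
                                    center_xy = NULL, z_range = NULL,
                                    hydration_fraction = 0.2, frame = 1) {
  wsel <- select_atoms(system, resname = water_resname, name = water_name)
  if (length(wsel) == 0) stop("no waters in system", call. = FALSE)
  xyz_all <- .frame_coords(system, frame)
  w <- xyz_all[wsel, , drop = FALSE]
  if (is.null(center_xy)) {
    other <- setdiff(seq_len(nrow(xyz_all)), wsel)
    center_xy <- if (length(other) > 0)
      colMeans(xyz_all[other, 1:2, drop = FALSE]) else c(0, 0)
  }
  if (is.null(membrane_span)) {
    psel <- select_atoms(system, name = "P")
    if (length(psel) == 0)
      stop("membrane_span not given and no phosphates to infer it from",
           call. = FALSE)
    pz <- xyz_all[psel, 3]
    mid <- mean(pz)
    membrane_span <- c(mean(pz[pz <= mid]), mean(pz[pz > mid]))
  }
  inside <- sqrt((w[, 1] - center_xy[1])^2 + (w[, 2] - center_xy[2])^2) <=
    cylinder_radius
  wz <- w[inside, 3]
  if (is.null(z_range)) z_range <- range(w[, 3])
  edges <- seq(z_range[1], z_range[2] + bin, by = bin)
  counts <- vapply(seq_len(length(edges) - 1), function(i)
    sum(wz >= edges[i] & wz < edges[i + 1]), numeric(1))
  centers <- edges[-length(edges)] + bin / 2
  vol_nm3 <- pi * cylinder_radius^2 * bin * 1e-3
  density <- counts / vol_nm3
  in_mem <- centers >= membrane_span[1] & centers <= membrane_span[2]
  out_mem <- centers < membrane_span[1] - bin | centers > membrane_span[2] + bin
  if (!any(out_mem))
    stop("no bins outside the membrane span to estimate bulk density",
         call. = FALSE)
  bulk <- mean(density[out_mem])
  hydrated_bin <- density >= hydration_fraction * bulk
  overall <- if (any(in_mem)) all(hydrated_bin[in_mem]) else TRUE
  structure(data.frame(z = centers, count = counts, density = density,
                       in_membrane = in_mem, hydrated = hydrated_bin),
            class = c("density_profile", "data.frame"),
            bulk_density = bulk, hydrated = overall,
            membrane_span = membrane_span,
            hydration_fraction = hydration_fraction)
}
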
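#' Construct a molecular system
#'
#' The common substrate of all structural metrics: an atom table with
#' coordinates in Angstrom, optional van der Waals radii, charges and
#' Lennard-Jones parameters, plus optional trajectory frames.
#'
#' @param atoms data frame with at least `serial`, `name`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`; optionally `vdw` (Angstrom), `charge`
#'   (e), `sigma` (Angstrom), `epsilon` (kJ/mol).
#' @param frames list of n_atoms x 3 coordinate matrices; defaults to a
#'   single frame built from the atom table.
#' @param box length-3 box vector, Angstrom (optional).
#' @param ground_truth free-form list recording generator parameters.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, frames = NULL, box = NULL,
                             ground_truth = NULL) {
  req <- c("serial", "name", "resname", "resid", "chain", "x", "y", "z")
  missing <- setdiff(req, names(atoms))
  if (length(missing) > 0)
    stop("atom table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite", call. = FALSE)
  if (!is.null(atoms$vdw) && any(atoms$vdw <= 0, na.rm = TRUE))
    stop("vdW radii must be positive", call. = FALSE)
  if (is.null(frames))
    frames <- list(unname(as.matrix(atoms[, c("x", "y", "z")])))
  n <- nrow(atoms)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("every frame must be an n_atoms x 3 matrix", call. = FALSE)
    if (!all(is.finite(f))) stop("frame coordinates must be finite",
                                 call. = FALSE)
  }
  structure(list(atoms = atoms, frames = frames, box = box,
                 ground_truth = ground_truth),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d atoms, %d frame(s), %d residues\n",
              nrow(x$atoms), length(x$frames),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' Number of frames
#' @param system a `molecular_system`.
#' @return Integer frame count.
#' @export
n_frames <- function(system) length(system$frames)

#' Select atom indices by attributes
#'
#' All given filters are combined with AND; vector values mean "any of".
#'
#' @param system a `molecular_system`.
#' @param resname,name,chain,resid optional filters.
#' @param heavy_only drop atoms whose name starts with `H`.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(system, resname = NULL, name = NULL, chain = NULL,
                         resid = NULL, heavy_only = FALSE) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (heavy_only) keep <- keep & !grepl("^H", a$name)
  which(keep)
}

## element-based fallback vdW radii (Angstrom), keyed on the leading
## element letter of the atom name
.default_vdw <- function(names) {
  first <- toupper(substr(gsub("^[0-9]+", "", names), 1, 1))
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
  out <- unname(r[first])
  out[is.na(out)] <- 1.70
  out
}

#' Load a molecular system from PDB
#'
#' Single or multi-model PDB files are read with bio3d; models become
#' trajectory frames. An optional parameter table supplies per-atom-type
#' charges, Lennard-Jones parameters and vdW radii; atoms without an entry
#' keep `NA` (element-based vdW radii are filled in as a default).
#'
#' @param structure_path PDB file.
#' @param trajectory_path optional additional multi-model PDB whose models
#'   are appended as frames (atom order must match).
#' @param parameter_table optional CSV path or data frame with columns
#'   `resname`, `atomname` and any of `sigma`, `epsilon`, `charge`, `vdw`.
#' @return A `molecular_system`.
#' @export
load_system <- function(structure_path, trajectory_path = NULL,
                        parameter_table = NULL) {
  pdb <- bio3d::read.pdb(structure_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                      resid = at$resno, chain = ifelse(is.na(at$chain), "A",
                                                       at$chain),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  xyz <- pdb$xyz
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  for (f in frames) if (nrow(f) != n)
    stop("frame atom count differs from structure", call. = FALSE)
  if (!is.null(trajectory_path)) {
    if (!grepl("\\.pdb$", trajectory_path, ignore.case = TRUE))
      stop("trajectory adapter supports multi-model PDB only", call. = FALSE)
    tr <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
    if (ncol(tr$xyz) != 3 * n)
      stop("atom-count mismatch between structure and trajectory frames",
           call. = FALSE)
    frames <- c(frames, lapply(seq_len(nrow(tr$xyz)), function(i)
      matrix(tr$xyz[i, ], ncol = 3, byrow = TRUE)))
  }
  atoms$x <- frames[[1]][, 1]
  atoms$y <- frames[[1]][, 2]
  atoms$z <- frames[[1]][, 3]
  atoms$vdw <- .default_vdw(atoms$name)
  if (!is.null(parameter_table)) {
    if (is.character(parameter_table))
      parameter_table <- read.csv(parameter_table, stringsAsFactors = FALSE)
    atoms <- .apply_parameters(atoms, parameter_table)
  }
  molecular_system(atoms, frames = frames)
}

.apply_parameters <- function(atoms, par) {
  if (!all(c("resname", "atomname") %in% names(par)))
    stop("parameter table needs resname and atomname columns", call. = FALSE)
  key_a <- paste(atoms$resname, atoms$name)
  key_p <- paste(par$resname, par$atomname)
  idx <- match(key_a, key_p)
  for (col in intersect(c("sigma", "epsilon", "charge", "vdw"), names(par))) {
    vals <- par[[col]][idx]
    if (col == "vdw") {
      atoms$vdw <- ifelse(is.na(vals), atoms$vdw, vals)
    } else {
      atoms[[col]] <- vals
    }
  }
  atoms
}

#' Write a molecular system as (multi-model) PDB
#'
#' Each frame becomes one MODEL record; coordinates are written at PDB
#' precision (1e-3 Angstrom).
#'
#' @param system a `molecular_system`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_system_pdb <- function(system, path) {
  a <- system$atoms
  write_one <- function(xyz, file) {
    bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)),
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain)
  }
  if (length(system$frames) == 1) {
    write_one(system$frames[[1]], path)
    return(invisible(path))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  out <- character(0)
  for (i in seq_along(system$frames)) {
    write_one(system$frames[[i]], tmp)
    body <- readLines(tmp)
    body <- body[!grepl("^END", body)]
    out <- c(out, sprintf("MODEL     %4d", i), body, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
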
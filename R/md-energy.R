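#' Pairwise Lennard-Jones and Coulomb interaction energy between two groups
#'
#' Plain-cutoff non-bonded pair energy:
#' `E_LJ = sum 4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6)` with
#' Lorentz-Berthelot combining (`sigma_ij` arithmetic mean, `eps_ij`
#' geometric mean), and `E_C = f q_i q_j / r` with
#' `f = 138.935458 kJ mol^-1 nm e^-2` (vacuum permittivity). Energies are
#' averaged over the analysis window of frames; the force-switch smoothing
#' used by simulation engines is not reproduced (documented deviation — a
#' plain cutoff changes window means by well under the frame-to-frame
#' spread for typical cutoffs).
#'
#' @param system a `molecular_system` whose atoms carry `charge`, `sigma`,
#'   `epsilon`.
#' @param group_a,group_b atom index vectors.
#' @param window_frames frame numbers of the analysis window (default all,
#'   e.g. the last frames of a trajectory).
#' @param cutoff pair distance cutoff, Angstrom.
#' @return A `pairwise_energy` list: `coulomb`, `lj`, `total` (kJ/mol,
#'   window means), `coulomb_sd`, `lj_sd`, `total_sd` (sd over the window),
#'   `n_frames`, `cutoff`.
#' @export
pairwise_energy <- function(system, group_a, group_b, window_frames = NULL,
                            cutoff = 12) {
  a <- system$atoms
  need <- c("charge", "sigma", "epsilon")
  for (col in need) {
    if (is.null(a[[col]]))
      stop("pairwise energy requires atom parameters; missing column: ", col,
           call. = FALSE)
    bad <- unique(c(group_a, group_b))[is.na(a[[col]][unique(c(group_a, group_b))])]
    if (length(bad) > 0)
      stop("parameters required but missing (", col, ") for atoms: ",
           paste(head(a$serial[bad], 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty atom group", call. = FALSE)
  if (is.null(window_frames)) window_frames <- seq_along(system$frames)
  cut2 <- cutoff^2
  per_frame <- vapply(window_frames, function(f) {
    xyz <- system$frames[[f]]
    pa <- xyz[group_a, , drop = FALSE]
    pb <- xyz[group_b, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    d2 <- pmax(d2, 0)
    ## drop self-pairs if the groups overlap
    if (length(intersect(group_a, group_b)) > 0) {
      same <- outer(group_a, group_b, "==")
      d2[same] <- Inf
    }
    within <- which(d2 <= cut2 & d2 > 0, arr.ind = TRUE)
    if (nrow(within) == 0) return(c(0, 0))
    r <- sqrt(d2[within])
    ia <- group_a[within[, 1]]
    ib <- group_b[within[, 2]]
    sig <- (a$sigma[ia] + a$sigma[ib]) / 2
    eps <- sqrt(a$epsilon[ia] * a$epsilon[ib])
    sr6 <- (sig / r)^6
    e_lj <- sum(4 * eps * (sr6^2 - sr6))
    e_c <- sum(.F_COULOMB * a$charge[ia] * a$charge[ib] / (r / 10))
    c(e_c, e_lj)
  }, numeric(2))
  coulomb <- per_frame[1, ]
  lj <- per_frame[2, ]
  total <- coulomb + lj
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  structure(list(coulomb = mean(coulomb), coulomb_sd = sd0(coulomb),
                 lj = mean(lj), lj_sd = sd0(lj),
                 total = mean(total), total_sd = sd0(total),
                 n_frames = length(window_frames), cutoff = cutoff),
            class = "pairwise_energy")
}

#' @export
print.pairwise_energy <- function(x, ...) {
  cat(sprintf(
    "<pairwise_energy> Coulomb %.2f (sd %.2f), LJ %.2f (sd %.2f), total %.2f (sd %.2f) kJ/mol over %d frame(s)\n",
    x$coulomb, x$coulomb_sd, x$lj, x$lj_sd, x$total, x$total_sd, x$n_frames))
  invisible(x)
}
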
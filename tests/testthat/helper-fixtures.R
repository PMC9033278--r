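# Shared fixture builders. Everything is generated in code at test time;
# small n_points keeps the ESEEM unit tests fast (the acceptance suite runs
# the full-size panels).

fast_eseem <- function(depth_k = 0.3, noise_sigma = 0, seed = NULL, ...) {
  eseem_sim_params(depth_k = depth_k, noise_sigma = noise_sigma, seed = seed,
                   n_points = 1024, ...)
}

# closed-form noiseless trace values, written independently of the
# simulator's internals (direct formula evaluation oracle)
eseem_closed_form <- function(T_ns, tau, k, nu, damping = Inf,
                              bg_amp = 1, bg_time = 20000, bg_stretch = 0.9) {
  w <- 2e-3 * pi * nu
  damp <- if (is.finite(damping)) exp(-T_ns / damping) else rep(1, length(T_ns))
  bg <- bg_amp * exp(-(T_ns / bg_time)^bg_stretch)
  bg * (1 - (k / 4) * (1 - cos(w * tau)) * (1 - cos(w * (T_ns + tau))) * damp)
}

# two-condition lipid-contact fixture: six probe residues around a line of
# lipid atoms; in the "tension" frame three residues move toward the lipids
# (gain contacts) and three move away (lose contacts)
contact_fixture <- function() {
  probes <- data.frame(
    serial = 1:6, name = "CB", resname = "ALA", resid = 1:6, chain = "A",
    x = seq(0, 50, by = 10), y = 3.5, z = 0, vdw = 1.7)
  lipids <- data.frame(
    serial = 7:12, name = "C1", resname = "LIP", resid = 101:106, chain = "L",
    x = seq(0, 50, by = 10), y = 0, z = 0, vdw = 1.7)
  atoms <- rbind(probes, lipids)
  ref <- as.matrix(atoms[, c("x", "y", "z")])
  tens <- ref
  tens[1:3, 2] <- 10    # residues 1-3 move away: lose contacts
  tens[4:6, 2] <- 2     # residues 4-6 move closer: keep/gain contacts
  ref[4:6, 2] <- 10     # in the reference they start far: gain under tension
  list(ref = molecular_system(atoms, frames = list(ref)),
       tension = molecular_system(atoms, frames = list(tens)),
       gained = 4:6, lost = 1:3)
}

# dense random-sampling oracle for the pore radius at one z slice:
# max over sampled (x, y) of min_i (|p - a_i| - R_i); sampling is confined
# to a disc around the axis so it cannot escape through the lining shell
pore_slice_oracle <- function(xyz, vdw, z, xy_lim = 2, n = 20000) {
  r <- xy_lim * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  px <- r * cos(a)
  py <- r * sin(a)
  best <- -Inf
  for (i in seq_len(n)) {
    d <- sqrt((xyz[, 1] - px[i])^2 + (xyz[, 2] - py[i])^2 + (xyz[, 3] - z)^2)
    r <- min(d - vdw)
    if (r > best) best <- r
  }
  best
}

# brute-force rotation-grid + refinement oracle for minimal RMSD
rmsd_bruteforce <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  obj <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((a %*% t(Rz %*% Ry %*% Rx) - b)^2)))
  }
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 7),
                                a2 = seq(0, pi, length.out = 5),
                                a3 = seq(0, 2 * pi, length.out = 7)))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
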
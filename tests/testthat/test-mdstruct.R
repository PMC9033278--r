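test_that("Kabsch RMSD: identity, rotation invariance and brute-force oracle", {
  xyz <- ideal_helix(20)
  expect_equal(rmsd_kabsch(xyz, xyz), 0)

  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  expect_lt(rmsd_kabsch(xyz, xyz %*% t(rot) + 3), 1e-10)

  set.seed(42)
  for (i in 1:5) {
    a <- matrix(rnorm(12), 4, 3)
    b <- a + matrix(rnorm(12, sd = 0.3), 4, 3)
    expect_equal(rmsd_kabsch(a, b), rmsd_bruteforce(a, b), tolerance = 1e-6)
  }
  expect_error(rmsd_kabsch(xyz[1:2, ], xyz[1:2, ]), "at least 3")

  # independent cross-check against bio3d's fitted RMSD
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(rmsd_kabsch(a, b), ref, tolerance = 1e-3)
})

test_that("membrane thickness per frame reproduces constructed thinning", {
  sys <- build_toy_structure(toy_system_params(bilayer_thickness = 3.8,
                                               seed = 2))
  expect_equal(membrane_thickness(sys), 3.8)
  sys26 <- build_toy_structure(toy_system_params(bilayer_thickness = 2.6,
                                                 seed = 2))
  expect_equal(membrane_thickness(sys26), 2.6)

  # a two-frame trajectory thinning 3.8 -> 2.6 nm (delta 1.2 nm)
  f1 <- sys$frames[[1]]
  f2 <- f1
  pz <- sys$atoms$name == "P"
  scale <- 2.6 / 3.8
  f2[, 3] <- f1[, 3] * ifelse(abs(f1[, 3]) <= 20, scale, 1)
  f2[pz, 3] <- f1[pz, 3] * scale
  traj <- molecular_system(sys$atoms, frames = list(f1, f2))
  th <- membrane_thickness(traj)
  expect_equal(th, c(3.8, 2.6), tolerance = 1e-6)
  expect_equal(th[1] - th[2], 1.2, tolerance = 1e-6)

  flat <- sys
  flat$atoms$z[pz] <- abs(flat$atoms$z[pz])
  flat$frames <- list(unname(as.matrix(flat$atoms[, c("x", "y", "z")])))
  expect_error(membrane_thickness(flat), "one leaflet")
})

test_that("pore profile matches analytic cylinder and cone shapes", {
  sys <- build_toy_structure(toy_system_params(pore_radius = 5, seed = 1))
  pp <- pore_profile(sys, z_range = c(-15, 15), step = 1)
  expect_true(all(abs(pp$radius - 3.5) < 0.05))

  cone <- build_toy_structure(toy_system_params(
    pore_shape = "cone", pore_radius = c(2.5, 7.5), seed = 1))
  ppc <- pore_profile(cone, z_range = c(-23, 23), step = 1)
  # free radius rises linearly 1 -> 6 Angstrom over the lining span
  z_half <- 24
  analytic <- (2.5 + 5 * (ppc$z + z_half) / (2 * z_half)) - 1.5
  expect_lt(max(abs(ppc$radius - analytic)), 0.1)
  expect_identical(unique(ppc$class[ppc$radius < 1.15]), "sub_water")
  expect_true(all(c("sub_water", "intermediate", "open") %in% ppc$class))

  hour <- build_toy_structure(toy_system_params(
    pore_shape = "hourglass", pore_radius = c(2.5, 7.5), seed = 1))
  pph <- pore_profile(hour, z_range = c(-10, 10), step = 0.5)
  waist <- pph[which.min(pph$radius), ]
  expect_lt(waist$radius, 1.15)
  expect_identical(waist$class, "sub_water")
})

test_that("pore profile agrees with a dense random-sampling oracle", {
  set.seed(7)
  hour <- build_toy_structure(toy_system_params(
    pore_shape = "hourglass", pore_radius = c(3, 7), seed = 1))
  lining <- hour$atoms$resname == "POR"
  xyz <- as.matrix(hour$atoms[lining, c("x", "y", "z")])
  vdw <- hour$atoms$vdw[lining]
  pp <- pore_profile(hour, z_range = c(-8, 8), step = 4)
  for (i in seq_len(nrow(pp))) {
    oracle <- pore_slice_oracle(xyz, vdw, pp$z[i])
    expect_lt(abs(pp$radius[i] - oracle), 0.1)
  }
})

test_that("solvent density profile flags dewetting and conserves counts", {
  wet <- build_toy_structure(toy_system_params(n_waters_in_pore = 2000,
                                               seed = 5))
  dp <- solvent_density_profile(wet, cylinder_radius = 3.5, bin = 5)
  expect_true(attr(dp, "hydrated"))
  expect_gt(attr(dp, "bulk_density"), 0)
  # uniform fill: all bins near bulk
  expect_lt(max(abs(dp$density - attr(dp, "bulk_density"))) /
              attr(dp, "bulk_density"), 0.5)

  dry <- build_toy_structure(toy_system_params(n_waters_in_pore = 2000,
                                               dewet_band = c(-6, 6),
                                               seed = 5))
  dp2 <- solvent_density_profile(dry, cylinder_radius = 3.5, bin = 5)
  expect_false(attr(dp2, "hydrated"))
  expect_true(any(dp2$density[dp2$in_membrane] == 0))

  # halving the bin width conserves the integrated count
  dp_half <- solvent_density_profile(wet, cylinder_radius = 3.5, bin = 2.5)
  expect_lt(abs(sum(dp_half$count) - sum(dp$count)) / sum(dp$count), 0.01)
})

test_that("lipid contacts count heavy-atom pairs within the cutoff", {
  probe <- data.frame(serial = 1:2, name = "CB", resname = "ALA",
                      resid = 1:2, chain = "A", x = c(0, 20), y = 0, z = 0,
                      vdw = 1.7)
  lipid <- data.frame(serial = 3, name = "C1", resname = "LIP", resid = 50,
                      chain = "L", x = 3.9, y = 0, z = 0, vdw = 1.7)
  sys <- molecular_system(rbind(probe, lipid))
  cm <- lipid_contacts(sys, 1:2, 3, cutoff = 4.0)
  expect_equal(cm$mean_contacts[cm$resid == 1], 1)
  expect_equal(cm$mean_contacts[cm$resid == 2], 0)
  expect_error(lipid_contacts(sys, integer(0), 3), "empty")
})

test_that("relative contact differences reproduce planted gains and losses", {
  fx <- contact_fixture()
  m_ref <- lipid_contacts(fx$ref, 1:6, 7:12)
  m_ten <- lipid_contacts(fx$tension, 1:6, 7:12)
  rd <- contact_relative_difference(m_ten, m_ref)
  expect_true(all(rd$rel_diff[rd$resid %in% fx$gained] > 0))
  expect_true(all(rd$rel_diff[rd$resid %in% fx$lost] < 0))
  expect_true(all(sign(rd$rel_diff_maxnorm) == sign(rd$rel_diff)))

  null <- contact_relative_difference(m_ref, m_ref)
  expect_true(all(null$rel_diff == 0))
})

test_that("order parameters hit the closed-form limits", {
  vert <- build_toy_structure(toy_system_params(chain_tilt = 0, seed = 1))
  op <- order_parameters(vert)
  expect_true(all(abs(op$S_CD + 0.5) < 1e-10))

  horiz <- build_toy_structure(toy_system_params(chain_tilt = 90, seed = 1))
  oph <- order_parameters(horiz)
  # horizontal chains shift S_CD toward the (3 cos^2 - 1)/4 envelope: the
  # magnitude drops relative to the vertical all-trans case
  expect_true(all(abs(oph$S_CD) < 0.5))
  expect_true(all(abs(oph$S_CD - 0.25) < 1e-10))

  # isotropically oriented C-H bonds average to zero
  set.seed(99)
  n <- 1e4
  v <- matrix(rnorm(3 * n), n, 3)
  ct <- v[, 3] / sqrt(rowSums(v^2))
  expect_lt(abs(mean((3 * ct^2 - 1) / 2)), 0.02)
})

test_that("Shrake-Rupley areas: sphere closed form and burial", {
  at <- data.frame(serial = 1, name = "C1", resname = "XXX", resid = 1,
                   chain = "A", x = 0, y = 0, z = 0, vdw = 1.7)
  one <- molecular_system(at)
  expect_equal(pocket_sasa(one, 1, probe = 1.4, n_points = 960),
               4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  two <- molecular_system(rbind(at, within(at, { serial <- 2; resid <- 2
                                                 x <- 1.7 })))
  expect_lt(pocket_sasa(two, 1:2), 2 * 4 * pi * (1.7 + 1.4)^2)

  # pulling pocket lining inward (collapse) strictly shrinks the area
  ring <- data.frame(serial = 1:8, name = "C1", resname = "XXX", resid = 1:8,
                     chain = "A",
                     x = 6 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
                     y = 6 * sin(seq(0, 2 * pi, length.out = 9)[-9]),
                     z = 0, vdw = 1.7)
  open_sys <- molecular_system(ring)
  collapsed <- ring
  collapsed$x <- collapsed$x / 2
  collapsed$y <- collapsed$y / 2
  closed_sys <- molecular_system(collapsed)
  expect_lt(pocket_sasa(closed_sys, 1:8), pocket_sasa(open_sys, 1:8))
  expect_error(pocket_sasa(open_sys, integer(0)), "empty")
})

test_that("pairwise energies: closed forms, oracle, symmetry, additivity", {
  mk <- function(xyz, q, sig = 3, eps = 0.5) {
    n <- nrow(xyz)
    molecular_system(data.frame(
      serial = seq_len(n), name = "C1", resname = "XXX", resid = seq_len(n),
      chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = 1.7,
      charge = q, sigma = sig, epsilon = eps))
  }
  # LJ minimum: r = 2^(1/6) sigma gives exactly -epsilon
  s <- mk(rbind(c(0, 0, 0), c(2^(1 / 6) * 3, 0, 0)), q = c(0, 0))
  expect_equal(pairwise_energy(s, 1, 2)$lj, -0.5, tolerance = 1e-12)
  expect_equal(pairwise_energy(s, 1, 2)$coulomb, 0)

  # opposite unit charges at 10 Angstrom = 1 nm
  s2 <- mk(rbind(c(0, 0, 0), c(10, 0, 0)), q = c(1, -1), eps = 0)
  expect_equal(pairwise_energy(s2, 1, 2)$coulomb, -138.935458,
               tolerance = 1e-6)

  # 5-atom configuration vs an independent double-loop sum
  set.seed(3)
  xyz <- matrix(runif(15, 0, 8), 5, 3)
  q <- c(0.3, -0.2, 0.5, -0.4, 0.1)
  sig <- c(3, 3.2, 2.9, 3.4, 3.1)
  eps <- c(0.4, 0.6, 0.5, 0.3, 0.7)
  s5 <- molecular_system(data.frame(
    serial = 1:5, name = "C1", resname = "XXX", resid = 1:5, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = 1.7, charge = q,
    sigma = sig, epsilon = eps))
  ga <- 1:2; gb <- 3:5
  e_c <- 0; e_lj <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= 12) {
      sij <- (sig[i] + sig[j]) / 2
      eij <- sqrt(eps[i] * eps[j])
      e_lj <- e_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
      e_c <- e_c + 138.935458 * q[i] * q[j] / (r / 10)
    }
  }
  got <- pairwise_energy(s5, ga, gb)
  expect_equal(got$lj, e_lj, tolerance = 1e-9)
  expect_equal(got$coulomb, e_c, tolerance = 1e-9)
  expect_equal(got$total, got$coulomb + got$lj)

  # symmetry in (A, B) and additivity over a partition of B
  rev <- pairwise_energy(s5, gb, ga)
  expect_equal(rev$total, got$total, tolerance = 1e-12)
  part <- pairwise_energy(s5, ga, 3)$total +
    pairwise_energy(s5, ga, 4:5)$total
  expect_equal(part, got$total, tolerance = 1e-12)

  # doubling epsilon of every B atom doubles the LJ energy exactly
  s5d <- s5
  s5d$atoms$epsilon[gb] <- 4 * s5$atoms$epsilon[gb]  # sqrt combining: x2
  expect_equal(pairwise_energy(s5d, ga, gb)$lj, 2 * got$lj,
               tolerance = 1e-12)

  s_no <- mk(rbind(c(0, 0, 0), c(5, 0, 0)), q = c(0, 0))
  s_no$atoms$charge <- NULL
  expect_error(pairwise_energy(s_no, 1, 2), "charge")
})

test_that("metrics are invariant under a co-rotated rigid transformation", {
  sys <- build_toy_structure(toy_system_params(helix_tilt = 30,
                                               n_waters_in_pore = 0,
                                               seed = 6))
  th <- 35 * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
                byrow = TRUE)
  xyz2 <- sys$frames[[1]] %*% t(rot)
  xyz2 <- sweep(xyz2, 2, c(5, -3, 2), "+")
  rsys <- sys
  rsys$frames <- list(xyz2)
  rsys$atoms[, c("x", "y", "z")] <- xyz2
  normal2 <- as.vector(rot %*% c(0, 0, 1))

  expect_equal(helix_tilt(rsys, c(1, 30), chain = "H", normal = normal2),
               helix_tilt(sys, c(1, 30), chain = "H"), tolerance = 1e-6)
  # contacts and SASA are rotation invariant outright
  cm1 <- lipid_contacts(sys, select_atoms(sys, chain = "H"),
                        select_atoms(sys, resname = "LIP"), cutoff = 8)
  cm2 <- lipid_contacts(rsys, select_atoms(rsys, chain = "H"),
                        select_atoms(rsys, resname = "LIP"), cutoff = 8)
  expect_equal(cm1$mean_contacts, cm2$mean_contacts)
  # invariant up to the angular resolution of the spiral point sampling
  expect_equal(pocket_sasa(sys, 1:5, chain = "H"),
               pocket_sasa(rsys, 1:5, chain = "H"), tolerance = 0.02)
  expect_equal(rmsd_kabsch(sys$frames[[1]], rsys$frames[[1]]), 0,
               tolerance = 1e-9)
})

test_that("load_system applies parameter tables and contracts errors", {
  sys <- build_toy_structure(toy_system_params(n_waters_in_pore = 5,
                                               n_lipids_per_leaflet = 4,
                                               seed = 2))
  f <- tempfile(fileext = ".pdb")
  write_system_pdb(sys, f)
  par <- data.frame(resname = "HOH", atomname = "OW", sigma = 3.15,
                    epsilon = 0.636, charge = -0.8, vdw = 1.52)
  pf <- tempfile(fileext = ".csv")
  write.csv(par, pf, row.names = FALSE)
  got <- load_system(f, parameter_table = pf)
  w <- got$atoms$resname == "HOH"
  expect_true(all(got$atoms$sigma[w] == 3.15))
  expect_true(all(is.na(got$atoms$sigma[!w])))
  expect_error(pairwise_energy(got, which(!w)[1:3], which(w)),
               "parameters required|missing")
})
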
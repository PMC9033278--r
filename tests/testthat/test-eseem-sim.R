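test_that("zero modulation depth gives the pure background", {
  p <- fast_eseem(depth_k = 0)
  tr <- simulate_eseem_trace(p)
  bg <- p$bg_amplitude * exp(-(tr$T / p$bg_time)^p$bg_stretch)
  expect_equal(max(abs(tr$amplitude - bg)), 0)
})

test_that("tau at an integer multiple of the deuterium period is blind", {
  nu <- 2.25
  for (m in 1:3) {
    p <- fast_eseem(depth_k = 0.5, tau = m * 1000 / nu, nu_D = nu)
    tr <- simulate_eseem_trace(p)
    bg <- p$bg_amplitude * exp(-(tr$T / p$bg_time)^p$bg_stretch)
    expect_lt(max(abs(tr$amplitude - bg)), 1e-12)
  }
})

test_that("noiseless trace matches the closed-form product at every point", {
  p <- eseem_sim_params(depth_k = 0.4, nu_D = 2.25, tau = 200,
                        damping_time = Inf, noise_sigma = 0, n_points = 600)
  tr <- simulate_eseem_trace(p)
  oracle <- eseem_closed_form(tr$T, 200, 0.4, 2.25, damping = Inf,
                              bg_time = p$bg_time, bg_stretch = p$bg_stretch)
  expect_equal(tr$amplitude, oracle, tolerance = 1e-12)
  # noiseless trace touches the background where cos(2 pi nu (T+tau)) = 1
  bg <- p$bg_amplitude * exp(-(tr$T / p$bg_time)^p$bg_stretch)
  expect_lt(min(bg - tr$amplitude), 1e-4)
  expect_true(all(bg - tr$amplitude > -1e-12))
})

test_that("panel simulation: shared grid, unique labels, derived seeds", {
  depths <- exp(seq(log(0.01), log(0.5), length.out = 26))
  names(depths) <- sprintf("S%02d", 1:26)
  panel <- simulate_accessibility_panel(depths, fast_eseem(noise_sigma = 0.003,
                                                           seed = 5))
  expect_length(panel, 26)
  grids <- vapply(panel, function(t) paste(range(t$T), collapse = "-"),
                  character(1))
  expect_length(unique(grids), 1)
  # different seed offsets give different noise
  expect_false(identical(panel[[1]]$amplitude, panel[[2]]$amplitude))
  # equal depths and equal explicit seed offsets reproduce identical traces
  d2 <- data.frame(label = c("A", "B"), depth_k = 0.3, seed_offset = 7)
  twin <- simulate_accessibility_panel(d2, fast_eseem(noise_sigma = 0.003,
                                                      seed = 5))
  expect_identical(twin$A$amplitude, twin$B$amplitude)
  expect_error(simulate_accessibility_panel(c(A = 0.1, A = 0.2),
                                            fast_eseem()),
               "duplicate")
})

test_that("simulation parameters are validated", {
  expect_error(eseem_sim_params(depth_k = 1.2), "depth_k")
  expect_error(eseem_sim_params(t_step = 0), "t_step")
  expect_error(eseem_sim_params(noise_sigma = -0.1), "noise_sigma")
  expect_error(eseem_sim_params(nu_D = -1), "nu_D")
})
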
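test_that("trace files round-trip and validate", {
  tr <- simulate_eseem_trace(fast_eseem(depth_k = 0.3, noise_sigma = 0.005,
                                        seed = 1))
  tr$label <- "V71_wt"
  f <- tempfile(fileext = ".dat")
  write_trace(tr, f)
  back <- load_trace(f)
  expect_equal(back$T, tr$T)
  expect_equal(back$amplitude, tr$amplitude)
  expect_equal(back$tau, tr$tau)
  expect_identical(back$label, "V71_wt")
  expect_equal(back$T[1], 400)
  expect_equal(back$T[2] - back$T[1], 12)
  # grid arithmetic: n points starting at 400 in steps of 12
  n <- length(back$T)
  expect_equal(max(back$T), 400 + (n - 1) * 12)

  # shuffled T column is rejected
  lines <- readLines(f)
  meta <- grepl("^#", lines)
  data <- lines[!meta]
  writeLines(c(lines[meta], data[c(2, 1, seq(3, length(data)))]), f)
  expect_error(load_trace(f), "increasing|uniform")

  # non-numeric row names the offending line
  write_trace(tr, f)
  lines <- readLines(f)
  lines[10] <- "400 not_a_number"
  writeLines(lines, f)
  expect_error(load_trace(f), "line 10")
})

test_that("background correction removes a pure decay and is scale invariant", {
  p <- fast_eseem(depth_k = 0)
  tr <- simulate_eseem_trace(p)
  m0 <- correct_background(tr)
  expect_lt(max(abs(m0$value)), 1e-6)

  tr2 <- simulate_eseem_trace(fast_eseem(depth_k = 0.4))
  m1 <- correct_background(tr2)
  tr10 <- tr2
  tr10$amplitude <- tr2$amplitude * 10
  m10 <- correct_background(tr10)
  expect_equal(m1$value, m10$value, tolerance = 1e-8)

  # max |modulation| near T = t_start matches the closed-form oscillation
  # amplitude 2A damp(t_start), A = k (1 - cos(2 pi nu tau)) / 4
  p4 <- fast_eseem(depth_k = 0.4)
  A <- 0.4 * (1 - cos(2e-3 * pi * p4$nu_D * p4$tau)) / 4
  expected_max <- 2 * A * exp(-p4$t_start / p4$damping_time)
  expect_equal(max(abs(m1$value)), expected_max, tolerance = 0.05)
})

test_that("damped harmonic fit recovers depth and flags no modulation", {
  f0 <- fit_modulation(correct_background(simulate_eseem_trace(
    fast_eseem(depth_k = 0))))
  expect_equal(f0$depth_k, 0, tolerance = 1e-6)
  expect_true(f0$no_modulation)

  tr <- simulate_eseem_trace(eseem_sim_params(depth_k = 0.30, nu_D = 2.25,
                                              noise_sigma = 0))
  ft <- fit_modulation(correct_background(tr))
  expect_equal(ft$depth_k, 0.30, tolerance = 1e-3 / 0.30)
  expect_equal(ft$nu, 2.25, tolerance = 1e-3 / 2.25)
})

test_that("magnitude spectrum peaks at the modulation frequency and is linear", {
  tr <- simulate_eseem_trace(fast_eseem(depth_k = 0.4, nu_D = 2.25))
  mf <- correct_background(tr)
  res <- spectrum_intensity(mf)
  spec <- res$spectrum
  peak <- spec$freq[which.max(spec$magnitude)]
  bin <- spec$freq[2] - spec$freq[1]
  expect_lt(abs(peak - 2.25), 2 * bin)
  mf2 <- mf
  mf2$value <- 2 * mf$value
  expect_equal(spectrum_intensity(mf2)$intensity, 2 * res$intensity,
               tolerance = 1e-10)
  expect_error(spectrum_intensity(mf, peak_center = 60), "outside")
})

test_that("panel normalization reproduces the printed ratio structure", {
  raw <- data.frame(label = c("A", "B"), value = c(0.4, 0.012), sd = 0)
  np <- normalize_panel(raw)
  expect_equal(np$accessibility_pct, c(100, 3))
  expect_identical(attr(np, "reference_label"), "A")
  expect_true(all(np$uncertainty_pct >= 5))

  # most-buried vs most-exposed panel: L72 ~3%, K100 100%, N70 90%, V71 80%
  raw4 <- data.frame(label = c("L72", "K100", "N70", "V71"),
                     value = c(0.012, 0.40, 0.36, 0.32), sd = 0)
  np4 <- normalize_panel(raw4)
  expect_equal(np4$accessibility_pct, c(3, 100, 90, 80))

  all_eq <- normalize_panel(data.frame(label = c("A", "B", "C"), value = 1))
  expect_true(all(all_eq$accessibility_pct == 100))
  expect_error(normalize_panel(data.frame(label = "A", value = 1)),
               "at least 2")
  expect_error(normalize_panel(data.frame(label = c("A", "B"),
                                          value = c(0, 0))),
               "zero")
})

test_that("state comparison classifies protection changes", {
  wt <- normalize_panel(data.frame(label = c("V71", "L72", "K100"),
                                   value = c(0.32, 0.012, 0.40), sd = 0))
  # V71 drops to 61% of its own panel scale, L72 rises to 35%
  mut <- normalize_panel(data.frame(label = c("V71", "L72", "K100"),
                                    value = c(0.2196, 0.126, 0.36), sd = 0))
  cmp <- compare_states(wt, mut)
  v71 <- cmp[cmp$label == "V71", ]
  expect_equal(v71$delta_pct, -19, tolerance = 0.01)
  expect_identical(v71$class, "protected")
  l72 <- cmp[cmp$label == "L72", ]
  expect_gt(l72$fold_change, 10)
  expect_identical(l72$class, "deprotected")

  same <- compare_states(wt, wt)
  expect_true(all(same$class == "no_change"))
  other <- normalize_panel(data.frame(label = c("X", "Y"), value = c(1, 2)))
  expect_error(compare_states(wt, other), "no residue labels")
})

test_that("accessibility is monotone in depth and tau-invariant (noiseless)", {
  depths <- c(R1 = 0.05, R2 = 0.15, R3 = 0.3, R4 = 0.6)
  vals <- lapply(c(205, 310), function(tau) {
    panel <- simulate_accessibility_panel(depths, fast_eseem(tau = tau))
    analyze_panel(panel, method = "fit")
  })
  for (np in vals) expect_false(is.unsorted(np$accessibility_pct))
  expect_equal(vals[[1]]$accessibility_pct, vals[[2]]$accessibility_pct,
               tolerance = 0.05)
})

test_that("recovered depth is robust to truncating the trace tail", {
  p <- fast_eseem(depth_k = 0.25, noise_sigma = 0.004, seed = 21)
  tr <- simulate_eseem_trace(p)
  full <- fit_modulation(correct_background(tr))$depth_k
  n <- length(tr$T)
  keep <- seq_len(floor(0.9 * n))
  tr_cut <- echo_trace(tr$T[keep], tr$amplitude[keep], tau = tr$tau,
                       nu = tr$nu)
  cut <- fit_modulation(correct_background(tr_cut))$depth_k
  expect_lt(abs(cut - full) / full, 0.02)
})
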
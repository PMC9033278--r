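test_that("uptake tables load, validate and count correctly", {
  p <- hdx_sim_params(sequence_length = 60,
                      peptide_set = tile_peptides(60, 11, 3),
                      seed = 3)
  tabs <- simulate_hdx_dataset(p)
  n_pep <- nrow(p$peptide_set)
  expect_equal(nrow(tabs$A), n_pep * 5 * 3)
  f <- tempfile(fileext = ".csv")
  write_uptake_table(rbind(tabs$A, tabs$B), f)
  back <- load_uptake_table(f)
  expect_equal(nrow(back), 2 * n_pep * 5 * 3)
  expect_s3_class(back, "peptide_uptake_table")

  bad <- tabs$A
  bad$start[1] <- 0
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_uptake_table(f), "1-based")

  dup <- tabs$A
  dup$replicate[2] <- dup$replicate[1]
  dup$exposure_min[2] <- dup$exposure_min[1]
  write.csv(dup, f, row.names = FALSE)
  expect_error(load_uptake_table(f), "duplicate")

  incomplete <- tabs$A[, -7]
  write.csv(incomplete, f, row.names = FALSE)
  expect_error(load_uptake_table(f), "missing column")
})

test_that("coverage statistics match direct counts", {
  mk <- function(peps, len) {
    tab <- do.call(rbind, lapply(seq_len(nrow(peps)), function(i)
      data.frame(peptide = "X", start = peps$start[i], end = peps$end[i],
                 state = "A", exposure_min = c(1, 1), replicate = 1:2,
                 uptake_Da = 1)))
    validate_uptake_table(tab, protein_length = len)
  }
  # tiling 1-115 of range 1-120: 95.8% with 5 residues uncovered
  tiled <- mk(tile_peptides(115, 10, 5), 120)
  cs <- coverage_stats(tiled, c(1, 120))
  expect_equal(cs$coverage_percent, 100 * 115 / 120, tolerance = 1e-10)
  expect_equal(cs$uncovered, 116:120)

  single <- mk(data.frame(start = 1, end = 120), 120)
  cs1 <- coverage_stats(single, c(1, 120))
  expect_equal(cs1$coverage_percent, 100)
  expect_equal(cs1$redundancy, 1.0)

  two <- mk(data.frame(start = c(1, 41), end = c(60, 120)), 120)
  expect_equal(coverage_stats(two, c(1, 120))$redundancy, (60 + 80) / 120)

  expect_error(coverage_stats(single, c(1, 200)), "outside")
})

test_that("identical states yield zero differences and no significance", {
  p <- hdx_sim_params(sequence_length = 60, seed = 9)
  tabs <- simulate_hdx_dataset(p)
  dr <- differential_uptake(tabs$A, tabs$A)
  expect_true(all(dr$summed_delta == 0))
  expect_true(all(dr$class == "not_significant"))
  # class is consistent with the threshold by construction
  expect_identical(abs(dr$summed_delta) > dr$threshold,
                   dr$class != "not_significant")
})

test_that("summed differences are antisymmetric and thresholds shrink with alpha", {
  p <- hdx_sim_params(sequence_length = 80,
                      deprotected_regions = list(c(30, 45, 5)), seed = 14)
  tabs <- simulate_hdx_dataset(p)
  ab <- differential_uptake(tabs$A, tabs$B)
  ba <- differential_uptake(tabs$B, tabs$A)
  expect_equal(ab$summed_delta, -ba$summed_delta)
  a05 <- differential_uptake(tabs$A, tabs$B, alpha = 0.05)
  expect_lte(attr(a05, "threshold"), attr(ab, "threshold"))
})

test_that("a planted deprotected region is classified correctly", {
  p <- hdx_sim_params(deprotected_regions = list(c(58, 69, 10)), seed = 31)
  tabs <- simulate_hdx_dataset(p)
  dr <- differential_uptake(tabs$A, tabs$B)
  wholly_inside <- dr$start >= 58 & dr$end <= 69 & dr$start < dr$end
  expect_true(all(dr$class[wholly_inside] == "deprotected"))
  disjoint <- dr$end < 58 | dr$start > 69
  expect_lt(mean(dr$class[disjoint] != "not_significant"), 0.05)
})

test_that("arithmetic of the summed difference", {
  # one peptide, constant +0.2 Da at each of 5 timepoints: summed 1.0 Da;
  # replicate spread chosen so the global threshold sits near 0.5 Da
  tps <- c(0.5, 1, 2, 10, 60)
  mk <- function(base, state) {
    do.call(rbind, lapply(tps, function(t)
      data.frame(peptide = "PEPTIDE", start = 10, end = 20, state = state,
                 exposure_min = t, replicate = 1:3,
                 uptake_Da = base[as.character(t)] + c(-0.1, 0, 0.1))))
  }
  a_means <- setNames(c(1, 2, 3, 4, 5), tps)
  ta <- validate_uptake_table(mk(a_means, "A"), 30)
  tb <- validate_uptake_table(mk(a_means + 0.2, "B"), 30)
  dr <- differential_uptake(ta, tb)
  expect_equal(dr$summed_delta, 1.0, tolerance = 1e-10)
  expect_lt(dr$threshold, 1.0)
  expect_identical(dr$class, "deprotected")
})

test_that("uptake curves summarise replicates", {
  p <- hdx_sim_params(sequence_length = 30,
                      peptide_set = data.frame(start = 1, end = 11),
                      noise_sd = 0, seed = 2)
  tabs <- simulate_hdx_dataset(p)
  uc <- uptake_curves(tabs$A, c(1, 11))
  expect_equal(nrow(uc), 5)
  expect_true(all(uc$sd == 0))
  expect_true(all(uc$n == 3))
  expect_false(is.unsorted(uc$mean))
  expect_equal(uc$mean[uc$exposure_min == 60],
               expected_uptake(10, 100, 10, 60))
  expect_error(uptake_curves(tabs$A, "NOSUCHPEPTIDE"), "not found")
})

test_that("planted regions map back to residues within 2 of their bounds", {
  p <- hdx_sim_params(deprotected_regions = list(c(37, 53, 10), c(58, 69, 10),
                                                 c(97, 111, 10)),
                      seed = 11)
  tabs <- simulate_hdx_dataset(p)
  mr <- map_regions(differential_uptake(tabs$A, tabs$B))
  expect_equal(nrow(mr$regions), 3)
  truth <- rbind(c(37, 53), c(58, 69), c(97, 111))
  for (i in 1:3) {
    expect_lte(abs(mr$regions$start[i] - truth[i, 1]), 2)
    expect_lte(abs(mr$regions$end[i] - truth[i, 2]), 2)
    expect_identical(mr$regions$class[i], "deprotected")
  }
  expect_true(all(mr$woods$class == "deprotected"))
})

test_that("region mapping degenerate cases", {
  p <- hdx_sim_params(sequence_length = 40, seed = 5)
  tabs <- simulate_hdx_dataset(p)
  dr <- differential_uptake(tabs$A, tabs$A)
  mr <- map_regions(dr)
  expect_equal(nrow(mr$regions), 0)

  # a single significant peptide maps to exactly its own span
  one <- dr[1, ]
  one$start <- 10; one$end <- 20
  one$summed_delta <- 5; one$class <- "deprotected"
  attr(one, "protein_length") <- attr(dr, "protein_length")
  mr1 <- map_regions(one)
  expect_equal(mr1$regions, data.frame(start = 10L, end = 20L,
                                       class = "deprotected"))
})
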
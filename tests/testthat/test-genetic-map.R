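test_that("map functions evaluate, invert and order correctly", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(haldane_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))

  r <- seq(0.001, 0.45, by = 0.001)
  expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-12)
  expect_equal(haldane_r(haldane_cm(r)), r, tolerance = 1e-12)
  expect_true(all(kosambi_cm(r) <= haldane_cm(r)))
  expect_true(all(diff(kosambi_cm(r)) > 0))

  # both converge to 100 r for small r
  expect_equal(kosambi_cm(1e-5) / (100 * 1e-5), 1, tolerance = 1e-6)
  expect_equal(haldane_cm(1e-5) / (100 * 1e-5), 1, tolerance = 1e-3)

  expect_error(kosambi_cm(0.5), "0 <= r < 0.5")
  expect_error(haldane_cm(-0.1), "0 <= r < 0.5")
})

test_that("recombination fractions follow the flanking-call rule with Wilson CIs", {
  markers <- make_markers(c(1e6, 2e6))
  calls <- rbind(matrix(rep(c("A", "H"), 10), ncol = 2, byrow = TRUE),
                 matrix(rep(c("A", "A"), 90), ncol = 2, byrow = TRUE))
  g <- make_genotypes(calls, markers)
  rf <- recombination_fraction(g, markers)
  expect_equal(rf$n_recombinant, 10)
  expect_equal(rf$n_informative, 100)
  expect_equal(rf$r, 0.10)

  # 0 of 50: Wilson upper limit 0.071
  g0 <- make_genotypes(matrix(rep(c("H", "H"), 50), ncol = 2, byrow = TRUE),
                       markers)
  rf0 <- recombination_fraction(g0, markers)
  expect_equal(rf0$r, 0)
  expect_equal(rf0$ci_low, 0)
  expect_equal(rf0$ci_high, 0.0714, tolerance = 1e-2)

  # missing flank for all plants: undefined, flagged
  gna <- make_genotypes(matrix(c(rep("A", 5), rep(NA, 5)), ncol = 2),
                        markers)
  rfna <- recombination_fraction(gna, markers)
  expect_true(rfna$undefined)
  expect_true(is.na(rfna$r))
})

test_that("genetic maps are additive over intervals and flag r >= 0.5", {
  markers <- make_markers(c(1e6, 2e6, 3e6))
  # 10 plants, interval 1 and 2 each with r = 0.1 (1/10)
  calls <- rbind(matrix(rep(c("A", "A", "A"), 9), ncol = 3, byrow = TRUE),
                 c("H", "A", "H"))
  g <- make_genotypes(calls, markers)
  gm <- build_genetic_map(g, markers)
  expect_equal(gm$intervals$r, c(0.1, 0.1))
  expect_equal(gm$genome_cm, 2 * kosambi_cm(0.1), tolerance = 1e-12)
  expect_equal(gm$chromosomes$total_cm, sum(gm$intervals$cm))

  # all identical: zero map
  g0 <- make_genotypes(matrix("A", 10, 3), markers)
  gm0 <- build_genetic_map(g0, markers)
  expect_true(all(gm0$intervals$cm == 0))
  expect_equal(gm0$genome_cm, 0)

  # r above one half is surfaced, not clamped
  calls_hot <- rbind(matrix(rep(c("A", "H", "A"), 8), ncol = 3, byrow = TRUE),
                     matrix(rep(c("A", "A", "A"), 2), ncol = 3, byrow = TRUE))
  gmh <- build_genetic_map(make_genotypes(calls_hot, markers), markers)
  expect_equal(gmh$intervals$r[1], 0.8)
  expect_true(gmh$intervals$r_out_of_range[1])
  expect_true(is.na(gmh$intervals$cm[1]))

  # haldane option gives larger distances
  gmH <- build_genetic_map(g, markers, map_function = "haldane")
  expect_gt(gmH$genome_cm, gm$genome_cm)
})

test_that("per-interval map distances are flat under a uniform landscape", {
  set.seed(31)
  devs <- replicate(20, {
    sim <- simulate_bc1_population(meiosis_sim_config(
      n_plants = 150, genotyping_error = 0, missing_rate = 0))
    gm <- build_genetic_map(sim$genotypes, sim$markers)
    iv <- gm$intervals
    rate <- iv$cm / (iv$length_bp / 1e6)
    (rate - mean(rate)) / (sd(rate) + 1e-12)
  })
  # no interval systematically deviates across replicates
  mean_dev <- rowMeans(devs)
  expect_true(all(abs(mean_dev) < 4 / sqrt(ncol(devs)) + 0.8))
})
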
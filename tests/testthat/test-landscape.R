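test_that("zero-rate landscapes never produce crossovers", {
  chr <- chromosome_spec("Chr1", 30e6, 15e6)
  model <- co_landscape("uniform", expected_events = 0)
  out <- sample_co_positions(model, chr, n = 20)
  expect_true(all(lengths(out) == 0))
  expect_error(
    sample_co_positions(co_landscape("uniform", expected_events = 0,
                                     obligate = TRUE), chr),
    "unsatisfiable")
})

test_that("uniform Poisson landscape matches the Poisson law", {
  chr <- chromosome_spec("Chr1", 30e6, 15e6)
  model <- co_landscape("uniform", expected_events = 2)
  set.seed(101)
  counts <- lengths(sample_co_positions(model, chr, n = 50000))
  # empirical mean within 3 standard errors of 2
  se <- sqrt(2 / 50000)
  expect_lt(abs(mean(counts) - 2), 3 * se)
  # chi-square goodness of fit against Poisson(2)
  kmax <- 8
  obs <- tabulate(pmin(counts, kmax) + 1, nbins = kmax + 1)
  p <- dpois(0:(kmax - 1), 2)
  p <- c(p, 1 - sum(p))
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.01)
  # positions stay inside the chromosome and sorted
  pos <- unlist(sample_co_positions(model, chr, n = 200))
  expect_true(all(pos > 0 & pos < chr$length_bp))
})

test_that("distal-exponential positions follow the analytic CDF", {
  # symmetric chromosome: centromere at the midpoint, rate b
  b <- 3
  chr <- chromosome_spec("Chr1", 30e6, 15e6)
  model <- co_landscape("distal_exponential", rate = b, expected_events = 1)
  set.seed(202)
  draws <- sample_co_positions(model, chr, n = 120000)
  x <- unlist(draws) / chr$length_bp
  expect_gt(length(x), 50000)
  # closed-form CDF of density prop to exp(b * |1 - 2t|) on [0, 1]
  total <- exp(b) * (1 - exp(-b)) / b
  cdf <- function(t) {
    left <- exp(b) * (1 - exp(-2 * b * pmin(t, 0.5))) / (2 * b)
    right <- ifelse(t > 0.5,
                    (exp(2 * b * (t - 0.5)) - 1) / (2 * b), 0)
    (left + right) / total
  }
  ks <- suppressWarnings(ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
  # density rises towards both ends
  expect_gt(mean(x < 0.05 | x > 0.95), mean(x > 0.45 & x < 0.55))
})

test_that("gamma-renewal interference keeps the mean and reduces the Fano factor", {
  chr <- chromosome_spec("Chr1", 30e6, 15e6)
  model <- co_landscape("uniform", expected_events = 2, interference_nu = 8)
  set.seed(303)
  counts <- lengths(sample_co_positions(model, chr, n = 8000))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2), 4 * se)
  expect_lt(var(counts) / mean(counts), 0.95)  # sub-Poisson dispersion
})

test_that("obligate sampling enforces at least one crossover and landscape validation works", {
  chr <- chromosome_spec("Chr1", 30e6, 15e6)
  model <- co_landscape("uniform", expected_events = 0.5, obligate = TRUE)
  set.seed(404)
  counts <- lengths(sample_co_positions(model, chr, n = 500))
  expect_true(all(counts >= 1))
  expect_error(co_landscape("piecewise", breaks = c(0, 1), heights = -1),
               "non-negative")
  expect_error(co_landscape("piecewise", breaks = c(0, 0.5),
                            heights = 1), "breaks")
  expect_error(co_landscape("uniform", expected_events = -1))
  expect_error(co_landscape("uniform", interference_nu = 0.5))
  expect_error(chromosome_spec("c", 100, 200), "centromere")
})

test_that("piecewise landscapes concentrate mass where the table says", {
  chr <- chromosome_spec("Chr1", 10e6, 5e6)
  model <- co_landscape("piecewise", breaks = c(0, 0.5, 1),
                        heights = c(0, 1), expected_events = 1)
  set.seed(505)
  pos <- unlist(sample_co_positions(model, chr, n = 2000))
  expect_true(all(pos / chr$length_bp >= 0.498))
})
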
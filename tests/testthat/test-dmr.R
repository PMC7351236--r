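# dml rows with chosen positions, p-values and pooled counts
make_dml <- function(pos, p, diff = 0.3, context = "CHH",
                     base = 0.1, cov = 100) {
  lvl_b <- base + diff
  tibble::tibble(
    chrom = "chr1", pos = pos, strand = "+", context = context,
    n_meth_a = round(base * cov), n_total_a = cov,
    n_meth_b = round(lvl_b * cov), n_total_b = cov,
    level_a = base, level_b = lvl_b, diff = lvl_b - base,
    p_value = p
  )
}

test_that("a qualifying run of significant sites yields exactly one hyper DMR", {
  dml <- make_dml(pos = c(10, 30, 50, 70, 90), p = rep(1e-6, 5))
  dmrs <- call_dmrs(dml, "CHH")
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$start, 10)
  expect_equal(dmrs$end, 90)
  expect_equal(dmrs$n_dml, 5L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$mean_diff, 0.3, tolerance = 1e-12)
})

test_that("the span rule rejects runs of 50 bp or less", {
  dml <- make_dml(pos = c(10, 20, 30, 40, 50), p = rep(1e-6, 5))
  expect_equal(nrow(call_dmrs(dml, "CHH")), 0L)   # span 41 <= 50
  dml2 <- make_dml(pos = c(10, 20, 30, 40, 61), p = rep(1e-6, 5))
  expect_equal(nrow(call_dmrs(dml2, "CHH")), 1L)  # span 52 > 50
})

test_that("minimum DML count and significant fraction are enforced", {
  dml <- make_dml(pos = c(10, 60, 120), p = c(1e-6, 1e-6, 1))
  expect_equal(nrow(call_dmrs(dml, "CHH")), 0L)   # only 2 significant loci
  # 3 significant loci among interspersed nulls, fraction must stay > 1/2
  dml2 <- make_dml(pos = seq(10, 130, by = 20),
                   p = c(1e-6, 1, 1e-6, 1, 1e-6, 1, 1))
  dmrs2 <- call_dmrs(dml2, "CHH")
  expect_equal(nrow(dmrs2), 1L)
  expect_equal(dmrs2$n_dml, 3L)
  expect_equal(dmrs2$frac_sig, 3 / 5)
})

test_that("nearby same-direction regions merge, distant ones stay separate", {
  cluster <- function(at, p = 1e-6) make_dml(pos = at, p = rep(p, length(at)))
  gapsites <- function(at) make_dml(pos = at, p = rep(1, length(at)),
                                    diff = 0)
  c1 <- c(20, 40, 60, 80, 100)
  between <- seq(102, 124, by = 2)
  near <- dplyr::arrange(dplyr::bind_rows(
    cluster(c1), gapsites(between), cluster(c1 + 110)), pos)
  dm_near <- call_dmrs(near, "CHH")
  expect_equal(nrow(dm_near), 1L)          # 29 bp apart < 50: merged
  expect_equal(dm_near$start, 20)
  expect_equal(dm_near$end, 210)
  expect_equal(dm_near$n_dml, 10L)

  far <- dplyr::arrange(dplyr::bind_rows(
    cluster(c1), gapsites(between), cluster(c1 + 141)), pos)
  dm_far <- call_dmrs(far, "CHH")
  expect_equal(nrow(dm_far), 2L)           # 60 bp apart: separate

  # opposite directions never merge
  opp <- dplyr::arrange(dplyr::bind_rows(
    cluster(c1), make_dml(pos = c1 + 110, p = rep(1e-6, 5), diff = -0.3)),
    pos)
  expect_equal(nrow(call_dmrs(opp, "CHH")), 2L)
})

test_that("per-context effect-size cutoffs separate CHH, CHG and CG calls", {
  pos <- c(10, 30, 50, 70, 90)
  for (spec in list(list(ctx = "CHH", lo = 0.05, hi = 0.15),
                    list(ctx = "CHG", lo = 0.15, hi = 0.25),
                    list(ctx = "CG", lo = 0.25, hi = 0.35))) {
    weak <- make_dml(pos, rep(1e-6, 5), diff = spec$lo, context = spec$ctx)
    strong <- make_dml(pos, rep(1e-6, 5), diff = spec$hi, context = spec$ctx)
    expect_equal(nrow(call_dmrs(weak, spec$ctx)), 0L)
    expect_equal(nrow(call_dmrs(strong, spec$ctx)), 1L)
  }
  # hypo direction
  hypo <- make_dml(pos, rep(1e-6, 5), diff = -0.3, base = 0.5)
  expect_equal(call_dmrs(hypo, "CHH")$direction, "hypo")
  expect_equal(nrow(call_dmrs(make_dml(pos, rep(1e-6, 5))[0, ], "CHH")), 0L)
})

test_that("relaxing thresholds never removes DMRs on a fixed input", {
  set.seed(91)
  n <- 400
  pos <- sort(sample.int(20000, n))
  sig <- runif(n) < 0.35
  dml <- make_dml(pos, p = ifelse(sig, 1e-6, runif(n, 0.1, 1)),
                  diff = 0.22)
  base_n <- nrow(call_dmrs(dml, "CHH"))
  expect_gte(nrow(call_dmrs(dml, "CHH", diff_cutoff = c(CHH = 0.05))),
             base_n)
  expect_gte(nrow(call_dmrs(dml, "CHH", min_dml = 2)), base_n)
  expect_gte(nrow(call_dmrs(dml, "CHH", min_len = 25)), base_n)
})

test_that("interval overlap fractions match the all-pairs oracle", {
  a <- tibble::tibble(chrom = "c", start = c(1, 100), end = c(10, 120))
  expect_equal(overlap_fraction(a, a)$fraction, 1)
  b <- tibble::tibble(chrom = "c", start = c(200, 400), end = c(210, 420))
  expect_equal(overlap_fraction(a, b)$fraction, 0)
  expect_warning(res <- overlap_fraction(a[0, ], b), "empty")
  expect_true(is.na(res$fraction))

  set.seed(92)
  ra <- tibble::tibble(chrom = sample(c("c1", "c2"), 300, TRUE),
                       start = sample.int(5000, 300))
  ra$end <- ra$start + sample.int(80, 300, replace = TRUE)
  rb <- tibble::tibble(chrom = sample(c("c1", "c2"), 300, TRUE),
                       start = sample.int(5000, 300))
  rb$end <- rb$start + sample.int(80, 300, replace = TRUE)
  expect_equal(overlap_fraction(ra, rb)$fraction, oracle_overlap(ra, rb))
})

test_that("recovery metrics score direction- and context-matched hits", {
  truth <- tibble::tibble(chrom = "chr1", start = c(100, 500),
                          end = c(200, 700), context = "CHH",
                          direction = "hyper")
  called <- dplyr::mutate(truth, mean_diff = 0.3)
  m <- dmr_recovery_metrics(called, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  none <- dmr_recovery_metrics(called[0, ], truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  wrong_dir <- dplyr::mutate(called, direction = "hypo")
  m2 <- dmr_recovery_metrics(wrong_dir, truth)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)
})
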
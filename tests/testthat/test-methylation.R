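make_report <- function(pos, n_meth, n_total, context = "CG",
                        strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                 context = context, n_meth = n_meth, n_total = n_total)
}

test_that("coverage filtering keeps >= min_total and conserves sites", {
  rep <- make_report(1:6, 0, c(0, 4, 5, 6, 2, 50))
  filt <- filter_coverage(rep, min_total = 5)
  expect_equal(filt$pos, c(3, 4, 6))
  expect_equal(nrow(filt) + sum(attr(filt, "n_removed")$n_removed),
               nrow(rep))
  expect_equal(nrow(filter_coverage(rep, min_total = 0)), nrow(rep))
  expect_warning(filter_coverage(rep, min_total = 100), "no sites")
})

test_that("tile levels are count-weighted and conserve genome-wide totals", {
  rep <- make_report(c(100, 200), c(2, 3), c(10, 10))
  tiles <- tile_methylation(rep, tile_bp = 1000)
  expect_equal(tiles$level, 0.25)

  rep2 <- make_report(c(100, 1100, 2100), c(5, 7, 9), c(5, 7, 9))
  tiles2 <- tile_methylation(rep2, tile_bp = 1000)
  expect_true(all(tiles2$level == 1))

  set.seed(72)
  big <- make_report(sample.int(50000, 3000), rbinom(3000, 20, 0.3),
                     20, context = sample(c("CG", "CHH"), 3000, TRUE))
  tiles3 <- tile_methylation(big, tile_bp = 7000)
  expect_equal(sum(tiles3$n_meth), sum(big$n_meth))
  expect_equal(sum(tiles3$n_total), sum(big$n_total))
  expect_error(tile_methylation(big, tile_bp = 0), "positive")
})

test_that("empty tiles appear when chromosome lengths are supplied", {
  rep <- make_report(c(100, 5100), c(1, 1), c(2, 2))
  tiles <- tile_methylation(rep, tile_bp = 1000,
                            chrom_lengths = tibble::tibble(chrom = "chr1",
                                                           length_bp = 8000))
  expect_equal(nrow(tiles), 8)
  expect_true(is.na(tiles$level[2]))
  expect_equal(tiles$n_sites[c(1, 6)], c(1L, 1L))
})

test_that("metagene profiles are flat for a constant methylome", {
  set.seed(73)
  ann <- tibble::tibble(chrom = "chr1", start = c(2001, 7001),
                        end = c(4000, 9500), strand = c("+", "-"),
                        class = "gene")
  rep <- make_report(seq(1, 12000, by = 7), 3, 10, context = "CG")
  prof <- metagene_profile(rep, ann, "gene", "CG")
  expect_true(all(abs(prof$level[prof$n_total > 0] - 0.3) < 1e-12))
  expect_equal(nrow(prof), 10 + 20 + 10)
})

test_that("a half-methylated feature maps onto the correct body bins", {
  ann <- tibble::tibble(chrom = "chr1", start = 1001, end = 3000,
                        strand = "+", class = "gene")
  pos <- seq(1001, 3000, by = 10)
  level <- ifelse(pos < 2001, 10, 0)
  rep <- make_report(pos, level, 10, context = "CG")
  prof <- metagene_profile(rep, ann, "gene", "CG")
  body <- prof[prof$region == "body", ]
  expect_equal(body$level[body$bin <= 10], rep(1, 10))
  expect_equal(body$level[body$bin > 10], rep(0, 10))

  # reversing the strand mirrors the body profile
  ann_m <- dplyr::mutate(ann, strand = "-")
  prof_m <- metagene_profile(rep, ann_m, "gene", "CG")
  body_m <- prof_m[prof_m$region == "body", ]
  expect_equal(body_m$level, rev(body$level))
})

test_that("short features contribute flanks only and are counted", {
  ann <- tibble::tibble(chrom = "chr1", start = 5001, end = 5010,
                        strand = "+", class = "TE")
  rep <- make_report(seq(4001, 6010, by = 3), 5, 10, context = "CHH")
  prof <- metagene_profile(rep, ann, "TE", "CHH")
  expect_equal(attr(prof, "n_short_features"), 1L)
  expect_true(all(prof$n_sites[prof$region == "body"] == 0))
  expect_true(any(prof$n_sites[prof$region == "upstream"] > 0))
})

test_that("complementary CG pairs merge onto the plus strand", {
  rep <- tibble::tibble(
    chrom = "chr1", pos = c(5L, 6L, 20L, 30L),
    strand = c("+", "-", "+", "-"),
    context = c("CG", "CG", "CG", "CHG"),
    n_meth = c(2L, 3L, 1L, 4L), n_total = c(10L, 10L, 5L, 8L))
  m <- merge_cg_strands(rep)
  cg5 <- m[m$pos == 5, ]
  expect_equal(nrow(cg5), 1L)
  expect_equal(cg5$n_meth, 5L)
  expect_equal(cg5$n_total, 20L)
  expect_equal(cg5$strand, "+")
  # unpaired CG and non-CG rows pass through
  expect_equal(m[m$pos == 20, ]$n_total, 5L)
  expect_equal(m[m$pos == 30, ]$context, "CHG")
  # counts conserved
  expect_equal(sum(m$n_meth), sum(rep$n_meth))
})

test_that("site-mean tile levels differ from weighted where coverage varies", {
  rep <- make_report(c(100, 200), c(0, 9), c(90, 10))
  w <- tile_methylation(rep, tile_bp = 1000)
  s <- tile_methylation(rep, tile_bp = 1000, level_type = "site_mean")
  expect_equal(w$level, 9 / 100)
  expect_equal(s$level, mean(c(0, 0.9)))
})

test_that("fixed-bp body bins track absolute position from the 5' end", {
  ann <- tibble::tibble(chrom = "chr1", start = 1001, end = 3000,
                        strand = "+", class = "gene")
  pos <- seq(1001, 3000, by = 10)
  rep <- make_report(pos, ifelse(pos < 1101, 10, 0), 10, context = "CG")
  prof <- metagene_profile(rep, ann, "gene", "CG", body_mode = "fixed_bp")
  body <- prof[prof$region == "body", ]
  expect_equal(body$level[1], 1)          # first 100 bp fully methylated
  expect_true(all(body$level[-1] == 0))
})
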
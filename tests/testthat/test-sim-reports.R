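small_cfg <- function(...) {
  methylome_sim_config(genome_length_bp = 4e4, n_genes = 3, n_tes = 3,
                       gene_length = c(800, 1500), te_length = c(800, 1500),
                       ...)
}

test_that("zero coverage still lists every site", {
  sim <- simulate_cytosine_reports(small_cfg(mean_coverage = 0, seed = 1))
  expect_true(all(sim$reports$n_total == 0))
  expect_gt(nrow(sim$reports), 0)
  # one row per site per replicate per genotype
  n_sites <- nrow(annotate_contexts(sim$genome))
  expect_equal(nrow(sim$reports), n_sites * 2 * sim$config$n_replicates)
})

test_that("pooled levels land within binomial error of the configured levels", {
  cfg <- methylome_sim_config(
    genome_length_bp = 3e5, n_genes = 20, n_tes = 20,
    gene_length = c(1500, 2500), te_length = c(1500, 2500),
    base_levels = list(gene = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                       TE = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                       intergenic = c(CG = 0.5, CHG = 0.5, CHH = 0.5)),
    te_deltas = c(CG = 0, CHG = 0, CHH = 0.30),
    mean_coverage = 50, n_replicates = 1, seed = 2)
  sim <- simulate_cytosine_reports(cfg)
  te <- sim$annotation[sim$annotation$class == "TE", ]
  gene <- sim$annotation[sim$annotation$class == "gene", ]
  mut <- sim$reports[sim$reports$genotype == "mut" &
                       sim$reports$context == "CHH", ]
  in_set <- function(pos, feats) {
    !is.na(meioscape:::interval_match(pos, feats$start, feats$end))
  }
  pool_level <- function(x) sum(x$n_meth) / sum(x$n_total)
  te_sites <- mut[in_set(mut$pos, te), ]
  gene_sites <- mut[in_set(mut$pos, gene), ]
  expect_gt(nrow(te_sites), 5000)
  se_te <- sqrt(0.35 * 0.65 / sum(te_sites$n_total))
  se_gene <- sqrt(0.05 * 0.95 / sum(gene_sites$n_total))
  expect_lt(abs(pool_level(te_sites) - 0.35), 3 * se_te)
  expect_lt(abs(pool_level(gene_sites) - 0.05), 3 * se_gene)
})

test_that("identical seeds give identical reports and truth", {
  s1 <- simulate_cytosine_reports(small_cfg(seed = 3))
  s2 <- simulate_cytosine_reports(small_cfg(seed = 3))
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$genome, s2$genome)
})

test_that("emitted report contexts equal an independent scan of the emitted genome", {
  sim <- simulate_cytosine_reports(small_cfg(seed = 4))
  got <- dplyr::distinct(sim$reports[, c("chrom", "pos", "strand",
                                         "context")])
  got <- dplyr::arrange(got, .data$pos, .data$strand)
  want <- oracle_context_scan(sim$genome[["chr1"]])
  expect_equal(got$pos, want$pos)
  expect_equal(got$strand, want$strand)
  expect_equal(got$context, want$context)
})

test_that("planted truth covers TE extents and flags clamped plateaus", {
  sim <- simulate_cytosine_reports(small_cfg(
    te_deltas = c(CG = 0.5, CHG = 0, CHH = 0.06), seed = 5))
  te <- sim$annotation[sim$annotation$class == "TE", ]
  cg <- sim$truth[sim$truth$context == "CG", ]
  expect_equal(nrow(cg), nrow(te))
  expect_equal(sort(cg$start), sort(te$start))
  expect_true(all(cg$clamped))        # 0.80 + 0.5 saturates at 1
  chh <- sim$truth[sim$truth$context == "CHH", ]
  expect_true(all(!chh$clamped))
  expect_false(any(sim$truth$context == "CHG"))  # zero delta, no planting
  expect_true(all(sim$truth$direction == "hyper"))
})

test_that("feature placement is non-overlapping and in bounds", {
  sim <- simulate_cytosine_reports(small_cfg(seed = 6))
  ann <- dplyr::arrange(sim$annotation, .data$start)
  expect_true(all(ann$start >= 1))
  expect_true(all(ann$end <= sim$config$genome_length_bp))
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(utils::head(ann$end, -1) < utils::tail(ann$start, -1)))
})
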
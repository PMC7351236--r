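# Vectorised two-sided Fisher exact p-values for 2x2 tables
# (meth/unmeth x genotype). Enumerates the hypergeometric support and sums
# all outcomes no more probable than the observed one, the same two-sided
# rule as stats::fisher.test.
fisher_p_twosided <- function(m1, t1, m2, t2) {
  K <- m1 + m2
  lo <- pmax(0, K - t2)
  hi <- pmin(K, t1)
  width <- hi - lo + 1
  idx <- rep.int(seq_along(K), width)
  x <- sequence(width) - 1 + lo[idx]
  d <- stats::dhyper(x, t1[idx], t2[idx], K[idx])
  dobs <- stats::dhyper(m1, t1, t2, K)
  contrib <- d * (d <= dobs[idx] * (1 + 1e-7))
  p <- as.vector(rowsum(contrib, idx, reorder = TRUE))
  pmin(p, 1)
}

#' Per-site differential methylation tests
#'
#' Pools methylated and total counts across replicates within each genotype,
#' then tests every cytosine present in both genotypes with a two-sided
#' Fisher exact test on the 2x2 table (methylated / unmethylated counts by
#' genotype). The reported difference is the pooled level in the second
#' (mutant) genotype minus the first.
#'
#' @param report_a,report_b Cytosine report tibbles for the reference and
#'   comparison genotype (replicates stacked; columns `chrom`, `pos`,
#'   `strand`, `context`, `n_meth`, `n_total`).
#' @param context Optional context restriction (`"CG"`, `"CHG"`, `"CHH"`).
#' @return A tibble with one row per common site: `chrom`, `pos`, `strand`,
#'   `context`, `n_meth_a`, `n_total_a`, `n_meth_b`, `n_total_b`, `level_a`,
#'   `level_b`, `diff` (`level_b - level_a`), `p_value`. The number of sites
#'   present in only one genotype is attached as attribute `"n_skipped"`.
#' @export
dml_test <- function(report_a, report_b, context = NULL) {
  pool <- function(rep) {
    if (!is.null(context)) rep <- rep[rep$context %in% context, ]
    id <- vctrs::vec_group_id(rep[c("chrom", "pos", "strand", "context")])
    first <- !duplicated(id)
    out <- rep[first, c("chrom", "pos", "strand", "context")]
    out$n_meth <- as.vector(rowsum(rep$n_meth, id))
    out$n_total <- as.vector(rowsum(rep$n_total, id))
    out
  }
  a <- pool(report_a)
  b <- pool(report_b)
  keys <- c("chrom", "pos", "strand", "context")
  merged <- dplyr::inner_join(a, b, by = keys, suffix = c("_a", "_b"))
  merged <- merged[merged$n_total_a > 0 & merged$n_total_b > 0, ]
  n_skipped <- nrow(a) + nrow(b) - 2L * nrow(merged)
  merged <- dplyr::arrange(merged, .data$chrom, .data$pos, .data$strand)
  merged$level_a <- merged$n_meth_a / merged$n_total_a
  merged$level_b <- merged$n_meth_b / merged$n_total_b
  merged$diff <- merged$level_b - merged$level_a
  merged$p_value <- if (nrow(merged)) {
    fisher_p_twosided(merged$n_meth_a, merged$n_total_a,
                      merged$n_meth_b, merged$n_total_b)
  } else numeric(0)
  attr(merged, "n_skipped") <- n_skipped
  merged
}
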
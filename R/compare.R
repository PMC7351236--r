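#' Two-stage Benjamini-Krieger-Yekutieli FDR adjustment
#'
#' Adaptive two-stage linear step-up procedure controlling the false
#' discovery rate at level `q`: stage 1 applies Benjamini-Hochberg at
#' `q' = q / (1 + q)`; with `r1` stage-1 rejections the number of true nulls
#' is estimated as `m0 = m - r1`; if `r1 = 0` nothing is rejected, if
#' `m0 = 0` everything is; otherwise stage 2 re-runs Benjamini-Hochberg on
#' the original p-values at level `q' * m / m0`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (no `NA`).
#' @param q Target FDR level in `(0, 1)`.
#' @return Logical vector of rejection flags, same length as `pvalues`.
#' @export
#' @examples
#' bky_adjust(c(0.0001, 0.003, 0.4, 0.9), q = 0.05)
bky_adjust <- function(pvalues, q) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  m <- length(pvalues)
  bh_reject <- function(p, alpha) {
    o <- order(p)
    below <- which(p[o] <= alpha * seq_len(m) / m)
    rej <- logical(m)
    if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  stage1 <- bh_reject(pvalues, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  bh_reject(pvalues, q1 * m / m0)
}

# Welch t-test on two samples of 0/1 indicators, robust to zero variance.
welch_binary_p <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  v1 <- p1 * (1 - p1) * n1 / (n1 - 1)   # sample variance of 0/1 data
  v2 <- p2 * (1 - p2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (p1 == p2) 1 else 0)
  tstat <- (p1 - p2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Two-proportion z-test (pooled), the asymptotic twin of the Welch test.
prop_z_p <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se2 <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (se2 == 0) return(if (p1 == p2) 1 else 0)
  2 * stats::pnorm(-abs((p1 - p2) / sqrt(se2)))
}

#' Compare interval crossover rates between two populations
#'
#' For every consecutive-marker interval, tests the per-plant recombination
#' indicator (0/1: flanking calls differ) between the two populations with a
#' two-sided Welch t-test (a two-proportion z-test is available via
#' `method`), then flags significant intervals with the two-stage
#' Benjamini-Krieger-Yekutieli procedure at FDR level `Q`. The FDR family is
#' all testable intervals across all chromosomes jointly; intervals with no
#' informative plants in either population are excluded from the family and
#' flagged.
#'
#' @param genotypes_a,genotypes_b Genotype tibbles for the two populations
#'   (e.g. wild type and mutant), sharing the same marker map.
#' @param markers Marker map tibble.
#' @param q FDR level for the BKY procedure.
#' @param method `"welch"` (default) or `"prop"` (two-proportion z).
#' @param labels Length-2 character vector naming the populations.
#' @return A tibble with one row per interval: positions, `r_a`, `r_b`,
#'   `n_informative_a`, `n_informative_b`, `p_value`, `excluded`,
#'   `significant` (BKY flag at level `q`), and `direction`
#'   (`"increased"` / `"decreased"` in population b where significant).
#' @export
compare_maps <- function(genotypes_a, genotypes_b, markers, q = 0.01,
                         method = c("welch", "prop"),
                         labels = c("a", "b")) {
  method <- match.arg(method)
  ra <- recombination_fraction(genotypes_a, markers)
  rb <- recombination_fraction(genotypes_b, markers)
  stopifnot(nrow(ra) == nrow(rb))
  test_fun <- if (method == "welch") welch_binary_p else prop_z_p
  out <- dplyr::select(ra, "chrom", "left_marker", "right_marker",
                       "left_bp", "right_bp", "mid_bp", "length_bp")
  out$r_a <- ra$r
  out$r_b <- rb$r
  out$n_informative_a <- ra$n_informative
  out$n_informative_b <- rb$n_informative
  out$excluded <- ra$undefined | rb$undefined
  out$p_value <- NA_real_
  idx <- which(!out$excluded)
  out$p_value[idx] <- vapply(idx, function(i) {
    test_fun(ra$n_recombinant[i], ra$n_informative[i],
             rb$n_recombinant[i], rb$n_informative[i])
  }, numeric(1))
  out$significant <- FALSE
  out$significant[idx] <- bky_adjust(out$p_value[idx], q)
  out$direction <- dplyr::case_when(
    !out$significant ~ NA_character_,
    out$r_b > out$r_a ~ "increased",
    out$r_b < out$r_a ~ "decreased",
    TRUE ~ NA_character_
  )
  attr(out, "q") <- q
  attr(out, "method") <- method
  attr(out, "labels") <- labels
  out
}

#' Pearson chi-square test of homogeneity for a count table
#'
#' Thin wrapper around [stats::chisq.test()] (no continuity correction) that
#' drops zero-margin rows and columns and warns when any expected cell falls
#' below 1.
#'
#' @param counts Matrix (or coercible) of non-negative integer counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_counts(rbind(c(10, 0), c(0, 10)))
chi_square_counts <- function(counts) {
  tab <- as.matrix(counts)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table degenerate after dropping zero margins", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-square approximation is poor")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}
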
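#' Call differentially methylated regions
#'
#' Builds candidate segments from per-site tests of one context, then applies
#' the DMR rule chain:
#' \enumerate{
#'   \item Greedy left-to-right segmentation: a segment opens at a
#'     significant site (`p < p_thresh`) and is extended to each subsequent
#'     significant site of the same difference sign as long as the fraction
#'     of significant sites over the spanned run stays above `min_frac_sig`;
#'     intervening non-significant sites are absorbed, never seeds.
#'   \item Candidates must span more than `min_len` bp
#'     (`end - start + 1 > min_len`) and contain at least `min_dml`
#'     significant loci.
#'   \item Surviving same-direction candidates separated by fewer than
#'     `merge_gap` bp are merged and re-scored over all sites in the merged
#'     span.
#'   \item Regions must show at least the per-context weighted methylation
#'     difference: `diff_cutoff` defaults to 10% for CHH, 20% for CHG, 30%
#'     for CG.
#' }
#'
#' @param dml Output of [dml_test()] for a single context.
#' @param context Context being called (must match the `context` column).
#' @param p_thresh Per-site significance threshold (default `1e-4`).
#' @param min_len Minimum region span in bp, exclusive (default 50).
#' @param min_dml Minimum number of significant loci (default 3, inclusive).
#' @param min_frac_sig Minimum fraction of significant sites, exclusive
#'   (default 0.5).
#' @param merge_gap Maximum gap (bp, exclusive) between merged regions
#'   (default 50).
#' @param diff_cutoff Named per-context cutoffs on `abs(mean_diff)`.
#' @return A tibble of DMRs: `chrom`, `start`, `end` (1-based inclusive),
#'   `context`, `n_sites`, `n_dml`, `frac_sig`, `mean_diff` (pooled weighted
#'   difference, genotype b minus a), `direction` (`"hyper"`/`"hypo"`).
#' @export
call_dmrs <- function(dml, context,
                      p_thresh = 1e-4, min_len = 50, min_dml = 3,
                      min_frac_sig = 0.5, merge_gap = 50,
                      diff_cutoff = c(CHH = 0.10, CHG = 0.20, CG = 0.30)) {
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), context = character(0),
                          n_sites = integer(0), n_dml = integer(0),
                          frac_sig = numeric(0), mean_diff = numeric(0),
                          direction = character(0))
  if (nrow(dml) == 0) return(empty)
  dml <- dml[dml$context == context, ]
  if (nrow(dml) == 0) return(empty)
  cutoff <- diff_cutoff[[context]]

  score_segment <- function(d, i, j) {
    idx <- i:j
    sig <- d$p_value[idx] < p_thresh
    tibble::tibble(
      chrom = d$chrom[i], start = d$pos[i], end = d$pos[j],
      context = context, n_sites = length(idx), n_dml = sum(sig),
      frac_sig = mean(sig),
      mean_diff = sum(d$n_meth_b[idx]) / sum(d$n_total_b[idx]) -
        sum(d$n_meth_a[idx]) / sum(d$n_total_a[idx]),
      i = i, j = j
    )
  }

  per_chrom <- lapply(split(dml, dml$chrom), function(d) {
    d <- dplyr::arrange(d, .data$pos, .data$strand)
    sig_idx <- which(d$p_value < p_thresh)
    if (length(sig_idx) == 0) return(NULL)
    sgn <- sign(d$diff)
    segs <- list()
    s <- sig_idx[1]
    e <- s
    n_sig <- 1L
    cur_sign <- sgn[s]
    if (length(sig_idx) > 1) {
      for (j in sig_idx[-1]) {
        frac_new <- (n_sig + 1L) / (j - s + 1L)
        if (sgn[j] == cur_sign && frac_new > min_frac_sig) {
          e <- j
          n_sig <- n_sig + 1L
        } else {
          segs[[length(segs) + 1L]] <- c(s, e)
          s <- j
          e <- j
          n_sig <- 1L
          cur_sign <- sgn[j]
        }
      }
    }
    segs[[length(segs) + 1L]] <- c(s, e)
    cand <- purrr::map_dfr(segs, function(se) score_segment(d, se[1], se[2]))
    cand <- cand[(cand$end - cand$start + 1) > min_len &
                   cand$n_dml >= min_dml, ]
    if (nrow(cand) == 0) return(NULL)

    # merge same-direction candidates separated by < merge_gap bp
    cand$dir <- ifelse(cand$mean_diff > 0, "hyper", "hypo")
    merged <- list()
    cur <- cand[1, ]
    if (nrow(cand) > 1) {
      for (k in 2:nrow(cand)) {
        nxt <- cand[k, ]
        gap <- nxt$start - cur$end - 1
        if (nxt$dir == cur$dir && gap < merge_gap) {
          resc <- score_segment(d, cur$i, nxt$j)
          resc$dir <- cur$dir
          cur <- resc
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- nxt
        }
      }
    }
    merged[[length(merged) + 1L]] <- cur
    dplyr::bind_rows(merged)
  })
  out <- dplyr::bind_rows(per_chrom)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[abs(out$mean_diff) >= cutoff, ]
  if (nrow(out) == 0) return(empty)
  out$direction <- ifelse(out$mean_diff > 0, "hyper", "hypo")
  out$dir <- NULL
  out$i <- NULL
  out$j <- NULL
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Fraction of one interval set overlapping another
#'
#' An interval of `a` "overlaps" `b` when it shares at least one base pair
#' with any interval of `b`. Overlap detection uses an interval tree
#' ([IRanges::findOverlaps()]) per chromosome.
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end` (1-based
#'   inclusive, same coordinate system).
#' @return A one-row tibble: `n_overlapping`, `n_total`, `fraction`
#'   (`NA` with a warning when `a` is empty).
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "c", start = c(1, 100), end = c(10, 120))
#' overlap_fraction(a, a)
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0) {
    warning("empty query interval set; overlap fraction undefined")
    return(tibble::tibble(n_overlapping = 0L, n_total = 0L,
                          fraction = NA_real_))
  }
  hit <- rep(FALSE, nrow(a))
  if (nrow(b) > 0) {
    for (ch in unique(a$chrom)) {
      ia <- which(a$chrom == ch)
      ib <- which(b$chrom == ch)
      if (length(ib) == 0) next
      qr <- IRanges::IRanges(start = a$start[ia], end = a$end[ia])
      sr <- IRanges::IRanges(start = b$start[ib], end = b$end[ib])
      ov <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
      hit[ia[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
  }
  tibble::tibble(n_overlapping = sum(hit), n_total = nrow(a),
                 fraction = sum(hit) / nrow(a))
}

#' Precision and recall of called DMRs against planted truth
#'
#' A planted region is recovered when at least one called DMR of the same
#' context and direction shares at least one base pair with it; a called DMR
#' is a true positive when it hits at least one planted region of matching
#' context and direction.
#'
#' @param called DMR tibble from [call_dmrs()].
#' @param truth Planted-DMR tibble (e.g. `simulate_cytosine_reports()$truth`)
#'   with `chrom`, `start`, `end`, `context`, `direction`.
#' @return A one-row tibble: `n_called`, `n_truth`, `precision` (`NA` when
#'   nothing was called), `recall`.
#' @export
dmr_recovery_metrics <- function(called, truth) {
  match_one <- function(x, y) {
    # per (context, direction) stratum
    strata <- dplyr::distinct(x[, c("context", "direction")])
    hits <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(strata))) {
      xi <- x$context == strata$context[i] & x$direction == strata$direction[i]
      yi <- y$context == strata$context[i] & y$direction == strata$direction[i]
      if (!any(yi)) next
      for (ch in unique(x$chrom[xi])) {
        ia <- which(xi & x$chrom == ch)
        ib <- which(yi & y$chrom == ch)
        if (length(ib) == 0) next
        qr <- IRanges::IRanges(x$start[ia], x$end[ia])
        sr <- IRanges::IRanges(y$start[ib], y$end[ib])
        fo <- IRanges::findOverlaps(qr, sr)
        hits[ia[unique(S4Vectors::queryHits(fo))]] <- TRUE
      }
    }
    hits
  }
  n_called <- nrow(called)
  n_truth <- nrow(truth)
  precision <- if (n_called == 0) NA_real_ else
    mean(match_one(called, truth))
  recall <- if (n_truth == 0) NA_real_ else
    mean(match_one(truth, called))
  tibble::tibble(n_called = n_called, n_truth = n_truth,
                 precision = precision, recall = recall)
}
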
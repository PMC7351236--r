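#' Call crossover breakpoints from a BC1 genotype matrix
#'
#' Scans each plant's non-missing calls in marker order, one chromosome at a
#' time. Every change of state between consecutive informative markers
#' contributes one breakpoint whose interval runs from the last informative
#' marker before the change to the first informative marker after it; missing
#' calls widen the interval but never create or destroy a breakpoint. The
#' breakpoint midpoint (interval midpoint) is attached for positional
#' statistics.
#'
#' @param genotypes Tibble with a `plant` column and one character column per
#'   marker, values in `"A"`, `"H"`, `NA`.
#' @param markers Marker map tibble with `marker`, `chrom`, `pos_bp`,
#'   positions strictly increasing within each chromosome.
#' @return A tibble with one row per plant x chromosome: `plant`, `chrom`,
#'   `n_co`, `n_informative`, `low_info` (fewer than 2 informative calls), and
#'   a list-column `breakpoints` of tibbles with `left_marker`,
#'   `right_marker`, `left_bp`, `right_bp`, `mid_bp`.
#' @export
#' @examples
#' sim <- simulate_bc1_population(meiosis_sim_config(n_plants = 10, seed = 1))
#' profiles <- call_breakpoints(sim$genotypes, sim$markers)
#' head(profiles)
call_breakpoints <- function(genotypes, markers) {
  validate_genotypes(genotypes, markers)
  plants <- genotypes$plant
  n <- length(plants)
  bp_tbl <- function(li, ri, mk) {
    vctrs::new_data_frame(
      list(left_marker = mk$marker[li], right_marker = mk$marker[ri],
           left_bp = mk$pos_bp[li], right_bp = mk$pos_bp[ri],
           mid_bp = (mk$pos_bp[li] + mk$pos_bp[ri]) / 2),
      class = c("tbl_df", "tbl")
    )
  }
  per_chrom <- lapply(unique(markers$chrom), function(ch) {
    mk <- markers[markers$chrom == ch, ]
    mat <- as.matrix(genotypes[, mk$marker, drop = FALSE])
    num <- matrix(match(mat, c("A", "H")), nrow = n)
    n_inf <- rowSums(!is.na(num))
    # single left-to-right sweep carrying the last informative call per plant
    res_pl <- integer(0); res_li <- integer(0); res_ri <- integer(0)
    last_val <- rep(NA_integer_, n)
    last_idx <- rep(NA_integer_, n)
    for (j in seq_len(ncol(num))) {
      cur <- num[, j]
      has <- !is.na(cur)
      chg <- has & !is.na(last_val) & cur != last_val
      if (any(chg)) {
        w <- which(chg)
        res_pl <- c(res_pl, w)
        res_li <- c(res_li, last_idx[w])
        res_ri <- c(res_ri, rep(j, length(w)))
      }
      last_val[has] <- cur[has]
      last_idx[has] <- j
    }
    n_co <- tabulate(res_pl, nbins = n)
    o <- order(res_pl, res_li)
    groups <- split(seq_along(o), factor(res_pl[o], levels = seq_len(n)))
    bps <- lapply(seq_len(n), function(i) {
      g <- o[groups[[i]]]
      bp_tbl(res_li[g], res_ri[g], mk)
    })
    tibble::tibble(plant = plants, chrom = ch, n_co = n_co,
                   n_informative = n_inf, low_info = n_inf < 2,
                   breakpoints = bps)
  })
  dplyr::arrange(dplyr::bind_rows(per_chrom), .data$plant, .data$chrom)
}

validate_genotypes <- function(genotypes, markers) {
  if (!"plant" %in% names(genotypes)) {
    stop("genotypes must have a 'plant' column", call. = FALSE)
  }
  miss <- setdiff(markers$marker, names(genotypes))
  if (length(miss)) {
    stop("genotypes lack marker columns: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_pos <- dplyr::summarise(dplyr::group_by(markers, .data$chrom),
                              ok = all(diff(.data$pos_bp) > 0) & dplyr::n() >= 2,
                              .groups = "drop")
  if (!all(bad_pos$ok)) {
    stop("marker positions must be strictly increasing with >= 2 markers ",
         "per chromosome", call. = FALSE)
  }
  vals <- unlist(genotypes[, markers$marker], use.names = FALSE)
  if (!all(is.na(vals) | vals %in% c("A", "H"))) {
    stop("genotype calls must be 'A', 'H' or NA", call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarise crossover counts per plant and per chromosome
#'
#' @param profiles Output of [call_breakpoints()].
#' @param conf Confidence level for the t-interval on the mean.
#' @return A list with
#'   \describe{
#'     \item{per_plant}{tibble `plant`, `n_co` (genome-wide total).}
#'     \item{per_chromosome}{tibble `chrom`, `co_class` in
#'       `"0","1","2","3+"`, `n_chromatids`.}
#'     \item{overall}{one-row tibble `n`, `mean_co`, `sd`, `ci_low`,
#'       `ci_high`, `degenerate` (zero variance).}
#'   }
#' @export
co_count_summary <- function(profiles, conf = 0.95) {
  if (nrow(profiles) == 0) stop("empty population", call. = FALSE)
  per_plant <- dplyr::summarise(dplyr::group_by(profiles, .data$plant),
                                n_co = sum(.data$n_co), .groups = "drop")
  per_chrom <- dplyr::count(
    dplyr::mutate(profiles,
                  co_class = ifelse(.data$n_co >= 3, "3+",
                                    as.character(.data$n_co))),
    .data$chrom, .data$co_class, name = "n_chromatids"
  )
  n <- nrow(per_plant)
  m <- mean(per_plant$n_co)
  s <- stats::sd(per_plant$n_co)
  degenerate <- n < 2 || s == 0
  half <- if (degenerate) 0 else stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  overall <- tibble::tibble(n = n, mean_co = m, sd = s,
                            ci_low = m - half, ci_high = m + half,
                            degenerate = degenerate)
  list(per_plant = per_plant, per_chromosome = per_chrom, overall = overall)
}
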
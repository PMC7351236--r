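#' Inter-crossover distances on double-crossover chromatids
#'
#' Selects chromatids carrying exactly two crossovers and expresses the
#' distance between the two breakpoint midpoints as a fraction of the
#' chromosome length. The observed distances are compared against a
#' random-placement null (distance between two independent uniform positions,
#' whose mean is 1/3) with a two-sided Welch t-test; a Kolmogorov-Smirnov
#' statistic is reported for shape.
#'
#' @param profiles Output of [call_breakpoints()].
#' @param chromosomes Chromosome tibble with `chrom`, `length_bp`.
#' @param n_null Number of null draws.
#' @return A list of class `co_distance_summary` with `distances` (tibble
#'   `plant`, `chrom`, `distance`), `null` (numeric vector), and `tests`
#'   (one-row tibble `n`, `mean_distance`, `null_mean`, `t_p_value`,
#'   `ks_statistic`, `ks_p_value`, `empty`).
#' @export
inter_co_distances <- function(profiles, chromosomes, n_null = 10000L) {
  two <- profiles[profiles$n_co == 2L, ]
  if (nrow(two) > 0) {
    bp <- tidyr::unnest(
      dplyr::select(two, "plant", "chrom", "breakpoints"), "breakpoints")
    d <- dplyr::summarise(dplyr::group_by(bp, .data$plant, .data$chrom),
                          span_bp = max(.data$mid_bp) - min(.data$mid_bp),
                          .groups = "drop")
    d <- dplyr::left_join(d, chromosomes[, c("chrom", "length_bp")],
                          by = "chrom")
    d$distance <- d$span_bp / d$length_bp
    distances <- dplyr::select(d, "plant", "chrom", "distance")
  } else {
    distances <- tibble::tibble(plant = character(0), chrom = character(0),
                                distance = numeric(0))
  }
  null <- abs(stats::runif(n_null) - stats::runif(n_null))
  if (nrow(distances) == 0) {
    warning("no chromatid carries exactly two crossovers")
    tests <- tibble::tibble(n = 0L, mean_distance = NA_real_,
                            null_mean = mean(null), t_p_value = NA_real_,
                            ks_statistic = NA_real_, ks_p_value = NA_real_,
                            empty = TRUE)
  } else {
    t_p <- if (nrow(distances) >= 2) {
      stats::t.test(distances$distance, null)$p.value
    } else NA_real_
    ks <- suppressWarnings(stats::ks.test(distances$distance, null))
    tests <- tibble::tibble(n = nrow(distances),
                            mean_distance = mean(distances$distance),
                            null_mean = mean(null),
                            t_p_value = t_p,
                            ks_statistic = unname(ks$statistic),
                            ks_p_value = ks$p.value,
                            empty = FALSE)
  }
  structure(list(distances = distances, null = null, tests = tests),
            class = "co_distance_summary")
}

#' @export
print.co_distance_summary <- function(x, ...) {
  cat("Inter-crossover distances (double-CO chromatids)\n")
  print(x$tests)
  invisible(x)
}
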
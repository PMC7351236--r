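#' Plot per-interval crossover rates along chromosomes
#'
#' @param comparison Output of [compare_maps()] (or a single map's intervals
#'   with `r` renamed to `r_a`).
#' @return A ggplot object: interval recombination fractions along each
#'   chromosome for both populations, significant intervals starred.
#' @export
plot_genetic_map <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, dplyr::all_of(c("r_a", "r_b")),
                              names_to = "population", values_to = "r")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid_bp / 1e6, y = .data$r,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$significant),
      shape = 8, colour = "black", show.legend = FALSE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Recombination fraction r",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tiled methylation levels along chromosomes
#'
#' @param tiles Output of [tile_methylation()].
#' @param context Optional single context to display.
#' @return A ggplot object.
#' @export
plot_tile_profile <- function(tiles, context = NULL) {
  if (!is.null(context)) tiles <- tiles[tiles$context == context, ]
  aes <- ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$level)
  if ("genotype" %in% names(tiles)) {
    aes <- utils::modifyList(aes, ggplot2::aes(colour = .data$genotype))
  }
  ggplot2::ggplot(tiles, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(context ~ chrom, scales = "free") +
    ggplot2::labs(x = "Position (Mb)", y = "Weighted methylation level") +
    ggplot2::theme_minimal()
}

#' Plot a metagene methylation profile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object with flank/body boundaries marked.
#' @export
plot_metagene <- function(profile) {
  n_up <- sum(profile$region == "upstream") /
    max(1, length(unique(profile$genotype)))
  n_body <- sum(profile$region == "body") /
    max(1, length(unique(profile$genotype)))
  aes <- ggplot2::aes(x = .data$position, y = .data$level)
  if ("genotype" %in% names(profile) && !all(is.na(profile$genotype))) {
    aes <- utils::modifyList(aes, ggplot2::aes(colour = .data$genotype))
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(n_up + 0.5, n_up + n_body + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Bin (5' flank | body | 3' flank)",
                  y = "Weighted methylation level") +
    ggplot2::theme_minimal()
}

#' Plot an exponential distality fit
#'
#' @param fit A [fit_distality()] object.
#' @return A ggplot object with the data points and fitted curve.
#' @export
plot_distality <- function(fit) {
  curve <- tibble::tibble(x = seq(min(fit$data$x), max(fit$data$x),
                                  length.out = 200))
  curve$y <- fit$a * exp(fit$b * curve$x)
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "Relative distance", y = "CO rate (cM/Mb)",
                  subtitle = sprintf("y = %.3g e^(%.3g x), r2 = %.3f",
                                     fit$a, fit$b, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Plot inter-crossover distance distributions against the random null
#'
#' @param x A [inter_co_distances()] summary.
#' @return A ggplot density plot.
#' @export
plot_inter_co_distances <- function(x) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = x$distances$distance, set = "observed"),
    tibble::tibble(distance = x$null, set = "random null")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Inter-CO distance (fraction of chromosome)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
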
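#' Map functions: Kosambi and Haldane
#'
#' Convert a recombination fraction `r` into a map distance in centiMorgan.
#' Kosambi, `d = 25 * log((1 + 2r) / (1 - 2r))`, allows for moderate
#' crossover interference; Haldane, `d = -50 * log(1 - 2r)`, assumes none.
#' The inverses `kosambi_r()` / `haldane_r()` round-trip to machine
#' precision.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @param cm Map distance(s) in cM, `>= 0`.
#' @return Numeric vector of map distances (cM) or recombination fractions.
#' @export
#' @examples
#' kosambi_cm(0.25)       # 25 * log(3)
#' kosambi_r(kosambi_cm(0.1))
kosambi_cm <- function(r) {
  check_r_domain(r)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
haldane_cm <- function(r) {
  check_r_domain(r)
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(cm) {
  stopifnot(all(cm >= 0))
  tanh(cm / 50) / 2
}

#' @rdname kosambi_cm
#' @export
haldane_r <- function(cm) {
  stopifnot(all(cm >= 0))
  (1 - exp(-cm / 50)) / 2
}

check_r_domain <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must satisfy 0 <= r < 0.5", call. = FALSE)
  }
  invisible(TRUE)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Per-interval recombination fractions
#'
#' For every pair of consecutive markers on each chromosome, computes
#' `r = (number of plants having recombined in the interval) / (number of
#' plants genotyped for this interval)`. A plant is "recombined in the
#' interval" iff its calls at the two flanking markers are both non-missing
#' and differ; plants missing either flank are not counted as informative.
#' 95% confidence limits on `r` use the Wilson score interval.
#'
#' @inheritParams call_breakpoints
#' @param conf Confidence level for the Wilson interval.
#' @return A tibble with one row per consecutive-marker interval: `chrom`,
#'   `left_marker`, `right_marker`, `left_bp`, `right_bp`, `mid_bp`,
#'   `length_bp`, `n_recombinant`, `n_informative`, `r`, `ci_low`, `ci_high`,
#'   `undefined` (no informative plants).
#' @export
recombination_fraction <- function(genotypes, markers, conf = 0.95) {
  validate_genotypes(genotypes, markers)
  rows <- lapply(unique(markers$chrom), function(ch) {
    mk <- markers[markers$chrom == ch, ]
    mat <- as.matrix(genotypes[, mk$marker, drop = FALSE])
    k <- nrow(mk) - 1L
    left <- mat[, -ncol(mat), drop = FALSE]
    right <- mat[, -1, drop = FALSE]
    informative <- !is.na(left) & !is.na(right)
    recomb <- informative & (left != right)
    tibble::tibble(
      chrom = ch,
      left_marker = mk$marker[seq_len(k)],
      right_marker = mk$marker[seq_len(k) + 1L],
      left_bp = mk$pos_bp[seq_len(k)],
      right_bp = mk$pos_bp[seq_len(k) + 1L],
      n_recombinant = unname(colSums(recomb)),
      n_informative = unname(colSums(informative))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$mid_bp <- (out$left_bp + out$right_bp) / 2
  out$length_bp <- out$right_bp - out$left_bp
  out$undefined <- out$n_informative == 0
  out$r <- ifelse(out$undefined, NA_real_,
                  out$n_recombinant / out$n_informative)
  ci <- matrix(NA_real_, nrow(out), 2)
  ok <- !out$undefined
  if (any(ok)) ci[ok, ] <- wilson_ci(out$n_recombinant[ok],
                                     out$n_informative[ok], conf)
  out$ci_low <- ci[, 1]
  out$ci_high <- ci[, 2]
  dplyr::select(out, "chrom", "left_marker", "right_marker", "left_bp",
                "right_bp", "mid_bp", "length_bp", "n_recombinant",
                "n_informative", "r", "ci_low", "ci_high", "undefined")
}

#' Build a genetic map
#'
#' Computes per-interval recombination fractions and converts them to map
#' distances (Kosambi by default, Haldane optionally), then aggregates
#' per-chromosome and genome totals. Intervals with `r >= 0.5` are reported
#' as-is with `cM = NA` and flagged rather than clamped, surfacing data
#' problems instead of hiding them.
#'
#' @inheritParams recombination_fraction
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return An object of class `genetic_map`: a list with `intervals`
#'   (the [recombination_fraction()] tibble plus `cm` and `cm_per_mb`),
#'   `chromosomes` (per-chromosome `total_cm`, `n_undefined`), `genome_cm`,
#'   and `map_function`.
#' @export
#' @examples
#' sim <- simulate_bc1_population(meiosis_sim_config(n_plants = 50, seed = 2))
#' gm <- build_genetic_map(sim$genotypes, sim$markers)
#' gm$genome_cm
build_genetic_map <- function(genotypes, markers,
                              map_function = c("kosambi", "haldane"),
                              conf = 0.95) {
  map_function <- match.arg(map_function)
  iv <- recombination_fraction(genotypes, markers, conf = conf)
  fun <- if (map_function == "kosambi") kosambi_cm else haldane_cm
  iv$r_out_of_range <- !is.na(iv$r) & iv$r >= 0.5
  iv$cm <- NA_real_
  ok <- !iv$undefined & !iv$r_out_of_range
  iv$cm[ok] <- fun(iv$r[ok])
  iv$cm_per_mb <- iv$cm / (iv$length_bp / 1e6)
  chroms <- dplyr::summarise(
    dplyr::group_by(iv, .data$chrom),
    total_cm = sum(.data$cm, na.rm = TRUE),
    n_intervals = dplyr::n(),
    n_undefined = sum(.data$undefined | .data$r_out_of_range),
    .groups = "drop"
  )
  structure(list(intervals = iv, chromosomes = chroms,
                 genome_cm = sum(chroms$total_cm),
                 map_function = map_function),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map (", x$map_function, "): ",
      nrow(x$intervals), " intervals on ", nrow(x$chromosomes),
      " chromosomes, total ", round(x$genome_cm, 1), " cM\n", sep = "")
  print(x$chromosomes)
  invisible(x)
}
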
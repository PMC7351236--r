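#' Define a chromosome
#'
#' A chromosome is described by its physical length and the position of its
#' centromere, which splits it into a North arm `[0, centromere)` and a South
#' arm `[centromere, length)`.
#'
#' @param name Chromosome label.
#' @param length_bp Chromosome length in base pairs.
#' @param centromere_bp Centromere position in base pairs; must lie strictly
#'   inside the chromosome.
#' @return A one-row tibble with columns `chrom`, `length_bp`, `centromere_bp`.
#' @export
#' @examples
#' chromosome_spec("Chr1", 30.4e6, 15.1e6)
chromosome_spec <- function(name, length_bp, centromere_bp) {
  stopifnot(length(name) == 1, length_bp > 0)
  if (!(centromere_bp > 0 && centromere_bp < length_bp)) {
    stop("centromere_bp must satisfy 0 < centromere_bp < length_bp",
         call. = FALSE)
  }
  tibble::tibble(chrom = as.character(name),
                 length_bp = as.numeric(length_bp),
                 centromere_bp = as.numeric(centromere_bp))
}

#' Arabidopsis-like five-chromosome genome
#'
#' TAIR10-like chromosome lengths and centromere positions, the default
#' genome used by the BC1 simulator.
#'
#' @return A tibble with columns `chrom`, `length_bp`, `centromere_bp`.
#' @export
arabidopsis_chromosomes <- function() {
  dplyr::bind_rows(
    chromosome_spec("Chr1", 30.4e6, 15.1e6),
    chromosome_spec("Chr2", 19.7e6, 3.6e6),
    chromosome_spec("Chr3", 23.5e6, 13.8e6),
    chromosome_spec("Chr4", 18.6e6, 4.0e6),
    chromosome_spec("Chr5", 27.0e6, 11.2e6)
  )
}

#' Crossover landscape model
#'
#' A positional crossover intensity on the relative chromosome coordinate
#' `[0, 1]` together with an expected per-chromatid event count, a
#' gamma-renewal interference shape, and an optional obligate-crossover flag.
#'
#' Families:
#' \describe{
#'   \item{`uniform`}{flat intensity.}
#'   \item{`distal_exponential`}{intensity `exp(rate * d)` where `d` is the
#'     per-arm relative distance from the centromere (0 at the centromere,
#'     1 at either telomere), so crossover rates rise exponentially towards
#'     both chromosome ends.}
#'   \item{`piecewise`}{piecewise-constant table over `breaks` (a partition
#'     of `[0, 1]`) with non-negative `heights`.}
#' }
#'
#' @param family One of `"uniform"`, `"distal_exponential"`, `"piecewise"`.
#' @param rate Exponential rate for `distal_exponential` (dimensionless).
#' @param breaks,heights Piecewise-constant table for `family = "piecewise"`:
#'   `breaks` is an increasing vector from 0 to 1, `heights` has one fewer
#'   entries, all non-negative with a positive sum.
#' @param expected_events Mean crossover count per chromatid per chromosome.
#' @param interference_nu Gamma-renewal shape `nu >= 1`; `nu = 1` gives a
#'   no-interference (Poisson) process.
#' @param obligate If `TRUE`, chromatids are rejection-sampled to carry at
#'   least one crossover.
#' @return An object of class `co_landscape`.
#' @export
#' @examples
#' co_landscape("distal_exponential", rate = 3, expected_events = 1.2)
co_landscape <- function(family = c("uniform", "distal_exponential", "piecewise"),
                         rate = 3,
                         breaks = NULL, heights = NULL,
                         expected_events = 1,
                         interference_nu = 1,
                         obligate = FALSE) {
  family <- match.arg(family)
  if (expected_events < 0) stop("expected_events must be >= 0", call. = FALSE)
  if (interference_nu < 1) stop("interference_nu must be >= 1", call. = FALSE)
  if (family == "piecewise") {
    if (is.null(breaks) || is.null(heights) ||
        length(heights) != length(breaks) - 1L ||
        any(diff(breaks) <= 0) || breaks[1] != 0 ||
        breaks[length(breaks)] != 1 ||
        any(heights < 0) || sum(heights) <= 0) {
      stop("piecewise landscape needs breaks spanning [0, 1] and ",
           "non-negative heights with a positive integral", call. = FALSE)
    }
  }
  structure(
    list(family = family, rate = rate, breaks = breaks, heights = heights,
         expected_events = expected_events,
         interference_nu = interference_nu, obligate = isTRUE(obligate)),
    class = "co_landscape"
  )
}

# Intensity lambda(x) on the relative coordinate, given the relative
# centromere position. Not normalised.
landscape_intensity <- function(model, x, centromere_rel) {
  switch(model$family,
    uniform = rep(1, length(x)),
    distal_exponential = {
      d <- ifelse(x < centromere_rel,
                  (centromere_rel - x) / centromere_rel,
                  (x - centromere_rel) / (1 - centromere_rel))
      exp(model$rate * d)
    },
    piecewise = {
      idx <- findInterval(x, model$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
      model$heights[idx]
    }
  )
}

# Normalised CDF of lambda on a grid, for inversion sampling.
landscape_cdf <- function(model, chrom, n_grid = 2048L) {
  grid <- seq(0, 1, length.out = n_grid)
  cen_rel <- chrom$centromere_bp / chrom$length_bp
  lam <- landscape_intensity(model, grid, cen_rel)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("landscape intensity must be finite and non-negative", call. = FALSE)
  }
  # trapezoidal cumulative integral
  dx <- diff(grid)
  inc <- dx * (lam[-1] + lam[-n_grid]) / 2
  cum <- c(0, cumsum(inc))
  total <- cum[n_grid]
  if (!is.finite(total) || total <= 0) {
    stop("landscape intensity must have a positive finite integral",
         call. = FALSE)
  }
  list(grid = grid, cdf = cum / total)
}

# Inverse-CDF map from uniform coordinate u in [0,1] to relative position.
landscape_quantile <- function(cdf_obj, u) {
  stats::approx(cdf_obj$cdf, cdf_obj$grid, xout = u, ties = "ordered",
                rule = 2)$y
}

# Stationary-ish gamma renewal arrivals on [0, 1] with mean rate `rate` and
# shape `nu`, using a burn-in of 12 mean inter-arrival times.
gamma_renewal_points <- function(rate, nu, burn_means = 12) {
  if (rate <= 0) return(numeric(0))
  t0 <- -burn_means / rate
  horizon <- 1 - t0
  pts <- numeric(0)
  t <- t0
  repeat {
    k <- max(16L, ceiling(rate * horizon * 1.5))
    arr <- t + cumsum(stats::rgamma(k, shape = nu, rate = nu * rate))
    pts <- c(pts, arr)
    t <- arr[k]
    if (t > 1) break
  }
  pts[pts > 0 & pts < 1]
}

#' Sample crossover positions for chromatids
#'
#' Draws crossover positions (in bp) for `n` chromatids from a
#' [co_landscape()] on a given chromosome. With `interference_nu = 1`
#' positions follow an inhomogeneous Poisson process obtained by
#' time-changing the intensity; with `interference_nu > 1` events of a
#' stationary gamma-renewal process at twice the chromatid rate are thinned
#' by 1/2 (chromatid sampling from a bivalent-level process) and then mapped
#' through the intensity's inverse CDF.
#'
#' @param model A [co_landscape()].
#' @param chrom A one-row chromosome tibble (see [chromosome_spec()]).
#' @param n Number of chromatids to draw.
#' @return A list of length `n`; each element is a sorted numeric vector of
#'   crossover positions in bp (possibly empty).
#' @export
#' @examples
#' chr <- chromosome_spec("Chr1", 30e6, 15e6)
#' set.seed(1)
#' sample_co_positions(co_landscape("uniform", expected_events = 2), chr, n = 3)
sample_co_positions <- function(model, chrom, n = 1L) {
  stopifnot(inherits(model, "co_landscape"), nrow(chrom) == 1)
  ev <- model$expected_events
  if (ev == 0) {
    if (model$obligate) {
      stop("obligate crossover with expected_events = 0 is unsatisfiable",
           call. = FALSE)
    }
    return(replicate(n, numeric(0), simplify = FALSE))
  }
  cdf_obj <- landscape_cdf(model, chrom)
  L <- chrom$length_bp
  nu <- model$interference_nu

  draw_one <- function() {
    if (nu == 1) {
      k <- stats::rpois(1, ev)
      u <- if (k > 0) stats::runif(k) else numeric(0)
    } else {
      u <- gamma_renewal_points(2 * ev, nu)
      if (length(u)) u <- u[stats::runif(length(u)) < 0.5]
    }
    sort(landscape_quantile(cdf_obj, u)) * L
  }

  out <- vector("list", n)
  if (nu == 1 && !model$obligate) {
    # fully vectorised Poisson path
    ks <- stats::rpois(n, ev)
    total <- sum(ks)
    pos <- landscape_quantile(cdf_obj, stats::runif(total)) * L
    idx <- rep.int(seq_len(n), ks)
    split_pos <- split(pos, factor(idx, levels = seq_len(n)))
    out <- lapply(split_pos, sort)
    names(out) <- NULL
  } else {
    for (i in seq_len(n)) {
      p <- draw_one()
      if (model$obligate) {
        tries <- 1L
        while (length(p) == 0) {
          tries <- tries + 1L
          if (tries > 10000L) {
            stop("obligate rejection sampling failed after 10000 tries",
                 call. = FALSE)
          }
          p <- draw_one()
        }
      }
      out[[i]] <- p
    }
  }
  out
}
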
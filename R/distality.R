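#' Relative distance of an interval midpoint along a chromosome arm
#'
#' Each chromosome arm is rescaled to `[0, 1]`. With `anchor = "telomere"`
#' the value is the arm-relative distance from the arm's telomere: North arm
#' `midpoint / arm_length` (positions measured from the chromosome start),
#' South arm `(chromosome_length - midpoint) / arm_length`; so 0 at the
#' telomere and 1 at the centromere. With `anchor = "centromere"` the value
#' is 1 minus that (0 at the centromere, 1 at the telomere). A midpoint
#' falling exactly on the centromere is assigned to the North arm.
#'
#' @param mid_bp Numeric vector of interval midpoints (bp).
#' @param length_bp,centromere_bp Chromosome length and centromere position
#'   (bp), recycled against `mid_bp`.
#' @param anchor `"centromere"` or `"telomere"`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' relative_distance(5e6, 30e6, 15e6, anchor = "telomere")    # 1/3
#' relative_distance(25e6, 30e6, 15e6, anchor = "telomere")   # (30-25)/15
relative_distance <- function(mid_bp, length_bp, centromere_bp,
                              anchor = c("centromere", "telomere")) {
  anchor <- match.arg(anchor)
  if (any(mid_bp < 0 | mid_bp > length_bp)) {
    stop("interval midpoint outside chromosome", call. = FALSE)
  }
  north <- mid_bp <= centromere_bp
  from_tel <- ifelse(north,
                     mid_bp / centromere_bp,
                     (length_bp - mid_bp) / (length_bp - centromere_bp))
  if (anchor == "telomere") from_tel else 1 - from_tel
}

#' Fit an exponential crossover-rate gradient
#'
#' Least-squares fit of `y = a * exp(b * x)` to (relative distance, crossover
#' rate) points by nonlinear minimisation of the residual sum of squares,
#' initialised from a log-linear regression on the positive responses. The
#' coefficient of determination is `r2 = 1 - SS_res / SS_tot`.
#'
#' @param data Data frame with the predictor and response columns.
#' @param x,y Column names (strings) of the predictor (relative distance in
#'   `[0, 1]`) and response (crossover rate, `>= 0`).
#' @return An object of class `distality_fit` with elements `a`, `b`, `r2`,
#'   `fitted`, `data`, `converged`, `degenerate`. Supports
#'   [generics::tidy()], [generics::glance()] and [plot_distality()].
#' @export
#' @examples
#' d <- data.frame(x = seq(0, 1, 0.1))
#' d$y <- 2 * exp(3 * d$x)
#' fit_distality(d)
fit_distality <- function(data, x = "x", y = "y") {
  xs <- data[[x]]
  ys <- data[[y]]
  if (length(xs) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(ys < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(ys == 0)) {
    fit <- list(a = 0, b = 0, r2 = 0, fitted = rep(0, length(xs)),
                data = tibble::tibble(x = xs, y = ys),
                converged = FALSE, degenerate = TRUE)
    class(fit) <- "distality_fit"
    return(fit)
  }
  pos <- ys > 0
  start <- if (sum(pos) >= 2 && stats::var(xs[pos]) > 0) {
    cf <- stats::coef(stats::lm(log(ys[pos]) ~ xs[pos]))
    list(a = exp(unname(cf[1])), b = unname(cf[2]))
  } else {
    list(a = mean(ys), b = 0)
  }
  df <- data.frame(x = xs, y = ys)
  start_rss <- sum((ys - start$a * exp(start$b * xs))^2)
  if (start_rss <= 1e-12 * max(1, sum(ys^2))) {
    # the log-linear start already interpolates the data; nls cannot
    # improve a zero-residual fit
    a <- start$a
    b <- start$b
    converged <- TRUE
    nls_fit <- NA
  } else {
  nls_fit <- tryCatch(
    stats::nls(y ~ a * exp(b * x), data = df, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(nls_fit)) {
    a <- start$a
    b <- start$b
    converged <- FALSE
  } else {
    cf <- stats::coef(nls_fit)
    a <- unname(cf["a"])
    b <- unname(cf["b"])
    converged <- TRUE
  }
  }
  fitted <- a * exp(b * xs)
  ss_res <- sum((ys - fitted)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  fit <- list(a = a, b = b, r2 = r2, fitted = fitted,
              data = tibble::tibble(x = xs, y = ys),
              converged = converged, degenerate = FALSE)
  class(fit) <- "distality_fit"
  fit
}

#' @export
print.distality_fit <- function(x, ...) {
  cat("Exponential fit y = a * exp(b * x)\n")
  cat(sprintf("  a = %.4g, b = %.4g, r2 = %.4f%s\n", x$a, x$b, x$r2,
              if (!x$converged) " (did not converge; log-linear start used)"
              else ""))
  invisible(x)
}

#' Tidy an exponential distality fit
#'
#' @param x A `distality_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @export
tidy.distality_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.distality_fit
#' @return For `glance()`: a one-row tibble with `r.squared`, `n`,
#'   `converged`, `degenerate`.
#' @export
glance.distality_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, n = nrow(x$data),
                 converged = x$converged, degenerate = x$degenerate)
}
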
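# Independent brute-force oracles, deliberately written in the most naive
# style possible and kept free of any code path they are used to check.

# Number of phase transitions in the non-missing subsequence of calls.
oracle_transition_count <- function(calls) {
  xx <- calls[!is.na(calls)]
  if (length(xx) < 2) return(0L)
  n <- 0L
  for (i in 2:length(xx)) if (xx[i] != xx[i - 1]) n <- n + 1L
  n
}

# Per-cytosine context table from a sequence string, by explicit looping.
oracle_context_scan <- function(seq_str, chrom = "chr1") {
  b <- strsplit(toupper(seq_str), "")[[1]]
  n <- length(b)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (i in seq_len(n)) {
    if (b[i] == "C" && i + 2 <= n) {
      tri <- b[i:(i + 2)]
      if (!any(tri == "N")) {
        ctx <- if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = i, strand = "+", context = ctx,
          trinucleotide = paste(tri, collapse = ""))
      }
    }
    if (b[i] == "G" && i - 2 >= 1) {
      tri <- rev(comp[b[(i - 2):i]])
      if (!any(tri == "N")) {
        ctx <- if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = i, strand = "-", context = ctx,
          trinucleotide = paste(tri, collapse = ""))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Two-stage adaptive step-up, coded independently (explicit loops).
oracle_bky <- function(p, q) {
  m <- length(p)
  qprime <- q / (1 + q)
  step_up <- function(pv, alpha) {
    o <- order(pv)
    k_max <- 0L
    for (k in 1:m) if (pv[o[k]] <= alpha * k / m) k_max <- k
    rej <- rep(FALSE, m)
    if (k_max > 0) for (k in 1:k_max) rej[o[k]] <- TRUE
    rej
  }
  s1 <- step_up(p, qprime)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, qprime * m / (m - r1))
}

# Two-sided Fisher p by full enumeration with choose() arithmetic.
oracle_fisher <- function(m1, t1, m2, t2) {
  K <- m1 + m2
  N <- t1 + t2
  prob_of <- function(x) choose(t1, x) * choose(t2, K - x) / choose(N, K)
  p_obs <- prob_of(m1)
  total <- 0
  for (x in max(0, K - t2):min(K, t1)) {
    px <- prob_of(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# Fraction of intervals in a overlapping any interval in b, all-pairs scan.
oracle_overlap <- function(a, b) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    found <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] <= b$end[j] && a$end[i] >= b$start[j]) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits / nrow(a)
}

# Build a genotype tibble directly from a matrix of calls.
make_genotypes <- function(calls, markers) {
  colnames(calls) <- markers$marker
  dplyr::bind_cols(
    tibble::tibble(plant = sprintf("p%03d", seq_len(nrow(calls)))),
    tibble::as_tibble(calls)
  )
}

# Equally spaced markers on one chromosome.
make_markers <- function(pos_bp, chrom = "Chr1") {
  tibble::tibble(marker = sprintf("%s_M%02d", chrom, seq_along(pos_bp)),
                 chrom = chrom, pos_bp = pos_bp)
}
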
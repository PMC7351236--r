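#' Annotate cytosine contexts from a genome sequence
#'
#' Lists every cytosine on both strands with its sequence context: `CG` when
#' the next base (5'->3' on the cytosine's strand) is G, otherwise `CHG`
#' when the base after that is G, otherwise `CHH` (H is A, T or C).
#' Cytosines whose three-base context window is truncated by a chromosome
#' end, or contains an N, are dropped and counted.
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @return A tibble with `chrom`, `pos` (1-based), `strand` (`"+"`/`"-"`),
#'   `context`, `trinucleotide` (read 5'->3' on the cytosine's strand),
#'   sorted by chromosome and position. The number of dropped cytosines is
#'   attached as attribute `"n_dropped"`.
#' @export
#' @examples
#' annotate_contexts(c(chr = "ACGTCAGCTT"))
annotate_contexts <- function(genome) {
  genome <- as_genome_strings(genome)
  dropped <- 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  acgt <- c("A", "C", "G", "T")
  classify <- function(n1, n2) {
    ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
  }
  res <- lapply(names(genome), function(ch) {
    b <- strsplit(toupper(genome[[ch]]), "", fixed = TRUE)[[1]]
    n <- length(b)

    # plus strand: C at i, context window bases i+1, i+2
    ip_all <- which(b == "C")
    ip <- ip_all[ip_all + 2L <= n]
    n1 <- b[ip + 1L]
    n2 <- b[ip + 2L]
    okp <- n1 %in% acgt & n2 %in% acgt
    dropped <<- dropped + (length(ip_all) - sum(okp))
    plus <- tibble::tibble(
      chrom = character(0), pos = integer(0), strand = character(0),
      context = character(0), trinucleotide = character(0))
    if (any(okp)) {
      plus <- tibble::tibble(
        chrom = ch, pos = ip[okp], strand = "+",
        context = unname(classify(n1[okp], n2[okp])),
        trinucleotide = paste0("C", n1[okp], n2[okp]))
    }

    # minus strand: C opposite a G at i; its 3' neighbours lie at i-1, i-2
    im_all <- which(b == "G")
    im <- im_all[im_all - 2L >= 1L]
    m1 <- unname(comp[b[im - 1L]])
    m2 <- unname(comp[b[im - 2L]])
    okm <- m1 %in% acgt & m2 %in% acgt
    dropped <<- dropped + (length(im_all) - sum(okm))
    minus <- tibble::tibble(
      chrom = character(0), pos = integer(0), strand = character(0),
      context = character(0), trinucleotide = character(0))
    if (any(okm)) {
      minus <- tibble::tibble(
        chrom = ch, pos = im[okm], strand = "-",
        context = unname(classify(m1[okm], m2[okm])),
        trinucleotide = paste0("C", m1[okm], m2[okm]))
    }
    dplyr::arrange(dplyr::bind_rows(plus, minus), .data$pos, .data$strand)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_dropped") <- dropped
  out
}

as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(as.list(out))
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(as.list(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    return(as.list(genome))
  }
  stop("genome must be a named character vector, DNAStringSet or FASTA path",
       call. = FALSE)
}
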
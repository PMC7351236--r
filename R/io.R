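#' Read and write the package's text formats
#'
#' Plain-text interchange formats:
#' \describe{
#'   \item{Genotype CSV}{header row of marker names after a `plant` column;
#'     one row per plant; calls `A`, `H` or `NA` (empty).}
#'   \item{Marker map TSV}{columns `marker`, `chrom`, `pos_bp`.}
#'   \item{Centromere table TSV}{columns `chrom`, `length_bp`,
#'     `centromere_bp`.}
#'   \item{CX-style cytosine report TSV}{headerless Bismark-like columns
#'     `chrom`, `pos` (1-based), `strand`, `count_methylated`,
#'     `count_unmethylated`, `context`, `trinucleotide`.}
#'   \item{Feature BED}{six columns `chrom`, `start` (0-based), `end`,
#'     `name`, `class`, `strand`; converted to 1-based inclusive on read.}
#' }
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name meioscape_io
NULL

#' @rdname meioscape_io
#' @export
write_genotypes_csv <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname meioscape_io
#' @export
read_genotypes_csv <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname meioscape_io
#' @export
write_marker_map_tsv <- function(x, path) {
  readr::write_tsv(x[, c("marker", "chrom", "pos_bp")], path)
  invisible(path)
}

#' @rdname meioscape_io
#' @export
read_marker_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(marker = "c", chrom = "c",
                                          pos_bp = "d"))
}

#' @rdname meioscape_io
#' @export
write_centromere_tsv <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "length_bp", "centromere_bp")], path)
  invisible(path)
}

#' @rdname meioscape_io
#' @export
read_centromere_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", length_bp = "d",
                                          centromere_bp = "d"))
}

#' @rdname meioscape_io
#' @export
write_cx_report <- function(x, path) {
  out <- tibble::tibble(
    chrom = x$chrom, pos = x$pos, strand = x$strand,
    count_methylated = x$n_meth,
    count_unmethylated = x$n_total - x$n_meth,
    context = x$context,
    trinucleotide = if ("trinucleotide" %in% names(x)) x$trinucleotide
                    else x$context
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname meioscape_io
#' @export
read_cx_report <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context", "trinucleotide"),
    col_types = readr::cols(chrom = "c", pos = "i", strand = "c",
                            count_methylated = "i",
                            count_unmethylated = "i", context = "c",
                            trinucleotide = "c"),
    show_col_types = FALSE)
  tibble::tibble(
    chrom = as.character(x$chrom), pos = as.integer(x$pos),
    strand = as.character(x$strand), context = as.character(x$context),
    trinucleotide = as.character(x$trinucleotide),
    n_meth = as.integer(x$count_methylated),
    n_total = as.integer(x$count_methylated) +
      as.integer(x$count_unmethylated)
  )
}

#' @rdname meioscape_io
#' @export
write_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(unlist(as_genome_strings(x)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname meioscape_io
#' @export
write_features_bed <- function(x, path) {
  out <- tibble::tibble(chrom = x$chrom, start = x$start - 1, end = x$end,
                        name = x$feature_id, class = x$class,
                        strand = x$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname meioscape_io
#' @export
read_features_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "class", "strand"),
                       show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", start = "d",
                                               end = "d", name = "c",
                                               class = "c", strand = "c"))
  tibble::tibble(chrom = x$chrom, start = x$start + 1, end = x$end,
                 strand = x$strand, class = x$class, feature_id = x$name)
}

#' @rdname meioscape_io
#' @export
write_dmrs_bed <- function(x, path) {
  out <- tibble::tibble(chrom = x$chrom, start = x$start - 1, end = x$end,
                        name = paste0(x$context, "_", x$direction),
                        score = round(x$mean_diff, 4),
                        strand = ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
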
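#' Filter cytosine sites by read coverage
#'
#' Removes sites covered by fewer than `min_total` reads. Only cytosines
#' passing this filter contribute to average methylation levels, tiles,
#' metagene profiles and differential tests.
#'
#' @param report Cytosine report tibble with at least `context` and
#'   `n_total` columns.
#' @param min_total Minimum read count (default 5).
#' @return The filtered tibble; per-context removal counts are attached as
#'   attribute `"n_removed"`.
#' @export
#' @examples
#' rep <- tibble::tibble(chrom = "chr1", pos = 1:3, strand = "+",
#'                       context = "CG", n_meth = c(1, 2, 3),
#'                       n_total = c(4, 5, 10))
#' filter_coverage(rep)
filter_coverage <- function(report, min_total = 5) {
  keep <- report$n_total >= min_total
  removed <- dplyr::count(report[!keep, ], .data$context, name = "n_removed")
  out <- report[keep, ]
  if (nrow(out) == 0) warning("no sites pass the coverage filter")
  attr(out, "n_removed") <- removed
  out
}

#' Merge complementary CG strand pairs
#'
#' CG sites come in complementary pairs (a C at position `p` on the plus
#' strand pairs with the C at `p + 1` on the minus strand). This helper sums
#' the counts of each pair onto the plus-strand position; CG sites whose
#' partner is absent are kept as they are. Non-CG sites pass through
#' untouched. Reports are not strand-merged by default anywhere in the
#' package.
#'
#' @param report Cytosine report tibble (`chrom`, `pos`, `strand`,
#'   `context`, `n_meth`, `n_total`, plus any grouping columns such as
#'   `genotype`/`replicate`).
#' @return A tibble of the same shape with merged CG rows on the plus
#'   strand.
#' @export
merge_cg_strands <- function(report) {
  cg <- report$context == "CG"
  rest <- report[!cg, ]
  cgr <- report[cg, ]
  # anchor each CG to the plus-strand position of its pair
  anchor <- ifelse(cgr$strand == "+", cgr$pos, cgr$pos - 1L)
  extra <- intersect(c("genotype", "replicate", "sample"), names(cgr))
  key <- cgr[extra]
  key$chrom <- cgr$chrom
  key$anchor <- anchor
  id <- vctrs::vec_group_id(key)
  first <- !duplicated(id)
  merged <- cgr[first, ]
  merged$pos <- anchor[first]
  merged$strand <- "+"
  merged$n_meth <- as.vector(rowsum(cgr$n_meth, id))
  merged$n_total <- as.vector(rowsum(cgr$n_total, id))
  dplyr::arrange(dplyr::bind_rows(rest, merged), .data$chrom, .data$pos)
}

#' Weighted methylation levels in non-overlapping genome tiles
#'
#' Splits each chromosome into non-overlapping tiles of `tile_bp` and
#' computes, per tile, the weighted methylation level
#' `sum(n_meth) / sum(n_total)` over all sites of the requested context,
#' with counts pooled across replicates (and grouped by `genotype` when that
#' column is present). Tiles without covered sites are reported with `NA`
#' level when `chrom_lengths` is supplied, and omitted otherwise.
#'
#' @param report (Filtered) cytosine report tibble.
#' @param tile_bp Tile width in bp (default 200 kb).
#' @param context `"CG"`, `"CHG"` or `"CHH"`; `NULL` keeps all contexts
#'   (grouped).
#' @param chrom_lengths Optional tibble `chrom`, `length_bp` used to emit
#'   empty tiles.
#' @param level_type `"weighted"` (count-pooled, the default) or
#'   `"site_mean"` (unweighted mean of per-site ratios).
#' @return A tibble with `genotype` (if present), `context`, `chrom`,
#'   `start`, `end` (1-based inclusive), `n_sites`, `n_meth`, `n_total`,
#'   `level`.
#' @export
tile_methylation <- function(report, tile_bp = 200000, context = NULL,
                             chrom_lengths = NULL,
                             level_type = c("weighted", "site_mean")) {
  level_type <- match.arg(level_type)
  if (tile_bp <= 0) stop("tile_bp must be positive", call. = FALSE)
  if (!is.null(context)) report <- report[report$context %in% context, ]
  grp <- intersect(c("genotype", "context", "chrom"), names(report))
  tiles <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(report, tile = (.data$pos - 1) %/% tile_bp),
      dplyr::across(dplyr::all_of(grp)), .data$tile),
    n_sites = dplyr::n(),
    site_mean = mean(.data$n_meth[.data$n_total > 0] /
                       .data$n_total[.data$n_total > 0]),
    n_meth = sum(.data$n_meth),
    n_total = sum(.data$n_total),
    .groups = "drop"
  )
  lvl <- if (level_type == "weighted") tiles$n_meth / tiles$n_total else
    tiles$site_mean
  tiles$level <- ifelse(tiles$n_total > 0, lvl, NA_real_)
  tiles$site_mean <- NULL
  tiles$start <- tiles$tile * tile_bp + 1
  tiles$end <- (tiles$tile + 1) * tile_bp
  if (!is.null(chrom_lengths)) {
    full <- tidyr::expand_grid(
      dplyr::distinct(tiles[setdiff(grp, "chrom")]),
      purrr::map_dfr(seq_len(nrow(chrom_lengths)), function(i) {
        n_tiles <- ceiling(chrom_lengths$length_bp[i] / tile_bp)
        tibble::tibble(chrom = chrom_lengths$chrom[i],
                       tile = seq_len(n_tiles) - 1)
      })
    )
    tiles <- dplyr::left_join(full, tiles, by = c(setdiff(grp, "chrom"),
                                                  "chrom", "tile"))
    tiles$n_sites <- dplyr::coalesce(tiles$n_sites, 0L)
    tiles$n_meth <- dplyr::coalesce(tiles$n_meth, 0)
    tiles$n_total <- dplyr::coalesce(tiles$n_total, 0)
    tiles$start <- tiles$tile * tile_bp + 1
    tiles$end <- (tiles$tile + 1) * tile_bp
  }
  dplyr::arrange(
    dplyr::select(tiles, dplyr::all_of(grp), "start", "end", "n_sites",
                  "n_meth", "n_total", "level"),
    dplyr::across(dplyr::all_of(grp)), .data$start)
}

#' Metagene methylation profile over a feature class
#'
#' Averages methylation over length-normalised feature bodies plus
#' fixed-width flanks: `flank_bp / flank_bin_bp` bins of `flank_bin_bp`
#' upstream (5', strand-oriented) and downstream, and `body_bins`
#' proportional slices of each feature body. Counts are pooled over features
#' and replicates (grouped by `genotype` if present) and each bin reports the
#' weighted level `sum(n_meth) / sum(n_total)`. Features shorter than
#' `body_bins` bp contribute to flanks only and are counted in the
#' `"n_short_features"` attribute.
#'
#' @param report (Filtered) cytosine report tibble.
#' @param annotation Feature tibble `chrom`, `start`, `end`, `strand`,
#'   `class` (1-based inclusive).
#' @param feature_class Class to profile (`"gene"` or `"TE"`).
#' @param context Cytosine context to profile.
#' @param flank_bp,flank_bin_bp Flank extent and bin width (bp).
#' @param body_bins Number of body bins.
#' @param body_mode `"proportional"` (default: each feature body is split
#'   into `body_bins` equal slices, so bodies are length-normalised) or
#'   `"fixed_bp"` (body bins are true `flank_bin_bp` windows from the 5'
#'   end; body positions beyond `body_bins` windows are dropped).
#' @return A tibble with `genotype` (if present), `region`
#'   (`"upstream"`/`"body"`/`"downstream"`), `bin` (1-based within region),
#'   `position` (overall bin index), `n_sites`, `n_meth`, `n_total`, `level`.
#' @export
metagene_profile <- function(report, annotation, feature_class, context,
                             flank_bp = 1000, flank_bin_bp = 100,
                             body_bins = 20,
                             body_mode = c("proportional", "fixed_bp")) {
  body_mode <- match.arg(body_mode)
  feats <- annotation[annotation$class == feature_class, ]
  if (nrow(feats) == 0) stop("no features of class ", feature_class,
                             call. = FALSE)
  sites <- report[report$context == context, ]
  n_flank <- as.integer(flank_bp / flank_bin_bp)
  short <- (feats$end - feats$start + 1) < body_bins

  assignments <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    s <- sites[sites$chrom == f$chrom &
                 sites$pos >= f$start - flank_bp &
                 sites$pos <= f$end + flank_bp, ]
    if (nrow(s) == 0) return(NULL)
    minus <- identical(f$strand, "-")
    # signed offset in feature orientation: <0 upstream, [0, len) body
    len <- f$end - f$start + 1
    off <- if (minus) f$end - s$pos else s$pos - f$start
    region <- dplyr::case_when(
      off < 0 ~ "upstream",
      off >= len ~ "downstream",
      TRUE ~ "body"
    )
    if (short[i]) {
      keep <- region != "body"
      s <- s[keep, ]
      off <- off[keep]
      region <- region[keep]
    }
    bin <- integer(length(off))
    up <- region == "upstream"
    bin[up] <- n_flank + 1L - ceiling(-off[up] / flank_bin_bp)
    dn <- region == "downstream"
    bin[dn] <- ceiling((off[dn] - len + 1) / flank_bin_bp)
    bd <- region == "body"
    if (body_mode == "proportional") {
      bin[bd] <- pmin(body_bins, floor(off[bd] / len * body_bins) + 1L)
    } else {
      bin[bd] <- floor(off[bd] / flank_bin_bp) + 1L
      drop_bd <- bd & bin > body_bins
      s <- s[!drop_bd, ]
      region <- region[!drop_bd]
      bin <- bin[!drop_bd]
    }
    tibble::tibble(genotype = if ("genotype" %in% names(s)) s$genotype else NA,
                   region = region, bin = bin,
                   n_meth = s$n_meth, n_total = s$n_total)
  })
  grp <- if ("genotype" %in% names(report)) c("genotype") else character(0)
  skeleton <- tibble::tibble(
    region = c(rep("upstream", n_flank), rep("body", body_bins),
               rep("downstream", n_flank)),
    bin = c(seq_len(n_flank), seq_len(body_bins), seq_len(n_flank)),
    position = seq_len(2L * n_flank + body_bins)
  )
  if (length(grp)) {
    skeleton <- tidyr::expand_grid(
      genotype = unique(report$genotype), skeleton)
  }
  pooled <- dplyr::summarise(
    dplyr::group_by(assignments,
                    dplyr::across(dplyr::all_of(c(grp, "region", "bin")))),
    n_sites = dplyr::n(), n_meth = sum(.data$n_meth),
    n_total = sum(.data$n_total), .groups = "drop")
  out <- dplyr::left_join(skeleton, pooled, by = c(grp, "region", "bin"))
  out$n_sites <- dplyr::coalesce(out$n_sites, 0L)
  out$n_meth <- dplyr::coalesce(out$n_meth, 0)
  out$n_total <- dplyr::coalesce(out$n_total, 0)
  out$level <- ifelse(out$n_total > 0, out$n_meth / out$n_total, NA_real_)
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(grp)),
                        .data$position)
  attr(out, "n_short_features") <- sum(short)
  attr(out, "context") <- context
  attr(out, "feature_class") <- feature_class
  out
}
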
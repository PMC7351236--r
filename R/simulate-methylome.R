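#' Configuration for a simulated paired bisulfite experiment
#'
#' Describes a toy genome with genes and transposable elements (TEs), base
#' methylation levels per feature class and context, per-context methylation
#' deltas planted in the mutant's TEs, sequencing depth and replication, for
#' [simulate_cytosine_reports()].
#'
#' @param genome_length_bp Toy genome length (single chromosome).
#' @param n_genes,n_tes Feature counts.
#' @param gene_length,te_length Length ranges `c(min, max)` in bp; lengths
#'   are drawn uniformly.
#' @param base_levels Named list of numeric vectors `c(CG=, CHG=, CHH=)`
#'   giving the methylation level for feature classes `gene`, `TE`,
#'   `intergenic`; all values in `[0, 1]`.
#' @param te_deltas Named numeric `c(CG=, CHG=, CHH=)` added to the TE level
#'   in the mutant genotype (clamped to `[0, 1]`); values in `[-1, 1]`.
#' @param mean_coverage Mean reads per cytosine (Poisson).
#' @param n_replicates Replicates per genotype.
#' @param gc GC content of the random genome.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `methylome_sim_config`.
#' @export
methylome_sim_config <- function(genome_length_bp = 1e6,
                                 n_genes = 60, n_tes = 40,
                                 gene_length = c(1000, 3000),
                                 te_length = c(500, 3000),
                                 base_levels = list(
                                   gene = c(CG = 0.20, CHG = 0.02, CHH = 0.02),
                                   TE = c(CG = 0.80, CHG = 0.40, CHH = 0.15),
                                   intergenic = c(CG = 0.05, CHG = 0.02, CHH = 0.02)
                                 ),
                                 te_deltas = c(CG = 0.12, CHG = 0.21, CHH = 0.06),
                                 mean_coverage = 30,
                                 n_replicates = 3,
                                 gc = 0.36,
                                 seed = NULL) {
  lv <- unlist(base_levels)
  if (any(lv < 0 | lv > 1)) stop("base levels must lie in [0, 1]", call. = FALSE)
  if (any(te_deltas < -1 | te_deltas > 1)) {
    stop("te_deltas must lie in [-1, 1]", call. = FALSE)
  }
  if (mean_coverage < 0) stop("mean_coverage must be >= 0", call. = FALSE)
  stopifnot(all(c("CG", "CHG", "CHH") %in% names(te_deltas)),
            all(c("gene", "TE", "intergenic") %in% names(base_levels)))
  total_feat <- n_genes * gene_length[2] + n_tes * te_length[2]
  if (total_feat > 0.8 * genome_length_bp) {
    stop("features would occupy more than 80% of the genome", call. = FALSE)
  }
  structure(list(genome_length_bp = genome_length_bp, n_genes = n_genes,
                 n_tes = n_tes, gene_length = gene_length,
                 te_length = te_length, base_levels = base_levels,
                 te_deltas = te_deltas, mean_coverage = mean_coverage,
                 n_replicates = as.integer(n_replicates), gc = gc,
                 seed = seed),
            class = "methylome_sim_config")
}

# Non-overlapping feature placement by stick-breaking of the spare sequence.
place_features <- function(config) {
  n_feat <- config$n_genes + config$n_tes
  lens <- c(
    round(stats::runif(config$n_genes, config$gene_length[1],
                       config$gene_length[2])),
    round(stats::runif(config$n_tes, config$te_length[1],
                       config$te_length[2]))
  )
  classes <- c(rep("gene", config$n_genes), rep("TE", config$n_tes))
  ord <- sample.int(n_feat)
  lens <- lens[ord]
  classes <- classes[ord]
  spare <- config$genome_length_bp - sum(lens)
  cuts <- sort(stats::runif(n_feat))
  gaps <- floor(diff(c(0, cuts)) * spare)
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n_feat])) + 1
  tibble::tibble(
    chrom = "chr1",
    start = starts,
    end = starts + lens - 1,
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    class = classes,
    feature_id = sprintf("%s_%03d", classes,
                         as.integer(stats::ave(seq_len(n_feat), classes,
                                               FUN = seq_along)))
  )
}

#' Simulate paired bisulfite cytosine reports
#'
#' Emits a random genome, annotates every cytosine context on both strands,
#' assigns each site the methylation level of its enclosing feature class and
#' context (plus the configured delta inside the mutant's TEs, clamped to
#' `[0, 1]`), then draws per-site totals from a Poisson and methylated counts
#' from a Binomial, independently per replicate and genotype. Planted
#' differentially methylated intervals (the full TE extents, per context with
#' a non-zero delta) are recorded as truth, with a flag where clamping
#' saturated the level at 0 or 1.
#'
#' @param config A [methylome_sim_config()].
#' @return A list with
#'   \describe{
#'     \item{reports}{tibble with `genotype` (`"wt"`/`"mut"`), `replicate`,
#'       `chrom`, `pos`, `strand`, `context`, `n_meth`, `n_total`.}
#'     \item{annotation}{feature tibble (`chrom`, `start`, `end`, `strand`,
#'       `class`, `feature_id`), 1-based inclusive coordinates.}
#'     \item{genome}{named character vector of the emitted sequence.}
#'     \item{truth}{tibble of planted DMRs: `chrom`, `start`, `end`,
#'       `context`, `delta`, `direction`, `clamped`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cytosine_reports(
#'   methylome_sim_config(genome_length_bp = 5e4, n_genes = 3, n_tes = 3,
#'                        seed = 1))
#' dplyr::count(sim$reports, genotype, replicate)
simulate_cytosine_reports <- function(config) {
  stopifnot(inherits(config, "methylome_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length_bp
  gc <- config$gc
  bases <- sample(c("A", "T", "C", "G"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  genome <- c(chr1 = paste(bases, collapse = ""))
  annotation <- place_features(config)
  sites <- annotate_contexts(genome)

  # feature class per site (features are non-overlapping)
  feat_idx <- interval_match(sites$pos, annotation$start, annotation$end)
  site_class <- ifelse(is.na(feat_idx), "intergenic",
                       annotation$class[feat_idx])
  lvl_tab <- do.call(rbind, config$base_levels)
  base_level <- lvl_tab[cbind(site_class, sites$context)]
  in_te <- !is.na(feat_idx) & annotation$class[feat_idx] == "TE"
  delta <- ifelse(in_te, config$te_deltas[sites$context], 0)
  mut_level <- pmin(1, pmax(0, base_level + delta))

  n_sites <- nrow(sites)
  reps <- config$n_replicates
  draw <- function(genotype, level) {
    purrr::map_dfr(seq_len(reps), function(rep_i) {
      total <- stats::rpois(n_sites, config$mean_coverage)
      meth <- stats::rbinom(n_sites, total, level)
      tibble::tibble(genotype = genotype, replicate = rep_i,
                     chrom = sites$chrom, pos = sites$pos,
                     strand = sites$strand, context = sites$context,
                     n_meth = meth, n_total = total)
    })
  }
  reports <- dplyr::bind_rows(draw("wt", base_level),
                              draw("mut", mut_level))

  te_rows <- annotation[annotation$class == "TE", ]
  truth <- purrr::map_dfr(names(config$te_deltas), function(ctx) {
    dl <- config$te_deltas[[ctx]]
    if (dl == 0) return(NULL)
    te_base <- config$base_levels$TE[[ctx]]
    tibble::tibble(chrom = te_rows$chrom, start = te_rows$start,
                   end = te_rows$end, context = ctx, delta = dl,
                   direction = ifelse(dl > 0, "hyper", "hypo"),
                   clamped = (te_base + dl) > 1 | (te_base + dl) < 0)
  })
  list(reports = reports, annotation = annotation, genome = genome,
       truth = truth, config = config)
}

# Index of the (non-overlapping, sorted-by-start) interval containing each
# position, NA when outside all intervals.
interval_match <- function(pos, start, end) {
  o <- order(start)
  idx <- findInterval(pos, start[o])
  hit <- idx >= 1 & pos <= end[o][pmax(idx, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[hit] <- o[idx[hit]]
  out
}
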
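#' Run the recombination analysis pipeline
#'
#' Composes the recombination track end-to-end: obtain genotype data for the
#' two populations (simulated from configured crossover landscapes, or read
#' from genotype CSV + marker TSV files), call breakpoints, summarise
#' crossover counts, build Kosambi genetic maps, compare interval rates
#' under the two-stage FDR, fit the exponential distality gradient on the
#' second population's map, and compute inter-crossover distances against
#' the random null. Identical seeds give identical outputs.
#'
#' @param config A named list (or path to a YAML file) with entries
#'   \describe{
#'     \item{seed}{integer, seeds all randomness.}
#'     \item{simulate}{list with `n_plants_a`, `n_plants_b`,
#'       `expected_co_a`, `expected_co_b`, `landscape_b`
#'       (`"distal_exponential"` by default), `distal_rate`, `n_markers`,
#'       `genotyping_error`, `missing_rate`; omit to read files instead.}
#'     \item{genotypes_a, genotypes_b, markers, centromeres}{input paths,
#'       used when `simulate` is absent.}
#'     \item{q}{FDR level (default 0.01).}
#'     \item{map_function}{`"kosambi"` (default) or `"haldane"`.}
#'     \item{anchor}{`"centromere"` (default) or `"telomere"` for the
#'       distality predictor.}
#'     \item{out_dir}{optional output directory; when set, all result
#'       tables, a summary JSON and the resolved config YAML are written.}
#'   }
#' @return A list with `summaries`, `maps`, `comparison`, `distality`,
#'   `distances`, `profiles` and `config` (the resolved configuration).
#' @export
run_recomb_pipeline <- function(config) {
  config <- resolve_config(config, defaults = list(
    seed = 1L, q = 0.01, map_function = "kosambi", anchor = "centromere",
    n_null = 10000L))
  set.seed(config$seed)
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim_defaults <- list(n_plants_a = 173, n_plants_b = 348,
                         expected_co_a = 5.1, expected_co_b = 5.2,
                         landscape_b = "distal_exponential", distal_rate = 3,
                         n_markers = 96, genotyping_error = 0,
                         missing_rate = 0.02)
    sc <- utils::modifyList(sim_defaults, sc)
    config$simulate <- sc
    chroms <- arabidopsis_chromosomes()
    sim_a <- simulate_bc1_population(meiosis_sim_config(
      chromosomes = chroms, landscape = co_landscape("uniform"),
      expected_co_per_gamete = sc$expected_co_a, n_plants = sc$n_plants_a,
      n_markers = sc$n_markers, genotyping_error = sc$genotyping_error,
      missing_rate = sc$missing_rate))
    sim_b <- simulate_bc1_population(meiosis_sim_config(
      chromosomes = chroms,
      landscape = co_landscape(sc$landscape_b, rate = sc$distal_rate),
      expected_co_per_gamete = sc$expected_co_b, n_plants = sc$n_plants_b,
      n_markers = sc$n_markers, genotyping_error = sc$genotyping_error,
      missing_rate = sc$missing_rate))
    geno_a <- sim_a$genotypes
    geno_b <- sim_b$genotypes
    markers <- sim_a$markers
  } else {
    geno_a <- read_genotypes_csv(config$genotypes_a)
    geno_b <- read_genotypes_csv(config$genotypes_b)
    markers <- read_marker_map_tsv(config$markers)
    chroms <- read_centromere_tsv(config$centromeres)
  }

  prof_a <- call_breakpoints(geno_a, markers)
  prof_b <- call_breakpoints(geno_b, markers)
  sum_a <- co_count_summary(prof_a)
  sum_b <- co_count_summary(prof_b)
  map_a <- build_genetic_map(geno_a, markers,
                             map_function = config$map_function)
  map_b <- build_genetic_map(geno_b, markers,
                             map_function = config$map_function)
  comparison <- compare_maps(geno_a, geno_b, markers, q = config$q)

  iv <- dplyr::left_join(map_b$intervals,
                         chroms[, c("chrom", "length_bp", "centromere_bp")],
                         by = "chrom", suffix = c("", "_chrom"))
  len_col <- if ("length_bp_chrom" %in% names(iv)) "length_bp_chrom" else
    "length_bp"
  iv$rel_dist <- relative_distance(iv$mid_bp, iv[[len_col]],
                                   iv$centromere_bp, anchor = config$anchor)
  pts <- iv[!is.na(iv$cm_per_mb), c("rel_dist", "cm_per_mb")]
  distality <- fit_distality(pts, x = "rel_dist", y = "cm_per_mb")

  dist_a <- inter_co_distances(prof_a, chroms, n_null = config$n_null)
  dist_b <- inter_co_distances(prof_b, chroms, n_null = config$n_null)

  summary_json <- list(
    seed = config$seed, q = config$q, map_function = config$map_function,
    anchor = config$anchor,
    mean_co_a = sum_a$overall$mean_co,
    ci_a = c(sum_a$overall$ci_low, sum_a$overall$ci_high),
    mean_co_b = sum_b$overall$mean_co,
    ci_b = c(sum_b$overall$ci_low, sum_b$overall$ci_high),
    genome_cm_a = map_a$genome_cm, genome_cm_b = map_b$genome_cm,
    n_flagged = sum(comparison$significant),
    n_flagged_increased = sum(comparison$direction %in% "increased"),
    n_flagged_decreased = sum(comparison$direction %in% "decreased"),
    distality_a = distality$a, distality_b = distality$b,
    distality_r2 = distality$r2,
    mean_inter_co_a = dist_a$tests$mean_distance,
    mean_inter_co_b = dist_b$tests$mean_distance
  )

  result <- list(
    summaries = list(a = sum_a, b = sum_b),
    maps = list(a = map_a, b = map_b),
    comparison = comparison, distality = distality,
    distances = list(a = dist_a, b = dist_b),
    profiles = list(a = prof_a, b = prof_b),
    summary = summary_json, config = config
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    readr::write_tsv(map_a$intervals, file.path(od, "map_a.tsv"))
    readr::write_tsv(map_b$intervals, file.path(od, "map_b.tsv"))
    readr::write_tsv(comparison, file.path(od, "comparison.tsv"))
    readr::write_tsv(iv[, c("chrom", "mid_bp", "rel_dist", "cm_per_mb")],
                     file.path(od, "distality_points.tsv"))
    readr::write_tsv(dist_b$distances, file.path(od, "inter_co_distances.tsv"))
    jsonlite::write_json(summary_json, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(config, file.path(od, "config_resolved.yaml"))
  }
  result
}

#' Run the methylome analysis pipeline
#'
#' Composes the methylation track: obtain paired cytosine reports (simulated
#' with planted hypermethylated TEs, or read from CX report files plus a
#' feature BED), filter by coverage, compute chromosome tiles and metagene
#' profiles for each context, run per-site differential tests and the DMR
#' rule chain, and — when simulation truth is available — report recovery
#' metrics.
#'
#' @param config A named list (or YAML path) with entries `seed`,
#'   `min_coverage` (default 5), `tile_bp` (200000), DMR parameters
#'   (`p_thresh`, `min_len`, `min_dml`, `min_frac_sig`, `merge_gap`,
#'   `cutoff_cg`, `cutoff_chg`, `cutoff_chh`), `contexts` (default all
#'   three), either `simulate` (a list of [methylome_sim_config()]
#'   arguments) or input paths (`reports_a`, `reports_b`: vectors of CX
#'   files; `features`: BED path), and optional `out_dir`.
#' @return A list with `tiles`, `metagenes`, `dml`, `dmrs`, `recovery`,
#'   `summary` and `config`.
#' @export
run_methylome_pipeline <- function(config) {
  config <- resolve_config(config, defaults = list(
    seed = 1L, min_coverage = 5, tile_bp = 200000, p_thresh = 1e-4,
    min_len = 50, min_dml = 3, min_frac_sig = 0.5, merge_gap = 50,
    cutoff_cg = 0.30, cutoff_chg = 0.20, cutoff_chh = 0.10,
    contexts = c("CG", "CHG", "CHH")))
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- do.call(methylome_sim_config, sim_args)
    simdata <- simulate_cytosine_reports(sim)
    reports <- simdata$reports
    annotation <- simdata$annotation
    truth <- simdata$truth
  } else {
    read_stack <- function(paths, genotype) {
      purrr::imap_dfr(paths, function(p, i) {
        dplyr::mutate(read_cx_report(p), genotype = genotype,
                      replicate = i, .before = 1)
      })
    }
    reports <- dplyr::bind_rows(read_stack(config$reports_a, "wt"),
                                read_stack(config$reports_b, "mut"))
    if (!"context" %in% names(reports)) {
      stop("reports lack a context column; expected CX-style input",
           call. = FALSE)
    }
    annotation <- read_features_bed(config$features)
  }
  filtered <- filter_coverage(reports, min_total = config$min_coverage)
  wt <- filtered[filtered$genotype == "wt", ]
  mut <- filtered[filtered$genotype == "mut", ]

  cutoffs <- c(CG = config$cutoff_cg, CHG = config$cutoff_chg,
               CHH = config$cutoff_chh)
  tiles <- tile_methylation(filtered, tile_bp = config$tile_bp)
  metagenes <- purrr::map_dfr(config$contexts, function(ctx) {
    purrr::map_dfr(intersect(c("gene", "TE"), annotation$class),
                   function(cl) {
      mp <- metagene_profile(filtered, annotation, cl, ctx)
      dplyr::mutate(mp, context = ctx, feature_class = cl)
    })
  })
  dml <- purrr::map(config$contexts, function(ctx) dml_test(wt, mut, ctx))
  names(dml) <- config$contexts
  dmrs <- purrr::map_dfr(config$contexts, function(ctx) {
    call_dmrs(dml[[ctx]], ctx, p_thresh = config$p_thresh,
              min_len = config$min_len, min_dml = config$min_dml,
              min_frac_sig = config$min_frac_sig,
              merge_gap = config$merge_gap, diff_cutoff = cutoffs)
  })
  recovery <- if (!is.null(truth) && nrow(truth) > 0) {
    dmr_recovery_metrics(dmrs, truth)
  } else NULL
  te_overlap <- if (nrow(dmrs) > 0) {
    overlap_fraction(dmrs, annotation[annotation$class == "TE", ])
  } else NULL

  summary_json <- list(
    seed = config$seed,
    thresholds = config[c("min_coverage", "tile_bp", "p_thresh", "min_len",
                          "min_dml", "min_frac_sig", "merge_gap",
                          "cutoff_cg", "cutoff_chg", "cutoff_chh")],
    n_sites_filtered = nrow(filtered),
    n_dmrs = nrow(dmrs),
    n_dmrs_by = if (nrow(dmrs)) as.list(table(paste(dmrs$context,
                                                    dmrs$direction))) else
      list(),
    te_overlap_fraction = if (!is.null(te_overlap)) te_overlap$fraction else
      NA,
    precision = if (!is.null(recovery)) recovery$precision else NA,
    recall = if (!is.null(recovery)) recovery$recall else NA
  )
  result <- list(tiles = tiles, metagenes = metagenes, dml = dml,
                 dmrs = dmrs, recovery = recovery, summary = summary_json,
                 config = config)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tiles, file.path(od, "tiles.tsv"))
    readr::write_tsv(metagenes, file.path(od, "metagenes.tsv"))
    if (nrow(dmrs)) {
      readr::write_tsv(dmrs, file.path(od, "dmrs.tsv"))
      write_dmrs_bed(dmrs, file.path(od, "dmrs.bed"))
    }
    jsonlite::write_json(summary_json, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(config, file.path(od, "config_resolved.yaml"))
  }
  result
}

# Accept a YAML path or a list, fill defaults.
resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  utils::modifyList(defaults, config)
}
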
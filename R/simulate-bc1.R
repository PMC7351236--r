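#' Configuration for a simulated BC1 genotyping experiment
#'
#' Bundles the genome, the per-chromosome crossover landscape, population
#' size, marker design and genotyping noise for [simulate_bc1_population()].
#'
#' When a single [co_landscape()] is supplied it is applied to every
#' chromosome, with `expected_co_per_gamete` split across chromosomes in
#' proportion to physical length. A named list of landscapes (one per
#' chromosome, using each landscape's own `expected_events`) overrides this.
#'
#' @param chromosomes Tibble of chromosomes ([chromosome_spec()] rows).
#' @param landscape A single [co_landscape()] or a list of one per chromosome.
#' @param expected_co_per_gamete Genome-wide mean crossover count per gamete;
#'   used only when `landscape` is a single object.
#' @param n_plants Number of BC1 plants (one gamete each).
#' @param n_markers Total marker count, allocated to chromosomes by physical
#'   length (largest remainder, at least 2 per chromosome) and spaced evenly
#'   along each chromosome.
#' @param genotyping_error Probability that a call is flipped (A <-> H).
#' @param missing_rate Probability that a call is masked to `NA`.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `meiosis_sim_config`.
#' @export
meiosis_sim_config <- function(chromosomes = arabidopsis_chromosomes(),
                               landscape = co_landscape("uniform"),
                               expected_co_per_gamete = 5.1,
                               n_plants = 173,
                               n_markers = 96,
                               genotyping_error = 0,
                               missing_rate = 0.02,
                               seed = NULL) {
  stopifnot(n_plants >= 1, n_markers >= 2 * nrow(chromosomes))
  if (genotyping_error < 0 || genotyping_error > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    stop("genotyping_error and missing_rate must lie in [0, 1]", call. = FALSE)
  }
  if (inherits(landscape, "co_landscape")) {
    share <- chromosomes$length_bp / sum(chromosomes$length_bp)
    landscape <- lapply(share, function(s) {
      l <- landscape
      l$expected_events <- expected_co_per_gamete * s
      l
    })
    names(landscape) <- chromosomes$chrom
  } else {
    if (length(landscape) != nrow(chromosomes)) {
      stop("need one landscape per chromosome", call. = FALSE)
    }
    if (is.null(names(landscape))) names(landscape) <- chromosomes$chrom
  }
  structure(list(chromosomes = chromosomes, landscape = landscape,
                 n_plants = as.integer(n_plants),
                 n_markers = as.integer(n_markers),
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate, seed = seed),
            class = "meiosis_sim_config")
}

# Evenly spaced markers over each chromosome, 96 genome-wide by default.
allocate_markers <- function(chromosomes, n_markers) {
  share <- chromosomes$length_bp / sum(chromosomes$length_bp)
  raw <- share * n_markers
  k <- pmax(2L, floor(raw))
  rem <- n_markers - sum(k)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep_len(ord, rem)
    for (i in idx) k[i] <- k[i] + 1L
  } else if (rem < 0) {
    ord <- order(raw - floor(raw))
    for (i in rep_len(ord[k[ord] > 2L], -rem)) k[i] <- k[i] - 1L
  }
  purrr::map2_dfr(seq_len(nrow(chromosomes)), k, function(i, ki) {
    L <- chromosomes$length_bp[i]
    pos <- round(seq(0.01 * L, 0.99 * L, length.out = ki))
    tibble::tibble(
      marker = sprintf("%s_M%02d", chromosomes$chrom[i], seq_len(ki)),
      chrom = chromosomes$chrom[i],
      pos_bp = pos
    )
  })
}

#' Simulate a BC1 backcross genotyping dataset
#'
#' Draws one gamete (chromatid) per plant from the configured crossover
#' landscapes, reads the gamete out at the marker positions, and applies
#' genotyping error and missingness. Each marker call is `"A"` (recurrent
#' homozygote) or `"H"` (heterozygote); the call at a marker is determined by
#' a random starting phase (probability 1/2) flipped once per crossover to
#' the marker's left. True crossover positions are recorded before error and
#' masking.
#'
#' @param config A [meiosis_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{tibble, one row per plant: `plant` plus one character
#'       column per marker with values `"A"`, `"H"`, or `NA`.}
#'     \item{markers}{tibble `marker`, `chrom`, `pos_bp` in map order.}
#'     \item{truth}{tibble `plant`, `chrom`, `pos_bp` of true crossovers.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_bc1_population(meiosis_sim_config(n_plants = 20, seed = 1))
#' dim(sim$genotypes)
simulate_bc1_population <- function(config) {
  stopifnot(inherits(config, "meiosis_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  chroms <- config$chromosomes
  markers <- allocate_markers(chroms, config$n_markers)
  n <- config$n_plants
  plants <- sprintf("plant_%04d", seq_len(n))

  geno_cols <- list()
  truth <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms[i, ]
    mk <- markers[markers$chrom == ch$chrom, ]
    if (nrow(mk) == 0) stop("chromosome without markers", call. = FALSE)
    gametes <- sample_co_positions(config$landscape[[ch$chrom]], ch, n = n)
    phase0 <- stats::rbinom(n, 1, 0.5)
    calls <- matrix(NA_character_, nrow = n, ncol = nrow(mk))
    for (p in seq_len(n)) {
      k_left <- findInterval(mk$pos_bp, gametes[[p]])
      state <- (phase0[p] + k_left) %% 2
      calls[p, ] <- ifelse(state == 1, "H", "A")
    }
    if (config$genotyping_error > 0) {
      flip <- matrix(stats::runif(length(calls)) < config$genotyping_error,
                     nrow = n)
      calls[flip] <- ifelse(calls[flip] == "A", "H", "A")
    }
    if (config$missing_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow = n)] <- NA_character_
    }
    colnames(calls) <- mk$marker
    geno_cols[[i]] <- calls
    n_co <- lengths(gametes)
    truth[[i]] <- tibble::tibble(
      plant = rep(plants, n_co),
      chrom = ch$chrom,
      pos_bp = unlist(gametes)
    )
  }
  genotypes <- tibble::as_tibble(do.call(cbind, geno_cols))
  genotypes <- dplyr::bind_cols(tibble::tibble(plant = plants), genotypes)
  list(genotypes = genotypes, markers = markers,
       truth = dplyr::bind_rows(truth), config = config)
}

#' Marker-resolution observable crossover counts from simulation truth
#'
#' Counts, per gamete, the marker intervals holding an odd number of true
#' crossovers. This is the quantity a breakpoint caller can recover at a
#' given marker density: an even number of crossovers between two adjacent
#' markers leaves no phase change and is invisible to any caller.
#'
#' @param truth Truth tibble from [simulate_bc1_population()].
#' @param markers Marker map tibble.
#' @param plants Character vector of all plant ids (so zero-crossover plants
#'   are included).
#' @return A tibble `plant`, `n_co_observable`.
#' @export
observable_co_counts <- function(truth, markers, plants) {
  per_chrom <- lapply(split(markers, markers$chrom), function(mk) {
    tr <- truth[truth$chrom == mk$chrom[1], ]
    if (nrow(tr) == 0) return(NULL)
    # interval index of each true CO; COs outside the marker span cannot
    # change any scored call
    iv <- findInterval(tr$pos_bp, sort(mk$pos_bp))
    keep <- iv >= 1 & iv < nrow(mk)
    if (!any(keep)) return(NULL)
    dplyr::count(
      dplyr::distinct(
        dplyr::filter(
          dplyr::count(tibble::tibble(plant = tr$plant[keep], iv = iv[keep]),
                       .data$plant, .data$iv),
          .data$n %% 2 == 1
        ),
        .data$plant, .data$iv
      ),
      .data$plant, name = "n_obs"
    )
  })
  obs <- dplyr::bind_rows(per_chrom)
  out <- tibble::tibble(plant = plants)
  if (nrow(obs) > 0) {
    tot <- dplyr::summarise(dplyr::group_by(obs, .data$plant),
                            n_co_observable = sum(.data$n_obs), .groups = "drop")
    out <- dplyr::left_join(out, tot, by = "plant")
  } else {
    out$n_co_observable <- NA_integer_
  }
  out$n_co_observable <- dplyr::coalesce(out$n_co_observable, 0L)
  out
}
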
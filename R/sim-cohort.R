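#' Generate a complete synthetic two-sample study
#'
#' Runs the full generative model: genotypes with block LD, latent methylation
#' propensities, the continuous phenotype under the configured causal model,
#' extreme-group selection (a larger pool is generated and the phenotype tails
#' retained, mirroring recruitment of divergent-phenotype subjects), RRBS
#' counts for the retained subjects, an independent outcome-GWAS cohort, and
#' annotation tracks enriched at the causal SNPs.
#'
#' The outcome cohort uses a distinct RNG stream and shares no subjects with
#' the methylation cohort. Identical config and seed give identical output.
#'
#' @param config A [sim_config()].
#' @param annotation_tracks,annotation_odds,annotation_q0 Annotation-track
#'   generation settings (see [simulate_annotations()]).
#' @param select_extremes If FALSE, the methylation cohort is a simple random
#'   cohort of `n_subjects` (used for estimator-focused experiments); group
#'   labels are then assigned by the sign of the phenotype.
#' @return An `mm_cohort` list: `config`, `genotypes`, `methylation`,
#'   `phenotypes`, `sumstats`, `annotations`, `truth` (focal CpG, causal SNP
#'   effects, scenario wiring).
#' @export
simulate_cohort <- function(config,
                            annotation_tracks = 2,
                            annotation_odds = 10,
                            annotation_q0 = 0.1,
                            select_extremes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  if (config$scenario == "linkage" && config$linkage_r2 > 0) {
    config$ld_block_spec$rho[1] <-
      latent_rho_for_r2(config$linkage_r2, mean(config$maf_range))
  }
  set.seed(derive_seed(seed, 0L))
  mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])

  set.seed(derive_seed(seed, 3L))
  signs <- if (config$pleiotropy_type == "directional") {
    rep(1, config$n_instruments)
  } else {
    sample(c(-1, 1), config$n_instruments, replace = TRUE)
  }

  cohort <- NULL
  for (attempt in 1:3) {
    pool_n <- if (select_extremes) {
      as.integer(ceiling(config$n_subjects / 0.30) * 2^(attempt - 1))
    } else config$n_subjects
    g_pool <- simulate_genotypes(config, n = pool_n,
                                 seed = derive_seed(seed, 20L + attempt),
                                 mafs = mafs)
    wiring <- scenario_wiring(config, g_pool$snps, pleiotropy_signs = signs)
    cpgs <- make_cpg_table(config, g_pool$snps)
    set.seed(derive_seed(seed, 30L + attempt))
    if (config$scenario == "reverse") {
      eps <- stats::rnorm(pool_n)
      y <- phenotype_from_model(g_pool, config, wiring, eps = eps,
                                mafs = mafs)
      lat <- meth_latent_matrix(g_pool, cpgs, wiring$assignments, config,
                                y = y, reverse_y_cpgs = wiring$reverse_y_cpgs)
    } else {
      lat <- meth_latent_matrix(g_pool, cpgs, wiring$assignments, config)
      mediator <- centered_mediator(lat, cpgs, wiring, mafs, g_pool$snps)
      y <- phenotype_from_model(g_pool, config, wiring,
                                mediator = if (wiring$use_mediator) mediator,
                                mafs = mafs)
    }
    if (select_extremes) {
      keep <- which(abs(y) >= config$group_z_threshold)
    } else {
      keep <- seq_len(pool_n)
    }
    if (length(keep) >= config$n_subjects) {
      keep <- keep[seq_len(config$n_subjects)]
      grp <- as.integer(y[keep] >= 0)
      if (sum(grp == 0L) >= 2 && sum(grp == 1L) >= 2) {
        cohort <- list(g = subset_geno(g_pool, subjects = keep),
                       lat = lat[, keep, drop = FALSE],
                       y = y[keep], cpgs = cpgs, wiring = wiring)
        break
      }
    }
  }
  if (is.null(cohort)) {
    stop_mm("could not assemble %d subjects with >= 2 per extreme group",
            config$n_subjects)
  }

  set.seed(derive_seed(seed, 4L))
  cnt <- draw_meth_counts(cohort$lat, config)
  meth <- structure(list(cpgs = cohort$cpgs, m = cnt$m, n = cnt$n,
                         latent = cohort$lat),
                    class = "meth_counts")

  pheno <- phenotype_table(cohort$y, rownames(cohort$g$dosages), config,
                           seed = derive_seed(seed, 5L))
  if (!select_extremes) pheno$group <- as.integer(pheno$y >= 0)

  sumstats <- simulate_outcome_gwas(config, cohort$wiring, mafs = mafs,
                                    snps_meta = cohort$g$snps,
                                    seed = derive_seed(seed, 6L))

  causal_snps <- unique(c(cohort$wiring$assignments$snp,
                          names(cohort$wiring$direct)[cohort$wiring$direct != 0]))
  ann <- simulate_annotations(cohort$g, causal_snps,
                              enrichment_odds = annotation_odds,
                              n_tracks = annotation_tracks,
                              q0 = annotation_q0,
                              seed = derive_seed(seed, 8L))

  structure(
    list(
      config = config,
      genotypes = cohort$g,
      methylation = meth,
      phenotypes = pheno,
      sumstats = sumstats,
      annotations = ann,
      truth = list(
        focal_cpg = cohort$wiring$focal_cpg,
        instruments = cohort$wiring$assignments,
        trait_snps = cohort$wiring$trait_snps,
        linkage_pair = cohort$wiring$linkage_pair,
        pleiotropy_signs = if (config$scenario == "pleiotropy") signs,
        wiring = cohort$wiring
      )
    ),
    class = "mm_cohort"
  )
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("<mm_cohort> scenario=%s: %d subjects (%d high / %d low), %d SNPs, %d CpGs\n",
              x$config$scenario, nrow(x$phenotypes),
              sum(x$phenotypes$group == 1L), sum(x$phenotypes$group == 0L),
              nrow(x$genotypes$snps), nrow(x$methylation$cpgs)))
  invisible(x)
}
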
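#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration object driving the synthetic-cohort
#' generator. The generator emulates a two-sample design: a small methylation
#' cohort recruited from the tails of the phenotype distribution (extreme
#' high/low groups, as in divergent bone-density sampling) plus a large,
#' independent outcome-GWAS cohort. One of five generative causal models links
#' genotype (G), CpG methylation (M) and the continuous phenotype (Y):
#'
#' * `mediation`: G -> M -> Y (methylation mediates the genetic effect),
#' * `linkage`: distinct SNPs in LD drive M and Y respectively,
#' * `pleiotropy`: G -> M -> Y plus a direct G -> Y path on each instrument,
#' * `reverse`: G -> Y -> M (methylation is downstream of the trait),
#' * `null`: no effects anywhere.
#'
#' @param n_subjects Target size of the retained extreme-phenotype methylation
#'   cohort (both groups combined).
#' @param n_outcome_gwas Size of the independent outcome-GWAS cohort.
#' @param n_cpgs Number of CpG sites. CpG 1 is the focal (causal-model) site;
#'   the rest are null.
#' @param ld_block_spec Tibble with columns `size`, `rho`, `chrom` and
#'   optionally `structure` (`"exchangeable"` or `"ar1"`). `rho` is the latent
#'   Gaussian haplotype correlation within the block; dosage correlation is
#'   attenuated relative to `rho` by the threshold model. Defaults to
#'   `n_instruments` blocks of 12 SNPs at latent rho 0.8 on chr1 plus one
#'   independent block of `n_trait_snps` SNPs on chr2; the block size keeps
#'   the number of HEIDI-eligible cis SNPs in the realistic (up to ~20)
#'   range.
#' @param maf_range Interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param mean_coverage,coverage_dispersion Negative-binomial read-coverage
#'   model: mean reads per CpG per subject and NB size (smaller = more
#'   over-dispersed). The default mean matches deep RRBS coverage (46.52x).
#' @param scenario One of `"mediation"`, `"linkage"`, `"pleiotropy"`,
#'   `"reverse"`, `"null"`.
#' @param b_gm Genotype-to-methylation effect, logit units per effect allele.
#'   Instruments receive effects `b_gm * seq(0.5, 1.5, length = n_instruments)`
#'   so the instrument-strength spread needed by Egger regression exists.
#' @param b_my Methylation-to-phenotype effect, phenotype SD per logit unit of
#'   the latent methylation propensity.
#' @param b_gy_direct Direct genotype-to-phenotype effect per allele: the
#'   instrument direct effects under pleiotropy, the trait-causal-SNP effect
#'   under linkage, and the trait-SNP effects under reverse causation.
#' @param b_gy_bg Effect per allele of the background trait SNPs (chr2 block)
#'   that supply reverse-direction instruments in the mediation, linkage and
#'   pleiotropy scenarios.
#' @param b_yg_rev Phenotype-to-methylation effect (logit units per phenotype
#'   SD) under the reverse scenario.
#' @param linkage_r2 Target dosage r^2 between the methylation-causal and
#'   trait-causal SNPs under the linkage scenario. The focal block's latent
#'   correlation is calibrated numerically so the realized LD hits this value
#'   in expectation.
#' @param n_instruments Number of causal mQTL SNPs for the focal CpG
#'   (mediation/pleiotropy), one per chr1 block.
#' @param n_trait_snps Number of trait-associated background SNPs (chr2).
#' @param pleiotropy_type `"balanced"` (random-sign direct effects) or
#'   `"directional"` (all positive).
#' @param logit_noise_sd SD of the subject-level Gaussian noise added to the
#'   latent methylation logit. Values above zero produce over-dispersion
#'   relative to the binomial read-sampling model.
#' @param baseline_beta_range Range of baseline methylation levels (beta
#'   values) for null CpGs; the focal CpG baseline is 0.5.
#' @param group_z_threshold Phenotype threshold defining the extreme groups:
#'   subjects with y >= +threshold form the high group, y <= -threshold the
#'   low group, and the rest are excluded.
#' @param pos_step Base-pair spacing between consecutive SNPs on a chromosome.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 150,
                       n_outcome_gwas = 50000,
                       n_cpgs = 20,
                       ld_block_spec = NULL,
                       maf_range = c(0.1, 0.5),
                       mean_coverage = 46.52,
                       coverage_dispersion = 8,
                       scenario = c("mediation", "linkage", "pleiotropy",
                                    "reverse", "null"),
                       b_gm = 0.8,
                       b_my = 0.3,
                       b_gy_direct = 1.0,
                       b_gy_bg = 0.15,
                       b_yg_rev = 0.5,
                       linkage_r2 = 0.5,
                       n_instruments = 5,
                       n_trait_snps = 5,
                       pleiotropy_type = c("balanced", "directional"),
                       logit_noise_sd = 1,
                       baseline_beta_range = c(0.2, 0.8),
                       group_z_threshold = 0.8,
                       pos_step = 2000,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  pleiotropy_type <- match.arg(pleiotropy_type)
  if (is.null(ld_block_spec)) {
    ld_block_spec <- dplyr::bind_rows(
      tibble::tibble(size = rep(12L, n_instruments), rho = 0.8, chrom = "chr1"),
      tibble::tibble(size = n_trait_snps, rho = 0, chrom = "chr2")
    )
  }
  ld_block_spec <- tibble::as_tibble(ld_block_spec)
  if (!all(c("size", "rho", "chrom") %in% names(ld_block_spec))) {
    stop_mm("ld_block_spec needs columns size, rho, chrom")
  }
  if (!"structure" %in% names(ld_block_spec)) {
    ld_block_spec$structure <- "exchangeable"
  }
  stopifnot(
    n_subjects >= 4, n_outcome_gwas >= 10, n_cpgs >= 1,
    all(ld_block_spec$size >= 1),
    all(ld_block_spec$rho >= 0 & ld_block_spec$rho < 1),
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    mean_coverage > 0, coverage_dispersion > 0,
    linkage_r2 >= 0, linkage_r2 <= 1,
    group_z_threshold > 0,
    logit_noise_sd >= 0
  )
  n_snps <- sum(ld_block_spec$size)
  if (scenario %in% c("mediation", "pleiotropy")) {
    n_chr1_blocks <- sum(ld_block_spec$chrom == "chr1")
    if (n_chr1_blocks < n_instruments) {
      stop_mm("need at least %d chr1 LD blocks for %d instruments",
              n_instruments, n_instruments)
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_outcome_gwas = as.integer(n_outcome_gwas),
      n_snps = as.integer(n_snps),
      n_cpgs = as.integer(n_cpgs),
      ld_block_spec = ld_block_spec,
      maf_range = as.numeric(maf_range),
      mean_coverage = mean_coverage,
      coverage_dispersion = coverage_dispersion,
      scenario = scenario,
      b_gm = b_gm,
      b_my = b_my,
      b_gy_direct = b_gy_direct,
      b_gy_bg = b_gy_bg,
      b_yg_rev = b_yg_rev,
      linkage_r2 = linkage_r2,
      n_instruments = as.integer(n_instruments),
      n_trait_snps = as.integer(n_trait_snps),
      pleiotropy_type = pleiotropy_type,
      logit_noise_sd = logit_noise_sd,
      baseline_beta_range = as.numeric(baseline_beta_range),
      group_z_threshold = group_z_threshold,
      pos_step = pos_step,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  scenario: %s (seed %d)\n", x$scenario, x$seed))
  cat(sprintf("  cohorts: %d methylation subjects (|y| >= %.2f), %d outcome-GWAS subjects\n",
              x$n_subjects, x$group_z_threshold, x$n_outcome_gwas))
  cat(sprintf("  genome: %d SNPs in %d LD blocks, %d CpGs\n",
              x$n_snps, nrow(x$ld_block_spec), x$n_cpgs))
  cat(sprintf("  effects: b_gm=%.2f b_my=%.2f b_gy_direct=%.2f b_yg_rev=%.2f\n",
              x$b_gm, x$b_my, x$b_gy_direct, x$b_yg_rev))
  invisible(x)
}
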
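# CpG site table for a synthetic genome: the focal CpG sits in the middle of
# the chr1 SNP span (cis to the instrument blocks); null CpGs are spread over
# the chromosomes beyond the SNP region.
make_cpg_table <- function(config, snps) {
  set.seed(derive_seed(config$seed, 11L))
  chr1_pos <- snps$pos[snps$chrom == "chr1"]
  focal_pos <- if (length(chr1_pos)) as.integer(round(mean(range(chr1_pos)))) else 1000L
  n_null <- config$n_cpgs - 1L
  chroms <- unique(snps$chrom)
  null_chrom <- rep(chroms, length.out = max(n_null, 0L))
  base_pos <- vapply(null_chrom, function(ch) max(snps$pos[snps$chrom == ch]), 0)
  null_pos <- as.integer(base_pos + 10000L + seq_len(max(n_null, 0L)) * 500L)
  baseline <- stats::runif(config$n_cpgs, config$baseline_beta_range[1],
                           config$baseline_beta_range[2])
  tibble::tibble(
    cpg = sprintf("cpg_%04d", seq_len(config$n_cpgs)),
    chrom = c("chr1", null_chrom)[seq_len(config$n_cpgs)],
    pos = c(focal_pos, null_pos)[seq_len(config$n_cpgs)],
    strand = "+",
    intercept = c(0, logit(baseline[-1]))[seq_len(config$n_cpgs)]
  )
}

# Latent methylation propensity on the logit scale: per-CpG intercept +
# additive genetic effects + subject-level Gaussian noise. Under reverse
# causation the phenotype replaces the genetic arm for the listed CpGs.
meth_latent_matrix <- function(g, cpgs, assignments, config,
                               y = NULL, reverse_y_cpgs = character()) {
  n <- nrow(g$dosages)
  lat <- matrix(rep(cpgs$intercept, each = 0), nrow(cpgs), n)
  lat[] <- cpgs$intercept
  u <- matrix(stats::rnorm(nrow(cpgs) * n, 0, config$logit_noise_sd),
              nrow(cpgs), n)
  lat <- lat + u
  if (!is.null(assignments) && nrow(assignments) > 0) {
    for (r in seq_len(nrow(assignments))) {
      k <- match(assignments$cpg[r], cpgs$cpg)
      j <- match(assignments$snp[r], g$snps$snp)
      if (is.na(k) || is.na(j)) stop_mm("mQTL assignment refers to unknown CpG or SNP")
      lat[k, ] <- lat[k, ] + assignments$b_gm[r] * g$dosages[, j]
    }
  }
  if (length(reverse_y_cpgs) > 0) {
    if (is.null(y)) stop_mm("reverse-causal CpGs need the phenotype vector")
    for (id in reverse_y_cpgs) {
      k <- match(id, cpgs$cpg)
      lat[k, ] <- lat[k, ] + config$b_yg_rev * y
    }
  }
  rownames(lat) <- cpgs$cpg
  colnames(lat) <- rownames(g$dosages)
  lat
}

# Draw RRBS-style counts given latent logits: coverage ~ NB(mean, size),
# methylated reads ~ Binomial(coverage, inv_logit(latent)). Zero coverage is
# retained as a missing observation (m = NA, n = 0).
draw_meth_counts <- function(latent, config) {
  nk <- length(latent)
  n_reads <- stats::rnbinom(nk, mu = config$mean_coverage,
                            size = config$coverage_dispersion)
  m <- stats::rbinom(nk, n_reads, inv_logit(as.vector(latent)))
  m[n_reads == 0L] <- NA_integer_
  list(
    m = matrix(m, nrow(latent), ncol(latent), dimnames = dimnames(latent)),
    n = matrix(n_reads, nrow(latent), ncol(latent), dimnames = dimnames(latent))
  )
}

#' Simulate RRBS-style methylation counts
#'
#' For subject i at CpG k, coverage n_ik is negative-binomial with the
#' configured mean and dispersion; the latent methylation propensity is
#' `logit(p_ik) = intercept_k + sum(b_gm * dosage) + noise_ik` with Gaussian
#' subject-level noise; methylated reads are `Binomial(n_ik, p_ik)`. Under the
#' reverse scenario the phenotype term `b_yg_rev * y_i` replaces the genetic
#' arm for the listed CpGs (genotype then reaches methylation only through the
#' phenotype).
#'
#' @param g A `geno_matrix` (see [simulate_genotypes()]).
#' @param config A [sim_config()].
#' @param mqtl_assignments Tibble with columns `cpg`, `snp`, `b_gm` mapping
#'   causal SNPs to CpGs. May be empty.
#' @param cpgs Optional CpG table (tibble: cpg, chrom, pos, strand,
#'   intercept); generated from the config when omitted.
#' @param y Optional phenotype vector (needed for `reverse_y_cpgs`).
#' @param reverse_y_cpgs CpG ids whose methylation is driven by the phenotype.
#' @param seed Integer seed.
#' @return A `meth_counts` object: list with `cpgs` (tibble), `m` and `n`
#'   (CpG x subject count matrices) and `latent` (the latent logit matrix,
#'   kept for parameter-recovery diagnostics).
#' @export
simulate_methylation <- function(g, config, mqtl_assignments = NULL,
                                 cpgs = NULL, y = NULL,
                                 reverse_y_cpgs = character(),
                                 seed = derive_seed(config$seed, 2L)) {
  set.seed(seed)
  if (is.null(cpgs)) cpgs <- make_cpg_table(config, g$snps)
  lat <- meth_latent_matrix(g, cpgs, mqtl_assignments, config,
                            y = y, reverse_y_cpgs = reverse_y_cpgs)
  cnt <- draw_meth_counts(lat, config)
  structure(list(cpgs = cpgs, m = cnt$m, n = cnt$n, latent = lat),
            class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("<meth_counts> %d CpGs x %d subjects, mean coverage %.1f\n",
              nrow(x$m), ncol(x$m), mean(x$n, na.rm = TRUE)))
  invisible(x)
}

#' Methylation beta values (m/n) as a matrix
#'
#' @param counts A `meth_counts` object.
#' @return CpG x subject matrix of methylation proportions; NA where coverage
#'   is zero.
#' @export
beta_values <- function(counts) {
  b <- counts$m / counts$n
  b[counts$n == 0L] <- NA_real_
  b
}
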
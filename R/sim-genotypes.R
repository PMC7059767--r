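#' Expected dosage correlation under the latent-threshold LD model
#'
#' Haplotype alleles are generated by thresholding correlated standard
#' normals at the MAF quantile, so the dosage (sum of two haplotypes)
#' correlation is attenuated relative to the latent correlation. This maps a
#' latent correlation to the implied dosage correlation via the bivariate
#' normal orthant probability.
#'
#' @param rho Latent Gaussian correlation.
#' @param maf1,maf2 Minor allele frequencies of the two SNPs.
#' @return Expected Pearson correlation of dosages.
#' @export
dosage_cor_from_latent <- function(rho, maf1, maf2 = maf1) {
  t1 <- stats::qnorm(maf1)
  t2 <- stats::qnorm(maf2)
  if (abs(rho) < 1e-12) return(0)
  p11 <- mvtnorm::pmvnorm(upper = c(t1, t2),
                          corr = matrix(c(1, rho, rho, 1), 2))[1]
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Latent correlation achieving a target dosage r-squared
#'
#' Inverts [dosage_cor_from_latent()] numerically so LD blocks can be
#' calibrated to a target dosage r^2 (used for the linkage scenario's
#' configured LD between the methylation-causal and trait-causal SNPs).
#'
#' @param target_r2 Target squared dosage correlation in (0, 1).
#' @param maf Representative minor allele frequency.
#' @return Latent correlation in (0, 1).
#' @export
latent_rho_for_r2 <- function(target_r2, maf = 0.3) {
  if (target_r2 <= 0) return(0)
  target_r <- sqrt(target_r2)
  f <- function(rho) dosage_cor_from_latent(rho, maf) - target_r
  if (f(0.9999) < 0) return(0.9999)
  stats::uniroot(f, c(1e-6, 0.9999), tol = 1e-8)$root
}

# Draw latent haplotype scores for one block: nhap x size matrix.
draw_block_latent <- function(nhap, size, rho, structure) {
  if (size == 1 || rho == 0) {
    return(matrix(stats::rnorm(nhap * size), nhap, size))
  }
  if (structure == "ar1") {
    sigma <- rho^abs(outer(seq_len(size), seq_len(size), "-"))
    z <- matrix(stats::rnorm(nhap * size), nhap, size)
    return(z %*% chol(sigma))
  }
  # exchangeable: shared factor + idiosyncratic noise
  w <- stats::rnorm(nhap)
  e <- matrix(stats::rnorm(nhap * size), nhap, size)
  sqrt(rho) * w + sqrt(1 - rho) * e
}

#' Simulate genotype dosages with block LD structure
#'
#' Haplotypes are drawn from a latent multivariate Gaussian (exchangeable or
#' AR(1) correlation within each block, independence across blocks) and
#' thresholded at the MAF quantile; dosages are the sum of two independent
#' haplotypes, so values lie in \{0, 1, 2\}. SNPs that come out monomorphic
#' are redrawn a bounded number of times.
#'
#' @param config A [sim_config()].
#' @param n Number of subjects.
#' @param seed Integer seed (defaults to the config seed).
#' @param mafs Optional per-SNP population allele frequencies (so several
#'   cohorts can share one population); drawn uniformly from `maf_range` when
#'   NULL.
#' @param max_retries Redraw attempts for monomorphic SNPs before failing.
#' @return A `geno_matrix` object: list with `dosages` (n x SNP integer
#'   matrix) and `snps` (tibble: snp, chrom, pos, effect_allele, other_allele,
#'   maf — the empirical allele frequency of the counted allele).
#' @export
simulate_genotypes <- function(config, n = config$n_subjects,
                               seed = config$seed, mafs = NULL,
                               max_retries = 20) {
  stopifnot(n >= 2)
  set.seed(seed)
  spec <- config$ld_block_spec
  if (is.null(mafs)) {
    mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  }
  nhap <- 2L * n
  dos <- matrix(0L, n, config$n_snps)
  col0 <- 0L
  for (b in seq_len(nrow(spec))) {
    size <- spec$size[b]
    idx <- col0 + seq_len(size)
    thr <- stats::qnorm(mafs[idx])
    for (attempt in seq_len(max_retries + 1L)) {
      z <- draw_block_latent(nhap, size, spec$rho[b], spec$structure[b])
      hap <- sweep(z, 2, thr, "<") * 1L
      d <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
      mono <- apply(d, 2, function(x) length(unique(x)) == 1L)
      if (!any(mono)) break
      if (attempt > max_retries) {
        stop_mm("block %d still monomorphic after %d retries; maf_range/n too restrictive",
                b, max_retries)
      }
    }
    dos[, idx] <- d
    col0 <- col0 + size
  }
  snp_ids <- sprintf("snp_%04d", seq_len(config$n_snps))
  chrom <- rep(spec$chrom, spec$size)
  pos <- integer(config$n_snps)
  for (chr in unique(chrom)) {
    k <- chrom == chr
    pos[k] <- seq_len(sum(k)) * config$pos_step
  }
  colnames(dos) <- snp_ids
  rownames(dos) <- sprintf("subj_%05d", seq_len(n))
  snps <- tibble::tibble(
    snp = snp_ids, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    maf = colMeans(dos) / 2,
    block = rep(seq_len(nrow(spec)), spec$size)
  )
  structure(list(dosages = dos, snps = snps), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d subjects x %d SNPs on %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

# Subset a geno_matrix by subject index and/or SNP id.
subset_geno <- function(g, subjects = NULL, snps = NULL) {
  dos <- g$dosages
  meta <- g$snps
  if (!is.null(subjects)) dos <- dos[subjects, , drop = FALSE]
  if (!is.null(snps)) {
    keep <- match(snps, meta$snp)
    dos <- dos[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  structure(list(dosages = dos, snps = meta), class = "geno_matrix")
}
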
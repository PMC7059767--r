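# Scenario wiring: which SNPs carry which effects under each causal model.
# Instruments (causal mQTLs of the focal CpG) are the first SNP of each chr1
# block; the trait-causal SNP under linkage is the second SNP of block 1; the
# background/reverse trait SNPs are the chr2 block.
scenario_wiring <- function(config, snps, pleiotropy_signs = NULL) {
  focal <- "cpg_0001"
  chr1_blocks <- unique(snps$block[snps$chrom == "chr1"])
  first_of_block <- vapply(chr1_blocks,
                           function(b) snps$snp[snps$block == b][1], "")
  trait_snps <- utils::head(snps$snp[snps$chrom == "chr2"], config$n_trait_snps)
  direct <- stats::setNames(numeric(nrow(snps)), snps$snp)
  assignments <- tibble::tibble(cpg = character(), snp = character(),
                                b_gm = numeric())
  reverse_y_cpgs <- character()
  k <- config$n_instruments
  inst_effects <- if (k == 1) config$b_gm else
    config$b_gm * seq(0.5, 1.5, length.out = k)
  if (config$scenario %in% c("mediation", "pleiotropy")) {
    inst <- first_of_block[seq_len(k)]
    assignments <- tibble::tibble(cpg = focal, snp = inst, b_gm = inst_effects)
    direct[trait_snps] <- config$b_gy_bg
    if (config$scenario == "pleiotropy") {
      signs <- pleiotropy_signs %||% rep(1, k)
      direct[inst] <- signs * config$b_gy_direct
    }
  } else if (config$scenario == "linkage") {
    b1 <- snps$snp[snps$block == chr1_blocks[1]]
    assignments <- tibble::tibble(cpg = focal, snp = b1[1], b_gm = config$b_gm)
    direct[b1[2]] <- config$b_gy_direct
    direct[trait_snps] <- config$b_gy_bg
  } else if (config$scenario == "reverse") {
    direct[trait_snps] <- config$b_gy_direct
    reverse_y_cpgs <- focal
  }
  list(
    focal_cpg = focal,
    assignments = assignments,
    direct = direct,
    use_mediator = config$scenario %in% c("mediation", "pleiotropy"),
    reverse_y_cpgs = reverse_y_cpgs,
    trait_snps = trait_snps,
    linkage_pair = if (config$scenario == "linkage") {
      c(meth = snps$snp[snps$block == chr1_blocks[1]][1],
        trait = snps$snp[snps$block == chr1_blocks[1]][2])
    } else NULL
  )
}

# Continuous phenotype under the active causal model. `mediator` is the
# population-centered latent methylation logit of the focal CpG (NULL when
# the model has no M -> Y arm); residual noise is standard normal. Genetic
# contributions are centered at their population means (2 * maf per SNP) so
# the phenotype is a Z-score-like deviation around zero.
phenotype_from_model <- function(g, config, wiring, mediator = NULL,
                                 eps = NULL, mafs = NULL) {
  n <- nrow(g$dosages)
  y <- if (is.null(eps)) stats::rnorm(n) else eps
  active <- wiring$direct[wiring$direct != 0]
  if (length(active) > 0) {
    j <- match(names(active), colnames(g$dosages))
    ctr <- 2 * (if (is.null(mafs)) g$snps$maf[j] else mafs[j])
    dc <- sweep(g$dosages[, j, drop = FALSE], 2, ctr, "-")
    y <- y + as.vector(dc %*% active)
  }
  if (wiring$use_mediator) {
    if (is.null(mediator)) stop_mm("scenario needs the latent mediator")
    y <- y + config$b_my * mediator
  }
  y
}

# Population-centered mediator: latent logit minus intercept and minus the
# population mean of the genetic arm.
centered_mediator <- function(lat, cpgs, wiring, mafs, snps) {
  k <- match(wiring$focal_cpg, cpgs$cpg)
  med <- lat[k, ] - cpgs$intercept[k]
  if (nrow(wiring$assignments) > 0) {
    j <- match(wiring$assignments$snp, snps$snp)
    med <- med - sum(wiring$assignments$b_gm * 2 * mafs[j])
  }
  med
}

#' Simulate phenotypes and an independent outcome GWAS
#'
#' Generates the continuous phenotype for the methylation cohort under the
#' configured causal model, selects the extreme-phenotype groups, and computes
#' summary statistics from a freshly generated, fully independent outcome
#' cohort (distinct RNG stream, no shared subjects) by per-SNP simple linear
#' regression of the phenotype on dosage.
#'
#' This is a convenience wrapper; [simulate_cohort()] performs the same steps
#' with pool-based extreme sampling and returns all pieces together.
#'
#' @param g_small `geno_matrix` for the methylation cohort.
#' @param meth_latent Latent logit matrix (CpG x subject) for `g_small`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `phenotypes` (tibble) and `sumstats` (tibble).
#' @export
simulate_phenotype_and_outcome_gwas <- function(g_small, meth_latent, config,
                                                seed = derive_seed(config$seed, 3L)) {
  set.seed(seed)
  signs <- sample(c(-1, 1), config$n_instruments, replace = TRUE)
  wiring <- scenario_wiring(config, g_small$snps, pleiotropy_signs = signs)
  focal_row <- match(wiring$focal_cpg, rownames(meth_latent))
  mediator <- if (wiring$use_mediator) {
    meth_latent[focal_row, ] - mean(meth_latent[focal_row, ])
  }
  y <- phenotype_from_model(g_small, config, wiring, mediator = mediator)
  pheno <- phenotype_table(y, rownames(g_small$dosages), config,
                           seed = derive_seed(seed, 1L))
  ss <- simulate_outcome_gwas(config, wiring,
                              mafs = NULL, snps_meta = g_small$snps,
                              seed = derive_seed(seed, 2L))
  list(phenotypes = pheno, sumstats = ss)
}

# Phenotype/covariate table with extreme-group labels. Subjects between the
# thresholds get group NA (excluded from the cohort by the caller).
phenotype_table <- function(y, subject_ids, config, seed) {
  set.seed(seed)
  n <- length(y)
  thr <- config$group_z_threshold
  group <- ifelse(y >= thr, 1L, ifelse(y <= -thr, 0L, NA_integer_))
  tibble::tibble(
    subject = subject_ids,
    y = unname(y),
    group = unname(group),
    age = round(stats::runif(n, 20, 40), 1),
    bmi = round(stats::rnorm(n, 25, 4), 1),
    smoking = stats::rbinom(n, 1, 0.25),
    drinking = stats::rbinom(n, 1, 0.40)
  )
}

#' Outcome GWAS summary statistics from an independent synthetic cohort
#'
#' Generates `config$n_outcome_gwas` subjects under the same causal model and
#' LD structure as the methylation cohort (its own RNG stream; no subjects
#' shared), then regresses the phenotype on each SNP dosage. Genotypes are
#' generated and discarded block by block in two passes, so memory stays flat
#' in the number of SNPs.
#'
#' @param config A [sim_config()].
#' @param wiring Scenario wiring from the cohort generator.
#' @param mafs Per-SNP population allele frequencies (shared with the
#'   methylation cohort); drawn from the config when NULL.
#' @param snps_meta SNP metadata tibble.
#' @param seed Integer seed.
#' @return Tibble: snp, effect_allele, other_allele, beta, se, p, eaf, n.
#' @export
simulate_outcome_gwas <- function(config, wiring, mafs = NULL,
                                  snps_meta = NULL, seed) {
  spec <- config$ld_block_spec
  if (is.null(mafs)) {
    set.seed(derive_seed(config$seed, 0L))
    mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  }
  n <- config$n_outcome_gwas
  nhap <- 2L * n
  snp_ids <- if (!is.null(snps_meta)) snps_meta$snp else
    sprintf("snp_%04d", seq_len(config$n_snps))
  # pass 1: accumulate causal contributions to the phenotype; for small
  # genomes the block dosages are kept so pass 2 need not regenerate them
  keep_blocks <- config$n_snps <= 500
  block_cache <- if (keep_blocks) vector("list", nrow(spec))
  gen_contrib <- numeric(n)   # genetic arm of the mediator (sum b_gm * G)
  direct_contrib <- numeric(n)
  col0 <- 0L
  for (b in seq_len(nrow(spec))) {
    size <- spec$size[b]
    idx <- col0 + seq_len(size)
    ids <- snp_ids[idx]
    a_idx <- which(wiring$assignments$snp %in% ids)
    d_act <- wiring$direct[ids]
    if (keep_blocks || length(a_idx) > 0 || any(d_act != 0)) {
      set.seed(derive_seed(seed, 100L + b))
      z <- draw_block_latent(nhap, size, spec$rho[b], spec$structure[b])
      hap <- sweep(z, 2, stats::qnorm(mafs[idx]), "<") * 1L
      d <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
      if (keep_blocks) block_cache[[b]] <- d
      for (r in a_idx) {
        j <- match(wiring$assignments$snp[r], ids)
        gen_contrib <- gen_contrib +
          wiring$assignments$b_gm[r] * (d[, j] - 2 * mafs[idx[j]])
      }
      nz <- which(d_act != 0)
      if (length(nz) > 0) {
        dc <- sweep(d[, nz, drop = FALSE], 2, 2 * mafs[idx[nz]], "-")
        direct_contrib <- direct_contrib + as.vector(dc %*% d_act[nz])
      }
    }
    col0 <- col0 + size
  }
  set.seed(derive_seed(seed, 7L))
  u <- stats::rnorm(n, 0, config$logit_noise_sd)  # subject noise in mediator
  eps <- stats::rnorm(n)
  y <- eps + direct_contrib
  if (wiring$use_mediator) y <- y + config$b_my * (gen_contrib + u)
  # (reverse scenario: methylation is downstream of y; no feedback into y)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)
  # pass 2: reuse cached blocks or regenerate each from its stream, then
  # regress y on dosage
  out <- vector("list", nrow(spec))
  col0 <- 0L
  for (b in seq_len(nrow(spec))) {
    size <- spec$size[b]
    idx <- col0 + seq_len(size)
    if (keep_blocks) {
      d <- block_cache[[b]]
    } else {
      set.seed(derive_seed(seed, 100L + b))
      z <- draw_block_latent(nhap, size, spec$rho[b], spec$structure[b])
      hap <- sweep(z, 2, stats::qnorm(mafs[idx]), "<") * 1L
      d <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
    }
    cx <- colMeans(d)
    sxx <- colSums(d^2) - n * cx^2
    sxy <- as.vector(crossprod(d, y)) - n * cx * ybar
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / ((n - 2) * sxx))
    tval <- beta / se
    out[[b]] <- tibble::tibble(
      snp = snp_ids[idx],
      beta = beta, se = se,
      p = 2 * stats::pt(-abs(tval), df = n - 2),
      eaf = cx / 2
    )
    col0 <- col0 + size
  }
  res <- dplyr::bind_rows(out)
  ea <- if (!is.null(snps_meta)) snps_meta$effect_allele else "A"
  oa <- if (!is.null(snps_meta)) snps_meta$other_allele else "G"
  tibble::tibble(
    snp = res$snp, effect_allele = ea, other_allele = oa,
    beta = res$beta, se = res$se, p = pmax(res$p, .Machine$double.xmin),
    eaf = res$eaf, n = n
  )
}
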
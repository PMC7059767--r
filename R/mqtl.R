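#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each possible heterozygote count is computed and the p-value is the
#' total probability of outcomes no more probable than the observed one
#' (mid-p not applied).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom ref, het, hom alt).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  # rare allele count
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  if (min(n_aa, n_bb) == n_aa) { hom_r <- n_aa } else { hom_r <- n_bb }
  het_obs <- n_ab
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log P(het | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs_pr <- pr[match(het_obs, hets)]
  min(1, sum(pr[pr <= obs_pr + 1e-12]))
}

#' SNP quality control
#'
#' Retains SNPs with minor allele frequency above `maf_min`, genotype call
#' rate above `call_rate_min`, and exact Hardy-Weinberg p above `hwe_p_min`.
#'
#' @param g A `geno_matrix` of hard-call dosages.
#' @param maf_min,call_rate_min,hwe_p_min Filter thresholds.
#' @return Filtered `geno_matrix`; attribute `qc` holds the per-SNP filter
#'   table.
#' @export
snp_qc <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                   hwe_p_min = 1e-6) {
  dos <- g$dosages
  stats_tbl <- purrr::map_dfr(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    call_rate <- mean(!is.na(x))
    x <- x[!is.na(x)]
    f <- mean(x) / 2
    maf <- min(f, 1 - f)
    hwe_p <- hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    tibble::tibble(snp = colnames(dos)[j], maf = maf,
                   call_rate = call_rate, hwe_p = hwe_p)
  })
  stats_tbl$pass <- stats_tbl$maf > maf_min &
    stats_tbl$call_rate > call_rate_min &
    stats_tbl$hwe_p > hwe_p_min
  out <- subset_geno(g, snps = stats_tbl$snp[stats_tbl$pass])
  attr(out, "qc") <- stats_tbl
  out
}

#' First principal components of the genotype matrix
#'
#' Mean-imputes missing dosages, LD-prunes the SNPs (greedy, keeping one
#' representative per correlated set, as is standard before ancestry PCA so
#' local LD blocks do not masquerade as structure), centers, and decomposes;
#' the leading score vector is the standard ancestry/stratification covariate
#' for the mQTL scan.
#'
#' @param g A `geno_matrix`.
#' @param k Number of components.
#' @param prune_r2 Pairwise r-squared above which SNPs are pruned before the
#'   decomposition (NULL disables pruning).
#' @return List with `scores` (subject x k) and `variance_explained`.
#' @export
genotype_pcs <- function(g, k = 1, prune_r2 = 0.2) {
  dos <- g$dosages
  dos <- apply(dos, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  dos <- dos[, apply(dos, 2, stats::var) > 0, drop = FALSE]
  if (!is.null(prune_r2) && ncol(dos) > 1) {
    r2 <- stats::cor(dos)^2
    keep <- integer(0)
    for (j in seq_len(ncol(dos))) {
      if (length(keep) == 0 || all(r2[j, keep] < prune_r2)) keep <- c(keep, j)
    }
    dos <- dos[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(dos, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)])
}

#' Count the enumerated same-chromosome SNP-CpG tests by class
#'
#' The scan tests every SNP-CpG pair on the same chromosome; a pair is cis
#' when the SNP-CpG distance is below 1 Mb and trans otherwise. The per-class
#' totals are the Bonferroni denominators.
#'
#' @param g A `geno_matrix`.
#' @param cpg_meta Tibble with `cpg`, `chrom`, `pos`.
#' @param cis_window Cis distance threshold in bp (strict `<`).
#' @return List with `n_cis` and `n_trans`.
#' @export
mqtl_test_counts <- function(g, cpg_meta, cis_window = 1e6) {
  n_cis <- 0; n_trans <- 0
  for (chr in intersect(unique(g$snps$chrom), unique(cpg_meta$chrom))) {
    sp <- g$snps$pos[g$snps$chrom == chr]
    cp <- cpg_meta$pos[cpg_meta$chrom == chr]
    if (length(sp) == 0 || length(cp) == 0) next
    d <- abs(outer(sp, cp, "-"))
    n_cis <- n_cis + sum(d < cis_window)
    n_trans <- n_trans + sum(d >= cis_window)
  }
  list(n_cis = n_cis, n_trans = n_trans)
}

#' Scan for methylation quantitative trait loci
#'
#' For every SNP-CpG pair on the same chromosome, fits the additive linear
#' model `methylation ~ dosage + covariates` by OLS and reports the per-allele
#' effect, its standard error and two-sided t-test p-value. Methylation enters
#' inverse-normal transformed by default (`values_mode = "int"`); raw beta
#' values or empirical-logit values are available. Pairs are classified cis
#' (distance < `cis_window` on the same chromosome) or trans.
#'
#' @param g A `geno_matrix`.
#' @param counts A `meth_counts` restricted to the CpGs to scan (typically the
#'   DMCs).
#' @param covariates Optional tibble of numeric covariates with a `subject`
#'   column (e.g. the first genotype PC).
#' @param values_mode `"int"`, `"raw"` or `"logit"` methylation scale.
#' @param cis_window Cis distance threshold in bp.
#' @return Tibble of mQTL records: snp, cpg, chrom, snp_pos, cpg_pos,
#'   distance, class, b_zx, se_zx, p, n. Monomorphic pairs are skipped and
#'   listed in the `skipped` attribute.
#' @export
scan_mqtl <- function(g, counts, covariates = NULL,
                      values_mode = c("int", "raw", "logit"),
                      cis_window = 1e6) {
  values_mode <- match.arg(values_mode)
  subjects <- colnames(counts$m)
  if (!identical(rownames(g$dosages), subjects)) {
    keep <- match(subjects, rownames(g$dosages))
    if (anyNA(keep)) stop_mm("subjects in counts and genotypes do not align")
    g <- structure(list(dosages = g$dosages[keep, , drop = FALSE],
                        snps = g$snps), class = "geno_matrix")
  }
  vals <- meth_values(counts, values_mode)
  cov_mat <- matrix(1, length(subjects), 1)
  if (!is.null(covariates)) {
    cv <- covariates[match(subjects, covariates$subject), , drop = FALSE]
    num <- cv[, setdiff(names(cv), "subject"), drop = FALSE]
    num <- num[, vapply(num, function(x) stats::var(x, na.rm = TRUE) > 0,
                        TRUE), drop = FALSE]
    if (ncol(num) > 0) cov_mat <- cbind(cov_mat, as.matrix(num))
  }
  skipped <- character()
  out <- vector("list", nrow(counts$cpgs))
  for (k in seq_len(nrow(counts$cpgs))) {
    chr <- counts$cpgs$chrom[k]
    snp_idx <- which(g$snps$chrom == chr)
    if (length(snp_idx) == 0) next
    y <- vals[k, ]
    ok <- !is.na(y) & stats::complete.cases(cov_mat)
    G <- g$dosages[ok, snp_idx, drop = FALSE]
    yk <- y[ok]
    Xc <- cov_mat[ok, , drop = FALSE]
    qrX <- qr(Xc)
    ry <- qr.resid(qrX, yk)
    slopes <- se <- pv <- rep(NA_real_, length(snp_idx))
    nn <- rep(NA_integer_, length(snp_idx))
    na_cols <- which(apply(G, 2, anyNA))
    full_cols <- setdiff(seq_along(snp_idx), na_cols)
    if (length(full_cols) > 0) {
      # vectorized OLS over all complete SNPs at once (Frisch-Waugh)
      rg <- qr.resid(qrX, G[, full_cols, drop = FALSE])
      sgg <- colSums(rg^2)
      ok_v <- sgg >= 1e-12
      bhat <- as.vector(crossprod(rg, ry)) / sgg
      df <- length(ry) - ncol(Xc) - 1L
      s2 <- pmax(sum(ry^2) - bhat^2 * sgg, 0) / df
      sej <- sqrt(s2 / sgg)
      idx_ok <- full_cols[ok_v & df >= 1]
      slopes[idx_ok] <- bhat[ok_v & df >= 1]
      se[idx_ok] <- sej[ok_v & df >= 1]
      nn[idx_ok] <- length(ry)
      pv[idx_ok] <- 2 * stats::pt(-abs(slopes[idx_ok] / se[idx_ok]), df = df)
      if (any(!ok_v)) {
        skipped <- c(skipped, sprintf("%s:%s",
                                      g$snps$snp[snp_idx[full_cols[!ok_v]]],
                                      counts$cpgs$cpg[k]))
      }
    }
    for (jj in na_cols) {
      gj <- G[, jj]
      okj <- !is.na(gj)
      qj <- qr(Xc[okj, , drop = FALSE])
      rg <- qr.resid(qj, gj[okj])
      ryj <- qr.resid(qj, yk[okj])
      sgg <- sum(rg^2)
      if (sgg < 1e-12) {
        skipped <- c(skipped, sprintf("%s:%s", g$snps$snp[snp_idx[jj]],
                                      counts$cpgs$cpg[k]))
        next
      }
      bhat <- sum(ryj * rg) / sgg
      df <- sum(okj) - ncol(Xc) - 1L
      if (df < 1) next
      s2 <- max(sum(ryj^2) - bhat^2 * sgg, 0) / df
      sej <- sqrt(s2 / sgg)
      slopes[jj] <- bhat; se[jj] <- sej; nn[jj] <- sum(okj)
      pv[jj] <- 2 * stats::pt(-abs(bhat / sej), df = df)
    }
    dist <- abs(g$snps$pos[snp_idx] - counts$cpgs$pos[k])
    out[[k]] <- tibble::tibble(
      snp = g$snps$snp[snp_idx], cpg = counts$cpgs$cpg[k], chrom = chr,
      snp_pos = g$snps$pos[snp_idx], cpg_pos = counts$cpgs$pos[k],
      distance = dist,
      class = ifelse(dist < cis_window, "cis", "trans"),
      b_zx = slopes, se_zx = se, p = pv, n = nn
    )
  }
  res <- dplyr::bind_rows(out)
  res <- res[!is.na(res$b_zx), , drop = FALSE]
  attr(res, "skipped") <- skipped
  res
}

#' Per-class Bonferroni selection of significant mQTLs
#'
#' Cis and trans tests are corrected separately using the full enumerated
#' test counts (not only the computed pairs): a cis record is significant iff
#' `p < alpha / n_cis_tests`, and likewise for trans.
#'
#' @param records mQTL tibble from [scan_mqtl()].
#' @param n_cis_tests,n_trans_tests Enumerated test counts by class.
#' @param alpha Family-wise error target.
#' @return Significant records, with `p_threshold` column; thresholds stored
#'   in attributes `cis_threshold` / `trans_threshold`.
#' @export
bonferroni_by_class <- function(records, n_cis_tests, n_trans_tests,
                                alpha = 0.05) {
  if (n_cis_tests <= 0 && n_trans_tests <= 0) {
    stop_mm("both test counts are zero")
  }
  if (n_cis_tests <= 0 && any(records$class == "cis")) {
    stop_mm("cis records present but n_cis_tests is zero")
  }
  if (n_trans_tests <= 0 && any(records$class == "trans")) {
    stop_mm("trans records present but n_trans_tests is zero")
  }
  cis_thr <- if (n_cis_tests > 0) alpha / n_cis_tests else NA_real_
  trans_thr <- if (n_trans_tests > 0) alpha / n_trans_tests else NA_real_
  thr <- ifelse(records$class == "cis", cis_thr, trans_thr)
  out <- records[!is.na(records$p) & records$p < thr, , drop = FALSE]
  out$p_threshold <- ifelse(out$class == "cis", cis_thr, trans_thr)
  attr(out, "cis_threshold") <- cis_thr
  attr(out, "trans_threshold") <- trans_thr
  out
}

#' Pairwise LD matrix of SNP dosages
#'
#' Signed Pearson correlations on pairwise-complete dosages. Near-singular
#' matrices (smallest eigenvalue below 1e-8) are flagged via the
#' `near_singular` attribute; downstream consumers apply a ridge before
#' inverting.
#'
#' @param g A `geno_matrix`.
#' @param snps Optional SNP ids to restrict to.
#' @return An `ld_matrix` object: list with `r` (correlation matrix), `snps`
#'   (ids, in order) and `source_n` (subjects used).
#' @export
ld_matrix <- function(g, snps = NULL) {
  if (!is.null(snps)) g <- subset_geno(g, snps = snps)
  dos <- g$dosages
  if (ncol(dos) < 1) stop_mm("need at least one SNP")
  sds <- apply(dos, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop_mm("monomorphic SNP(s): %s",
            paste(colnames(dos)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  r <- stats::cor(dos, use = "pairwise.complete.obs")
  out <- structure(list(r = r, snps = colnames(dos), source_n = nrow(dos)),
                   class = "ld_matrix")
  attr(out, "near_singular") <- min(eigen(r, symmetric = TRUE,
                                          only.values = TRUE)$values) < 1e-8
  out
}
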
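#' Select SNPs for the HEIDI heterogeneity test
#'
#' From the cis-mQTL region, keeps SNPs in moderate LD with the top (causal)
#' mQTL — `r2_low < r^2 < r2_high` — and with an mQTL p-value at or below
#' `p_max` (weaker associations are removed to avoid weak-instrument bias).
#' If more than `cap` SNPs remain, the `cap` with the smallest mQTL p are
#' used.
#'
#' @param locus_stats Tibble of mQTL statistics at the locus (`snp`, `p`).
#' @param top_snp Id of the top cis-mQTL.
#' @param ld An `ld_matrix` covering the locus.
#' @param r2_low,r2_high LD window relative to the top SNP (strict
#'   inequalities).
#' @param p_max Maximum mQTL p-value for inclusion.
#' @param cap Maximum number of SNPs used.
#' @return Character vector of selected SNP ids (possibly empty); the counts
#'   of exclusions by reason are in the `excluded` attribute.
#' @export
select_heidi_snps <- function(locus_stats, top_snp, ld,
                              r2_low = 0.05, r2_high = 0.9,
                              p_max = 1.6e-3, cap = 20) {
  if (!top_snp %in% ld$snps) stop_mm("top SNP %s not in LD matrix", top_snp)
  cand <- locus_stats[locus_stats$snp != top_snp &
                        locus_stats$snp %in% ld$snps, , drop = FALSE]
  r2 <- ld$r[cand$snp, top_snp]^2
  ld_ok <- r2 > r2_low & r2 < r2_high
  p_ok <- !is.na(cand$p) & cand$p <= p_max
  sel <- cand[ld_ok & p_ok, , drop = FALSE]
  excluded <- c(r2_out_of_range = sum(!ld_ok),
                weak_instrument = sum(ld_ok & !p_ok),
                over_cap = max(0L, nrow(sel) - cap))
  if (nrow(sel) > cap) sel <- sel[order(sel$p)[seq_len(cap)], , drop = FALSE]
  out <- sel$snp
  attr(out, "excluded") <- excluded
  out
}

# First-order covariance matrix of the per-SNP ratio estimates b_zy/b_zx.
# The outcome term r_ij*se_zy_i*se_zy_j/(b_zx_i*b_zx_j) is always included;
# with exposure_uncertainty the exposure-noise term
# b_zy_i*b_zy_j*cov(b_zx_i,b_zx_j)/(b_zx_i^2*b_zx_j^2) is added, which
# dominates when the exposure sample is much smaller than the outcome GWAS.
# The exposure-slope covariance is r_ij*se_zx_i*se_zx_j unless an exact
# matrix v_zx (e.g. from mqtl_slope_cov()) is supplied.
ratio_cov_matrix <- function(stats, r, exposure_uncertainty = TRUE,
                             v_zx = NULL) {
  bx <- stats$b_zx; by <- stats$b_zy
  sx <- stats$se_zx; sy <- stats$se_zy
  vy <- outer(sy / bx, sy / bx) * r
  v <- vy
  if (exposure_uncertainty) {
    czx <- if (is.null(v_zx)) outer(sx, sx) * r else v_zx
    v <- v + outer(by / bx^2, by / bx^2) * czx
  }
  v
}

#' Empirical covariance of marginal mQTL slopes at a locus
#'
#' The per-SNP mQTL effects at one CpG are marginal regression slopes
#' estimated from the same subjects, so they are correlated. With
#' individual-level exposure data the full sampling covariance can be
#' computed exactly from the slope influence functions (an HC0 sandwich over
#' the per-subject score contributions), rather than approximated via the LD
#' matrix. In a small exposure cohort the approximation error is material
#' for the HEIDI heterogeneity test, so the pipeline uses this empirical
#' covariance.
#'
#' @param g A `geno_matrix` covering the locus SNPs (subjects aligned with
#'   `values`).
#' @param values Numeric methylation values per subject (the same scale used
#'   in the scan).
#' @param snps SNP ids in the desired order.
#' @param covariates Optional tibble of numeric covariates with `subject`
#'   column (projected out, as in [scan_mqtl()]).
#' @return List with `b` (slopes), `v` (covariance matrix of the slopes).
#' @export
mqtl_slope_cov <- function(g, values, snps, covariates = NULL) {
  subjects <- rownames(g$dosages)
  ok <- !is.na(values)
  G <- g$dosages[ok, snps, drop = FALSE]
  y <- values[ok]
  X <- matrix(1, length(y), 1)
  if (!is.null(covariates)) {
    cv <- covariates[match(subjects[ok], covariates$subject), , drop = FALSE]
    num <- cv[, setdiff(names(cv), "subject"), drop = FALSE]
    num <- num[, vapply(num, function(x) stats::var(x, na.rm = TRUE) > 0,
                        TRUE), drop = FALSE]
    if (ncol(num) > 0) X <- cbind(X, as.matrix(num))
  }
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  rg <- qr.resid(qrX, G)
  sgg <- colSums(rg^2)
  b <- as.vector(crossprod(rg, ry)) / sgg
  # influence functions psi_sj = rg_sj * e_sj / sum(rg_j^2), with HC3-style
  # leverage correction (small-sample variance of HC0 is downward biased)
  e <- ry - sweep(rg, 2, b, "*")
  hx <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  h <- pmin(hx + sweep(rg^2, 2, sgg, "/"), 0.999)
  psi <- sweep(rg * e / (1 - h), 2, sgg, "/")
  v <- crossprod(psi)
  dimnames(v) <- list(snps, snps)
  list(b = stats::setNames(b, snps), v = v)
}

# Covariance matrix of the cross-product contrasts
# t_j = Y_j X_t - Y_t X_j (X = exposure effects, Y = outcome effects, t =
# top index 1), from exact product-moment identities for independent X and Y
# blocks with the observed effects as plug-in means.
crossprod_cov_matrix <- function(mx, my, vx, vy) {
  m <- length(mx) - 1
  idx <- 2:(m + 1)
  v <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      i <- idx[a]; j <- idx[b]
      termA <- vy[i, j] * vx[1, 1] + vy[i, j] * mx[1]^2 +
        my[i] * my[j] * vx[1, 1]
      termB <- vy[i, 1] * vx[1, j] + vy[i, 1] * mx[1] * mx[j] +
        my[i] * my[1] * vx[1, j]
      termC <- vy[1, j] * vx[i, 1] + vy[1, j] * mx[i] * mx[1] +
        my[1] * my[j] * vx[i, 1]
      termD <- vy[1, 1] * vx[i, j] + vy[1, 1] * mx[i] * mx[j] +
        my[1]^2 * vx[i, j]
      v[a, b] <- v[b, a] <- termA - termB - termC + termD
    }
  }
  v
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Under a single shared causal variant (pleiotropy at one SNP), the causal
#' effect of methylation on the trait estimated from any SNP in LD with that
#' variant is identical; under linkage of distinct causal variants the
#' per-SNP estimates differ.
#'
#' Two equivalent parameterizations of the proportionality null are
#' implemented. The default (`statistic = "crossprod"`) contrasts
#' `t_i = b_zy_i b_zx_top - b_zy_top b_zx_i`, which is exactly zero-mean
#' under the null for any instrument strength because no noisy estimate
#' appears in a denominator; its covariance follows from exact
#' product-moment identities. The classical form (`statistic = "ratio"`)
#' contrasts the per-SNP ratio estimates, `d_i = b_xy_i - b_xy_top` with
#' `b_xy = b_zy/b_zx`, with first-order delta covariance (including, by
#' default, the exposure-side sampling noise); it is accurate when the
#' exposure associations are strong (small coefficient of variation of
#' b_zx) but becomes skewed and anti-conservative when the exposure cohort
#' is small. In both cases `T = sum_i (contrast_i / sd_i)^2`; the null
#' distribution of T is a weighted sum of one-degree chi-squares with
#' weights the eigenvalues of the contrast correlation matrix, and the
#' p-value uses the Satterthwaite scaled-chi-square approximation, with a
#' Monte-Carlo multivariate-normal oracle available via [heidi_p_mc()].
#'
#' @param stats Tibble with `snp`, `b_zx`, `se_zx`, `b_zy`, `se_zy` covering
#'   the top SNP and the selected SNPs.
#' @param top_snp Id of the top cis-mQTL.
#' @param ld An `ld_matrix` covering all SNPs in `stats`.
#' @param statistic `"crossprod"` (default) or `"ratio"` parameterization of
#'   the proportionality contrast (see Details).
#' @param exposure_uncertainty Include exposure-noise terms in the covariance
#'   (recommended; setting FALSE treats b_zx as fixed).
#' @param v_zx Optional exact covariance matrix of the exposure slopes (rows
#'   and columns in `stats$snp` order after reordering to top-first; see
#'   [mqtl_slope_cov()]); defaults to the LD approximation
#'   `r_ij se_zx_i se_zx_j`.
#' @param ridge Ridge added to the d-covariance before use.
#' @return One-row tibble: `top_snp`, `t_stat`, `p_heidi`, `n_snp_heidi`.
#'   With no selected SNPs the result is NA. The standardized d covariance is
#'   attached as attribute `d_corr` for oracle checks.
#' @export
heidi_test <- function(stats, top_snp, ld,
                       statistic = c("crossprod", "ratio"),
                       exposure_uncertainty = TRUE,
                       v_zx = NULL, ridge = 1e-8) {
  statistic <- match.arg(statistic)
  sel <- setdiff(stats$snp, top_snp)
  if (length(sel) == 0) {
    return(tibble::tibble(top_snp = top_snp, t_stat = NA_real_,
                          p_heidi = NA_real_, n_snp_heidi = 0L))
  }
  ordered <- c(top_snp, sel)
  st <- stats[match(ordered, stats$snp), , drop = FALSE]
  r <- ld$r[ordered, ordered]
  if (!is.null(v_zx)) v_zx <- v_zx[ordered, ordered]
  m <- length(sel)
  idx <- 2:(m + 1)
  if (statistic == "crossprod") {
    vx <- if (is.null(v_zx)) outer(st$se_zx, st$se_zx) * r else v_zx
    if (!exposure_uncertainty) vx <- vx * 0
    vy <- outer(st$se_zy, st$se_zy) * r
    d <- st$b_zy[idx] * st$b_zx[1] - st$b_zy[1] * st$b_zx[idx]
    v_d <- crossprod_cov_matrix(st$b_zx, st$b_zy, vx, vy)
  } else {
    v_bxy <- ratio_cov_matrix(st, r, exposure_uncertainty, v_zx = v_zx)
    bxy <- st$b_zy / st$b_zx
    d <- bxy[-1] - bxy[1]
    v_d <- v_bxy[idx, idx, drop = FALSE] -
      matrix(v_bxy[idx, 1], m, m) -
      matrix(v_bxy[idx, 1], m, m, byrow = TRUE) +
      v_bxy[1, 1]
  }
  v_d <- v_d + diag(ridge * max(1, mean(diag(v_d))), m)
  ev <- eigen(v_d, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev))) {
    stop_mm("HEIDI covariance not positive semi-definite")
  }
  sdd <- sqrt(diag(v_d))
  z <- d / sdd
  t_stat <- sum(z^2)
  cmat <- v_d / outer(sdd, sdd)
  lam <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  # Satterthwaite: T ~ c * chisq(df), matching mean and variance
  cc <- sum(lam^2) / sum(lam)
  df <- sum(lam)^2 / sum(lam^2)
  p <- stats::pchisq(t_stat / cc, df = df, lower.tail = FALSE)
  out <- tibble::tibble(top_snp = top_snp, t_stat = t_stat,
                        p_heidi = max(p, .Machine$double.xmin),
                        n_snp_heidi = m)
  attr(out, "d_corr") <- cmat
  out
}

#' Selection-calibrated HEIDI p-value
#'
#' At a small exposure sample size the HEIDI machinery is doubly finite-
#' sample: the SNP-selection rules (top SNP = smallest mQTL p; candidates
#' kept only when they pass the weak-instrument filter) act on noisy
#' estimates, and the analytic null distribution of the statistic relies on
#' approximate covariances. This calibrates the test by simulating the
#' entire procedure under the fitted single-shared-causal null: exposure
#' slopes for the whole locus are recomputed on bootstrap resamples of the
#' exposure-cohort subjects (capturing their exact finite-sample joint
#' distribution, including any distortion from extreme-phenotype
#' recruitment); outcome effects are set to the common causal ratio times
#' the observed exposure slopes plus parametric GWAS noise (the outcome
#' cohort being far larger, its noise is well approximated analytically);
#' the full selection procedure (top pick, LD window, p filter, cap) is
#' re-applied to every draw; and the observed statistic is compared with
#' the resampled ones (add-one empirical p).
#'
#' When `g` is NULL the exposure side is drawn parametrically from `v_zx`
#' instead (summary-statistics mode).
#'
#' @param locus_stats Harmonized statistics for all cis SNPs at the locus
#'   (`snp`, `b_zx`, `se_zx`, `b_zy`, `se_zy`, `p` = exposure p).
#' @param ld An `ld_matrix` covering the locus.
#' @param g Optional `geno_matrix` for the exposure cohort (subject-level
#'   calibration).
#' @param values Methylation values per subject (scan scale; required with
#'   `g`).
#' @param covariates Optional covariate tibble (as in [scan_mqtl()]).
#' @param v_zx Exposure-slope covariance for all locus SNPs (see
#'   [mqtl_slope_cov()]); NULL falls back to the LD approximation.
#' @param statistic Contrast parameterization passed to [heidi_test()].
#' @param r2_low,r2_high,p_max,cap Selection settings (see
#'   [select_heidi_snps()]).
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @return One-row tibble as from [heidi_test()] (`p_heidi` is the
#'   calibrated p), with the observed selection's SNP count.
#' @export
heidi_selection_calibrated <- function(locus_stats, ld, g = NULL,
                                       values = NULL, covariates = NULL,
                                       v_zx = NULL,
                                       statistic = "crossprod",
                                       r2_low = 0.05, r2_high = 0.9,
                                       p_max = 1.6e-3, cap = 20,
                                       n_boot = 400, seed = 1L) {
  snps <- locus_stats$snp
  m <- length(snps)
  r <- ld$r[snps, snps]
  if (is.null(v_zx)) {
    v_zx <- outer(locus_stats$se_zx, locus_stats$se_zx) * r
    dimnames(v_zx) <- list(snps, snps)
  } else {
    v_zx <- v_zx[snps, snps]
  }
  sy <- locus_stats$se_zy
  vy <- outer(sy, sy) * r
  observe <- function(st) {
    top_i <- which.min(st$p)
    top <- st$snp[top_i]
    sel <- select_heidi_snps(st, top, ld, r2_low, r2_high, p_max, cap)
    if (length(sel) == 0) return(NULL)
    sub <- st[st$snp %in% c(top, sel), , drop = FALSE]
    ht <- heidi_test(sub, top, ld, statistic = statistic,
                     v_zx = v_zx[sub$snp, sub$snp])
    list(t = ht$t_stat, n = ht$n_snp_heidi, top = top)
  }
  obs <- observe(locus_stats)
  if (is.null(obs)) {
    return(tibble::tibble(top_snp = locus_stats$snp[which.min(locus_stats$p)],
                          t_stat = NA_real_, p_heidi = NA_real_,
                          n_snp_heidi = 0L))
  }
  ti <- match(obs$top, snps)
  bxy0 <- locus_stats$b_zy[ti] / locus_stats$b_zx[ti]
  # null outcome means: common causal ratio times the exposure slopes
  mu_zy <- bxy0 * locus_stats$b_zx
  set.seed(seed)
  subject_mode <- !is.null(g)
  if (subject_mode) {
    stopifnot(!is.null(values))
    subjects <- rownames(g$dosages)
    ok <- !is.na(values)
    G <- g$dosages[ok, snps, drop = FALSE]
    yv <- values[ok]
    X <- matrix(1, length(yv), 1)
    if (!is.null(covariates)) {
      cv <- covariates[match(subjects[ok], covariates$subject), , drop = FALSE]
      num <- cv[, setdiff(names(cv), "subject"), drop = FALSE]
      num <- num[, vapply(num, function(x) stats::var(x, na.rm = TRUE) > 0,
                          TRUE), drop = FALSE]
      if (ncol(num) > 0) X <- cbind(X, as.matrix(num))
    }
    slope_fn <- function(idx) {
      qrX <- qr(X[idx, , drop = FALSE])
      ry <- qr.resid(qrX, yv[idx])
      rg <- qr.resid(qrX, G[idx, , drop = FALSE])
      sg <- colSums(rg^2)
      if (any(sg < 1e-12)) return(NULL)
      list(b = as.vector(crossprod(rg, ry)) / sg,
           df = length(idx) - ncol(X) - 1L,
           se = {
             b <- as.vector(crossprod(rg, ry)) / sg
             res2 <- colSums((ry - sweep(rg, 2, b, "*"))^2)
             sqrt(pmax(res2 - 0, 0) / pmax(length(idx) - ncol(X) - 1L, 1) / sg)
           })
    }
    bx_full <- slope_fn(seq_along(yv))
    if (is.null(bx_full)) {
      return(tibble::tibble(top_snp = obs$top, t_stat = obs$t,
                            p_heidi = NA_real_, n_snp_heidi = obs$n))
    }
    # center resampled slopes at the null-consistent observed values
    draw_bx <- function() {
      idx <- sample.int(length(yv), replace = TRUE)
      sf <- slope_fn(idx)
      if (is.null(sf)) return(NULL)
      list(b = locus_stats$b_zx + (sf$b - bx_full$b), se = sf$se)
    }
  } else {
    ex_chol <- chol(v_zx + diag(1e-12, m))
    draw_bx <- function() {
      list(b = locus_stats$b_zx + as.vector(stats::rnorm(m) %*% ex_chol),
           se = locus_stats$se_zx)
    }
  }
  oy_chol <- chol(vy + diag(1e-12, m))
  exceed <- 0L; used <- 0L
  for (b in seq_len(n_boot)) {
    bx <- draw_bx()
    if (is.null(bx)) next
    st_b <- locus_stats
    st_b$b_zx <- bx$b
    st_b$se_zx <- bx$se
    st_b$b_zy <- mu_zy + as.vector(stats::rnorm(m) %*% oy_chol)
    zb <- st_b$b_zx / st_b$se_zx
    st_b$p <- 2 * stats::pnorm(-abs(zb))
    ob <- observe(st_b)
    if (is.null(ob)) next
    used <- used + 1L
    if (ob$t >= obs$t) exceed <- exceed + 1L
  }
  p <- if (used < 50) NA_real_ else (1 + exceed) / (used + 1)
  tibble::tibble(top_snp = obs$top, t_stat = obs$t, p_heidi = p,
                 n_snp_heidi = obs$n)
}

#' Monte-Carlo p-value for the HEIDI statistic
#'
#' Draws the standardized difference vector from its multivariate normal
#' null distribution and compares the simulated statistics with the observed
#' one (add-one empirical p). Used as the independent oracle for the
#' Satterthwaite approximation.
#'
#' @param t_stat Observed statistic.
#' @param d_corr Correlation matrix of the standardized differences (the
#'   `d_corr` attribute of [heidi_test()]).
#' @param n_mc Monte-Carlo draws.
#' @param seed Integer seed.
#' @return Scalar p-value.
#' @export
heidi_p_mc <- function(t_stat, d_corr, n_mc = 20000, seed = 1L) {
  set.seed(seed)
  m <- nrow(d_corr)
  z <- mvtnorm::rmvnorm(n_mc, sigma = d_corr + diag(1e-10, m))
  tt <- rowSums(z^2)
  (1 + sum(tt >= t_stat)) / (n_mc + 1)
}

#' Classify loci as pleiotropy-consistent or linkage
#'
#' A locus whose HEIDI p-value falls below `alpha` (by default the
#' Bonferroni-corrected level 0.05 / number of tested loci) is classified
#' linkage — the mediation interpretation is rejected because distinct causal
#' variants in LD explain the methylation and trait signals; otherwise the
#' data are consistent with a single shared causal variant.
#'
#' @param heidi_results Tibble with `p_heidi` per locus.
#' @param alpha Significance threshold; default `0.05 / n` with n the number
#'   of defined tests.
#' @return The input with `verdict` column (`"linkage"`,
#'   `"single_shared_variant"`, or NA when untested).
#' @export
classify_pleiotropy_vs_linkage <- function(heidi_results, alpha = NULL) {
  n_tested <- sum(!is.na(heidi_results$p_heidi))
  if (is.null(alpha)) alpha <- if (n_tested > 0) 0.05 / n_tested else 0.05
  heidi_results$heidi_alpha <- alpha
  heidi_results$verdict <- dplyr::case_when(
    is.na(heidi_results$p_heidi) ~ NA_character_,
    heidi_results$p_heidi < alpha ~ "linkage",
    TRUE ~ "single_shared_variant"
  )
  heidi_results
}
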
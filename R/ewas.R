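#' Filter CpGs by sequencing coverage
#'
#' Retains CpGs covered by at least `min_coverage` reads in at least
#' `min_subjects_per_group` subjects of *each* phenotype group, the standard
#' count-based inclusion rule for RRBS differential methylation.
#'
#' @param counts A `meth_counts` object.
#' @param groups Tibble with columns `subject` and `group` (0 = low,
#'   1 = high), or a named 0/1 vector.
#' @param min_coverage Minimum read depth per observation.
#' @param min_subjects_per_group Minimum number of adequately covered subjects
#'   in each group.
#' @return A filtered `meth_counts`; attributes `n_total` and `n_retained`
#'   record the filtering outcome.
#' @export
filter_cpgs <- function(counts, groups, min_coverage = 3,
                        min_subjects_per_group = 30) {
  grp <- group_vector(groups, colnames(counts$m))
  if (!any(grp == 0L, na.rm = TRUE) || !any(grp == 1L, na.rm = TRUE)) {
    stop_mm("both phenotype groups must be non-empty")
  }
  if (min(sum(grp == 0L, na.rm = TRUE), sum(grp == 1L, na.rm = TRUE)) <
      min_subjects_per_group) {
    warn_mm("a group has fewer than %d subjects; all CpGs will be filtered out",
            min_subjects_per_group)
  }
  covered <- counts$n >= min_coverage
  n_low <- rowSums(covered[, which(grp == 0L), drop = FALSE], na.rm = TRUE)
  n_high <- rowSums(covered[, which(grp == 1L), drop = FALSE], na.rm = TRUE)
  keep <- n_low >= min_subjects_per_group & n_high >= min_subjects_per_group
  out <- structure(
    list(cpgs = counts$cpgs[keep, , drop = FALSE],
         m = counts$m[keep, , drop = FALSE],
         n = counts$n[keep, , drop = FALSE],
         latent = if (!is.null(counts$latent)) counts$latent[keep, , drop = FALSE]),
    class = "meth_counts"
  )
  attr(out, "n_total") <- nrow(counts$m)
  attr(out, "n_retained") <- sum(keep)
  out
}

# Normalize a group specification to an integer vector aligned to subjects.
group_vector <- function(groups, subjects) {
  if (is.data.frame(groups)) {
    grp <- groups$group[match(subjects, groups$subject)]
  } else if (!is.null(names(groups))) {
    grp <- unname(groups[subjects])
  } else {
    if (length(groups) != length(subjects)) {
      stop_mm("group vector length does not match subject count")
    }
    grp <- groups
  }
  as.integer(grp)
}

#' Per-CpG binomial logistic regression for differential methylation
#'
#' Fits `logit(P_i) = b0 + b1 * X_i + covariate terms` where `P_i` is the
#' proportion of methylated reads for subject i and `X_i` the group indicator
#' (0 = low, 1 = high), as a binomial GLM on (methylated, unmethylated) read
#' counts so each subject contributes with weight equal to its coverage.
#' `b1` is the log odds ratio between the groups; its two-sided Wald p-value
#' tests no differential methylation.
#'
#' @param m,n Integer vectors of methylated and total read counts per subject
#'   (subjects with `n` 0 or missing are dropped).
#' @param design Tibble with column `group` and optional covariate columns
#'   (any further numeric columns are included in the model).
#' @return One-row tibble: `beta1`, `se_beta1`, `p`, `meth_diff` (mean beta
#'   high minus low, in percent), `mean_coverage`, `n_obs`, `converged`.
#'   Non-converged or separated fits carry `p = NA` and `converged = FALSE`.
#' @export
test_dmc <- function(m, n, design) {
  ok <- !is.na(n) & n > 0 & !is.na(m) & !is.na(design$group)
  m <- m[ok]; n <- n[ok]
  design <- design[ok, , drop = FALSE]
  covars <- setdiff(names(design), c("subject", "group"))
  beta <- m / n
  md <- 100 * (mean(beta[design$group == 1L]) - mean(beta[design$group == 0L]))
  base <- tibble::tibble(beta1 = NA_real_, se_beta1 = NA_real_, p = NA_real_,
                         meth_diff = md, mean_coverage = mean(n),
                         n_obs = length(n), converged = FALSE)
  if (length(unique(design$group)) < 2) return(base)
  X <- stats::model.matrix(
    stats::reformulate(c("group", covars)),
    data = as.data.frame(design)
  )
  # drop constant covariate columns (keep intercept), then check rank
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(x) stats::var(x) > 0))
  X <- X[, keep_col, drop = FALSE]
  if (qr(X)$rank < ncol(X)) return(base)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, m / n, weights = n,
                                    family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(base)
  j <- match("group", colnames(X))
  co <- fit$coefficients
  # covariance of coefficients from the final IRLS weights
  w <- fit$weights
  xtx <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(cov)) return(base)
  se <- sqrt(diag(cov))[j]
  if (!is.finite(se) || se > 50) return(base)  # quasi-separation
  z <- unname(co[j] / se)
  tibble::tibble(beta1 = unname(co[j]), se_beta1 = unname(se),
                 p = 2 * stats::pnorm(-abs(z)), meth_diff = md,
                 mean_coverage = mean(n), n_obs = length(n), converged = TRUE)
}

#' Epigenome-wide scan for differentially methylated CpGs
#'
#' Applies [test_dmc()] to every CpG with the group indicator plus the
#' standard covariates (age, BMI, smoking, drinking) and, by default, the
#' first principal component of normalized methylation as a cell-admixture /
#' batch adjustment. Bonferroni correction uses the number of CpGs with a
#' converged fit as the family size.
#'
#' @param counts A `meth_counts` object (already coverage-filtered).
#' @param phenotypes Phenotype tibble (`subject`, `group`, covariates).
#' @param covariates Covariate column names to include.
#' @param use_meth_pc1 Include the first methylation PC as a covariate.
#' @return Tibble with one row per CpG: cpg, chrom, pos, beta1, se_beta1, p,
#'   p_bonferroni, meth_diff (percent), mean_coverage, n_obs, converged,
#'   n_tested.
#' @export
ewas_scan <- function(counts, phenotypes,
                      covariates = c("age", "bmi", "smoking", "drinking"),
                      use_meth_pc1 = TRUE) {
  subjects <- colnames(counts$m)
  design <- tibble::tibble(
    subject = subjects,
    group = group_vector(phenotypes, subjects)
  )
  for (cv in covariates) {
    design[[cv]] <- phenotypes[[cv]][match(subjects, phenotypes$subject)]
  }
  if (use_meth_pc1) {
    pc1 <- tryCatch(methylation_pcs(counts, k = 1)$scores[, 1],
                    error = function(e) NULL)
    if (!is.null(pc1)) design$meth_pc1 <- pc1
  }
  if (nrow(counts$m) == 0) {
    return(tibble::tibble(cpg = character(), chrom = character(),
                          pos = integer(), beta1 = numeric(),
                          se_beta1 = numeric(), p = numeric(),
                          meth_diff = numeric(), mean_coverage = numeric(),
                          n_obs = integer(), converged = logical(),
                          n_tested = integer(), p_bonferroni = numeric()))
  }
  res <- purrr::map_dfr(seq_len(nrow(counts$m)), function(k) {
    test_dmc(counts$m[k, ], counts$n[k, ], design)
  })
  res <- dplyr::bind_cols(counts$cpgs[, c("cpg", "chrom", "pos")], res)
  n_tested <- sum(res$converged)
  res$n_tested <- n_tested
  res$p_bonferroni <- pmin(1, res$p * n_tested)
  res
}

#' Classify differentially methylated CpGs
#'
#' A CpG is a DMC when its Wald p-value passes the Bonferroni threshold
#' `alpha / n_tested` and its absolute group difference in mean methylation
#' exceeds `diff_threshold`. The difference rule is strict (`>`) at the 0.05
#' threshold and inclusive (`>=`) at 0.10, matching the two reporting
#' conventions for moderate and large methylation differences.
#'
#' @param results Output of [ewas_scan()].
#' @param alpha Family-wise error target.
#' @param diff_threshold Methylation-difference threshold, as a fraction
#'   (0.05 or 0.10).
#' @return `results` filtered to DMCs, with a `dmc_threshold` column.
#' @export
classify_dmcs <- function(results, alpha = 0.05, diff_threshold = 0.05) {
  if (nrow(results) == 0) {
    results$dmc_threshold <- numeric(0)
    return(results)
  }
  n_tested <- results$n_tested[1]
  frac_diff <- abs(results$meth_diff) / 100
  pass_diff <- if (diff_threshold >= 0.10) frac_diff >= diff_threshold
               else frac_diff > diff_threshold
  keep <- !is.na(results$p) & results$p < alpha / n_tested & pass_diff
  out <- results[keep, , drop = FALSE]
  out$dmc_threshold <- diff_threshold
  out
}

#' Monte-Carlo power of the count-based differential methylation test
#'
#' Simulates two groups with Poisson coverage and binomial methylated counts
#' at baseline probability `p_low` and `p_low + diff`, runs [test_dmc()]
#' without covariates, and reports the rejection proportion at `alpha`.
#'
#' @param n_low,n_high Group sizes.
#' @param mean_coverage Mean read depth.
#' @param p_low Baseline methylation probability in the low group.
#' @param diff Methylation-probability difference (high minus low).
#' @param alpha Significance level.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return Tibble: `power`, `se` (binomial standard error), `reps`.
#' @export
power_simulation <- function(n_low, n_high, mean_coverage, p_low, diff,
                             alpha = 0.05, reps = 200, seed = 1L) {
  stopifnot(reps >= 100)
  set.seed(seed)
  p_high <- min(max(p_low + diff, 0), 1)
  design <- tibble::tibble(group = rep(c(0L, 1L), c(n_low, n_high)))
  rejections <- vapply(seq_len(reps), function(r) {
    n <- stats::rpois(n_low + n_high, mean_coverage)
    m <- stats::rbinom(n_low + n_high, n,
                       ifelse(design$group == 1L, p_high, p_low))
    res <- test_dmc(m, n, design)
    isTRUE(res$p < alpha)
  }, logical(1))
  power <- mean(rejections)
  tibble::tibble(power = power,
                 se = sqrt(power * (1 - power) / reps),
                 reps = reps)
}

#' Over-dispersion of methylation proportions relative to the binomial model
#'
#' Within each group, the observed variance of the beta values m/n is divided
#' by the binomial-expected variance `mean(p_hat * (1 - p_hat) / n)` with
#' `p_hat` the coverage-weighted group methylation level; group ratios are
#' pooled by a coverage-weighted average. A ratio near 1 indicates pure
#' read-sampling noise; ratios above 1 indicate extra subject-level
#' variability the binomial regression does not model.
#'
#' @param m,n Methylated and total read counts per subject.
#' @param group 0/1 group labels per subject.
#' @return One-row tibble: `ratio` (pooled), `ratio_low`, `ratio_high`.
#' @export
estimate_overdispersion <- function(m, n, group) {
  ok <- !is.na(m) & !is.na(n) & n > 0 & !is.na(group)
  m <- m[ok]; n <- n[ok]; group <- group[ok]
  one_group <- function(g) {
    mg <- m[group == g]; ng <- n[group == g]
    if (length(ng) < 2) return(c(ratio = NA_real_, w = 0))
    phat <- sum(mg) / sum(ng)
    if (phat <= 0 || phat >= 1) return(c(ratio = NA_real_, w = 0))
    obs <- stats::var(mg / ng)
    expe <- mean(phat * (1 - phat) / ng)
    c(ratio = obs / expe, w = sum(ng))
  }
  lo <- one_group(0L); hi <- one_group(1L)
  ratios <- c(lo["ratio"], hi["ratio"])
  ws <- c(lo["w"], hi["w"])
  pooled <- wmean(ratios, ws)
  tibble::tibble(ratio = pooled,
                 ratio_low = unname(lo["ratio"]),
                 ratio_high = unname(hi["ratio"]))
}
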
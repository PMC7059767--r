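mr_result_row <- function(method, n_snp, b_xy = NA_real_, se = NA_real_,
                          p = NA_real_, egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_,
                          top_snp = NA_character_) {
  tibble::tibble(method = method, n_snp = as.integer(n_snp), b_xy = b_xy,
                 se = se, p = p, egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p, top_snp = top_snp)
}

new_mr_result <- function(row, instruments) {
  structure(row, class = c("mr_result", class(row)),
            instruments = instruments)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `b_xy = b_zy / b_zx`, the outcome effect rescaled by the exposure effect.
#' The default standard error is the first-order delta approximation
#' `se_zy / |b_zx|`; the second-order form adds the exposure-uncertainty term
#' `b_zy^2 se_zx^2 / b_zx^4`.
#'
#' @param inst One-row harmonized instrument tibble.
#' @param second_order Use the second-order delta standard error.
#' @return An `mr_result` tibble row.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  stopifnot(nrow(inst) == 1)
  if (inst$b_zx == 0) stop_mm("Wald ratio undefined: exposure effect is zero")
  b <- inst$b_zy / inst$b_zx
  se <- if (second_order) {
    sqrt(inst$se_zy^2 / inst$b_zx^2 +
         inst$b_zy^2 * inst$se_zx^2 / inst$b_zx^4)
  } else {
    inst$se_zy / abs(inst$b_zx)
  }
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_result(mr_result_row("wald_ratio", 1L, b, se, p,
                              top_snp = inst$snp), inst)
}

#' Inverse-variance weighted causal estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights `1/se_zy^2` (equivalently, the inverse-variance meta-analysis of
#' the per-instrument Wald ratios). In fixed-effect mode the residual
#' variance is forced to 1; in multiplicative-random-effect (MRE) mode the
#' standard error is inflated by `sqrt(max(1, Q/(n-1)))` with Q the Cochran
#' heterogeneity statistic.
#'
#' @param instruments Harmonized instruments (>= 2 rows).
#' @param mode `"fixed"` or `"mre"`.
#' @return An `mr_result` row (method `ivw_fe` or `ivw_mre`) with `q_stat`.
#' @export
ivw <- function(instruments, mode = c("fixed", "mre")) {
  mode <- match.arg(mode)
  if (nrow(instruments) < 2) {
    stop_mm("IVW needs >= 2 instruments; use wald_ratio() for one")
  }
  w <- 1 / instruments$se_zy^2
  x <- instruments$b_zx; y <- instruments$b_zy
  b <- sum(w * x * y) / sum(w * x^2)
  se <- sqrt(1 / sum(w * x^2))
  q <- sum(w * (y - b * x)^2)
  n <- nrow(instruments)
  if (mode == "mre") se <- se * sqrt(max(1, q / (n - 1)))
  p <- 2 * stats::pnorm(-abs(b / se))
  row <- mr_result_row(if (mode == "fixed") "ivw_fe" else "ivw_mre",
                       n, b, se, p,
                       top_snp = instruments$snp[which.min(instruments$p_exposure)])
  row$q_stat <- q
  new_mr_result(row, instruments)
}

#' Egger regression: causal slope with a pleiotropy intercept
#'
#' Instruments are oriented so exposure effects are non-negative, then the
#' outcome effects are regressed on the exposure effects with a free
#' intercept, weighted by `1/se_zy^2`. The slope estimates the causal effect
#' under the InSIDE condition; the intercept estimates the average
#' directional pleiotropy. Tests use the t distribution with `n_snp - 2`
#' degrees of freedom. With fewer than three instruments the result is
#' reported as missing (the model is not identified).
#'
#' @param instruments Harmonized instruments.
#' @return An `mr_result` row (method `egger`) with intercept fields.
#' @export
egger <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3) {
    return(new_mr_result(mr_result_row("egger", n), instruments))
  }
  flip <- sign(instruments$b_zx)
  flip[flip == 0] <- 1
  x <- instruments$b_zx * flip
  y <- instruments$b_zy * flip
  fit <- stats::lm(y ~ x, weights = 1 / instruments$se_zy^2)
  sm <- summary(fit)$coefficients
  row <- mr_result_row(
    "egger", n,
    b_xy = sm["x", "Estimate"], se = sm["x", "Std. Error"],
    p = sm["x", "Pr(>|t|)"],
    egger_intercept = sm["(Intercept)", "Estimate"],
    egger_intercept_p = sm["(Intercept)", "Pr(>|t|)"],
    top_snp = instruments$snp[which.min(instruments$p_exposure)]
  )
  row$egger_intercept_se <- sm["(Intercept)", "Std. Error"]
  new_mr_result(row, instruments)
}

# Weighted median of x at weights w (Bowden's interpolation form).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cs <- cumsum(w) - 0.5 * w
  cs <- cs / sum(w)
  if (cs[1] >= 0.5) return(x[1])
  below <- max(which(cs < 0.5))
  if (below == length(x)) return(x[length(x)])
  x[below] + (x[below + 1] - x[below]) * (0.5 - cs[below]) /
    (cs[below + 1] - cs[below])
}

#' Weighted-median causal estimate
#'
#' The inverse-variance weighted median of the per-instrument Wald ratios:
#' consistent when instruments carrying at least half the weight are valid,
#' hence robust to a minority of pleiotropic instruments. The standard error
#' comes from a parametric bootstrap of the summary statistics.
#'
#' @param instruments Harmonized instruments (>= 3).
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_result` row (method `weighted_median`).
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  n <- nrow(instruments)
  if (n < 3) {
    return(new_mr_result(mr_result_row("weighted_median", n), instruments))
  }
  ratio <- instruments$b_zy / instruments$b_zx
  w <- instruments$b_zx^2 / instruments$se_zy^2
  est <- weighted_median_point(ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, instruments$b_zx, instruments$se_zx)
    by <- stats::rnorm(n, instruments$b_zy, instruments$se_zy)
    weighted_median_point(by / bx, bx^2 / instruments$se_zy^2)
  }, numeric(1))
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(est / se))
  new_mr_result(
    mr_result_row("weighted_median", n, est, se, p,
                  top_snp = instruments$snp[which.min(instruments$p_exposure)]),
    instruments
  )
}

# Profile negative log-likelihood for the bivariate-normal MR model:
# (b_zx_j, b_zy_j) ~ N((g_j, beta*g_j), diag(se_zx_j^2, se_zy_j^2)), with the
# per-SNP true effects g_j profiled out analytically.
ml_profile_negll <- function(beta, x, y, sx2, sy2) {
  g <- (x / sx2 + beta * y / sy2) / (1 / sx2 + beta^2 / sy2)
  0.5 * sum((x - g)^2 / sx2 + (y - beta * g)^2 / sy2)
}

#' Maximum-likelihood causal estimate
#'
#' Treats the observed exposure and outcome effects as independent normals
#' around `(g_j, beta * g_j)`, profiles out the per-SNP true exposure effects
#' analytically, and maximizes over beta. The standard error comes from the
#' curvature of the profile likelihood at the maximum.
#'
#' @param instruments Harmonized instruments (>= 2).
#' @return An `mr_result` row (method `max_likelihood`); non-convergence is
#'   flagged by missing fields.
#' @export
max_likelihood <- function(instruments) {
  n <- nrow(instruments)
  if (n < 2) stop_mm("maximum likelihood needs >= 2 instruments")
  x <- instruments$b_zx; y <- instruments$b_zy
  sx2 <- instruments$se_zx^2; sy2 <- instruments$se_zy^2
  ratios <- y / x
  half <- max(1, 10 * max(abs(ratios)))
  opt <- tryCatch(
    stats::optimize(ml_profile_negll, interval = c(-half, half),
                    x = x, y = y, sx2 = sx2, sy2 = sy2, tol = 1e-10),
    error = function(e) NULL
  )
  if (is.null(opt) || abs(opt$minimum) > 0.999 * half) {
    return(new_mr_result(mr_result_row("max_likelihood", n), instruments))
  }
  b <- opt$minimum
  h <- 1e-4 * (1 + abs(b))
  d2 <- (ml_profile_negll(b + h, x, y, sx2, sy2) -
         2 * opt$objective +
         ml_profile_negll(b - h, x, y, sx2, sy2)) / h^2
  if (!is.finite(d2) || d2 <= 0) {
    return(new_mr_result(mr_result_row("max_likelihood", n), instruments))
  }
  se <- 1 / sqrt(d2)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_mr_result(
    mr_result_row("max_likelihood", n, b, se, p,
                  top_snp = instruments$snp[which.min(instruments$p_exposure)]),
    instruments
  )
}

#' Run the MR estimator battery for one exposure
#'
#' Applies the primary estimator (Wald ratio for a single instrument, IVW
#' fixed-effect otherwise) plus the sensitivity estimators where their
#' instrument-count preconditions hold: IVW-MRE (>= 2), Egger (>= 3),
#' weighted median (>= 3), maximum likelihood (>= 2).
#'
#' @param instruments Harmonized, LD-pruned instruments for one CpG.
#' @param cpg CpG id recorded in the output.
#' @param seed Bootstrap seed for the weighted median.
#' @return Tibble of MR results, one row per method, with a `primary` flag.
#' @export
mr_analyze <- function(instruments, cpg = NA_character_, seed = 1L) {
  n <- nrow(instruments)
  if (n < 1) return(tibble::tibble())
  res <- list()
  if (n == 1) {
    res$primary <- wald_ratio(instruments)
  } else {
    res$primary <- ivw(instruments, "fixed")
    res$mre <- ivw(instruments, "mre")
    res$ml <- max_likelihood(instruments)
  }
  res$egger <- egger(instruments)
  if (n >= 3) res$wm <- weighted_median(instruments, seed = seed)
  out <- dplyr::bind_rows(lapply(res, tibble::as_tibble))
  out$primary <- out$method %in% c("wald_ratio", "ivw_fe") &
    seq_len(nrow(out)) == 1L
  dplyr::bind_cols(tibble::tibble(cpg = cpg), out)
}

#' Select mediator CpGs by false discovery rate
#'
#' Benjamini-Hochberg adjustment of the primary MR p-values across the DMC
#' family; a DMC is a mediator when its adjusted value falls below `fdr_q`.
#'
#' @param primary_results Tibble with one primary MR result per CpG (columns
#'   `cpg`, `p`).
#' @param fdr_q FDR threshold.
#' @return The input with `q` and `mediator` columns.
#' @export
select_mediators <- function(primary_results, fdr_q = 0.05) {
  out <- primary_results
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$mediator <- !is.na(out$q) & out$q < fdr_q
  out
}
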
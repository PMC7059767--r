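#' Reverse-direction two-stage least squares
#'
#' Tests whether the trait causally alters methylation (reverse causation) in
#' a one-sample design: stage 1 regresses the trait on all instrument SNPs
#' jointly; stage 2 regresses methylation on the stage-1 fitted values,
#' either as a linear model on transformed methylation values or as a
#' binomial logistic model on read counts. The reported standard error is the
#' naive stage-2 error (no small-sample instrumental-variable correction).
#' A stage-1 F statistic below 10 attaches a weak-instrument warning flag.
#'
#' @param g_iv Dosage matrix (subjects x instrument SNPs) or `geno_matrix`
#'   restricted to the trait-associated instruments.
#' @param trait Continuous phenotype vector (aligned to rows of `g_iv`).
#' @param meth For `mode = "linear"`: numeric methylation values (e.g.
#'   inverse-normal transformed betas). For `mode = "logistic"`: a list with
#'   integer vectors `m` and `n`.
#' @param mode `"linear"` or `"logistic"` stage-2 model.
#' @return One-row tibble: `estimate`, `se`, `p`, `f_stat`,
#'   `weak_instruments`, `n_iv`, `n_obs`.
#' @export
reverse_mr_2sls <- function(g_iv, trait, meth,
                            mode = c("linear", "logistic")) {
  mode <- match.arg(mode)
  G <- if (inherits(g_iv, "geno_matrix")) g_iv$dosages else as.matrix(g_iv)
  if (ncol(G) < 1) stop_mm("reverse MR needs at least one instrument")
  meth_vals <- if (mode == "linear") meth else meth$m
  ok <- stats::complete.cases(G) & !is.na(trait) & !is.na(meth_vals)
  if (mode == "logistic") ok <- ok & !is.na(meth$n) & meth$n > 0
  G <- G[ok, , drop = FALSE]
  trait <- trait[ok]
  # stage 1: trait on all IVs jointly
  s1 <- stats::lm(trait ~ G)
  f_stat <- summary(s1)$fstatistic
  fval <- if (is.null(f_stat)) NA_real_ else unname(f_stat[1])
  fitted_trait <- stats::fitted(s1)
  weak <- !is.na(fval) && fval < 10
  if (weak) warn_mm("stage-1 F = %.2f < 10: weak instruments", fval)
  if (stats::var(fitted_trait) < 1e-12) {
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, p = NA_real_,
                          f_stat = fval, weak_instruments = weak,
                          n_iv = ncol(G), n_obs = sum(ok)))
  }
  if (mode == "linear") {
    s2 <- stats::lm(meth[ok] ~ fitted_trait)
    sm <- summary(s2)$coefficients["fitted_trait", ]
    est <- sm["Estimate"]; se <- sm["Std. Error"]; p <- sm["Pr(>|t|)"]
  } else {
    m <- meth$m[ok]; n <- meth$n[ok]
    s2 <- suppressWarnings(
      stats::glm(cbind(m, n - m) ~ fitted_trait, family = stats::binomial())
    )
    sm <- summary(s2)$coefficients["fitted_trait", ]
    est <- sm["Estimate"]; se <- sm["Std. Error"]; p <- sm["Pr(>|z|)"]
  }
  tibble::tibble(estimate = unname(est), se = unname(se), p = unname(p),
                 f_stat = fval, weak_instruments = weak,
                 n_iv = ncol(G), n_obs = sum(ok))
}
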
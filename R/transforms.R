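#' Rank-based inverse normal transform
#'
#' Replaces non-missing values by `qnorm((rank - 0.5) / m)` with tie-averaged
#' ranks, where `m` is the number of non-missing values. The output is
#' strictly monotone in the input up to ties; missing values stay missing.
#' Used to normalize methylation levels before principal-component analysis
#' and the mQTL scan, reducing the influence of outliers.
#'
#' @param values Numeric vector, possibly with NAs.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 2) stop_mm("inverse_normal_transform needs >= 2 non-missing values")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / m)
  out
}

#' Principal components of normalized methylation
#'
#' Each CpG's beta values are inverse-normal transformed across subjects;
#' CpGs with any missing value are excluded (optionally mean-imputed instead)
#' and the subject x CpG matrix is decomposed by PCA. Subjects with similar
#' cell-type composition or batch share multi-locus methylation patterns,
#' which the leading components capture; the first score vector is the
#' standard cell-admixture/batch covariate.
#'
#' @param counts A `meth_counts` object.
#' @param k Number of components to return.
#' @param missing `"drop"` (default) excludes CpGs with missing values;
#'   `"impute"` mean-imputes them.
#' @return List with `scores` (subject x k matrix) and `variance_explained`
#'   (length-k vector, non-increasing, summing to <= 1).
#' @export
methylation_pcs <- function(counts, k = 1, missing = c("drop", "impute")) {
  missing <- match.arg(missing)
  b <- beta_values(counts)
  intb <- t(apply(b, 1, function(row) {
    if (sum(!is.na(row)) < 2) return(rep(NA_real_, length(row)))
    inverse_normal_transform(row)
  }))
  has_na <- apply(intb, 1, anyNA)
  if (missing == "drop") {
    intb <- intb[!has_na, , drop = FALSE]
  } else {
    intb <- t(apply(intb, 1, function(row) {
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      row
    }))
    intb <- intb[apply(intb, 1, function(r) all(is.finite(r))), , drop = FALSE]
  }
  if (nrow(intb) < k) {
    stop_mm("only %d complete CpGs available for %d principal components",
            nrow(intb), k)
  }
  pc <- stats::prcomp(t(intb), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)])
}

# Methylation value matrix on a given scale: "int" (per-CpG inverse normal
# transform), "raw" beta values, or "logit" (empirical logit of counts).
meth_values <- function(counts, mode = c("int", "raw", "logit")) {
  mode <- match.arg(mode)
  b <- beta_values(counts)
  switch(mode,
    raw = b,
    int = t(apply(b, 1, function(r) {
      if (sum(!is.na(r)) < 3) rep(NA_real_, length(r))
      else inverse_normal_transform(r)
    })),
    logit = {
      el <- emp_logit(counts$m, counts$n)
      el[counts$n == 0L] <- NA_real_
      el
    }
  )
}

# Genomic inflation factor of a p-value vector (median chi-square ratio).
inflation_factor <- function(p) {
  p <- p[is.finite(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
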
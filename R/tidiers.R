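#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR result
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One row per estimate: term, estimate, std.error, p.value, plus
#'   the intercept row for Egger fits.
#' @exportS3Method generics::tidy
tidy.mr_result <- function(x, ...) {
  out <- tibble::tibble(
    term = x$method, estimate = x$b_xy, std.error = x$se, p.value = x$p,
    n_snp = x$n_snp
  )
  if (identical(x$method, "egger") && !is.na(x$egger_intercept)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "egger_intercept", estimate = x$egger_intercept,
      std.error = x$egger_intercept_se %||% NA_real_,
      p.value = x$egger_intercept_p, n_snp = x$n_snp
    ))
  }
  out
}

#' @exportS3Method generics::glance
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q_stat = if ("q_stat" %in% names(x)) x$q_stat else NA_real_)
}

#' Tidy a fine-mapping posterior
#'
#' @param x A `locus_posterior`.
#' @param ... Unused.
#' @return Per-SNP tibble with Z-scores and posterior inclusion
#'   probabilities.
#' @exportS3Method generics::tidy
tidy.locus_posterior <- function(x, ...) {
  out <- x$pip
  out$top_causal <- out$snp == x$top_causal
  out
}

#' @exportS3Method generics::glance
glance.locus_posterior <- function(x, ...) {
  tibble::tibble(cpg = x$cpg %||% NA_character_,
                 n_snp = nrow(x$pip),
                 top_causal = x$top_causal,
                 top_pip = max(x$pip$pip),
                 p_null_config = x$configs$posterior[x$configs$size == 0],
                 log_marginal = x$log_marginal)
}

#' Tidy a pipeline report
#'
#' @param x An `mm_report`.
#' @param ... Unused.
#' @return The per-DMC report tibble.
#' @exportS3Method generics::tidy
tidy.mm_report <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.mm_report <- function(x, ...) {
  tibble::tibble(
    scenario = x$config$scenario, seed = x$config$seed,
    n_cpg_tested = x$ewas$n_tested[1] %||% NA_integer_,
    n_dmc = nrow(x$dmcs),
    n_mqtl_sig = nrow(x$mqtl_sig),
    n_mediator = if (nrow(x$primary) > 0) sum(x$primary$mediator) else 0L,
    n_mediation_consistent = if (nrow(x$report) > 0)
      sum(x$report$verdict == "mediation-consistent") else 0L
  )
}
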
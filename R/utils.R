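# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# Empirical logit of read counts; the 0.5 offset keeps 0 and n finite.
emp_logit <- function(m, n) log((m + 0.5) / (n - m + 0.5))

# Derive a reproducible sub-stream seed (kept inside 32-bit integer range).
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483587L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mm <- function(...) stop(sprintf(...), call. = FALSE)

warn_mm <- function(...) warning(sprintf(...), call. = FALSE)

# Weighted mean that tolerates missing values in x.
wmean <- function(x, w) {
  keep <- is.finite(x) & is.finite(w)
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}
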
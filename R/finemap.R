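#' Bundle locus data for fine-mapping
#'
#' @param cpg Locus (CpG) id.
#' @param snps SNP ids, ordered.
#' @param z mQTL Z-scores (`b_zx / se_zx`) for the SNPs.
#' @param sigma LD correlation matrix (an `ld_matrix` or plain matrix)
#'   restricted to the locus.
#' @param annotations SNP x track binary matrix (may have zero columns).
#' @return A `locus_data` list.
#' @export
locus_data <- function(cpg, snps, z, sigma, annotations = NULL) {
  if (inherits(sigma, "ld_matrix")) sigma <- sigma$r[snps, snps, drop = FALSE]
  stopifnot(length(snps) == length(z), all(is.finite(z)),
            nrow(sigma) == length(snps))
  if (is.null(annotations)) {
    annotations <- matrix(0L, length(snps), 0, dimnames = list(snps, NULL))
  } else {
    annotations <- annotations[snps, , drop = FALSE]
  }
  structure(list(cpg = cpg, snps = snps, z = as.numeric(z),
                 sigma = unname(as.matrix(sigma)), annotations = annotations),
            class = "locus_data")
}

#' Log marginal likelihood of a causal configuration
#'
#' Summary-statistics multivariate-normal model: with LD matrix S (ridge
#' regularized) and causal set c, the Z-score vector is
#' `z ~ N(0, S + S[,c] w2 I S[c,])` — each causal SNP contributes
#' non-centrality variance `w2`, spread over its LD neighbours. The empty
#' configuration gives the plain `N(0, S)` density.
#'
#' @param locus A [locus_data()].
#' @param c_idx Integer indices of the causal SNPs (possibly empty).
#' @param w2 Prior variance of the causal non-centrality (default 25,
#'   i.e. signals around |z| = 5).
#' @param ridge Ridge added to the LD matrix for invertibility.
#' @return Scalar log density.
#' @export
config_likelihood <- function(locus, c_idx, w2 = 25, ridge = 0.001) {
  m <- length(locus$z)
  s <- locus$sigma + diag(ridge, m)
  v <- s
  if (length(c_idx) > 0) {
    sc <- s[, c_idx, drop = FALSE]
    v <- s + sc %*% (w2 * diag(length(c_idx))) %*% t(sc)
  }
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) stop_mm("configuration covariance not positive definite")
  quad <- sum(backsolve(ch, locus$z, transpose = TRUE)^2)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

#' Log prior of a causal configuration under the annotation model
#'
#' Independent-Bernoulli prior with logistic annotation weights:
#' `P(j causal) = plogis(a0 + a . A_j)`. The log prior of configuration c is
#' the sum of `log pi_j` over members and `log(1 - pi_j)` over non-members.
#' (Posterior normalization over the enumerated configurations makes the
#' truncation renormalization implicit.)
#'
#' @param c_idx Integer indices of the causal SNPs.
#' @param annotations SNP x track binary matrix.
#' @param a0 Baseline log-odds.
#' @param a Per-track log-odds weights (length = tracks).
#' @return Scalar log prior.
#' @export
config_prior <- function(c_idx, annotations, a0, a = numeric(0)) {
  m <- nrow(annotations)
  eta <- rep(a0, m)
  if (length(a) > 0) eta <- eta + as.vector(annotations %*% a)
  lp <- stats::plogis(eta, log.p = TRUE)
  lq <- stats::plogis(-eta, log.p = TRUE)   # log(1 - pi)
  inc <- rep(FALSE, m)
  inc[c_idx] <- TRUE
  sum(lp[inc]) + sum(lq[!inc])
}

# All configurations with at most max_causal SNPs, as a list of index
# vectors (the first is the empty configuration).
enumerate_configs <- function(m, max_causal = 2) {
  configs <- list(integer(0))
  if (max_causal >= 1) configs <- c(configs, as.list(seq_len(m)))
  if (max_causal >= 2 && m >= 2) {
    pairs <- utils::combn(m, 2, simplify = FALSE)
    configs <- c(configs, pairs)
  }
  configs
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Enumerate causal configurations and compute posterior probabilities
#'
#' Exhaustively scores every configuration of at most `max_causal` causal
#' SNPs (including the empty configuration, so a locus can report no credible
#' causal variant), combining the annotation prior with the
#' summary-statistics likelihood; per-SNP posterior inclusion probabilities
#' (PIPs) are the sums of configuration posteriors containing each SNP.
#'
#' @param locus A [locus_data()].
#' @param a0,a Annotation prior weights (see [config_prior()]).
#' @param max_causal Maximum causal SNPs per configuration (default 2).
#' @param w2,ridge Likelihood settings (see [config_likelihood()]).
#' @param max_snps Guard on locus size (enumeration is quadratic).
#' @return A `locus_posterior`: list with `configs` (tibble: config, size,
#'   log_lik, log_prior, posterior), `pip` (tibble: snp, pip, annotations),
#'   `top_causal`, `log_marginal` and the settings used.
#' @export
enumerate_posteriors <- function(locus, a0 = stats::qlogis(0.01),
                                 a = numeric(0), max_causal = 2, w2 = 25,
                                 ridge = 0.001, max_snps = 1000) {
  m <- length(locus$z)
  if (m > max_snps) {
    stop_mm("locus has %d SNPs (cap %d); pre-filter the locus", m, max_snps)
  }
  configs <- enumerate_configs(m, max_causal)
  log_lik <- vapply(configs, function(cc)
    config_likelihood(locus, cc, w2 = w2, ridge = ridge), numeric(1))
  log_prior <- vapply(configs, function(cc)
    config_prior(cc, locus$annotations, a0, a), numeric(1))
  lw <- log_lik + log_prior
  lz <- log_sum_exp(lw)
  post <- exp(lw - lz)
  pip <- numeric(m)
  for (i in seq_along(configs)) {
    if (length(configs[[i]]) > 0) {
      pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
    }
  }
  cfg <- tibble::tibble(
    config = vapply(configs, function(cc)
      if (length(cc) == 0) "" else paste(locus$snps[cc], collapse = ","), ""),
    size = lengths(configs),
    log_lik = log_lik, log_prior = log_prior, posterior = post
  )
  structure(
    list(cpg = locus$cpg,
         configs = cfg,
         pip = tibble::tibble(snp = locus$snps, z = locus$z, pip = pip),
         top_causal = locus$snps[which.max(pip)],
         log_marginal = lz,
         a0 = a0, a = a, w2 = w2, max_causal = max_causal),
    class = "locus_posterior"
  )
}

#' @export
print.locus_posterior <- function(x, ...) {
  cat(sprintf("<locus_posterior> %s: %d SNPs, top causal %s (PIP %.3f)\n",
              x$cpg %||% "?", nrow(x$pip), x$top_causal,
              max(x$pip$pip)))
  invisible(x)
}

#' Fit annotation prior weights across loci by EM
#'
#' Empirical-Bayes fitting of the logistic annotation prior: the E-step
#' computes per-SNP posterior inclusion probabilities at the current weights;
#' the M-step refits the weights by (quasi-binomial) logistic regression of
#' the PIPs on the annotations. Iterates until the largest weight change
#' falls below `tol`. The total marginal log-likelihood is tracked and the
#' iteration stops (keeping the previous weights) if it ever decreases, so
#' the returned trace is non-decreasing. Weights are clipped at |a| <= 10
#' (separation guard).
#'
#' @param loci List of [locus_data()] objects sharing the same tracks.
#' @param max_iter,tol EM controls.
#' @param w2,max_causal,ridge Passed to [enumerate_posteriors()].
#' @return List with `a0`, `a`, `n_iter`, `loglik_trace`, and `posteriors`
#'   (the per-locus `locus_posterior` objects at the final weights).
#' @export
em_fit_annotations <- function(loci, max_iter = 100, tol = 1e-4,
                               w2 = 25, max_causal = 2, ridge = 0.001) {
  stopifnot(length(loci) >= 1)
  n_tracks <- ncol(loci[[1]]$annotations)
  total_snps <- sum(vapply(loci, function(l) length(l$z), 0L))
  if (total_snps < n_tracks + 1) stop_mm("more tracks than SNPs")
  mean_m <- total_snps / length(loci)
  a0 <- stats::qlogis(min(0.5, 1 / mean_m))
  a <- rep(0, n_tracks)
  trace <- numeric(0)
  posts <- NULL
  for (iter in seq_len(max_iter)) {
    posts_new <- lapply(loci, enumerate_posteriors, a0 = a0, a = a,
                        max_causal = max_causal, w2 = w2, ridge = ridge)
    ll <- sum(vapply(posts_new, function(p) p$log_marginal, numeric(1)))
    if (length(trace) > 0 && ll < trace[length(trace)] - 1e-9) break
    posts <- posts_new
    trace <- c(trace, ll)
    pips <- unlist(lapply(posts, function(p) p$pip$pip))
    ann <- do.call(rbind, lapply(loci, function(l) l$annotations))
    if (n_tracks == 0) {
      mean_pip <- min(max(mean(pips), 1e-6), 1 - 1e-6)
      coefs <- stats::qlogis(mean_pip)
    } else {
      df <- data.frame(pip = pmin(pmax(pips, 1e-12), 1 - 1e-12), ann)
      fit <- suppressWarnings(
        stats::glm(pip ~ ., data = df, family = stats::quasibinomial())
      )
      coefs <- stats::coef(fit)
      coefs[is.na(coefs)] <- 0  # collinear/constant track within these loci
    }
    if (any(abs(coefs) > 10)) {
      warn_mm("annotation weights clipped at |a| = 10 (possible separation)")
      coefs <- pmin(pmax(coefs, -10), 10)
    }
    new_a0 <- unname(coefs[1])
    new_a <- if (n_tracks > 0) unname(coefs[-1]) else numeric(0)
    delta <- max(abs(c(new_a0 - a0, new_a - a)))
    if (delta < tol) {
      posts2 <- lapply(loci, enumerate_posteriors, a0 = new_a0, a = new_a,
                       max_causal = max_causal, w2 = w2, ridge = ridge)
      ll2 <- sum(vapply(posts2, function(p) p$log_marginal, numeric(1)))
      if (ll2 >= trace[length(trace)]) {
        a0 <- new_a0; a <- new_a
        posts <- posts2
        trace <- c(trace, ll2)
      }
      break
    }
    a0 <- new_a0; a <- new_a
  }
  list(a0 = a0, a = a, n_iter = length(trace), loglik_trace = trace,
       posteriors = posts)
}
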
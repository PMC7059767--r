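# Independent brute-force posterior: builds each configuration covariance
# explicitly, evaluates the density via solve() and determinant(), the prior
# by direct products, and normalizes with plain arithmetic.
brute_force_posterior <- function(z, sigma, ann, a0, a, w2 = 25,
                                  ridge = 0.001, max_causal = 2) {
  m <- length(z)
  s <- sigma + diag(ridge, m)
  configs <- list(integer(0))
  if (max_causal >= 1) configs <- c(configs, as.list(seq_len(m)))
  if (max_causal >= 2 && m >= 2) {
    configs <- c(configs, utils::combn(m, 2, simplify = FALSE))
  }
  pi_j <- plogis(a0 + if (ncol(ann) > 0) as.vector(ann %*% a) else 0)
  dens <- vapply(configs, function(cc) {
    v <- s
    for (j in cc) for (k in cc) v <- v + w2 * outer(s[, j], s[, k]) *
        (j == k)
    # (loop keeps only the diagonal W contribution, matching w2 * S_c S_c')
    det_v <- determinant(v, logarithm = TRUE)$modulus
    quad <- drop(t(z) %*% solve(v) %*% z)
    lik <- exp(-0.5 * (m * log(2 * pi) + det_v + quad))
    inc <- seq_len(m) %in% cc
    lik * prod(ifelse(inc, pi_j, 1 - pi_j))
  }, numeric(1))
  post <- dens / sum(dens)
  pip <- numeric(m)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  list(post = post, pip = pip)
}

random_locus <- function(m, seed, tracks = 1) {
  set.seed(seed)
  a <- matrix(rnorm(m * m), m)
  sigma <- cov2cor(crossprod(a) + diag(m))
  z <- as.numeric(mvtnorm::rmvnorm(1, sigma = sigma)) + sample(c(0, 4), m,
                                                              replace = TRUE)
  ann <- matrix(rbinom(m * tracks, 1, 0.3), m, tracks)
  rownames(ann) <- sprintf("s%02d", 1:m)
  locus_data("locus", sprintf("s%02d", 1:m), z, sigma, ann)
}

test_that("configuration likelihood matches closed forms in the scalar case", {
  loc <- locus_data("c", "s1", z = 2, sigma = matrix(1, 1, 1))
  w2 <- 25; ridge <- 0.001
  l0 <- config_likelihood(loc, integer(0), w2, ridge)
  l1 <- config_likelihood(loc, 1L, w2, ridge)
  s <- 1 + ridge
  expect_equal(l0, dnorm(2, 0, sqrt(s), log = TRUE), tolerance = 1e-12)
  expect_equal(l1, dnorm(2, 0, sqrt(s + w2 * s^2), log = TRUE),
               tolerance = 1e-12)
  # likelihood ratio increases with |z|
  lr <- vapply(c(1, 2, 4, 6), function(zz) {
    lz <- locus_data("c", "s1", z = zz, sigma = matrix(1, 1, 1))
    config_likelihood(lz, 1L) - config_likelihood(lz, integer(0))
  }, numeric(1))
  expect_true(all(diff(lr) > 0))
  # raising w2 increases the single-SNP odds while w2 < z^2 - 1 (the
  # scalar likelihood ratio peaks at w2 = z^2 - 1 and declines beyond)
  odds <- vapply(c(4, 9, 25), function(w) {
    lz <- locus_data("c", "s1", z = 6, sigma = matrix(1, 1, 1))
    config_likelihood(lz, 1L, w2 = w) - config_likelihood(lz, integer(0))
  }, numeric(1))
  expect_true(all(diff(odds) > 0))
})

test_that("configuration likelihood matches numerical integration over effects", {
  set.seed(2)
  sigma <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.4, 0.2, 0.4, 1), 3)
  z <- c(3, 2.5, 1)
  loc <- locus_data("c", c("a", "b", "c"), z, sigma)
  w2 <- 9; ridge <- 0.001
  s <- sigma + diag(ridge, 3)
  # single causal SNP j: z ~ N(s[,j] * b, s), b ~ N(0, w2)
  for (j in 1:3) {
    integrand <- function(b) {
      vapply(b, function(bb) {
        mvtnorm::dmvnorm(z, mean = s[, j] * bb, sigma = s) *
          dnorm(bb, 0, sqrt(w2))
      }, numeric(1))
    }
    quad <- pracma::integral(integrand, -40, 40, reltol = 1e-10)
    expect_equal(config_likelihood(loc, j, w2 = w2, ridge = ridge),
                 log(quad), tolerance = 1e-4)
  }
})

test_that("annotation prior follows the logistic odds model", {
  ann <- matrix(c(1L, 0L, 1L), 3, 1, dimnames = list(c("a", "b", "c"), "t1"))
  # no annotation effect: every SNP has prior 0.01
  lp <- config_prior(1L, ann, a0 = qlogis(0.01), a = 0)
  expect_equal(lp, log(0.01) + 2 * log(0.99), tolerance = 1e-12)
  # one track at log(10): annotated SNPs have 10x prior odds
  a0 <- qlogis(0.05)
  pa <- plogis(a0 + log(10))
  odds_ratio <- (pa / (1 - pa)) / (0.05 / 0.95)
  expect_equal(odds_ratio, 10, tolerance = 1e-12)
  # enumeration sum: posteriors normalize to 1 even though the truncated
  # prior mass is below 1
  loc <- random_locus(5, seed = 3)
  post <- enumerate_posteriors(loc, a0 = qlogis(0.1), a = 0.5)
  expect_equal(sum(post$configs$posterior), 1, tolerance = 1e-12)
  prior_mass <- sum(exp(post$configs$log_prior))
  expect_lt(prior_mass, 1)
})

test_that("enumeration equals the independent brute-force posterior", {
  for (seed in 1:6) {
    m <- sample(3:12, 1)
    loc <- random_locus(m, seed = seed)
    a0 <- qlogis(0.05); a <- 0.7
    res <- enumerate_posteriors(loc, a0 = a0, a = a)
    bf <- brute_force_posterior(loc$z, loc$sigma, loc$annotations, a0, a)
    expect_equal(res$configs$posterior, bf$post, tolerance = 1e-10)
    expect_equal(res$pip$pip, bf$pip, tolerance = 1e-10)
  }
})

test_that("PIP identities and symmetries hold", {
  loc <- random_locus(8, seed = 9)
  res <- enumerate_posteriors(loc)
  # PIP_j equals the sum of posteriors of configurations containing j
  for (j in c(1, 4, 8)) {
    id <- loc$snps[j]
    in_cfg <- vapply(strsplit(res$configs$config, ","), function(s)
      id %in% s, logical(1))
    expect_equal(res$pip$pip[j], sum(res$configs$posterior[in_cfg]),
                 tolerance = 1e-12)
  }
  expect_true(all(res$pip$pip >= 0 & res$pip$pip <= 1))
  # two SNPs in perfect LD with identical z: equal PIPs by symmetry
  sig <- matrix(c(1, 1, 1, 1), 2) + diag(1e-9, 2)
  twin <- locus_data("c", c("a", "b"), c(4, 4), cov2cor(sig))
  rt <- enumerate_posteriors(twin)
  expect_equal(rt$pip$pip[1], rt$pip$pip[2], tolerance = 1e-9)
  # locus-size cap
  big <- random_locus(12, seed = 1)
  expect_error(enumerate_posteriors(big, max_snps = 10), "cap")
})

test_that("planted causal SNP attains the top PIP in strong-signal loci", {
  set.seed(20)
  hits <- 0L
  n_loci <- 60
  for (i in seq_len(n_loci)) {
    m <- 10
    r <- 0.5  # neighbours at r^2 = 0.25 <= 0.3
    sigma <- diag(m)
    sigma[1, -1] <- sigma[-1, 1] <- r
    sigma[-1, -1][upper.tri(diag(m - 1)) | lower.tri(diag(m - 1))] <- r^2
    causal <- 1L
    mu <- sigma[, causal] * 8
    z <- as.numeric(mvtnorm::rmvnorm(1, mean = mu, sigma = sigma))
    loc <- locus_data("c", sprintf("s%02d", 1:m), z, sigma)
    res <- enumerate_posteriors(loc)
    if (res$top_causal == "s01") hits <- hits + 1L
  }
  expect_gte(hits / n_loci, 0.8)
})

test_that("EM recovers annotation enrichment and stays monotone", {
  set.seed(30)
  make_loci <- function(odds) {
    lapply(1:30, function(i) {
      m <- 12
      a <- matrix(rnorm(m * m, 0, 0.4), m)
      sigma <- cov2cor(crossprod(a) + diag(m))
      causal <- sample.int(m, 1)
      q0 <- 0.1
      q1 <- plogis(qlogis(q0) + log(odds))
      ann <- matrix(rbinom(m, 1, ifelse(seq_len(m) == causal, q1, q0)), m, 1)
      rownames(ann) <- sprintf("s%02d", 1:m)
      mu <- sigma[, causal] * 6
      z <- as.numeric(mvtnorm::rmvnorm(1, mean = mu, sigma = sigma))
      locus_data(sprintf("locus%02d", i), sprintf("s%02d", 1:m), z, sigma, ann)
    })
  }
  fit10 <- em_fit_annotations(make_loci(10), max_iter = 40)
  expect_true(all(diff(fit10$loglik_trace) >= -1e-6))
  expect_gt(exp(fit10$a), 3)
  expect_lt(exp(fit10$a), 30)
  # no enrichment: fitted weight near zero
  fit1 <- em_fit_annotations(make_loci(1), max_iter = 40)
  expect_lt(abs(fit1$a), 1)
  # zero tracks: reduces to the intercept-only prior
  loci0 <- lapply(make_loci(1), function(l) {
    l$annotations <- l$annotations[, 0, drop = FALSE]
    l
  })
  fit0 <- em_fit_annotations(loci0, max_iter = 40)
  ref <- enumerate_posteriors(loci0[[1]], a0 = fit0$a0)
  expect_equal(fit0$posteriors[[1]]$pip$pip, ref$pip$pip, tolerance = 1e-12)
})
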
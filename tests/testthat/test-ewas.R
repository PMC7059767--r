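test_that("coverage filter enforces per-group subject minimums", {
  # 70 subjects: 35 low, 35 high
  grp <- tibble::tibble(subject = sprintf("s%02d", 1:70),
                        group = rep(0:1, each = 35))
  n <- matrix(0L, 3, 70, dimnames = list(NULL, grp$subject))
  # CpG 1: >= 3x in 30 low and 30 high -> retained
  n[1, c(1:30, 36:65)] <- 5L
  # CpG 2: 29 low + 35 high -> dropped
  n[2, c(1:29, 36:70)] <- 5L
  # CpG 3: covered but below depth
  n[3, ] <- 2L
  m <- matrix(0L, 3, 70, dimnames = dimnames(n))
  counts <- make_counts(m, n)
  filt <- filter_cpgs(counts, grp)
  expect_equal(filt$cpgs$cpg, "cpg_001")
  expect_equal(attr(filt, "n_total"), 3L)
  expect_equal(attr(filt, "n_retained"), 1L)
  # empty input passes through without error
  empty <- make_counts(m[0, , drop = FALSE], n[0, , drop = FALSE])
  expect_equal(nrow(filter_cpgs(empty, grp)$m), 0L)
  # undersized groups warn
  small <- tibble::tibble(subject = grp$subject,
                          group = c(rep(0L, 5), rep(1L, 65)))
  expect_warning(filter_cpgs(counts, small), "fewer than")
})

test_that("inverse normal transform matches closed-form quantiles", {
  # m = 2: ranks 1,2 -> qnorm(0.25), qnorm(0.75)
  out <- inverse_normal_transform(c(3, 10))
  expect_equal(out, qnorm(c(0.25, 0.75)), tolerance = 1e-12)
  expect_equal(out[2], 0.6744898, tolerance = 1e-6)
  # monotone in the input; NA preserved
  x <- c(5, NA, 1, 3, 9)
  out <- inverse_normal_transform(x)
  expect_true(is.na(out[2]))
  expect_equal(order(x[-2]), order(out[-2]))
  # all ties -> all equal
  expect_equal(var(inverse_normal_transform(rep(4, 6))), 0)
  expect_error(inverse_normal_transform(c(NA, NA, 1)), "non-missing")
})

test_that("methylation PCA recovers dominant structure", {
  set.seed(1)
  # rank-1 matrix + tiny noise: PC1 explains nearly everything
  u <- rnorm(40, 0, 3)
  v <- sample(c(-1, 1), 30, TRUE) * runif(30, 0.8, 1.5)
  b <- 1 / (1 + exp(-outer(v, u) - matrix(rnorm(1200, 0, 0.01), 30)))
  n <- matrix(500L, 30, 40, dimnames = list(NULL, sprintf("s%02d", 1:40)))
  m <- matrix(rbinom(1200, 500, as.vector(b)), 30, 40, dimnames = dimnames(n))
  counts <- make_counts(m, n)
  pcs <- methylation_pcs(counts, k = 3)
  expect_gt(pcs$variance_explained[1], 0.9)
  expect_true(all(diff(pcs$variance_explained) <= 1e-12))
  expect_lte(sum(pcs$variance_explained), 1 + 1e-8)
  # eigen-oracle: scores match a direct spectral decomposition
  bmat <- beta_values(counts)
  intb <- t(apply(bmat, 1, inverse_normal_transform))
  x <- scale(t(intb), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / 1)
  proj <- x %*% ev$vectors[, 1]
  expect_gt(abs(cor(proj, pcs$scores[, 1])), 0.999)
  expect_error(methylation_pcs(counts, k = 31), "complete CpGs")
})

test_that("injected cell-admixture factor is captured by PC1", {
  set.seed(42)
  n_subj <- 80; n_cpg <- 60
  admix <- rnorm(n_subj)             # latent cell-composition factor
  load <- rnorm(n_cpg, 0, 0.8)       # per-CpG loading
  lat <- outer(load, admix) + matrix(rnorm(n_cpg * n_subj, 0, 0.3), n_cpg)
  nr <- matrix(100L, n_cpg, n_subj, dimnames = list(NULL, sprintf("s%02d", 1:n_subj)))
  mr <- matrix(rbinom(n_cpg * n_subj, 100, 1 / (1 + exp(-as.vector(lat)))),
               n_cpg, n_subj, dimnames = dimnames(nr))
  counts <- make_counts(mr, nr)
  pcs <- methylation_pcs(counts, k = 1)
  expect_gt(abs(cor(pcs$scores[, 1], admix)), 0.8)
})

test_that("test_dmc equals the closed-form aggregated log odds ratio", {
  # group0: 20/100 x 50 subjects; group1: 40/100 x 50 subjects
  design <- tibble::tibble(group = rep(0:1, each = 50))
  m <- rep(c(20L, 40L), each = 50)
  n <- rep(100L, 100)
  res <- test_dmc(m, n, design)
  oracle <- log((0.4 / 0.6) / (0.2 / 0.8))
  expect_equal(res$beta1, oracle, tolerance = 1e-8)
  expect_equal(oracle, 0.9808293, tolerance = 1e-6)
  expect_true(res$converged)
  expect_equal(res$meth_diff, 20)   # percent
  # identical proportions in both groups: beta1 = 0, p = 1
  res0 <- test_dmc(rep(30L, 40), rep(100L, 40),
                   tibble::tibble(group = rep(0:1, 20)))
  expect_equal(res0$beta1, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-8)
})

test_that("test_dmc p-values are uniform under a pure binomial null", {
  set.seed(99)
  n_subj <- 80
  design <- tibble::tibble(group = rep(0:1, each = n_subj / 2))
  pvals <- replicate(400, {
    n <- rpois(n_subj, 40)
    keep <- n > 0
    m <- rbinom(n_subj, n, 0.4)
    test_dmc(m[keep], n[keep], design[keep, ])$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("test_dmc flags degenerate fits instead of returning junk", {
  # complete separation: group 0 fully unmethylated, group 1 fully methylated
  design <- tibble::tibble(group = rep(0:1, each = 10))
  m <- c(rep(0L, 10), rep(50L, 10))
  n <- rep(50L, 20)
  res <- test_dmc(m, n, design)
  expect_false(res$converged)
  expect_true(is.na(res$p))
})

test_that("DMC classification applies the Bonferroni and difference rules", {
  res <- tibble::tibble(
    cpg = c("a", "b", "c", "d"),
    p = c(3.9e-8, 1e-3, 1e-9, 1e-9),
    meth_diff = c(6, 20, 5, 11),       # percent
    n_tested = 1267919L
  )
  # p = 3.9e-8 with family 1,267,919 passes 0.05/n = 3.94e-8; diff 6% > 5%
  dmc05 <- classify_dmcs(res, diff_threshold = 0.05)
  expect_true("a" %in% dmc05$cpg)
  # p = 1e-3 never a DMC at that family size
  expect_false("b" %in% dmc05$cpg)
  # diff exactly 5% fails the strict > rule
  expect_false("c" %in% dmc05$cpg)
  # at the 0.10 threshold the rule is >=, and 11% passes; 6% does not
  dmc10 <- classify_dmcs(res, diff_threshold = 0.10)
  expect_false("a" %in% dmc10$cpg)
  expect_true("d" %in% dmc10$cpg)
  # boundary: diff exactly 10% passes >=
  res$meth_diff[3] <- 10
  expect_true("c" %in% classify_dmcs(res, diff_threshold = 0.10)$cpg)
})

test_that("power simulation: size equals level, large effects saturate, coverage helps", {
  null_pow <- power_simulation(30, 30, 30, 0.4, diff = 0, alpha = 0.05,
                               reps = 300, seed = 2)
  expect_lt(abs(null_pow$power - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  big <- power_simulation(54, 64, 30, 0.25, diff = 0.5, alpha = 0.05,
                          reps = 150, seed = 3)
  expect_gt(big$power, 0.99)
  # monotone (within MC noise) in coverage at fixed difference
  grid <- vapply(c(5, 15, 45), function(cv) {
    power_simulation(30, 30, cv, 0.4, diff = 0.08, alpha = 0.05,
                     reps = 250, seed = 4)$power
  }, numeric(1))
  expect_true(all(diff(grid) > -0.075))
  expect_gt(grid[3], grid[1])
})

test_that("over-dispersion ratio is ~1 for binomial data, inflated with subject noise", {
  set.seed(11)
  n <- rpois(200, 30); n[n == 0] <- 1
  group <- rep(0:1, each = 100)
  m_bin <- rbinom(200, n, 0.35)
  r_bin <- estimate_overdispersion(m_bin, n, group)
  expect_lt(abs(r_bin$ratio - 1), 0.35)
  # logit-noise SD 1 at coverage 30, n = 100 per group: ratio > 1.5
  lat <- rnorm(200, logit(0.35), 1)
  m_od <- rbinom(200, n, inv_logit(lat))
  r_od <- estimate_overdispersion(m_od, n, group)
  expect_gt(r_od$ratio, 1.5)
  # degenerate group (all zero counts) -> NA for that group
  m_deg <- m_bin; m_deg[group == 0] <- 0L
  r_deg <- estimate_overdispersion(m_deg, n, group)
  expect_true(is.na(r_deg$ratio_low))
})
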
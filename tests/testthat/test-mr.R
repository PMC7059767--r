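inst_row <- function(snp = "s1", b_zx = 0.5, se_zx = 0.05, b_zy = 0.1,
                     se_zy = 0.02, p = 1e-10, pos = 1L) {
  tibble::tibble(snp = snp, snp_pos = pos, b_zx = b_zx, se_zx = se_zx,
                 p_exposure = p, b_zy = b_zy, se_zy = se_zy,
                 palindromic = FALSE)
}

test_that("harmonization aligns alleles, flips swaps, drops ambiguous palindromes", {
  exposure <- tibble::tibble(
    snp = c("same", "swap", "strand", "pal_ok", "pal_amb", "missing", "bad"),
    b_zx = 1, se_zx = 0.1, p = 1e-8, snp_pos = 1:7,
    effect_allele = c("A", "A", "A", "A", "A", "A", "A"),
    other_allele  = c("G", "G", "G", "T", "T", "G", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.2, 0.50, 0.3, 0.3)
  )
  outcome <- tibble::tibble(
    snp = c("same", "swap", "strand", "pal_ok", "pal_amb", "bad"),
    effect_allele = c("A", "G", "T", "A", "A", "C"),
    other_allele  = c("G", "A", "C", "T", "T", "G"),
    beta = 0.5, se = 0.05, p = 1e-5, eaf = c(0.3, 0.7, 0.3, 0.25, 0.50, 0.3),
    n = 1000
  )
  h <- harmonize(exposure, outcome)
  expect_equal(h$b_zy[h$snp == "same"], 0.5)
  expect_equal(h$b_zy[h$snp == "swap"], -0.5)
  expect_equal(h$b_zy[h$snp == "strand"], 0.5)   # complement, same order
  expect_equal(h$b_zy[h$snp == "pal_ok"], 0.5)   # EAFs agree on direction
  expect_false("pal_amb" %in% h$snp)
  expect_false("missing" %in% h$snp)
  expect_false("bad" %in% h$snp)
  dropped <- attr(h, "dropped")
  expect_setequal(dropped$snp, c("pal_amb", "missing", "bad"))
})

test_that("greedy LD pruning keeps the best SNP per correlated set", {
  insts <- dplyr::bind_rows(
    inst_row("A", p = 1e-20, pos = 1L),
    inst_row("B", p = 1e-3, pos = 2L),
    inst_row("C", p = 1e-5, pos = 3L)
  )
  r <- diag(3); dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
  # all independent: all kept
  ld0 <- structure(list(r = r, snps = c("A", "B", "C"), source_n = 100),
                   class = "ld_matrix")
  expect_equal(nrow(prune_ld(insts, ld0)), 3)
  # A and B perfectly correlated: only the smaller-p SNP survives
  r1 <- r; r1["A", "B"] <- r1["B", "A"] <- 1
  ld1 <- structure(list(r = r1, snps = c("A", "B", "C"), source_n = 100),
                   class = "ld_matrix")
  kept <- prune_ld(insts, ld1)
  expect_true("A" %in% kept$snp)
  expect_false("B" %in% kept$snp)
  # chain A-B r2 0.5, B-C r2 0.5, A-C r2 0: p order A < C < B keeps {A, C}
  r2 <- r
  r2["A", "B"] <- r2["B", "A"] <- sqrt(0.5)
  r2["B", "C"] <- r2["C", "B"] <- sqrt(0.5)
  ld2 <- structure(list(r = r2, snps = c("A", "B", "C"), source_n = 100),
                   class = "ld_matrix")
  kept2 <- prune_ld(insts, ld2)
  expect_setequal(kept2$snp, c("A", "C"))
  # exhaustive-subset oracle: the greedy result is a maximal valid subset
  valid <- function(s) all(ld2$r[s, s][upper.tri(diag(length(s)))]^2 < 0.2)
  expect_true(valid(kept2$snp))
  for (extra in setdiff(c("A", "B", "C"), kept2$snp)) {
    expect_false(valid(c(kept2$snp, extra)))
  }
})

test_that("Wald ratio matches its closed forms", {
  r <- wald_ratio(inst_row(b_zx = 0.5, b_zy = 0.1, se_zy = 0.02))
  expect_equal(r$b_xy, 0.2)
  expect_equal(r$se, 0.04)
  expect_equal(r$method, "wald_ratio")
  # zero outcome effect: estimate 0, p = 1
  r0 <- wald_ratio(inst_row(b_zy = 0))
  expect_equal(r0$b_xy, 0)
  expect_equal(r0$p, 1)
  # second-order delta: sqrt(0.02^2/0.25 + 0.1^2 * 0.05^2 / 0.5^4)
  r2 <- wald_ratio(inst_row(b_zx = 0.5, se_zx = 0.05, b_zy = 0.1,
                            se_zy = 0.02), second_order = TRUE)
  expect_equal(r2$se, sqrt(0.02^2 / 0.25 + 0.1^2 * 0.05^2 / 0.5^4),
               tolerance = 1e-12)
  expect_error(wald_ratio(inst_row(b_zx = 0)), "zero")
})

test_that("IVW matches the closed-form weighted least squares oracle", {
  insts <- dplyr::bind_rows(
    inst_row("s1", b_zx = 1, b_zy = 0.2, se_zy = 0.1),
    inst_row("s2", b_zx = 1, b_zy = 0.4, se_zy = 0.1)
  )
  fe <- ivw(insts, "fixed")
  expect_equal(fe$b_xy, 0.3)
  expect_equal(fe$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # identical ratios with equal weights: estimate is that ratio
  same <- dplyr::bind_rows(
    inst_row("s1", b_zx = 0.5, b_zy = 0.15, se_zy = 0.1),
    inst_row("s2", b_zx = 1.0, b_zy = 0.30, se_zy = 0.1)
  )
  expect_equal(ivw(same, "fixed")$b_xy, 0.3, tolerance = 1e-12)
  # MRE inflates the SE when heterogeneity exceeds its expectation
  het <- dplyr::bind_rows(
    inst_row("s1", b_zx = 1, b_zy = 0.0, se_zy = 0.01),
    inst_row("s2", b_zx = 1, b_zy = 0.5, se_zy = 0.01),
    inst_row("s3", b_zx = 1, b_zy = 0.25, se_zy = 0.01)
  )
  expect_gt(ivw(het, "mre")$se, ivw(het, "fixed")$se)
  expect_error(ivw(insts[1, ], "fixed"), "wald_ratio")
  # estimator invariance: instrument order and joint sign flips
  perm <- ivw(insts[2:1, ], "fixed")
  expect_equal(perm$b_xy, fe$b_xy)
  flipped <- insts
  flipped$b_zx <- -flipped$b_zx; flipped$b_zy <- -flipped$b_zy
  expect_equal(ivw(flipped, "fixed")$b_xy, fe$b_xy, tolerance = 1e-12)
})

test_that("Egger regression separates directional pleiotropy from the slope", {
  set.seed(5)
  n_inst <- 10
  reps <- 150
  got_int <- got_slope <- numeric(reps)
  cover0 <- logical(reps)
  for (r in seq_len(reps)) {
    bx <- runif(n_inst, 0.3, 1.2)
    by <- 0.05 + 0.3 * bx + rnorm(n_inst, 0, 0.02)   # intercept 0.05
    insts <- tibble::tibble(snp = sprintf("s%d", 1:n_inst), snp_pos = 1:n_inst,
                            b_zx = bx, se_zx = 0.05, p_exposure = 1e-8,
                            b_zy = by, se_zy = 0.02, palindromic = FALSE)
    e <- egger(insts)
    got_int[r] <- e$egger_intercept
    got_slope[r] <- e$b_xy
    # no-pleiotropy data for the unbiasedness check
    by0 <- 0.3 * bx + rnorm(n_inst, 0, 0.02)
    insts0 <- insts; insts0$b_zy <- by0
    e0 <- egger(insts0)
    cover0[r] <- abs(e0$egger_intercept) < 2 * e0$egger_intercept_se
  }
  expect_equal(mean(got_int), 0.05, tolerance = 0.1)
  expect_equal(mean(got_slope), 0.3, tolerance = 0.05)
  expect_gt(mean(cover0), 0.90)
  # fewer than three instruments: NA result, mirroring reported-NA convention
  two <- dplyr::bind_rows(inst_row("s1"), inst_row("s2"))
  e2 <- egger(two)
  expect_true(is.na(e2$b_xy))
  expect_equal(e2$n_snp, 2L)
})

test_that("weighted median is robust to outlying and invalid instruments", {
  # all ratios equal: estimate is that ratio under any weights
  same <- dplyr::bind_rows(
    inst_row("s1", b_zx = 0.5, b_zy = 0.1, se_zy = 0.05),
    inst_row("s2", b_zx = 1.0, b_zy = 0.2, se_zy = 0.02),
    inst_row("s3", b_zx = 2.0, b_zy = 0.4, se_zy = 0.08)
  )
  expect_equal(weighted_median(same, seed = 1)$b_xy, 0.2, tolerance = 1e-9)
  # ratios (1, 2, 100) with equal weights: median 2
  out <- dplyr::bind_rows(
    inst_row("s1", b_zx = 1, b_zy = 1, se_zy = 1),
    inst_row("s2", b_zx = 1, b_zy = 2, se_zy = 1),
    inst_row("s3", b_zx = 1, b_zy = 100, se_zy = 1)
  )
  expect_equal(weighted_median(out, seed = 1)$b_xy, 2, tolerance = 1e-9)
  # breakdown: 6 valid at 0.3, 4 with large pleiotropy; median stays near
  # truth while IVW is dragged away
  set.seed(6)
  bx <- runif(10, 0.5, 1.5)
  by <- 0.3 * bx
  by[7:10] <- by[7:10] + 0.6
  insts <- tibble::tibble(snp = sprintf("s%d", 1:10), snp_pos = 1:10,
                          b_zx = bx, se_zx = 0.03, p_exposure = 1e-8,
                          b_zy = by + rnorm(10, 0, 0.01), se_zy = 0.01,
                          palindromic = FALSE)
  wm <- weighted_median(insts, seed = 2)
  fe <- ivw(insts, "fixed")
  expect_lt(abs(wm$b_xy - 0.3), 0.1)
  expect_gt(abs(fe$b_xy - 0.3), 0.1)
})

test_that("maximum likelihood agrees with its limits and stays calibrated", {
  # noiseless proportional inputs: exact recovery
  exact <- tibble::tibble(snp = c("a", "b", "c"), snp_pos = 1:3,
                          b_zx = c(0.4, 0.8, 1.2), se_zx = 1e-6,
                          p_exposure = 1e-10,
                          b_zy = 0.3 * c(0.4, 0.8, 1.2), se_zy = 1e-6,
                          palindromic = FALSE)
  expect_equal(max_likelihood(exact)$b_xy, 0.3, tolerance = 1e-6)
  # se_zx -> 0 limit: matches IVW fixed within 1%
  set.seed(8)
  insts <- tibble::tibble(snp = sprintf("s%d", 1:6), snp_pos = 1:6,
                          b_zx = runif(6, 0.4, 1.2), se_zx = 1e-8,
                          p_exposure = 1e-8,
                          b_zy = 0.25 * runif(6, 0.4, 1.2) + rnorm(6, 0, 0.02),
                          se_zy = 0.02, palindromic = FALSE)
  ml <- max_likelihood(insts)
  fe <- ivw(insts, "fixed")
  expect_lt(abs(ml$b_xy - fe$b_xy) / abs(fe$b_xy), 0.01)
  # null calibration at moderate replicate count
  set.seed(9)
  rej <- replicate(400, {
    bx <- rnorm(5, 0.8, 0.05)
    null_i <- tibble::tibble(snp = sprintf("s%d", 1:5), snp_pos = 1:5,
                             b_zx = bx, se_zx = 0.05, p_exposure = 1e-8,
                             b_zy = rnorm(5, 0, 0.02), se_zy = 0.02,
                             palindromic = FALSE)
    isTRUE(max_likelihood(null_i)$p < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("BH mediator selection follows the step-up procedure", {
  res <- tibble::tibble(cpg = c("a", "b", "c", "d"),
                        p = c(0.001, 0.01, 0.02, 0.9))
  sel <- select_mediators(res, fdr_q = 0.05)
  expect_equal(sel$q, p.adjust(res$p, "BH"))
  expect_equal(sel$cpg[sel$mediator], c("a", "b", "c"))
  expect_true(all(sel$q >= sel$p))
  # all p = 1: nothing selected
  none <- select_mediators(tibble::tibble(cpg = "x", p = 1))
  expect_false(any(none$mediator))
  # single test: q equals p
  one <- select_mediators(tibble::tibble(cpg = "x", p = 0.03))
  expect_equal(one$q, 0.03)
})

test_that("mr_analyze routes one instrument to Wald and several to IVW", {
  one <- inst_row("only")
  r1 <- mr_analyze(one, cpg = "c1")
  expect_equal(r1$method[r1$primary], "wald_ratio")
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    inst_row(sprintf("s%d", i), b_zx = 0.5 + 0.1 * i,
             b_zy = 0.3 * (0.5 + 0.1 * i), pos = i)
  }))
  r5 <- mr_analyze(five, cpg = "c2", seed = 3)
  expect_equal(r5$method[r5$primary], "ivw_fe")
  expect_setequal(r5$method,
                  c("ivw_fe", "ivw_mre", "max_likelihood", "egger",
                    "weighted_median"))
  expect_true(all(r5$n_snp == 5))
})

test_that("reverse 2SLS recovers the phenotype-to-methylation effect", {
  set.seed(10)
  n <- 2000
  g <- matrix(rbinom(3 * n, 2, 0.3), n, 3,
              dimnames = list(sprintf("i%04d", 1:n), c("g1", "g2", "g3")))
  trait <- 0.5 * g[, 1] + 0.4 * g[, 2] + 0.45 * g[, 3] + rnorm(n)
  meth_lat <- 0.5 * trait + rnorm(n, 0, 0.5)
  res <- reverse_mr_2sls(g, trait, meth_lat, mode = "linear")
  expect_lt(abs(res$estimate - 0.5), 0.1)
  expect_lt(res$p, 1e-6)
  expect_false(res$weak_instruments)
  # logistic mode on counts recovers the logit-scale effect direction
  nr <- rpois(n, 50) + 1L
  mr <- rbinom(n, nr, inv_logit(-0.2 + 0.5 * trait))
  res_log <- suppressWarnings(
    reverse_mr_2sls(g, trait, list(m = mr, n = nr), mode = "logistic"))
  expect_lt(abs(res_log$estimate - 0.5), 0.1)
  # forward-only causation does not leak into the reverse test
  set.seed(11)
  rej <- replicate(200, {
    gm <- matrix(rbinom(2 * 300, 2, 0.3), 300, 2)
    m_lat <- rnorm(300)                 # methylation independent of the IVs
    tr <- 0.4 * gm[, 1] + 0.4 * gm[, 2] + 0.3 * m_lat + rnorm(300)
    suppressWarnings(reverse_mr_2sls(gm, tr, m_lat, mode = "linear")$p < 0.05)
  })
  expect_lt(mean(rej), 0.12)
  # weak instruments raise a warning flag
  gw <- matrix(rbinom(200, 2, 0.3), 200, 1)
  expect_warning(res_w <- reverse_mr_2sls(gw, rnorm(200), rnorm(200)),
                 "weak")
  expect_true(res_w$weak_instruments)
})
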
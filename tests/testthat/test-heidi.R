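make_ld <- function(r, snps) {
  dimnames(r) <- list(snps, snps)
  structure(list(r = r, snps = snps, source_n = 1000), class = "ld_matrix")
}

# compound-symmetric LD: top SNP correlates r_top with everyone; the others
# correlate r_others among themselves
cs_ld <- function(m, r_top, r_others, snps = sprintf("s%02d", seq_len(m))) {
  r <- matrix(r_others, m, m)
  r[1, ] <- r[, 1] <- r_top
  diag(r) <- 1
  make_ld(r, snps)
}

heidi_stats <- function(snps, b_zx, se_zx, b_zy, se_zy, p = NULL) {
  tibble::tibble(snp = snps, b_zx = b_zx, se_zx = se_zx,
                 b_zy = b_zy, se_zy = se_zy,
                 p = p %||% 2 * pnorm(-abs(b_zx / se_zx)))
}

test_that("HEIDI SNP selection applies the LD window, p filter and cap", {
  m <- 31
  snps <- sprintf("s%02d", 1:m)
  r <- diag(m)
  r[1, 2:m] <- r[2:m, 1] <- sqrt(0.5)
  r[1, 2] <- r[2, 1] <- sqrt(0.95)   # too correlated with the top
  r[1, 3] <- r[3, 1] <- sqrt(0.01)   # too weakly correlated
  ld <- make_ld(r, snps)
  stats <- tibble::tibble(snp = snps, p = rep(1e-5, m))
  stats$p[4] <- 0.01                 # weak mQTL, filtered
  sel <- select_heidi_snps(stats, "s01", ld)
  expect_false("s02" %in% sel)
  expect_false("s03" %in% sel)
  expect_false("s04" %in% sel)
  # 27 remain eligible; the cap keeps 20
  expect_equal(length(sel), 20)
  excl <- attr(sel, "excluded")
  expect_equal(unname(excl["over_cap"]), 7)
  expect_equal(unname(excl["weak_instrument"]), 1)
})

test_that("HEIDI statistic vanishes under exact proportionality", {
  snps <- c("top", "a", "b")
  st <- heidi_stats(snps, b_zx = c(1, 0.7, 0.5), se_zx = 1e-4,
                    b_zy = 0.3 * c(1, 0.7, 0.5), se_zy = 1e-4)
  ld <- cs_ld(3, 0.7, 0.5, snps)
  for (statistic in c("crossprod", "ratio")) {
    ht <- heidi_test(st, "top", ld, statistic = statistic)
    expect_lt(ht$t_stat, 1e-6)
    expect_gt(ht$p_heidi, 0.99)
  }
})

test_that("single independent contrast reduces to a one-degree chi-square", {
  snps <- c("top", "a")
  st <- heidi_stats(snps, b_zx = c(1, 0.6), se_zx = c(0.02, 0.03),
                    b_zy = c(0.31, 0.16), se_zy = c(0.01, 0.01))
  ld <- make_ld(diag(2), snps)
  ht <- heidi_test(st, "top", ld)
  expect_equal(ht$n_snp_heidi, 1L)
  expect_equal(ht$p_heidi, pchisq(ht$t_stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # no selected SNPs: NA result
  ht0 <- heidi_test(st[1, ], "top", ld)
  expect_true(is.na(ht0$p_heidi))
  expect_equal(ht0$n_snp_heidi, 0L)
})

test_that("HEIDI is invariant to relabeling and joint sign flips", {
  set.seed(4)
  m <- 6
  snps <- sprintf("s%02d", 1:m)
  ld <- cs_ld(m, 0.6, 0.4, snps)
  st <- heidi_stats(snps, b_zx = c(1, runif(m - 1, 0.4, 0.8)),
                    se_zx = 0.05,
                    b_zy = 0.3 * c(1, runif(m - 1, 0.4, 0.8)), se_zy = 0.01)
  ht <- heidi_test(st, "s01", ld)
  # permute the non-top rows
  perm <- c(1, sample(2:m))
  ht_p <- heidi_test(st[perm, ], "s01", ld)
  expect_equal(ht_p$t_stat, ht$t_stat, tolerance = 1e-10)
  # joint sign flip of one SNP's exposure and outcome effects
  st_f <- st
  st_f$b_zx[3] <- -st_f$b_zx[3]; st_f$b_zy[3] <- -st_f$b_zy[3]
  ld_f <- ld
  ld_f$r[3, -3] <- -ld_f$r[3, -3]; ld_f$r[-3, 3] <- -ld_f$r[-3, 3]
  ht_f <- heidi_test(st_f, "s01", ld_f)
  expect_equal(ht_f$t_stat, ht$t_stat, tolerance = 1e-10)
})

# Summary-statistics generator under a single shared causal variant: the top
# SNP is causal for the exposure with z ~ z0; every SNP's expected effects
# are the LD projection; a common causal ratio links outcome to exposure.
draw_shared_causal <- function(m, r_top, r_others, z0 = 8, bxy = 0.3,
                               se_zx = 0.05, se_zy = 0.01) {
  snps <- sprintf("s%02d", seq_len(m))
  ld <- cs_ld(m, r_top, r_others, snps)
  mu_zx <- ld$r[, 1] * z0 * se_zx
  noise_x <- as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * se_zx^2))
  noise_y <- as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * se_zy^2))
  st <- heidi_stats(snps, b_zx = mu_zx + noise_x, se_zx = se_zx,
                    b_zy = bxy * mu_zx + noise_y, se_zy = se_zy)
  list(st = st, ld = ld)
}

test_that("HEIDI rejection rate is near nominal under a shared causal variant", {
  set.seed(12)
  rej <- replicate(400, {
    d <- draw_shared_causal(8, 0.65, 0.45)
    ht <- heidi_test(d$st, "s01", d$ld)
    isTRUE(ht$p_heidi < 0.05)
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})

test_that("Satterthwaite p agrees with the Monte-Carlo oracle", {
  set.seed(21)
  for (i in 1:8) {
    m <- sample(3:10, 1)
    r_top <- runif(1, 0.5, 0.8)
    d <- draw_shared_causal(m, r_top, r_top^2 + 0.1, z0 = runif(1, 6, 10))
    ht <- heidi_test(d$st, "s01", d$ld)
    if (is.na(ht$p_heidi) || ht$p_heidi < 0.01 || ht$p_heidi > 0.99) next
    p_mc <- heidi_p_mc(ht$t_stat, attr(ht, "d_corr"), n_mc = 20000,
                       seed = 100 + i)
    expect_lt(abs(ht$p_heidi - p_mc), 0.02)
  }
})

test_that("linkage of distinct causal variants is detected and classified", {
  set.seed(31)
  # exposure causal at s01, outcome causal at s02 (r^2 = 0.5 apart)
  m <- 8
  r <- sqrt(0.5)
  rej <- replicate(200, {
    snps <- sprintf("s%02d", 1:m)
    ld <- cs_ld(m, r, 0.5, snps)
    mu_zx <- ld$r[, 1] * 8 * 0.05
    mu_zy <- ld$r[, 2] * 0.12          # trait driven by s02, not s01
    st <- heidi_stats(snps,
                      b_zx = mu_zx + as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * 0.05^2)),
                      se_zx = 0.05,
                      b_zy = mu_zy + as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * 0.01^2)),
                      se_zy = 0.01)
    isTRUE(heidi_test(st, "s01", ld)$p_heidi < 0.05)
  })
  expect_gte(mean(rej), 0.6)
  # verdict assignment: Bonferroni over 30 tested loci gives 0.001, and a
  # p of 0.0005 is classified linkage
  res <- tibble::tibble(cpg = sprintf("c%02d", 1:30),
                        p_heidi = c(5e-4, runif(29, 0.2, 1)))
  cls <- classify_pleiotropy_vs_linkage(res)
  expect_equal(cls$heidi_alpha[1], 0.05 / 30)
  expect_equal(cls$verdict[1], "linkage")
  expect_true(all(cls$verdict[-1] == "single_shared_variant"))
  # NA p stays unclassified
  res$p_heidi[2] <- NA
  cls2 <- classify_pleiotropy_vs_linkage(res)
  expect_true(is.na(cls2$verdict[2]))
})

test_that("selection-calibrated HEIDI keeps size and detects linkage (summary mode)", {
  set.seed(41)
  one <- function(linked) {
    m <- 10
    snps <- sprintf("s%02d", 1:m)
    ld <- cs_ld(m, sqrt(0.5), 0.5, snps)
    mu_zx <- ld$r[, 1] * 5 * 0.1       # moderate exposure strength
    mu_zy <- if (linked) ld$r[, 2] * 0.12 else 0.3 * mu_zx
    st <- heidi_stats(
      snps,
      b_zx = mu_zx + as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * 0.1^2)),
      se_zx = 0.1,
      b_zy = mu_zy + as.numeric(mvtnorm::rmvnorm(1, sigma = ld$r * 0.01^2)),
      se_zy = 0.01
    )
    heidi_selection_calibrated(st, ld, n_boot = 150,
                               seed = sample.int(1e6, 1))$p_heidi
  }
  p_null <- replicate(30, one(FALSE))
  p_link <- replicate(30, one(TRUE))
  expect_lte(mean(p_null < 0.05, na.rm = TRUE), 0.15)
  expect_gt(mean(p_link < 0.05, na.rm = TRUE),
            mean(p_null < 0.05, na.rm = TRUE))
})
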
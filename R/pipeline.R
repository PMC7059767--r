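# Default annotation tracks for the synthetic pipeline: one BED-style
# interval per chromosome covering its SNP region (the focal CpG lies inside
# the chr1 region; null CpGs are placed beyond it).
default_cpg_tracks <- function(g) {
  out <- list()
  for (ch in unique(g$snps$chrom)) {
    pos <- g$snps$pos[g$snps$chrom == ch]
    out[[paste0("snp_region_", ch)]] <-
      tibble::tibble(chrom = ch, start = min(pos) - 1L, end = max(pos) + 500L)
  }
  out
}

#' Run the full mediation-analysis pipeline
#'
#' Executes, in order: coverage filtering and the count-based EWAS; DMC
#' classification; SNP QC and the cis/trans mQTL scan with per-class
#' Bonferroni correction; two-sample MR per DMC (instrument harmonization,
#' LD pruning at r^2 < 0.2, Wald ratio / IVW primary routing plus Egger and
#' the other sensitivity estimators, BH-FDR mediator selection); the
#' reverse-direction 2SLS using trait-associated SNPs outside the CpG's cis
#' region; the HEIDI test at each DMC locus; annotation-aware fine-mapping of
#' mediator-DMC loci; permutation annotation enrichment; and the final
#' per-DMC report with a causal-model verdict.
#'
#' @param x A [sim_config()] (the cohort is generated) or an `mm_cohort`.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV (deterministic bytes for a fixed config and seed).
#' @param dmc_alpha,dmc_diff DMC family-wise alpha and methylation-difference
#'   threshold (fraction).
#' @param min_coverage,min_subjects_per_group Coverage filter settings.
#' @param mqtl_alpha Per-class Bonferroni alpha for the mQTL scan.
#' @param fdr_q Mediator FDR threshold.
#' @param heidi_alpha HEIDI significance level; default 0.05 / number of
#'   tested loci.
#' @param reverse_alpha Reverse-2SLS significance level (BH across DMCs).
#' @param gwas_sig Genome-wide significance for selecting reverse-direction
#'   instruments from the outcome GWAS.
#' @param mqtl_values_mode Methylation scale for the mQTL scan
#'   (`"int"`, `"raw"`, `"logit"`).
#' @param use_geno_pc1 Include the first (LD-pruned) genotype principal
#'   component as a covariate in the mQTL scan. Off by default: the
#'   adjustment targets genome-wide ancestry structure, and in a small
#'   unstructured synthetic panel the leading "component" is just a contrast
#'   of the strongest LD blocks — conditioning on it distorts the very
#'   signals being mapped. Turn on for genotype panels large enough for the
#'   PC to capture ancestry.
#' @param finemap_locus_size Cis SNPs retained per fine-mapping locus (top by
#'   mQTL p).
#' @param n_perm Permutations for the enrichment stage.
#' @param tracks Optional named list of BED-style tracks for enrichment.
#' @return An `mm_report` list with all stage tables, the final `report`
#'   tibble and the `thresholds` actually applied.
#' @export
run_pipeline <- function(x, out_dir = NULL,
                         dmc_alpha = 0.05, dmc_diff = 0.05,
                         min_coverage = 3, min_subjects_per_group = 30,
                         mqtl_alpha = 0.05, fdr_q = 0.05,
                         heidi_alpha = NULL, reverse_alpha = 0.05,
                         gwas_sig = 5e-8,
                         mqtl_values_mode = "int",
                         use_geno_pc1 = FALSE,
                         finemap_locus_size = 50,
                         n_perm = 1000, tracks = NULL) {
  cohort <- if (inherits(x, "sim_config")) simulate_cohort(x) else x
  stopifnot(inherits(cohort, "mm_cohort"))
  config <- cohort$config
  seed <- config$seed

  ## -- EWAS ----------------------------------------------------------------
  filtered <- filter_cpgs(cohort$methylation, cohort$phenotypes,
                          min_coverage = min_coverage,
                          min_subjects_per_group = min_subjects_per_group)
  ewas <- ewas_scan(filtered, cohort$phenotypes)
  dmcs <- classify_dmcs(ewas, alpha = dmc_alpha, diff_threshold = dmc_diff)

  ## -- mQTL ----------------------------------------------------------------
  g_qc <- snp_qc(cohort$genotypes)
  covars <- if (use_geno_pc1) {
    geno_pc <- genotype_pcs(g_qc, k = 1)
    tibble::tibble(subject = rownames(g_qc$dosages),
                   geno_pc1 = geno_pc$scores[, 1])
  } else NULL
  dmc_counts <- subset_meth(filtered, dmcs$cpg)
  mqtl <- if (nrow(dmcs) > 0) {
    scan_mqtl(g_qc, dmc_counts, covariates = covars,
              values_mode = mqtl_values_mode)
  } else tibble::tibble()
  counts_by_class <- mqtl_test_counts(g_qc, dmc_counts$cpgs)
  mqtl_sig <- if (nrow(mqtl) > 0 &&
                  (counts_by_class$n_cis > 0 || counts_by_class$n_trans > 0)) {
    bonferroni_by_class(mqtl, counts_by_class$n_cis, counts_by_class$n_trans,
                        alpha = mqtl_alpha)
  } else tibble::tibble()

  ## -- forward MR ----------------------------------------------------------
  snp_meta <- g_qc$snps
  mr_all <- list(); instr_used <- list()
  for (cp in dmcs$cpg) {
    sig_cis <- mqtl_sig[mqtl_sig$cpg == cp & mqtl_sig$class == "cis", ,
                        drop = FALSE]
    if (nrow(sig_cis) == 0) next
    exp_rec <- dplyr::left_join(
      sig_cis,
      snp_meta[, c("snp", "effect_allele", "other_allele", "maf")],
      by = "snp"
    )
    exp_rec$eaf <- exp_rec$maf
    harm <- harmonize(exp_rec, cohort$sumstats)
    if (nrow(harm) == 0) next
    ld <- ld_matrix(g_qc, snps = harm$snp)
    kept <- prune_ld(harm, ld, r2_max = 0.2)
    res <- mr_analyze(kept, cpg = cp,
                      seed = derive_seed(seed, 40L + match(cp, dmcs$cpg)))
    mr_all[[cp]] <- res
    instr_used[[cp]] <- kept
  }
  mr_tbl <- dplyr::bind_rows(mr_all)
  primary <- if (nrow(mr_tbl) > 0) {
    select_mediators(mr_tbl[mr_tbl$primary, , drop = FALSE], fdr_q = fdr_q)
  } else tibble::tibble()

  ## -- reverse MR ----------------------------------------------------------
  trait_snps <- cohort$sumstats$snp[cohort$sumstats$p < gwas_sig]
  trait_snps <- intersect(trait_snps, snp_meta$snp)
  rev_tbl <- list()
  int_vals <- if (nrow(dmcs) > 0) meth_values(dmc_counts, "int")
  scan_vals <- if (nrow(dmcs) > 0) meth_values(dmc_counts, mqtl_values_mode)
  for (cp in dmcs$cpg) {
    k <- match(cp, dmc_counts$cpgs$cpg)
    cis_excl <- snp_meta$snp[
      snp_meta$chrom == dmc_counts$cpgs$chrom[k] &
        abs(snp_meta$pos - dmc_counts$cpgs$pos[k]) < 1e6
    ]
    ivs <- setdiff(trait_snps, cis_excl)
    if (length(ivs) == 0) {
      rev_tbl[[cp]] <- tibble::tibble(cpg = cp, estimate = NA_real_,
                                      se = NA_real_, p = NA_real_,
                                      f_stat = NA_real_,
                                      weak_instruments = NA, n_iv = 0L,
                                      n_obs = NA_integer_)
      next
    }
    giv <- g_qc$dosages[, ivs, drop = FALSE]
    trait <- cohort$phenotypes$y[match(rownames(giv),
                                       cohort$phenotypes$subject)]
    r <- suppressWarnings(
      reverse_mr_2sls(giv, trait, int_vals[k, ], mode = "linear")
    )
    # standard weak-instrument rule: below F = 10 the 2SLS estimate is
    # biased toward the observational association, so the test is not
    # evaluable rather than evidence either way
    if (isTRUE(r$weak_instruments)) r$p <- NA_real_
    rev_tbl[[cp]] <- dplyr::bind_cols(tibble::tibble(cpg = cp), r)
  }
  reverse <- dplyr::bind_rows(rev_tbl)
  if (nrow(reverse) > 0) {
    reverse$q_rev <- stats::p.adjust(reverse$p, method = "BH")
  }

  ## -- HEIDI ---------------------------------------------------------------
  heidi_tbl <- list()
  for (cp in names(instr_used)) {
    locus <- mqtl[mqtl$cpg == cp & mqtl$class == "cis", , drop = FALSE]
    top <- locus$snp[which.min(locus$p)]
    loc_rec <- dplyr::left_join(
      locus, snp_meta[, c("snp", "effect_allele", "other_allele", "maf")],
      by = "snp"
    )
    loc_rec$eaf <- loc_rec$maf
    harm <- harmonize(loc_rec, cohort$sumstats)
    harm$p <- loc_rec$p[match(harm$snp, loc_rec$snp)]
    if (!top %in% harm$snp) {
      heidi_tbl[[cp]] <- tibble::tibble(cpg = cp, top_snp = top,
                                        t_stat = NA_real_,
                                        p_heidi = NA_real_, n_snp_heidi = 0L)
      next
    }
    ld <- ld_matrix(g_qc, snps = harm$snp)
    sel <- select_heidi_snps(harm, top, ld)
    st <- harm[harm$snp %in% c(top, sel), , drop = FALSE]
    k <- match(cp, dmc_counts$cpgs$cpg)
    vzx <- mqtl_slope_cov(g_qc, scan_vals[k, ], st$snp,
                          covariates = covars)$v
    ht <- heidi_test(st, top, ld, v_zx = vzx)
    heidi_tbl[[cp]] <- dplyr::bind_cols(tibble::tibble(cpg = cp), ht)
  }
  heidi <- dplyr::bind_rows(heidi_tbl)
  n_heidi_tested <- if (nrow(heidi) > 0) sum(!is.na(heidi$p_heidi)) else 0L
  if (is.null(heidi_alpha)) {
    heidi_alpha <- if (n_heidi_tested > 0) 0.05 / n_heidi_tested else 0.05
  }
  if (nrow(heidi) > 0) {
    heidi <- classify_pleiotropy_vs_linkage(heidi, alpha = heidi_alpha)
  }

  ## -- fine-mapping --------------------------------------------------------
  mediator_cpgs <- if (nrow(primary) > 0) primary$cpg[primary$mediator] else
    character(0)
  finemap <- list()
  if (length(mediator_cpgs) > 0) {
    loci <- list()
    for (cp in mediator_cpgs) {
      locus <- mqtl[mqtl$cpg == cp & mqtl$class == "cis", , drop = FALSE]
      locus <- locus[order(locus$p), , drop = FALSE]
      locus <- locus[seq_len(min(nrow(locus), finemap_locus_size)), ,
                     drop = FALSE]
      if (nrow(locus) == 0) next
      ld <- ld_matrix(g_qc, snps = locus$snp)
      ann <- cohort$annotations[locus$snp, , drop = FALSE]
      loci[[cp]] <- locus_data(cp, locus$snp, locus$b_zx / locus$se_zx,
                               ld, ann)
    }
    if (length(loci) > 0) {
      fit <- em_fit_annotations(loci)
      finemap <- fit$posteriors
      attr(finemap, "weights") <- list(a0 = fit$a0, a = fit$a)
    }
  }
  finemap_pip <- dplyr::bind_rows(lapply(finemap, function(p) {
    dplyr::bind_cols(tibble::tibble(cpg = p$cpg), p$pip)
  }))

  ## -- enrichment ----------------------------------------------------------
  if (is.null(tracks)) tracks <- default_cpg_tracks(g_qc)
  background <- filtered$cpgs[, c("cpg", "chrom", "pos")]
  enrichment <- if (nrow(dmcs) > 0 && length(tracks) > 0) {
    annotation_enrichment(dmcs$cpg, background, tracks, n_perm = n_perm,
                          seed = derive_seed(seed, 60L))
  } else tibble::tibble()

  ## -- report --------------------------------------------------------------
  report <- build_report(dmcs, primary, mr_tbl, heidi, reverse, finemap,
                         snp_meta, fdr_q, heidi_alpha, reverse_alpha)
  thresholds <- tibble::tibble(
    name = c("dmc_alpha", "dmc_n_tested", "dmc_p_threshold", "dmc_diff",
             "n_cis_tests", "n_trans_tests", "cis_p_threshold",
             "trans_p_threshold", "prune_r2_max", "fdr_q",
             "heidi_r2_low", "heidi_r2_high", "heidi_p_max",
             "heidi_alpha", "reverse_alpha", "gwas_sig"),
    value = c(dmc_alpha, ewas$n_tested[1] %||% NA_real_,
              dmc_alpha / max(ewas$n_tested[1], 1), dmc_diff,
              counts_by_class$n_cis, counts_by_class$n_trans,
              ifelse(counts_by_class$n_cis > 0,
                     mqtl_alpha / counts_by_class$n_cis, NA),
              ifelse(counts_by_class$n_trans > 0,
                     mqtl_alpha / counts_by_class$n_trans, NA),
              0.2, fdr_q, 0.05, 0.9, 1.6e-3, heidi_alpha, reverse_alpha,
              gwas_sig)
  )
  out <- structure(
    list(config = config, cohort = cohort, ewas = ewas, dmcs = dmcs,
         mqtl = mqtl, mqtl_sig = mqtl_sig, mr = mr_tbl, primary = primary,
         reverse = reverse, heidi = heidi, finemap = finemap,
         finemap_pip = finemap_pip, enrichment = enrichment,
         report = report, thresholds = thresholds),
    class = "mm_report"
  )
  if (!is.null(out_dir)) write_report_files(out, out_dir)
  out
}

# Subset a meth_counts to given CpG ids (in that order).
subset_meth <- function(counts, cpg_ids) {
  keep <- match(cpg_ids, counts$cpgs$cpg)
  structure(
    list(cpgs = counts$cpgs[keep, , drop = FALSE],
         m = counts$m[keep, , drop = FALSE],
         n = counts$n[keep, , drop = FALSE],
         latent = if (!is.null(counts$latent))
           counts$latent[keep, , drop = FALSE]),
    class = "meth_counts"
  )
}

# Assemble the per-DMC report and assign the causal-model verdict:
# mediation-consistent needs a forward-MR FDR hit, no HEIDI rejection, and a
# non-significant reverse test; a HEIDI rejection reclassifies the locus as
# linkage; a significant reverse test as reverse-causal.
build_report <- function(dmcs, primary, mr_tbl, heidi, reverse, finemap,
                         snp_meta, fdr_q, heidi_alpha, reverse_alpha) {
  if (nrow(dmcs) == 0) return(tibble::tibble())
  eg <- if (nrow(mr_tbl) > 0) mr_tbl[mr_tbl$method == "egger", , drop = FALSE]
        else tibble::tibble()
  rows <- lapply(dmcs$cpg, function(cp) {
    pr <- if (nrow(primary) > 0) primary[primary$cpg == cp, , drop = FALSE]
          else tibble::tibble()
    er <- if (nrow(eg) > 0) eg[eg$cpg == cp, , drop = FALSE] else tibble::tibble()
    hr <- if (nrow(heidi) > 0) heidi[heidi$cpg == cp, , drop = FALSE]
          else tibble::tibble()
    rr <- if (nrow(reverse) > 0) reverse[reverse$cpg == cp, , drop = FALSE]
          else tibble::tibble()
    fm <- finemap[[cp]]
    top_snp <- if (nrow(pr) == 1) pr$top_snp else NA_character_
    q_mr <- if (nrow(pr) == 1) pr$q else NA_real_
    p_heidi <- if (nrow(hr) == 1) hr$p_heidi else NA_real_
    q_rev <- if (nrow(rr) == 1) rr$q_rev else NA_real_
    rev_sig <- !is.na(q_rev) && q_rev < reverse_alpha
    verdict <- if (!is.na(q_mr) && q_mr < fdr_q) {
      if (!is.na(p_heidi) && p_heidi < heidi_alpha) "linkage"
      else if (rev_sig) "reverse-causal"
      else "mediation-consistent"
    } else if (rev_sig) "reverse-causal" else "inconclusive"
    tibble::tibble(
      cpg = cp,
      method = if (nrow(pr) == 1) pr$method else NA_character_,
      n_snp = if (nrow(pr) == 1) pr$n_snp else NA_integer_,
      b_mr = if (nrow(pr) == 1) pr$b_xy else NA_real_,
      se_mr = if (nrow(pr) == 1) pr$se else NA_real_,
      p_mr = if (nrow(pr) == 1) pr$p else NA_real_,
      q_mr = q_mr,
      b_egger = if (nrow(er) == 1) er$b_xy else NA_real_,
      se_egger = if (nrow(er) == 1) er$se else NA_real_,
      p_egger = if (nrow(er) == 1) er$p else NA_real_,
      egger_intercept = if (nrow(er) == 1) er$egger_intercept else NA_real_,
      top_snp = top_snp,
      top_snp_pos = if (!is.na(top_snp))
        snp_meta$pos[match(top_snp, snp_meta$snp)] else NA_integer_,
      p_heidi = p_heidi,
      n_snp_heidi = if (nrow(hr) == 1) hr$n_snp_heidi else NA_integer_,
      top_causal_mqtl = if (!is.null(fm)) fm$top_causal else NA_character_,
      pip = if (!is.null(fm)) max(fm$pip$pip) else NA_real_,
      meth_diff = dmcs$meth_diff[dmcs$cpg == cp],
      p_dmc = dmcs$p[dmcs$cpg == cp],
      p_reverse = if (nrow(rr) == 1) rr$p else NA_real_,
      q_reverse = q_rev,
      verdict = verdict
    )
  })
  dplyr::bind_rows(rows)
}

# Write every stage table as TSV (deterministic bytes).
write_report_files <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) {
      df <- tibble::tibble()
    }
    readr::write_tsv(tibble::as_tibble(df), file.path(out_dir, name))
  }
  wr(res$ewas, "ewas.tsv")
  wr(res$dmcs, "dmc.tsv")
  wr(res$mqtl, "mqtl.tsv")
  wr(res$mqtl_sig, "mqtl_sig.tsv")
  wr(res$mr, "mr.tsv")
  wr(res$primary, "mr_primary.tsv")
  wr(res$reverse, "reverse_mr.tsv")
  wr(res$heidi, "heidi.tsv")
  wr(res$finemap_pip, "finemap_pip.tsv")
  wr(res$enrichment, "enrichment.tsv")
  wr(res$report, "report.tsv")
  wr(res$thresholds, "thresholds.tsv")
  invisible(out_dir)
}

#' @export
print.mm_report <- function(x, ...) {
  cat(sprintf("<mm_report> scenario=%s seed=%d\n", x$config$scenario,
              x$config$seed))
  cat(sprintf("  CpGs tested: %s | DMCs: %d | significant mQTLs: %d\n",
              x$ewas$n_tested[1] %||% 0, nrow(x$dmcs), nrow(x$mqtl_sig)))
  if (nrow(x$report) > 0) {
    cat(sprintf("  verdicts: %s\n",
                paste(sprintf("%s=%s", x$report$cpg, x$report$verdict),
                      collapse = ", ")))
  } else cat("  no DMCs -> empty report\n")
  invisible(x)
}
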
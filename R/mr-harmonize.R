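allele_complement <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

is_palindromic <- function(a1, a2) {
  toupper(a2) == allele_complement(a1)
}

#' Harmonize exposure and outcome effects to a common effect allele
#'
#' Joins mQTL (exposure) records with outcome GWAS summary statistics by SNP
#' id and aligns the outcome effect to the exposure's effect allele: swapped
#' alleles flip the outcome beta, strand flips are resolved via allele
#' complements, and palindromic SNPs (A/T, C/G) are dropped when the effect
#' allele frequency is ambiguous (within `eaf_ambiguous` of 0.5 on either
#' side) or aligned by frequency otherwise. Instruments absent from the
#' outcome data or with irreconcilable alleles are dropped; all drops are
#' recorded with reasons in the `dropped` attribute.
#'
#' @param exposure Tibble with `snp`, `b_zx`, `se_zx`, `p`, `effect_allele`,
#'   `other_allele` and optionally `eaf`, `snp_pos`.
#' @param outcome Summary-statistics tibble (`snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `eaf`, ...).
#' @param eaf_ambiguous Palindromic SNPs whose EAF (on either side) lies in
#'   this interval are dropped as strand-ambiguous.
#' @return Tibble of harmonized instruments: snp, snp_pos, b_zx, se_zx,
#'   p_exposure, b_zy, se_zy, palindromic.
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguous = c(0.42, 0.58)) {
  stopifnot(all(c("effect_allele", "other_allele") %in% names(exposure)),
            all(c("effect_allele", "other_allele") %in% names(outcome)))
  dropped <- tibble::tibble(snp = character(), reason = character())
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    oi <- match(ex$snp, outcome$snp)
    if (is.na(oi)) {
      dropped <- dplyr::add_row(dropped, snp = ex$snp,
                                reason = "absent from outcome")
      next
    }
    ou <- outcome[oi, ]
    ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
    ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)
    pal <- is_palindromic(ea_x, oa_x)
    flip <- NA
    if (ea_y == ea_x && oa_y == oa_x) flip <- FALSE
    else if (ea_y == oa_x && oa_y == ea_x) flip <- TRUE
    else if (!pal && ea_y == allele_complement(ea_x) &&
             oa_y == allele_complement(oa_x)) flip <- FALSE
    else if (!pal && ea_y == allele_complement(oa_x) &&
             oa_y == allele_complement(ea_x)) flip <- TRUE
    if (is.na(flip)) {
      dropped <- dplyr::add_row(dropped, snp = ex$snp,
                                reason = "irreconcilable alleles")
      next
    }
    if (pal) {
      eaf_x <- if ("eaf" %in% names(ex)) ex$eaf else NA_real_
      eaf_y <- ou$eaf
      ambiguous <- function(f) is.na(f) ||
        (f >= eaf_ambiguous[1] && f <= eaf_ambiguous[2])
      if (ambiguous(eaf_x) || ambiguous(eaf_y)) {
        dropped <- dplyr::add_row(dropped, snp = ex$snp,
                                  reason = "palindromic, ambiguous EAF")
        next
      }
      # same-label palindromic pair: alignment decided by frequency only
      flip <- sign(eaf_x - 0.5) != sign(eaf_y - 0.5)
    }
    rows[[i]] <- tibble::tibble(
      snp = ex$snp,
      snp_pos = if ("snp_pos" %in% names(ex)) ex$snp_pos else NA_integer_,
      b_zx = ex$b_zx, se_zx = ex$se_zx, p_exposure = ex$p,
      b_zy = if (flip) -ou$beta else ou$beta,
      se_zy = ou$se,
      palindromic = pal
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- dropped
  out
}

#' Greedy LD pruning of instruments
#'
#' Orders instruments by ascending exposure p-value (ties broken by position
#' then id) and keeps a candidate iff its squared LD correlation with every
#' already-kept SNP is below `r2_max`, ensuring approximately independent
#' instruments.
#'
#' @param instruments Harmonized instrument tibble (needs `snp`,
#'   `p_exposure`; optional `snp_pos`).
#' @param ld An `ld_matrix` covering all instruments.
#' @param r2_max Maximum allowed pairwise r-squared (strict `<`).
#' @return The retained subset, in selection order.
#' @export
prune_ld <- function(instruments, ld, r2_max = 0.2) {
  if (nrow(instruments) <= 1) return(instruments)
  if (!all(instruments$snp %in% ld$snps)) {
    stop_mm("LD matrix does not cover all instruments")
  }
  pos <- if ("snp_pos" %in% names(instruments)) instruments$snp_pos else
    seq_len(nrow(instruments))
  ord <- order(instruments$p_exposure, pos, instruments$snp)
  kept <- integer(0)
  for (i in ord) {
    ri <- ld$r[instruments$snp[i], instruments$snp[kept], drop = TRUE]
    if (length(kept) == 0 || all(ri^2 < r2_max)) kept <- c(kept, i)
  }
  instruments[kept, , drop = FALSE]
}
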
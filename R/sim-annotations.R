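#' Simulate binary functional annotation tracks
#'
#' Each track marks SNPs as members with baseline probability `q0`; SNPs in
#' `true_causal` are marked with the probability implied by the configured
#' odds ratio, `q1 = OR * q0/(1-q0) / (1 + OR * q0/(1-q0))`. With
#' `enrichment_odds = 1` causal and non-causal SNPs are annotated at the same
#' rate.
#'
#' @param g A `geno_matrix` (or its `snps` tibble).
#' @param true_causal Character vector of causal SNP ids.
#' @param enrichment_odds Odds ratio of annotation membership, causal vs not.
#' @param n_tracks Number of tracks; zero returns an empty matrix.
#' @param q0 Baseline membership probability.
#' @param seed Integer seed.
#' @return SNP x track binary matrix (rownames = SNP ids, colnames =
#'   track_01, ...).
#' @export
simulate_annotations <- function(g, true_causal, enrichment_odds = 1,
                                 n_tracks = 1, q0 = 0.1, seed = 1L) {
  stopifnot(enrichment_odds > 0, q0 > 0, q0 < 1)
  snps <- if (inherits(g, "geno_matrix")) g$snps$snp else g$snp
  set.seed(seed)
  odds1 <- enrichment_odds * q0 / (1 - q0)
  q1 <- odds1 / (1 + odds1)
  prob <- ifelse(snps %in% true_causal, q1, q0)
  ann <- matrix(0L, length(snps), n_tracks,
                dimnames = list(snps, sprintf("track_%02d", seq_len(n_tracks))))
  if (n_tracks > 0) {
    for (t in seq_len(n_tracks)) ann[, t] <- stats::rbinom(length(snps), 1, prob)
  }
  ann
}

#' Write annotation tracks as BED files
#'
#' Each track becomes one BED file (0-based half-open) with a single-base
#' interval per member SNP.
#'
#' @param ann SNP x track binary matrix from [simulate_annotations()].
#' @param snps SNP metadata tibble (`snp`, `chrom`, `pos`).
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, named by track.
#' @export
write_annotation_beds <- function(ann, snps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(
    file.path(dir, paste0(colnames(ann), ".bed")), colnames(ann))
  for (t in colnames(ann)) {
    member <- rownames(ann)[ann[, t] == 1L]
    idx <- match(member, snps$snp)
    write_bed(tibble::tibble(chrom = snps$chrom[idx],
                             start = snps$pos[idx] - 1L,
                             end = snps$pos[idx]), paths[t])
  }
  invisible(paths)
}
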
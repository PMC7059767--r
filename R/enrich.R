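# Merge possibly overlapping intervals (0-based half-open) per chromosome
# and return them sorted.
merge_intervals <- function(track) {
  track <- track[order(track$chrom, track$start, track$end), , drop = FALSE]
  out <- vector("list", 0)
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    s <- tr$start; e <- tr$end
    keep_s <- s[1]; keep_e <- e[1]
    ss <- c(); ee <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= keep_e) {
        keep_e <- max(keep_e, e[i])
      } else {
        ss <- c(ss, keep_s); ee <- c(ee, keep_e)
        keep_s <- s[i]; keep_e <- e[i]
      }
    }
    ss <- c(ss, keep_s); ee <- c(ee, keep_e)
    out[[length(out) + 1]] <- tibble::tibble(chrom = ch, start = ss, end = ee)
  }
  dplyr::bind_rows(out)
}

#' Overlap CpG positions with a BED-style annotation track
#'
#' A CpG at 1-based position p overlaps a 0-based half-open interval
#' `[start, end)` iff `start < p <= end` — i.e. interval (100, 101) covers
#' position 101 but not 100.
#'
#' @param cpgs Tibble with `chrom` and `pos` (1-based).
#' @param track Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   intervals are merged internally.
#' @return Integer 0/1 vector, one per CpG row.
#' @export
overlap_track <- function(cpgs, track) {
  if (nrow(track) == 0) return(integer(nrow(cpgs)))
  tr <- merge_intervals(track)
  ov <- integer(nrow(cpgs))
  for (ch in unique(cpgs$chrom)) {
    idx <- which(cpgs$chrom == ch)
    trc <- tr[tr$chrom == ch, , drop = FALSE]
    if (nrow(trc) == 0) next
    # interval containing p (0-based coordinate p - 1): find last start <= p-1
    p0 <- cpgs$pos[idx] - 1L
    j <- findInterval(p0, trc$start)
    hit <- j > 0 & p0 < trc$end[pmax(j, 1)]
    ov[idx] <- as.integer(hit)
  }
  ov
}

#' Permutation test for annotation enrichment of DMCs
#'
#' Compares the fraction of DMCs overlapping a track with the overlap
#' fractions of `n_perm` random CpG sets of the same size drawn without
#' replacement from the tested background. The empirical p-value uses the
#' add-one convention, `(1 + #\{perm >= observed\}) / (n_perm + 1)`, so it is
#' never exactly zero; enrichment is one-sided (depletion shows as
#' fold < 1).
#'
#' @param dmc_ids Character ids of the DMCs (must be a subset of the
#'   background).
#' @param background Tibble of all tested CpGs (`cpg`, `chrom`, `pos`).
#' @param track BED-style tibble (`chrom`, `start`, `end`).
#' @param n_perm Number of random sets.
#' @param seed Integer seed.
#' @param track_name Label carried into the output.
#' @return One-row tibble: track, n_dmc, observed_prop, expected_prop, fold,
#'   p_emp, n_perm.
#' @export
permute_enrichment <- function(dmc_ids, background, track, n_perm = 1000,
                               seed = 1L, track_name = "track") {
  stopifnot(all(dmc_ids %in% background$cpg),
            length(dmc_ids) <= nrow(background), length(dmc_ids) >= 1)
  ov <- overlap_track(background, track)
  is_dmc <- background$cpg %in% dmc_ids
  observed <- mean(ov[is_dmc])
  k <- sum(is_dmc)
  set.seed(seed)
  perm_props <- vapply(seq_len(n_perm), function(b) {
    mean(ov[sample.int(nrow(background), k)])
  }, numeric(1))
  expected <- mean(perm_props)
  fold <- if (expected > 0) observed / expected else NA_real_
  if (expected == 0) warn_mm("expected overlap is zero; fold undefined")
  p_emp <- (1 + sum(perm_props >= observed)) / (n_perm + 1)
  tibble::tibble(track = track_name, n_dmc = k,
                 observed_prop = observed, expected_prop = expected,
                 fold = fold, p_emp = p_emp, n_perm = n_perm)
}

#' Enrichment of DMCs across several annotation tracks
#'
#' @param dmc_ids DMC ids.
#' @param background Tibble of all tested CpGs.
#' @param tracks Named list of BED-style tibbles.
#' @param n_perm,seed Permutation settings (per-track seeds derive from
#'   `seed`).
#' @return Tibble with one row per track (see [permute_enrichment()]).
#' @export
annotation_enrichment <- function(dmc_ids, background, tracks,
                                  n_perm = 1000, seed = 1L) {
  purrr::imap_dfr(tracks, function(tr, nm) {
    permute_enrichment(dmc_ids, background, tr, n_perm = n_perm,
                       seed = derive_seed(seed, match(nm, names(tracks))),
                       track_name = nm)
  })
}
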
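# Interchange formats. Coordinate conventions: VCF and Bismark coverage
# files are 1-based inclusive; BED is 0-based half-open. All writers are
# plain text and byte-deterministic given identical inputs.

#' Write genotypes to a minimal VCF (GT field)
#'
#' REF is the other allele, ALT the effect (dosage-counted) allele; dosages
#' 0/1/2 map to genotypes 0/0, 0/1, 1/1 and missing to ./. .
#'
#' @param g A `geno_matrix`.
#' @param path Output file.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  subjects <- rownames(g$dosages)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", subjects), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$snp[j],
                       g$snps$other_allele[j], g$snps$effect_allele[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a `geno_matrix`
#'
#' Parses genotypes with vcfR and counts ALT alleles, matching the dosage
#' convention of [write_vcf()] (effect allele = ALT).
#'
#' @param path VCF file.
#' @return A `geno_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(x %in% c("0/0", "0|0"), 0L,
      ifelse(x %in% c("0/1", "1/0", "0|1", "1|0"), 1L,
        ifelse(x %in% c("1/1", "1|1"), 2L, NA_integer_)))
  }
  dos_vs <- matrix(count_alt(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  dos <- t(dos_vs)
  colnames(dos) <- fix[, "ID"]
  maf <- colMeans(dos, na.rm = TRUE) / 2
  snps <- tibble::tibble(
    snp = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
    maf = maf
  )
  structure(list(dosages = dos, snps = snps), class = "geno_matrix")
}

#' Write genotype dosages to a plain TSV
#' @param g A `geno_matrix`.
#' @param path Output file (columns: subject, then one per SNP).
#' @export
write_dosage_tsv <- function(g, path) {
  df <- tibble::as_tibble(g$dosages)
  df <- dplyr::bind_cols(tibble::tibble(subject = rownames(g$dosages)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write Bismark-coverage-style methylation files, one per subject
#'
#' Columns: chrom, start, end (1-based inclusive, start = end = CpG
#' position), methylation percentage, count methylated, count unmethylated.
#' Positions with zero coverage are omitted, as in real coverage files.
#'
#' @param counts A `meth_counts`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, named by subject.
#' @export
write_bismark_cov <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- colnames(counts$m)
  paths <- stats::setNames(file.path(dir, paste0(subjects, ".cov")), subjects)
  for (i in seq_along(subjects)) {
    ok <- !is.na(counts$n[, i]) & counts$n[, i] > 0
    df <- tibble::tibble(
      chrom = counts$cpgs$chrom[ok],
      start = counts$cpgs$pos[ok],
      end = counts$cpgs$pos[ok],
      pct = round(100 * counts$m[ok, i] / counts$n[ok, i], 6),
      count_m = counts$m[ok, i],
      count_u = counts$n[ok, i] - counts$m[ok, i]
    )
    readr::write_tsv(df, paths[i], col_names = FALSE)
  }
  invisible(paths)
}

#' Read Bismark-coverage files into a `meth_counts`
#'
#' @param paths Named character vector of files (names become subject ids;
#'   unnamed paths use the file basename).
#' @return A `meth_counts` over the union of observed CpG positions
#'   (zero-coverage entries where a subject lacks a position).
#' @export
read_bismark_cov <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.cov$", "", basename(paths))
  }
  per <- lapply(paths, function(p) {
    df <- readr::read_tsv(p, col_names = c("chrom", "start", "end", "pct",
                                           "count_m", "count_u"),
                          col_types = "ciidii", progress = FALSE)
    bad <- which(df$count_m < 0 | df$count_u < 0 | df$start > df$end)
    if (length(bad) > 0) {
      stop_mm("%s: malformed coverage record at line %d", p, bad[1])
    }
    df
  })
  keys <- unique(dplyr::bind_rows(lapply(per, function(d)
    d[, c("chrom", "start")])))
  keys <- keys[order(keys$chrom, keys$start), ]
  key_id <- paste(keys$chrom, keys$start)
  m <- matrix(NA_integer_, nrow(keys), length(paths),
              dimnames = list(NULL, names(paths)))
  n <- matrix(0L, nrow(keys), length(paths),
              dimnames = list(NULL, names(paths)))
  for (i in seq_along(per)) {
    d <- per[[i]]
    idx <- match(paste(d$chrom, d$start), key_id)
    m[idx, i] <- d$count_m
    n[idx, i] <- d$count_m + d$count_u
  }
  cpgs <- tibble::tibble(
    cpg = sprintf("cpg_%s_%d", keys$chrom, keys$start),
    chrom = keys$chrom, pos = keys$start, strand = "+",
    intercept = NA_real_
  )
  structure(list(cpgs = cpgs, m = m, n = n, latent = NULL),
            class = "meth_counts")
}

#' Write outcome GWAS summary statistics to TSV
#' @param sumstats Tibble (snp, effect_allele, other_allele, beta, se, p,
#'   eaf, n).
#' @param path Output file with header SNP A1 A2 BETA SE P EAF N.
#' @export
write_sumstats <- function(sumstats, path) {
  df <- tibble::tibble(SNP = sumstats$snp, A1 = sumstats$effect_allele,
                       A2 = sumstats$other_allele, BETA = sumstats$beta,
                       SE = sumstats$se, P = sumstats$p, EAF = sumstats$eaf,
                       N = sumstats$n)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read outcome GWAS summary statistics
#'
#' Validates each record; rows with missing or non-positive SE, p outside
#' (0, 1], or EAF outside (0, 1) are rejected with their line number.
#'
#' @param path TSV with header SNP A1 A2 BETA SE P EAF N.
#' @return Summary-statistics tibble.
#' @export
read_sumstats <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccddddd", progress = FALSE)
  need <- c("SNP", "A1", "A2", "BETA", "SE", "P", "EAF", "N")
  if (!all(need %in% names(df))) {
    stop_mm("%s: missing columns %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(is.na(df$SE) | df$SE <= 0 | is.na(df$BETA) |
                 is.na(df$P) | df$P <= 0 | df$P > 1 |
                 is.na(df$EAF) | df$EAF <= 0 | df$EAF >= 1)
  if (length(bad) > 0) {
    stop_mm("%s: invalid summary-statistics record at line %d",
            path, bad[1] + 1L)  # + header line
  }
  tibble::tibble(snp = df$SNP, effect_allele = df$A1, other_allele = df$A2,
                 beta = df$BETA, se = df$SE, p = df$P, eaf = df$EAF,
                 n = df$N)
}

#' Write a BED track (0-based half-open)
#' @param track Tibble with chrom, start, end.
#' @param path Output file (no header, tab-separated).
#' @export
write_bed <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a BED track
#'
#' @param path BED file (>= 3 columns, 0-based half-open). Malformed lines
#'   (non-integer coordinates, start >= end) raise an error naming the line.
#' @return Tibble with chrom, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop_mm("%s: fewer than 3 fields at line %d", path, i)
    s <- suppressWarnings(as.integer(p[2]))
    e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      stop_mm("%s: malformed interval at line %d", path, i)
    }
    out[[i]] <- tibble::tibble(chrom = p[1], start = s, end = e)
  }
  dplyr::bind_rows(out)
}

#' Write an LD matrix to TSV (snp column + one column per SNP)
#' @param ld An `ld_matrix`.
#' @param path Output file.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- tibble::as_tibble(ld$r)
  names(df) <- ld$snps
  df <- dplyr::bind_cols(tibble::tibble(snp = ld$snps), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#' @param path TSV file.
#' @param source_n Optional subject count annotation.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, source_n = NA_integer_) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  snps <- df$snp
  r <- as.matrix(df[, -1, drop = FALSE])
  rownames(r) <- snps
  structure(list(r = r, snps = snps, source_n = source_n),
            class = "ld_matrix")
}

#' Write the phenotype/covariate table to TSV
#' @param phenotypes Phenotype tibble.
#' @param path Output file.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(path)
}

#' Read a phenotype/covariate table
#' @param path TSV with subject, y, group and covariate columns.
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
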
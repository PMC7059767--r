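# Small shared fixtures, built in code.

tiny_config <- function(scenario = "mediation", seed = 1L, ...) {
  sim_config(n_subjects = 60, n_outcome_gwas = 4000, n_cpgs = 6,
             n_instruments = 2,
             ld_block_spec = dplyr::bind_rows(
               tibble::tibble(size = c(4L, 4L), rho = 0.8, chrom = "chr1"),
               tibble::tibble(size = 3L, rho = 0, chrom = "chr2")
             ),
             scenario = scenario, seed = seed, ...)
}

# meth_counts object from explicit matrices
make_counts <- function(m, n, chrom = "chr1", pos = NULL) {
  k <- nrow(m)
  if (is.null(pos)) pos <- seq_len(k) * 100L
  if (is.null(colnames(m))) {
    colnames(m) <- colnames(n) <- sprintf("s%02d", seq_len(ncol(m)))
  }
  structure(list(
    cpgs = tibble::tibble(cpg = sprintf("cpg_%03d", seq_len(k)),
                          chrom = rep(chrom, length.out = k),
                          pos = pos, strand = "+", intercept = 0),
    m = m, n = n, latent = NULL
  ), class = "meth_counts")
}

# geno_matrix from an explicit dosage matrix
make_geno <- function(dos, chrom = "chr1", pos = NULL,
                      ea = "A", oa = "G") {
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("s%04d", seq_len(ncol(dos)))
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("subj%03d", seq_len(nrow(dos)))
  p <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  structure(list(
    dosages = dos,
    snps = tibble::tibble(snp = colnames(dos),
                          chrom = rep(chrom, length.out = p),
                          pos = pos,
                          effect_allele = rep(ea, length.out = p),
                          other_allele = rep(oa, length.out = p),
                          maf = colMeans(dos, na.rm = TRUE) / 2,
                          block = 1L)
  ), class = "geno_matrix")
}
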
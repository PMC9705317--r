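# Programmatic fixtures shared across test files.

# A small genotype matrix built directly from allele matrices.
toy_gt <- function(a1, a2, contig = "ctgA", pos = NULL) {
  ns <- nrow(a1)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  sites <- tibble::tibble(
    contig = rep(contig, length.out = ns), pos = as.integer(pos),
    ref = rep("A", ns), alt = rep(list(c("C", "G", "T")), ns))
  genotype_matrix(a1, a2, sites, sprintf("s%02d", seq_len(ncol(a1))))
}

# Small two-population cohort configuration for fast end-to-end tests.
small_cohort_config <- function(...) {
  cohort_config(
    n_contigs = 1, contig_length_bp = 5e5, n_sites_per_contig = 3000,
    pop_names = c("A", "B"), pop_sizes = c(15, 20), pop_f = c(0.05, 0.05),
    multiallelic_fraction = 0.1, n_outliers = 0, n_mislabeled = 0,
    mislabel_from = "B", mislabel_as = "A",
    missing_rate = 0.01, gene_fraction = 0.1, seed = 42, ...)
}

# Draw allele-count matrices (n - i, i) with derived-allele counts i sampled
# from the neutral site-frequency spectrum P(i) proportional to 1/i.
neutral_sfs_counts <- function(s, n) {
  probs <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  i <- sample(seq_len(n - 1), s, replace = TRUE, prob = probs)
  cbind(allele0 = n - i, allele1 = i, allele2 = 0L, allele3 = 0L)
}

# Chromosome matrix (rows = chromosomes) realising an allele-count matrix.
counts_to_chrom_matrix <- function(counts) {
  n <- sum(counts[1, ])
  sapply(seq_len(nrow(counts)), function(s) {
    rep(0:3, counts[s, ])
  })
}
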
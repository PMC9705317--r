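# Independent oracles, written before (and kept independent of) the package
# kernels they check.

# Brute-force nucleotide diversity: explicit chromosome-pair comparisons on a
# small genotype matrix. Missing chromosomes are dropped per site.
oracle_pi <- function(gt, accessible) {
  chroms <- rbind(gt$allele1, gt$allele2)  # not used; kept per-site below
  total <- 0
  for (s in seq_len(nrow(gt$allele1))) {
    alleles <- c(gt$allele1[s, ], gt$allele2[s, ])
    alleles <- alleles[!is.na(alleles)]
    n <- length(alleles)
    if (n < 2) next
    diff <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diff <- diff + (alleles[i] != alleles[j])
    }
    total <- total + diff / (n * (n - 1) / 2)
  }
  unname(total / accessible)
}

# Tajima's D transcribed from the 1989 definitions, computed from explicit
# chromosome-pair differences over a chromosome matrix (rows = chromosomes).
oracle_tajimas_d <- function(chrom_mat) {
  n <- nrow(chrom_mat)
  seg <- apply(chrom_mat, 2, function(col) length(unique(col)) > 1)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # mean number of pairwise differences
  total_diff <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total_diff <- total_diff + sum(chrom_mat[i, ] != chrom_mat[j, ])
    }
  }
  k_hat <- total_diff / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Per-site Hudson Fst by direct arithmetic on two allele-count vectors
# (counts over alleles 0..3), for cross-checking the vectorised components.
oracle_hudson_site <- function(cnt1, cnt2) {
  n1 <- sum(cnt1); n2 <- sum(cnt2)
  present <- which((cnt1 + cnt2) > 0)
  stopifnot(length(present) == 2, n1 >= 2, n2 >= 2)
  alt <- max(present)
  p1 <- cnt1[alt] / n1
  p2 <- cnt2[alt] / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}
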
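#' Diploid genotype matrix
#'
#' The universal substrate of the package: diploid allele indices at `n_sites`
#' variant positions for `n_samples` individuals. Alleles are coded as integers
#' (0 = reference, 1..3 = alternate alleles in VCF order); missing genotypes
#' are `NA` on both haplotypes. Two integer matrices (one per haplotype) back
#' the object; every tabular result derived from it is a tibble.
#'
#' @param allele1,allele2 Integer matrices, sites in rows, samples in columns.
#' @param sites Tibble with columns `contig`, `pos` (1-based), `ref` (single
#'   base) and `alt` (list column of character vectors of alternate bases).
#' @param samples Character vector of sample ids, one per column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(allele1, allele2, sites, samples) {
  stopifnot(
    is.matrix(allele1), is.matrix(allele2),
    all(dim(allele1) == dim(allele2)),
    nrow(allele1) == nrow(sites),
    ncol(allele1) == length(samples)
  )
  if (any(allele1 > 3L, na.rm = TRUE) || any(allele2 > 3L, na.rm = TRUE)) {
    abort("allele index above 3: only a reference and up to three alternates are modelled")
  }
  colnames(allele1) <- colnames(allele2) <- samples
  structure(
    list(allele1 = allele1, allele2 = allele2,
         sites = as_tibble(sites), samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples, %d contig(s)\n",
              n_sites(x), n_samples(x), length(unique(x$sites$contig))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_sites <- function(x) nrow(x$allele1)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) ncol(x$allele1)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param x A `genotype_matrix`.
#' @param sites Integer or logical index over sites (rows).
#' @param samples Integer, logical, or character index over samples.
#' @return A `genotype_matrix`.
#' @export
gt_subset <- function(x, sites = NULL, samples = NULL) {
  a1 <- x$allele1; a2 <- x$allele2; st <- x$sites; sm <- x$samples
  if (!is.null(sites)) {
    a1 <- a1[sites, , drop = FALSE]
    a2 <- a2[sites, , drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, sm)
    a1 <- a1[, samples, drop = FALSE]
    a2 <- a2[, samples, drop = FALSE]
    sm <- sm[samples]
  }
  genotype_matrix(a1, a2, st, sm)
}

#' Per-site allele counts
#'
#' Counts each allele (0..3) over the non-missing chromosomes of the chosen
#' samples. Columns of the result correspond to alleles 0..3; repeated sample
#' indices are allowed (used by the sample bootstrap).
#'
#' @param x A `genotype_matrix`.
#' @param samples Optional sample index (integer/character/logical); default
#'   all samples. Repeats count with multiplicity.
#' @return Integer matrix `n_sites x 4` of chromosome counts.
#' @export
allele_counts <- function(x, samples = NULL) {
  a1 <- x$allele1; a2 <- x$allele2
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, x$samples)
    a1 <- a1[, samples, drop = FALSE]
    a2 <- a2[, samples, drop = FALSE]
  }
  out <- matrix(0L, nrow = nrow(a1), ncol = 4L,
                dimnames = list(NULL, paste0("allele", 0:3)))
  for (v in 0:3) {
    out[, v + 1L] <- rowSums(a1 == v, na.rm = TRUE) + rowSums(a2 == v, na.rm = TRUE)
  }
  out
}

#' Alternate-allele dosage matrix for PCA
#'
#' Returns a samples x sites numeric matrix of alternate-allele dosages
#' (0/1/2). For biallelic sites the dosage counts the single segregating
#' non-reference allele; missing genotypes are imputed to the site mean.
#'
#' @param x A `genotype_matrix`.
#' @param sites Integer index of (biallelic) sites to use.
#' @param impute Impute missing dosages to the site mean (default `TRUE`).
#' @return Numeric matrix, samples in rows.
#' @export
dosage_matrix <- function(x, sites = seq_len(n_sites(x)), impute = TRUE) {
  a1 <- x$allele1[sites, , drop = FALSE]
  a2 <- x$allele2[sites, , drop = FALSE]
  d <- (a1 > 0L) + (a2 > 0L)
  storage.mode(d) <- "double"
  d[is.na(a1) | is.na(a2)] <- NA_real_
  if (impute && anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1L]]
  }
  t(d)
}

#' Number of distinct alleles observed per site
#'
#' @param counts Allele-count matrix from [allele_counts()].
#' @return Integer vector: distinct alleles among called chromosomes (0 when
#'   the site is fully missing).
#' @export
n_alleles <- function(counts) as.integer(rowSums(counts > 0L))
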
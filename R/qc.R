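#' Sample-level quality control on coverage summaries
#'
#' A sample passes when its median genome-wide coverage is at least
#' `min_median` (fold-coverage) and at least `min_breadth` of the reference is
#' covered at 1x or more. Both thresholds are inclusive: the defaults exclude
#' samples with median coverage below 10x or breadth below 80%.
#'
#' @param summaries Tibble with columns `sample_id`, `median_coverage`,
#'   `breadth_1x`.
#' @param min_median Minimum median fold-coverage (default 10).
#' @param min_breadth Minimum fraction of the reference covered at >= 1x
#'   (default 0.8).
#' @param samples Optional character vector of sample ids that must each have
#'   a summary row (e.g. the VCF sample set); a missing summary is an error.
#' @return The input tibble with logical column `qc_pass` and a `reason`
#'   column (`NA` for passing samples).
#' @export
sample_qc <- function(summaries, min_median = 10, min_breadth = 0.8,
                      samples = NULL) {
  summaries <- as_tibble(summaries)
  stopifnot(all(c("sample_id", "median_coverage", "breadth_1x") %in% names(summaries)))
  if (!is.null(samples)) {
    missing <- setdiff(samples, summaries$sample_id)
    if (length(missing) > 0) {
      abort(sprintf("no coverage summary for sample(s): %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  summaries |>
    mutate(
      qc_pass = .data$median_coverage >= min_median & .data$breadth_1x >= min_breadth,
      reason = case_when(
        .data$median_coverage < min_median ~ sprintf("median coverage < %gx", min_median),
        .data$breadth_1x < min_breadth ~ sprintf("breadth at 1x < %g", min_breadth),
        TRUE ~ NA_character_
      )
    )
}

#' Site-class census
#'
#' Classifies every site by the number of distinct alleles observed among
#' non-missing genotype calls: 1 allele = invariant, 2 = biallelic,
#' 3 = triallelic, 4 = quadriallelic. Sites where every call is missing are
#' counted separately as unclassified. Segregating = biallelic + triallelic +
#' quadriallelic.
#'
#' @param genotypes A [genotype_matrix()].
#' @return A one-row tibble: `invariant`, `biallelic`, `triallelic`,
#'   `quadriallelic`, `segregating`, `multiallelic_fraction` (share of
#'   segregating sites with more than two alleles), `unclassified`, `total`.
#' @export
classify_sites <- function(genotypes) {
  counts <- allele_counts(genotypes)
  k <- n_alleles(counts)
  seg <- sum(k >= 2L)
  tibble(
    invariant = sum(k == 1L),
    biallelic = sum(k == 2L),
    triallelic = sum(k == 3L),
    quadriallelic = sum(k == 4L),
    segregating = seg,
    multiallelic_fraction = if (seg > 0) sum(k >= 3L) / seg else NA_real_,
    unclassified = sum(k == 0L),
    total = length(k)
  )
}

#' Apply a per-contig accessibility mask to a genotype matrix
#'
#' Retains only sites whose position is accessible under the mask and reports
#' the accessible-position count (the denominator for per-base statistics).
#' Site filters themselves are treated as an input: the mask is whatever
#' upstream filtering produced (or all-true).
#'
#' @param genotypes A [genotype_matrix()].
#' @param mask Named list of logical vectors, one per contig, `TRUE` at
#'   accessible positions; each vector's length must equal the contig length.
#' @param contig_lengths Named integer vector of contig lengths used to
#'   validate the mask.
#' @return List with `genotypes` (filtered) and `accessible` (total number of
#'   accessible positions across the masked contigs).
#' @export
apply_site_mask <- function(genotypes, mask, contig_lengths = NULL) {
  st <- genotypes$sites
  contigs <- unique(st$contig)
  if (!all(contigs %in% names(mask))) {
    abort("mask missing for contig(s) present in the genotype matrix")
  }
  if (!is.null(contig_lengths)) {
    for (ctg in names(mask)) {
      if (!is.na(contig_lengths[ctg]) && length(mask[[ctg]]) != contig_lengths[ctg]) {
        abort(sprintf("mask length for %s does not match contig length", ctg))
      }
    }
  }
  keep <- purrr::map2(st$contig, st$pos, function(ctg, p) {
    p <= length(mask[[ctg]]) && mask[[ctg]][p]
  }) |> unlist()
  list(
    genotypes = gt_subset(genotypes, sites = which(keep)),
    accessible = sum(vapply(mask, sum, numeric(1)))
  )
}
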
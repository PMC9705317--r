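#' Four-fold degenerate site mask
#'
#' Walks every codon of every CDS (reverse-complemented for minus-strand
#' features, phase-adjusted) and flags the third codon position when all four
#' nucleotide substitutions there leave the amino acid unchanged. Positions
#' covered by more than one CDS are flagged only if every covering frame
#' agrees the position is four-fold degenerate; incomplete terminal codons
#' are ignored. CDS features that run off the contig end are skipped with a
#' warning.
#'
#' @param sequences A [Biostrings::DNAStringSet] of contigs.
#' @param cds Tibble of CDS features: `contig`, `start`, `end`, `strand`,
#'   optionally `phase` (default 0). 1-based inclusive coordinates.
#' @return Named list of logical vectors, one per contig (length = contig
#'   length), `TRUE` at four-fold degenerate positions.
#' @export
fourfold_degenerate_mask <- function(sequences, cds) {
  fams <- fourfold_dimers()
  contigs <- names(sequences)
  lens <- Biostrings::width(sequences)
  cover <- lapply(lens, function(l) integer(l))
  agree <- lapply(lens, function(l) integer(l))
  names(cover) <- names(agree) <- contigs

  cds <- as_tibble(cds)
  if (!"phase" %in% names(cds)) cds$phase <- 0L
  cds$phase[is.na(cds$phase)] <- 0L

  for (i in seq_len(nrow(cds))) {
    row <- cds[i, ]
    ci <- match(row$contig, contigs)
    if (is.na(ci)) next
    if (row$start < 1 || row$end > lens[ci]) {
      warn(sprintf("CDS %d runs off contig %s; skipped", i, row$contig))
      next
    }
    s <- Biostrings::subseq(sequences[[ci]], row$start, row$end)
    minus <- identical(row$strand, "-")
    if (minus) s <- Biostrings::reverseComplement(s)
    seq_chr <- as.character(s)
    ph <- row$phase %% 3L
    cds_len <- nchar(seq_chr) - ph
    n_codon <- cds_len %/% 3L
    if (n_codon == 0L) next
    # reading-frame offsets of third codon positions within the feature
    third_off <- ph + 3L * seq_len(n_codon) - 1L          # 0-based within feature
    dimer_start <- ph + 3L * (seq_len(n_codon) - 1L) + 1L # 1-based
    dimers <- substring(seq_chr, dimer_start, dimer_start + 1L)
    is4 <- dimers %in% fams
    genome_pos <- if (minus) row$end - third_off else row$start + third_off
    # every complete-codon position counts as covered; only four-fold third
    # positions count as agreeing, so a frame in which the base is a first or
    # second codon position vetoes the flag
    codon_off <- ph + seq_len(3L * n_codon) - 1L
    codon_pos <- if (minus) row$end - codon_off else row$start + codon_off
    cover[[ci]][codon_pos] <- cover[[ci]][codon_pos] + 1L
    agree[[ci]][genome_pos] <- agree[[ci]][genome_pos] + as.integer(is4)
  }
  out <- purrr::map2(cover, agree, function(cv, ag) cv > 0L & ag == cv)
  names(out) <- contigs
  out
}

# Dinucleotide prefixes whose codon family is four-fold degenerate under the
# standard genetic code, derived from Biostrings' GENETIC_CODE.
fourfold_dimers <- function() {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  dimers <- as.vector(outer(bases, bases, paste0))
  keep <- vapply(dimers, function(d) {
    aa <- gc[paste0(d, bases)]
    length(unique(aa)) == 1L
  }, logical(1))
  dimers[keep]
}

#' Export a degeneracy mask as BED intervals
#'
#' @param mask Output of [fourfold_degenerate_mask()].
#' @param path Optional path; when given, a 0-based half-open BED file is
#'   written.
#' @return Tibble: `contig`, `start` (0-based), `end` (half-open).
#' @export
mask_to_bed <- function(mask, path = NULL) {
  bed <- purrr::imap(mask, function(v, ctg) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    tibble(contig = ctg, start = starts[r$values], end = ends[r$values])
  }) |> list_rbind()
  if (!is.null(path)) readr::write_tsv(bed, path, col_names = FALSE)
  bed
}

#' Nucleotide diversity from allele counts
#'
#' Per site, the mean number of pairwise differences among the `n` sampled
#' chromosomes is `1 - sum_a C(c_a, 2) / C(n, 2)`; pi is the sum over sites
#' divided by the accessible-site count. All alleles of multiallelic sites
#' contribute.
#'
#' @param counts Allele-count matrix from [allele_counts()].
#' @param accessible Number of accessible positions (denominator).
#' @return Per-base nucleotide diversity (`NA` when `accessible` is 0).
#' @export
nucleotide_diversity <- function(counts, accessible) {
  if (accessible <= 0) {
    warn("accessible-site count is 0: nucleotide diversity undefined")
    return(NA_real_)
  }
  sum(site_heterozygosity(counts), na.rm = TRUE) / accessible
}

# mean pairwise difference per site; NA when fewer than 2 chromosomes called
site_heterozygosity <- function(counts) {
  n <- rowSums(counts)
  same <- rowSums(counts * (counts - 1L))
  h <- 1 - same / (n * (n - 1L))
  h[n < 2L] <- NA_real_
  h
}

#' Watterson's theta
#'
#' `theta_W = S / a_n / L` with `a_n` the harmonic number `sum(1/i)` for
#' `i = 1 .. n-1`.
#'
#' @param s Number of segregating sites.
#' @param n Number of sampled chromosomes (>= 2).
#' @param accessible Accessible-site count `L` (> 0).
#' @return Per-base Watterson estimator.
#' @export
watterson_theta <- function(s, n, accessible) {
  if (n < 2) abort("Watterson's theta needs at least two chromosomes")
  if (accessible <= 0) abort("accessible-site count must be positive")
  a1 <- sum(1 / seq_len(n - 1))
  s / a1 / accessible
}

#' Tajima's D
#'
#' Normalised difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta, using the standard constants
#' (Tajima 1989). Requires a uniform chromosome count across sites, which the
#' caller enforces by restricting to fully called sites in the downsampled
#' set. Undefined (NA) when no site segregates.
#'
#' @param counts Allele-count matrix over the sites entering the statistic;
#'   every row must sum to `n`.
#' @param n Number of chromosomes at every site.
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(counts, n) {
  if (n < 2) abort("Tajima's D needs at least two chromosomes")
  if (nrow(counts) > 0 && any(rowSums(counts) != n)) {
    abort("Tajima's D requires the same chromosome count at every site")
  }
  seg <- rowSums(counts > 0L) >= 2L
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  ppi <- sum(site_heterozygosity(counts)[seg])
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (ppi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Downsample populations to a common size
#'
#' Draws `target` samples uniformly without replacement from each population
#' (seeded), so every population enters the diversity statistics with equal
#' sample size — by default the size of the smallest population.
#'
#' @param assignment Tibble with `sample_id` and `population` columns for
#'   assigned samples.
#' @param target Common size; default the smallest population size.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `population` with exactly `target` rows per
#'   population.
#' @export
downsample_populations <- function(assignment, target = NULL, seed = 1L) {
  assignment <- as_tibble(assignment)
  sizes <- assignment |> count(.data$population)
  if (is.null(target)) target <- min(sizes$n)
  if (any(sizes$n < target)) {
    abort(sprintf("target %d exceeds the size of population %s", target,
                  sizes$population[which.min(sizes$n)]))
  }
  withr::with_seed(substream_seed(seed, "downsample"), {
    assignment |>
      group_by(.data$population) |>
      slice_sample(n = target) |>
      ungroup() |>
      arrange(.data$population, .data$sample_id)
  })
}

#' Percentile bootstrap confidence interval over samples
#'
#' Resamples individuals with replacement `n_boot` times, recomputes the
#' statistic, and returns the percentile interval. The interval is flagged
#' unreliable when the statistic is undefined (NA) on more than 20% of
#' replicates.
#'
#' @param stat_fn Function taking a character vector of sample ids and
#'   returning a scalar statistic.
#' @param sample_ids Character vector of the population's samples.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble: `ci_lo`, `ci_hi`, `n_boot`, `n_failed`, `reliable`.
#' @export
bootstrap_ci <- function(stat_fn, sample_ids, n_boot = 100, level = 0.95,
                         seed = 1L) {
  reps <- withr::with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      stat_fn(sample(sample_ids, length(sample_ids), replace = TRUE))
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble(ci_lo = qs[1], ci_hi = qs[2], n_boot = n_boot, n_failed = n_failed,
         reliable = n_failed <= 0.2 * n_boot)
}

#' Per-population diversity statistics with bootstrap CIs
#'
#' Computes nucleotide diversity, Watterson's theta and Tajima's D per
#' population over a chosen site set (typically four-fold degenerate sites on
#' large autosomal contigs), after downsampling every population to a common
#' size, with percentile bootstrap confidence intervals over samples.
#' Tajima's D is computed over sites fully called in the (down)sampled set so
#' the chromosome count is uniform.
#'
#' @param genotypes A [genotype_matrix()].
#' @param assignment Tibble `sample_id`, `population` of assigned samples.
#' @param sites Integer index of sites to include (e.g. variants inside the
#'   four-fold degenerate mask); default all.
#' @param accessible Accessible-position count used as the per-base
#'   denominator for pi and theta_W.
#' @param target Downsampling target; default smallest population.
#' @param n_boot Bootstrap replicates (default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble: `population`, `statistic` (`pi`, `theta_w`, `tajimas_d`),
#'   `estimate`, `ci_lo`, `ci_hi`, `n_samples`, `accessible`, `reliable`.
#' @export
population_diversity <- function(genotypes, assignment,
                                 sites = seq_len(n_sites(genotypes)),
                                 accessible, target = NULL, n_boot = 100,
                                 level = 0.95, seed = 1L) {
  g <- gt_subset(genotypes, sites = sites)
  down <- downsample_populations(assignment, target = target, seed = seed)
  pops <- unique(down$population)

  one_pop <- function(pop) {
    ids <- down$sample_id[down$population == pop]
    n_chrom <- 2L * length(ids)

    stat_all <- function(chosen) {
      counts <- allele_counts(g, samples = chosen)
      full <- rowSums(counts) == n_chrom
      seg <- n_alleles(counts) >= 2L
      c(pi = nucleotide_diversity(counts, accessible),
        theta_w = watterson_theta(sum(seg), n_chrom, accessible),
        tajimas_d = tajimas_d(counts[full, , drop = FALSE], n_chrom))
    }
    point <- stat_all(ids)
    cis <- purrr::map(c("pi", "theta_w", "tajimas_d"), function(stat) {
      bootstrap_ci(function(chosen) stat_all(chosen)[[stat]], ids,
                   n_boot = n_boot, level = level,
                   seed = substream_seed(seed, "diversity", pop, stat))
    }) |> list_rbind()
    tibble(population = pop,
           statistic = c("pi", "theta_w", "tajimas_d"),
           estimate = unname(point),
           ci_lo = cis$ci_lo, ci_hi = cis$ci_hi,
           n_samples = length(ids), accessible = accessible,
           reliable = cis$reliable)
  }
  purrr::map(pops, one_pop) |> list_rbind()
}

#' Plot diversity estimates with confidence intervals
#'
#' @param diversity Output of [population_diversity()].
#' @return A ggplot with one panel per statistic.
#' @export
plot_diversity <- function(diversity) {
  ggplot2::ggplot(diversity,
                  ggplot2::aes(.data$population, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}
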
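test_that("four-fold degenerate flags follow the genetic code on both strands", {
  # forward CDS 4..12: GCT (Ala, four-fold third position), TGG (Trp, none),
  # CTA (Leu, four-fold)
  seqs <- Biostrings::DNAStringSet(c(ctgA = "AAAGCTTGGCTAAAAA"))
  cds <- tibble::tibble(contig = "ctgA", start = 4L, end = 12L, strand = "+",
                        phase = 0L)
  m <- fourfold_degenerate_mask(seqs, cds)
  expect_equal(which(m$ctgA), c(6L, 12L))

  # minus-strand CDS 2..7 read as reverse complement GCT GGC (Ala, Gly - both
  # four-fold); third codon positions map to forward coordinates 5 and 2
  seqs2 <- Biostrings::DNAStringSet(c(ctgB = "AGCCAGCAA"))
  cds2 <- tibble::tibble(contig = "ctgB", start = 2L, end = 7L, strand = "-",
                         phase = 0L)
  m2 <- fourfold_degenerate_mask(seqs2, cds2)
  expect_equal(which(m2$ctgB), c(2L, 5L))

  # overlapping frames must agree: same bases annotated on both strands
  both <- tibble::tibble(contig = "ctgB", start = c(2L, 2L), end = c(7L, 7L),
                         strand = c("-", "+"), phase = 0L)
  m3 <- fourfold_degenerate_mask(seqs2, both)
  # + frame on GCCAGC flags position 4 only (GCC, Ala); the - frame flags 2
  # and 5; no position is four-fold in both frames, so none survives
  expect_equal(which(m3$ctgB), integer(0))

  # CDS running off the contig is skipped with a warning
  off <- tibble::tibble(contig = "ctgB", start = 5L, end = 30L, strand = "+",
                        phase = 0L)
  expect_warning(m4 <- fourfold_degenerate_mask(seqs2, off), "runs off")
  expect_false(any(m4$ctgB))

  # masked positions always lie inside an annotated CDS
  cfg <- small_cohort_config()
  ref <- build_reference(cfg)
  mask <- fourfold_degenerate_mask(ref$sequences,
                                   ref$genes |> dplyr::mutate(phase = 0L))
  flagged <- which(mask[[1]])
  in_cds <- rep(FALSE, cfg$contig_length_bp)
  for (i in seq_len(nrow(ref$genes))) {
    in_cds[ref$genes$start[i]:ref$genes$end[i]] <- TRUE
  }
  expect_true(all(in_cds[flagged]))
  expect_lte(length(flagged), sum(in_cds) / 3)
})

test_that("nucleotide diversity matches enumeration and the pairwise oracle", {
  counts <- rbind(c(4L, 0L, 0L, 0L),   # monomorphic: 0
                  c(1L, 1L, 0L, 0L),   # single pair: 1
                  c(2L, 2L, 0L, 0L))   # 4 differing pairs of 6: 2/3
  h <- minpop:::site_heterozygosity(counts)
  expect_equal(h, c(0, 1, 2 / 3))
  expect_equal(nucleotide_diversity(counts, 10), (0 + 1 + 2 / 3) / 10)
  expect_warning(expect_true(is.na(nucleotide_diversity(counts, 0))),
                 "undefined")

  # oracle equivalence on random small matrices, with missing data
  withr::with_seed(11, {
    for (rep in 1:5) {
      ns <- sample(20:60, 1)
      nsamp <- sample(5:20, 1)
      a1 <- matrix(sample(c(0L, 0L, 1L, 2L), ns * nsamp, TRUE), ns, nsamp)
      a2 <- matrix(sample(c(0L, 0L, 0L, 1L), ns * nsamp, TRUE), ns, nsamp)
      miss <- matrix(runif(ns * nsamp) < 0.1, ns, nsamp)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      gt <- toy_gt(a1, a2)
      expect_equal(nucleotide_diversity(allele_counts(gt), 100),
                   oracle_pi(gt, 100), tolerance = 1e-12)
    }
  })
})

test_that("Watterson's theta follows the harmonic-number formula", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(11, 4, 100), 11 / (11 / 6) / 100)  # a_4 = 11/6
  expect_equal(watterson_theta(11, 4, 100), 0.06)
  expect_equal(watterson_theta(50, 20, 200), watterson_theta(50, 20, 100) / 2)
  expect_error(watterson_theta(5, 1, 100), "two chromosomes")
})

test_that("Tajima's D equals the independent oracle to 1e-10", {
  # hand-sized toy: n = 10, counts {(1,9) x 3, (5,5) x 1}
  counts <- rbind(matrix(rep(c(9L, 1L, 0L, 0L), 3), 3, byrow = TRUE),
                  c(5L, 5L, 0L, 0L))
  d_pkg <- tajimas_d(counts, 10)
  d_oracle <- oracle_tajimas_d(counts_to_chrom_matrix(counts))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-10)

  # random configurations
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(c(6L, 10L, 16L), 1)
      s <- sample(10:80, 1)
      counts <- neutral_sfs_counts(s, n)
      expect_equal(tajimas_d(counts, n),
                   oracle_tajimas_d(counts_to_chrom_matrix(counts)),
                   tolerance = 1e-10)
    }
  })

  # excess of rare variants drives D negative
  sing <- cbind(rep(39L, 50), rep(1L, 50), 0L, 0L)
  expect_lt(tajimas_d(sing, 40), 0)
  # S = 0 is undefined, never zero
  expect_true(is.na(tajimas_d(cbind(10L, 0L, 0L, 0L)[rep(1, 5), ], 10)))
  expect_error(tajimas_d(rbind(c(5L, 5L, 0L, 0L), c(4L, 5L, 0L, 0L)), 10),
               "same chromosome count")
})

test_that("pi and Watterson's theta agree under the neutral SFS", {
  withr::with_seed(29, {
    n <- 56  # 28 diploids
    s <- 50000
    counts <- neutral_sfs_counts(s, n)
    L <- 1e6
    pi <- nucleotide_diversity(counts, L)
    tw <- watterson_theta(s, n, L)
    expect_lt(abs(pi - tw) / tw, 0.05)
  })
})

test_that("downsampling yields equal-size seeded subsets", {
  assignment <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:283),
    population = rep(c("TD", "PV", "RK1", "RK2"), c(41, 156, 58, 28)))
  down <- downsample_populations(assignment, seed = 3)
  expect_true(all(table(down$population) == 28))
  expect_equal(nrow(down), 4 * 28)
  expect_identical(down, downsample_populations(assignment, seed = 3))
  # identity subset when target equals population size
  one <- assignment |> dplyr::filter(population == "RK2")
  expect_setequal(downsample_populations(one, target = 28, seed = 1)$sample_id,
                  one$sample_id)
  expect_error(downsample_populations(assignment, target = 50), "exceeds")
})

test_that("bootstrap CIs behave: zero width for constants, deterministic, calibrated", {
  ids <- sprintf("s%d", 1:20)
  ci <- bootstrap_ci(function(x) 1.5, ids, n_boot = 50, seed = 2)
  expect_equal(ci$ci_lo, 1.5)
  expect_equal(ci$ci_hi, 1.5)
  expect_true(ci$reliable)
  stat <- function(x) mean(nchar(x))
  expect_identical(bootstrap_ci(stat, ids, seed = 5),
                   bootstrap_ci(stat, ids, seed = 5))
  # coverage: for a mean-like statistic (unbiased under resampling) the
  # percentile interval contains the point estimate in every seeded run
  withr::with_seed(8, {
    contained <- vapply(1:20, function(r) {
      vals <- stats::setNames(rnorm(25), sprintf("t%d", 1:25))
      point <- mean(vals)
      ci <- bootstrap_ci(function(x) mean(vals[x]), names(vals),
                         n_boot = 100, seed = r)
      ci$ci_lo <= point && point <= ci$ci_hi
    }, logical(1))
    expect_gte(mean(contained), 0.95)
  })
  # unreliability flag when the statistic is mostly undefined
  flaky <- function(x) NA_real_
  expect_false(bootstrap_ci(flaky, ids, n_boot = 20, seed = 1)$reliable)
})

test_that("population diversity recovers a planted diversity ordering", {
  # population B simulated with lower diversity via stronger drift (higher F
  # pushes frequencies toward fixation, reducing heterozygosity)
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 1e6,
                       n_sites_per_contig = 6000,
                       pop_names = c("A", "B"), pop_sizes = c(30, 30),
                       pop_f = c(0.02, 0.4), multiallelic_fraction = 0,
                       n_outliers = 0, n_mislabeled = 0,
                       mislabel_from = "B", mislabel_as = "A",
                       missing_rate = 0, gene_fraction = 0, seed = 37)
  co <- simulate_cohort(cfg)
  assignment <- co$truth$samples |>
    dplyr::transmute(sample_id, population = true_population)
  div <- population_diversity(co$genotypes, assignment, accessible = 1e6,
                              n_boot = 30, seed = 7)
  expect_equal(nrow(div), 6L)
  expect_true(all(div$ci_lo <= div$ci_hi))
  # the sample bootstrap of pi/theta_w carries a small downward resampling
  # bias (duplicated individuals share genotypes), so the percentile interval
  # sits within a few percent of the point rather than guaranteeing containment
  pt <- div[div$statistic %in% c("pi", "theta_w"), ]
  expect_true(all(pt$ci_lo <= pt$estimate & pt$ci_hi >= pt$estimate * 0.90))
  expect_true(all(is.finite(div$ci_lo) & is.finite(div$ci_hi)))
  pi_a <- div$estimate[div$population == "A" & div$statistic == "pi"]
  pi_b <- div$estimate[div$population == "B" & div$statistic == "pi"]
  tw_a <- div$estimate[div$population == "A" & div$statistic == "theta_w"]
  tw_b <- div$estimate[div$population == "B" & div$statistic == "theta_w"]
  expect_lt(pi_b, pi_a)
  expect_lt(tw_b, tw_a)
  expect_true(all(div$estimate[div$statistic %in% c("pi", "theta_w")] >= 0))
  expect_equal(unique(div$n_samples), 30L)
  expect_s3_class(plot_diversity(div), "ggplot")
})
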
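test_that("reference building is deterministic and gene models are well-formed", {
  cfg <- cohort_config(n_contigs = 2, contig_length_bp = 1e5,
                       n_sites_per_contig = 500, gene_fraction = 0.3, seed = 5)
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(as.character(ref1$sequences), as.character(ref2$sequences))
  expect_identical(ref1$genes, ref2$genes)

  g <- ref1$genes
  expect_true(all(g$start >= 1 & g$end <= 1e5))
  expect_true(all((g$end - g$start + 1) %% 3 == 0))
  expect_true(all(g$strand %in% c("+", "-")))
  # non-overlapping within contig
  by_ctg <- split(g, g$contig)
  for (d in by_ctg) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }

  # byte-identical files from a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference(ref1, file.path(d1, "r.fa"), file.path(d1, "r.gff3"))
  write_reference(ref2, file.path(d2, "r.fa"), file.path(d2, "r.gff3"))
  expect_identical(readLines(file.path(d1, "r.fa")), readLines(file.path(d2, "r.fa")))
  expect_identical(readLines(file.path(d1, "r.gff3")), readLines(file.path(d2, "r.gff3")))
})

test_that("zero gene density yields a bare reference", {
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 5e4,
                       n_sites_per_contig = 100, gene_fraction = 0, seed = 2)
  ref <- build_reference(cfg)
  expect_equal(length(ref$sequences), 1L)
  expect_equal(nrow(ref$genes), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(pop_f = c(0.5, 0.5, 0.5, 1.2)), "0, 1")
  expect_error(cohort_config(missing_rate = 1.2), "proportions")
  expect_error(cohort_config(
    sweep_specs = tibble::tibble(contig = "ctg01", start_bp = 1, end_bp = 100,
                                 target_population = "TD", f_sweep = 0.01)),
    "f_sweep")
  expect_error(cohort_config(pop_sizes = c(10, 10)), "equal length")
  cfg <- cohort_config()
  expect_equal(total_samples(cfg), 302L)
  expect_equal(sum(cfg$pop_sizes), 283L)
})

test_that("cohort truth plants exactly the configured mislabels and outliers", {
  cfg <- small_cohort_config()
  cfg2 <- cohort_config(n_contigs = 1, contig_length_bp = 2e5,
                        n_sites_per_contig = 500,
                        pop_names = c("A", "B"), pop_sizes = c(10, 12),
                        pop_f = c(0.02, 0.02), n_outliers = 3, n_mislabeled = 4,
                        mislabel_from = "B", mislabel_as = "A",
                        gene_fraction = 0, seed = 9)
  co <- simulate_cohort(cfg2)
  tr <- co$truth$samples
  expect_equal(nrow(tr), 10 + 12 + 3 + 4)
  expect_equal(sum(tr$is_mislabeled), 4L)
  expect_equal(sum(tr$is_outlier), 3L)
  expect_true(all(tr$recorded_population[tr$is_mislabeled] == "A"))
  expect_true(all(tr$true_population[tr$is_mislabeled] == "B"))
  expect_equal(sum(!tr$is_outlier & tr$true_population == "A"), 10L)
})

test_that("genotype simulation is reproducible for a fixed seed", {
  cfg <- small_cohort_config()
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$genotypes$allele1, co2$genotypes$allele1)
  expect_identical(co1$genotypes$allele2, co2$genotypes$allele2)
  expect_identical(co1$genotypes$sites, co2$genotypes$sites)
})

test_that("multiallelic fraction matches the configuration", {
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 2e6,
                       n_sites_per_contig = 12000,
                       pop_names = c("A", "B"), pop_sizes = c(30, 30),
                       pop_f = c(0.02, 0.02), multiallelic_fraction = 0.134,
                       n_outliers = 0, n_mislabeled = 0, missing_rate = 0,
                       mislabel_from = "B", mislabel_as = "A",
                       gene_fraction = 0, seed = 13)
  co <- simulate_cohort(cfg)
  census <- classify_sites(co$genotypes)
  expect_gt(census$segregating, 10000)
  expect_lt(abs(census$multiallelic_fraction - 0.134), 0.02)
})

test_that("at F = 0 population frequencies converge to the ancestral frequency", {
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 1e6,
                       n_sites_per_contig = 2000,
                       pop_names = c("A", "B"), pop_sizes = c(150, 150),
                       pop_f = c(0, 0), multiallelic_fraction = 0,
                       n_outliers = 0, n_mislabeled = 0, missing_rate = 0,
                       mislabel_from = "B", mislabel_as = "A",
                       gene_fraction = 0, seed = 21)
  co <- simulate_cohort(cfg)
  tr <- co$truth$samples
  fa <- allele_counts(co$genotypes, tr$sample_id[tr$true_population == "A"])
  fb <- allele_counts(co$genotypes, tr$sample_id[tr$true_population == "B"])
  pa <- fa[, 2] / rowSums(fa)
  pb <- fb[, 2] / rowSums(fb)
  # both populations sample the same underlying frequency; the expected mean
  # absolute deviation from pure binomial noise at n = 300 chromosomes is
  # sigma * sqrt(2/pi) <= sqrt(2 * 0.25 / 300) * 0.8 = 0.033
  expect_lt(mean(abs(pa - pb)), 0.04)
})

test_that("planted outliers are geometrically isolated from every population", {
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 1e6,
                       n_sites_per_contig = 4000,
                       pop_names = c("A", "B"), pop_sizes = c(15, 15),
                       pop_f = c(0.02, 0.04), n_outliers = 3, n_mislabeled = 0,
                       mislabel_from = "B", mislabel_as = "A",
                       missing_rate = 0, gene_fraction = 0, seed = 31)
  co <- simulate_cohort(cfg)
  tr <- co$truth$samples
  d <- dosage_matrix(co$genotypes)
  centroids <- rbind(colMeans(d[tr$true_population == "A", ]),
                     colMeans(d[tr$true_population == "B", ]))
  dist_to <- function(rows, centroid) {
    sqrt(rowSums(sweep(d[rows, , drop = FALSE], 2, centroid)^2))
  }
  max_within <- max(dist_to(which(tr$true_population == "A"), centroids[1, ]),
                    dist_to(which(tr$true_population == "B"), centroids[2, ]))
  out_rows <- which(tr$is_outlier)
  min_outlier <- min(dist_to(out_rows, centroids[1, ]),
                     dist_to(out_rows, centroids[2, ]))
  expect_gt(min_outlier, max_within)
})

test_that("sweep intervals inflate local windowed differentiation", {
  sweeps <- tibble::tibble(contig = "ctg01", start_bp = 2e5, end_bp = 3.5e5,
                           target_population = "A", f_sweep = 0.5)
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 1e6,
                       n_sites_per_contig = 8000,
                       pop_names = c("A", "B"), pop_sizes = c(25, 25),
                       pop_f = c(0.01, 0.01), sweep_specs = sweeps,
                       multiallelic_fraction = 0, n_outliers = 0,
                       n_mislabeled = 0, mislabel_from = "B", mislabel_as = "A",
                       missing_rate = 0, gene_fraction = 0, seed = 8)
  co <- simulate_cohort(cfg)
  tr <- co$truth$samples
  comp <- hudson_fst_components(co$genotypes,
                                tr$sample_id[tr$true_population == "A"],
                                tr$sample_id[tr$true_population == "B"])
  win <- windowed_fst(comp, mode = "bp", window_bp = 20000)
  inside <- win$fst[win$start >= 2e5 & win$end <= 3.5e5]
  expect_gt(max(inside), 5 * mean(win$fst))
})
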
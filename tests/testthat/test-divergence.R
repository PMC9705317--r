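test_that("Hudson components match hand arithmetic and the site oracle", {
  # counts 8/10 vs 2/10: num 0.32444..., den 0.68, ratio 0.47712...
  a1_p1 <- matrix(c(1L, 1L, 1L, 1L, 1L), 1)  # 5 samples
  a2_p1 <- matrix(c(1L, 1L, 1L, 0L, 0L), 1)  # 8 alt of 10
  a1_p2 <- matrix(c(1L, 0L, 0L, 0L, 0L), 1)
  a2_p2 <- matrix(c(1L, 0L, 0L, 0L, 0L), 1)  # 2 alt of 10
  gt <- toy_gt(cbind(a1_p1, a1_p2), cbind(a2_p1, a2_p2))
  comp <- hudson_fst_components(gt, 1:5, 6:10)
  expect_equal(comp$num, 0.36 - 2 * (0.8 * 0.2 / 9), tolerance = 1e-10)
  expect_equal(comp$num, 0.32444, tolerance = 1e-4)
  expect_equal(comp$den, 0.68, tolerance = 1e-10)
  expect_equal(comp$num / comp$den, 0.47712, tolerance = 1e-4)
  o <- oracle_hudson_site(c(2L, 8L, 0L, 0L), c(8L, 2L, 0L, 0L))
  expect_equal(comp$num, unname(o["num"]))
  expect_equal(comp$den, unname(o["den"]))

  # fixed difference: (1, 1), site Fst 1
  gt_fix <- toy_gt(cbind(matrix(1L, 1, 4), matrix(0L, 1, 4)),
                   cbind(matrix(1L, 1, 4), matrix(0L, 1, 4)))
  cf <- hudson_fst_components(gt_fix, 1:4, 5:8)
  expect_equal(cf$num, 1)
  expect_equal(cf$den, 1)

  # identical frequencies: the within-population correction makes the
  # numerator negative: p1 = p2 = 0.5, n1 = n2 = 10 (five heterozygotes each)
  gt_h <- toy_gt(matrix(1L, 1, 10), matrix(0L, 1, 10))
  ch <- hudson_fst_components(gt_h, 1:5, 6:10)
  expect_equal(ch$num, -2 * 0.25 / 9, tolerance = 1e-12)

  # monomorphic-in-both and multiallelic sites are excluded
  a_mono <- matrix(0L, 1, 10)
  a_tri <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L), 1)
  gt_mix <- toy_gt(rbind(a_mono, a_tri), rbind(a_mono, a_tri))
  expect_equal(nrow(hudson_fst_components(gt_mix, 1:5, 6:10)), 0L)
})

test_that("windowed Fst is a ratio of sums, bounded by 1, label-symmetric", {
  co <- simulate_cohort(small_cohort_config())
  tr <- co$truth$samples
  ids_a <- tr$sample_id[tr$true_population == "A"]
  ids_b <- tr$sample_id[tr$true_population == "B"]
  comp <- hudson_fst_components(co$genotypes, ids_a, ids_b)
  win <- windowed_fst(comp, mode = "snp", window_snps = 200)
  expect_true(all(win$n_snps == 200))
  expect_true(all(win$fst <= 1))
  expect_true(all(diff(win$start) > 0))
  # swap population labels: identical windows
  comp_sw <- hudson_fst_components(co$genotypes, ids_b, ids_a)
  win_sw <- windowed_fst(comp_sw, mode = "snp", window_snps = 200)
  expect_equal(win$fst, win_sw$fst, tolerance = 1e-12)
  # manual ratio-of-sums for the first window
  first <- comp |> dplyr::slice(1:200)
  expect_equal(win$fst[1], sum(first$num) / sum(first$den), tolerance = 1e-12)

  # positional windows tile half-open intervals and drop empty windows
  winbp <- windowed_fst(comp, mode = "bp", window_bp = 20000)
  expect_true(all(winbp$end - winbp$start == 20000))
  expect_true(all(winbp$n_snps > 0))

  # all-fixed-difference series: every window Fst = 1
  nfix <- 400
  gt_fix <- toy_gt(cbind(matrix(1L, nfix, 4), matrix(0L, nfix, 4)),
                   cbind(matrix(1L, nfix, 4), matrix(0L, nfix, 4)))
  cfx <- hudson_fst_components(gt_fix, 1:4, 5:8)
  wfx <- windowed_fst(cfx, mode = "snp", window_snps = 100)
  expect_equal(wfx$fst, rep(1, 4))
})

test_that("the average Fst matrix is symmetric with zero diagonal", {
  cfg <- cohort_config(n_contigs = 1, contig_length_bp = 5e5,
                       n_sites_per_contig = 4000,
                       pop_names = c("A", "B", "C"), pop_sizes = c(20, 20, 20),
                       pop_f = c(0.003, 0.003, 0.055), multiallelic_fraction = 0,
                       n_outliers = 0, n_mislabeled = 0,
                       mislabel_from = "B", mislabel_as = "A",
                       missing_rate = 0, gene_fraction = 0, seed = 41)
  co <- simulate_cohort(cfg)
  assignment <- co$truth$samples |>
    dplyr::transmute(sample_id, population = true_population)
  m <- average_fst_matrix(co$genotypes, assignment, "ctg01")
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 3))
  # the strongly drifted population is about tenfold more differentiated
  expect_gt(m["A", "C"] / m["A", "B"], 5)
  expect_error(average_fst_matrix(co$genotypes, assignment, "nope"), "absent")

  # a population split at random against itself is undifferentiated
  ids <- assignment$sample_id[assignment$population == "B"]
  split_asg <- tibble::tibble(
    sample_id = ids, population = rep(c("B1", "B2"), length.out = length(ids)))
  ms <- average_fst_matrix(co$genotypes, split_asg, "ctg01")
  expect_lt(abs(ms["B1", "B2"]), 0.01)
})

test_that("signal detection applies the run-length and threshold rules", {
  flat <- tibble::tibble(contig = "c1", start = (0:19) * 1e4,
                         end = (1:20) * 1e4, midpoint = (0:19) * 1e4 + 5e3,
                         n_snps = 1000, fst = 0.05)
  expect_equal(nrow(detect_signals(flat)), 0L)

  mk_series <- function(vals) {
    tibble::tibble(contig = "c1", start = (seq_along(vals) - 1) * 1e4,
                   end = seq_along(vals) * 1e4,
                   midpoint = (seq_along(vals) - 1) * 1e4 + 5e3,
                   n_snps = 1000, fst = vals)
  }
  # run of 4 above-threshold windows: too short
  v4 <- c(rep(0.01, 40), rep(0.5, 4), rep(0.01, 16))
  expect_equal(nrow(detect_signals(mk_series(v4), min_run = 5)), 0L)
  # run of 8: one signal with the right peak and count
  v8 <- c(rep(0.01, 40), 0.3, 0.35, 0.4, 0.62, 0.5, 0.45, 0.33, 0.31,
          rep(0.01, 12))
  sig <- detect_signals(mk_series(v8), min_run = 5)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$n_windows_above, 8L)
  expect_equal(sig$peak_fst, 0.62)
  expect_equal(sig$peak_midpoint, mk_series(v8)$midpoint[44])
  # one below-threshold window splits a run at the default gap tolerance
  vsplit <- c(rep(0.01, 40), rep(0.5, 4), 0.01, rep(0.5, 4), rep(0.01, 11))
  expect_equal(nrow(detect_signals(mk_series(vsplit), min_run = 5)), 0L)
  expect_equal(nrow(detect_signals(mk_series(vsplit), min_run = 5, max_gap = 1)), 1L)
  expect_error(detect_signals(flat[0, ]), "empty")
})

test_that("signal ranking is total and invariant to contig order", {
  two <- dplyr::bind_rows(
    tibble::tibble(contig = "c2", start = (0:59) * 1e4, end = (1:60) * 1e4,
                   midpoint = (0:59) * 1e4 + 5e3, n_snps = 1000,
                   fst = c(rep(0.01, 20), rep(0.45, 6), rep(0.01, 34))),
    tibble::tibble(contig = "c1", start = (0:59) * 1e4, end = (1:60) * 1e4,
                   midpoint = (0:59) * 1e4 + 5e3, n_snps = 1000,
                   fst = c(rep(0.01, 5), rep(0.6, 7), rep(0.01, 48))))
  sig <- detect_signals(two, min_run = 5)
  expect_equal(sig$rank, 1:2)
  expect_equal(sig$contig, c("c1", "c2"))
  sig_rev <- detect_signals(two |> dplyr::arrange(contig, start), min_run = 5)
  expect_equal(sig, sig_rev)
})

test_that("gene annotation respects the inclusive 100-kb radius", {
  sig <- tibble::tibble(rank = 1L, contig = "c1", run_start = 5.9e6,
                        run_end = 6.1e6, n_windows_above = 6L,
                        peak_midpoint = 6.0e6, peak_mbp = 6, peak_fst = 0.5,
                        threshold = 0.1)
  genes <- tibble::tibble(
    gene_id = c("g_overlap", "g_edge", "g_in", "g_out"),
    contig = "c1",
    start = c(5.99e6, 6.1e6, 5.92e6, 6.15e6),
    end = c(6.01e6, 6.2e6, 5.95e6, 6.20e6),
    product = letters[1:4])
  # g_edge starts exactly radius away; g_in ends 50 kb left; g_out starts
  # 150 kb right of the peak
  ann <- annotate_signals(sig, genes, radius = 1e5)
  hits <- ann$genes[[1]]
  expect_setequal(hits$gene_id, c("g_overlap", "g_edge", "g_in"))
  expect_equal(hits$distance_bp[hits$gene_id == "g_overlap"], 0)
  expect_equal(hits$distance_bp[hits$gene_id == "g_in"], 5.95e6 - 6.0e6)
  expect_equal(hits$distance_bp[hits$gene_id == "g_edge"], 1e5)
  expect_equal(ann$n_genes, 3L)
})
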
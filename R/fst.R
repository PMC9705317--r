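#' Per-site Hudson Fst components
#'
#' For each biallelic site with at least two non-missing chromosomes in both
#' populations, computes the Hudson estimator's numerator and denominator
#' (Bhatia et al. parameterisation): with `p_k` the alternate-allele
#' frequency and `n_k` the chromosome count in population `k`,
#' `num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `den = p1(1-p2) + p2(1-p1)`. Sites failing the preconditions (not
#' biallelic, too few chromosomes) are skipped; sites monomorphic for the
#' same allele in both populations have zero denominator and are excluded
#' from ratios downstream.
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples1,samples2 Sample id (or index) vectors for the two
#'   populations.
#' @return Tibble: `site_index`, `contig`, `pos`, `num`, `den`. Only usable
#'   sites are returned.
#' @export
hudson_fst_components <- function(genotypes, samples1, samples2) {
  c1 <- allele_counts(genotypes, samples1)
  c2 <- allele_counts(genotypes, samples2)
  tot <- c1 + c2
  k <- n_alleles(tot)
  n1 <- rowSums(c1)
  n2 <- rowSums(c2)
  usable <- k == 2L & n1 >= 2L & n2 >= 2L
  # the "alternate" allele of the biallelic pair: the larger-index allele of
  # the two observed in the union (the reference allele when present is 0)
  idx <- which(usable)
  if (length(idx) == 0) {
    return(tibble(site_index = integer(), contig = character(),
                  pos = integer(), num = double(), den = double()))
  }
  alt_idx <- max.col(tot[idx, , drop = FALSE] > 0L, ties.method = "last")
  pick <- cbind(idx, alt_idx)
  p1 <- c1[pick] / n1[idx]
  p2 <- c2[pick] / n2[idx]
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n1[idx] - 1) -
    p2 * (1 - p2) / (n2[idx] - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(site_index = idx,
         contig = genotypes$sites$contig[idx],
         pos = genotypes$sites$pos[idx],
         num = num, den = den) |>
    filter(.data$den > 0)
}

#' Windowed Fst as a ratio of sums
#'
#' Combines per-site Hudson components into windows, either positional
#' (tiling `[0, contig length)` half-open, default 20 kb) or SNP-count
#' (consecutive non-overlapping blocks of exactly `window_snps` usable SNPs;
#' the final partial block is dropped). Window Fst is the ratio of summed
#' numerators to summed denominators. Positional windows with no usable site
#' are omitted.
#'
#' @param components Output of [hudson_fst_components()].
#' @param mode `"snp"` (default) or `"bp"`.
#' @param window_snps SNPs per window in `"snp"` mode (default 1000).
#' @param window_bp Window width in `"bp"` mode (default 20000).
#' @param contig_lengths Optional named vector used to tile positional
#'   windows to the contig end.
#' @return A `windowed_series` tibble: `contig`, `start`, `end` (0-based
#'   half-open), `midpoint`, `n_snps`, `fst`.
#' @export
windowed_fst <- function(components, mode = c("snp", "bp"),
                         window_snps = 1000, window_bp = 20000,
                         contig_lengths = NULL) {
  mode <- match.arg(mode)
  comp <- as_tibble(components) |> arrange(.data$contig, .data$pos)
  out <- comp |>
    group_by(.data$contig) |>
    group_modify(function(d, g) {
      if (mode == "snp") {
        n_win <- nrow(d) %/% window_snps
        if (n_win == 0) return(tibble())
        d <- d[seq_len(n_win * window_snps), ]
        w <- rep(seq_len(n_win), each = window_snps)
      } else {
        w <- d$pos %/% window_bp   # positions are 1-based; windows half-open
      }
      d |>
        mutate(.win = w) |>
        group_by(.data$.win) |>
        summarise(
          start = if (mode == "bp") .data$.win[1] * window_bp else min(.data$pos) - 1L,
          end = if (mode == "bp") (.data$.win[1] + 1) * window_bp else max(.data$pos),
          n_snps = dplyr::n(),
          fst = sum(.data$num) / sum(.data$den),
          .groups = "drop") |>
        select(-".win")
    }) |>
    ungroup() |>
    mutate(midpoint = (.data$start + .data$end) / 2) |>
    select("contig", "start", "end", "midpoint", "n_snps", "fst") |>
    arrange(.data$contig, .data$start)
  class(out) <- c("windowed_series", class(out))
  out
}

#' Plot a windowed Fst series along the genome
#'
#' @param object A `windowed_series` from [windowed_fst()].
#' @param threshold Optional horizontal reference line (e.g. the
#'   signal-detection threshold).
#' @param ... Unused.
#' @return A ggplot faceted by contig.
#' @export
autoplot.windowed_series <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$midpoint / 1e6, .data$fst)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contig), scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "Fst") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Average pairwise Fst matrix over one contig
#'
#' For every population pair, the mean of 20-kb-window Fst values over the
#' named contig; the matrix is symmetric with a zero diagonal.
#'
#' @param genotypes A [genotype_matrix()].
#' @param assignment Tibble `sample_id`, `population`.
#' @param contig Contig name.
#' @param window_bp Positional window width (default 20000).
#' @param contig_length Optional contig length for window tiling.
#' @return Symmetric numeric matrix with population dimnames.
#' @export
average_fst_matrix <- function(genotypes, assignment, contig,
                               window_bp = 20000, contig_length = NULL) {
  if (!contig %in% genotypes$sites$contig) {
    abort(sprintf("contig %s absent from the genotype matrix", contig))
  }
  assignment <- as_tibble(assignment)
  pops <- sort(unique(assignment$population))
  if (length(pops) < 2) abort("need at least two populations")
  g <- gt_subset(genotypes, sites = which(genotypes$sites$contig == contig))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      comp <- hudson_fst_components(
        g,
        assignment$sample_id[assignment$population == pops[i]],
        assignment$sample_id[assignment$population == pops[j]])
      win <- windowed_fst(comp, mode = "bp", window_bp = window_bp,
                          contig_lengths = contig_length)
      m[i, j] <- m[j, i] <- mean(win$fst)
    }
  }
  m
}

#' Detect selection signals in a windowed Fst series
#'
#' The detection threshold is `threshold_mult` times the genome-wide mean of
#' all window values in the series. Candidate runs are maximal sets of
#' consecutive above-threshold windows within a contig (a configurable gap
#' tolerance defaults to 0: one below-threshold window splits a run); runs of
#' at least `min_run` windows become signals, each summarised by its peak
#' window (maximum Fst). Signals are ranked by peak Fst descending, ties
#' broken by contig then position.
#'
#' @param series A `windowed_series` covering all scanned contigs for one
#'   population pair.
#' @param min_run Minimum run length in windows (default 5).
#' @param threshold_mult Multiple of the genome-wide mean (default 2).
#' @param max_gap Below-threshold windows tolerated inside a run (default 0).
#' @return Tibble: `rank`, `contig`, `run_start`, `run_end` (bp bounds of the
#'   run), `n_windows_above`, `peak_midpoint`, `peak_mbp` (midpoint in Mbp,
#'   2 decimals), `peak_fst`, `threshold`.
#' @export
detect_signals <- function(series, min_run = 5, threshold_mult = 2.0,
                           max_gap = 0) {
  if (nrow(series) == 0) abort("empty windowed series")
  threshold <- threshold_mult * mean(series$fst)
  sig <- series |>
    group_by(.data$contig) |>
    arrange(.data$start, .by_group = TRUE) |>
    group_modify(function(d, g) {
      above <- d$fst > threshold
      if (!any(above)) return(tibble())
      run_id <- run_segments(above, max_gap)
      d |>
        mutate(.run = run_id) |>
        filter(!is.na(.data$.run)) |>
        group_by(.data$.run) |>
        summarise(
          run_start = min(.data$start), run_end = max(.data$end),
          n_windows_above = sum(.data$fst > threshold),
          peak_midpoint = .data$midpoint[which.max(.data$fst)],
          peak_fst = max(.data$fst), .groups = "drop") |>
        filter(.data$n_windows_above >= min_run) |>
        select(-".run")
    }) |>
    ungroup()
  if (nrow(sig) == 0) {
    return(tibble(rank = integer(), contig = character(), run_start = double(),
                  run_end = double(), n_windows_above = integer(),
                  peak_midpoint = double(), peak_mbp = double(),
                  peak_fst = double(), threshold = double()))
  }
  sig |>
    arrange(desc(.data$peak_fst), .data$contig, .data$peak_midpoint) |>
    mutate(rank = dplyr::row_number(),
           peak_mbp = round(.data$peak_midpoint / 1e6, 2),
           threshold = threshold) |>
    select("rank", "contig", "run_start", "run_end", "n_windows_above",
           "peak_midpoint", "peak_mbp", "peak_fst", "threshold")
}

# Label maximal runs of TRUE, allowing up to max_gap interior FALSEs; NA
# outside runs. Two above-threshold windows belong to the same run iff the
# number of below-threshold windows between them is <= max_gap; gap windows
# between same-run members inherit the run id.
run_segments <- function(above, max_gap = 0) {
  n <- length(above)
  run <- rep(NA_integer_, n)
  hits <- which(above)
  if (length(hits) == 0) return(run)
  cur <- 1L
  run[hits[1]] <- cur
  for (j in seq_along(hits)[-1]) {
    gap <- hits[j] - hits[j - 1] - 1L
    if (gap > max_gap) cur <- cur + 1L
    run[hits[j]] <- cur
    if (gap > 0 && gap <= max_gap) run[(hits[j - 1] + 1L):(hits[j] - 1L)] <- cur
  }
  run
}

#' Attach candidate genes to selection signals
#'
#' Genes whose interval overlaps `[peak - radius, peak + radius]` (inclusive
#' boundaries) are attached to each signal with the signed distance from the
#' peak to the nearest feature edge (0 when the gene overlaps the peak;
#' negative when the gene lies left of the peak).
#'
#' @param signals Output of [detect_signals()].
#' @param genes Tibble of gene features: `gene_id`, `contig`, `start`, `end`,
#'   optionally `product`.
#' @param radius Search radius in bp (default 100000).
#' @return `signals` with a `genes` list column (tibbles: `gene_id`,
#'   `product`, `distance_bp`) and an `n_genes` count.
#' @export
annotate_signals <- function(signals, genes, radius = 100000) {
  genes <- as_tibble(genes)
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  hits <- purrr::map(seq_len(nrow(signals)), function(i) {
    sg <- signals[i, ]
    g <- genes |> filter(.data$contig == sg$contig)
    if (nrow(g) == 0) {
      inform(sprintf("contig %s absent from annotation", sg$contig))
      return(tibble(gene_id = character(), product = character(),
                    distance_bp = double()))
    }
    g |>
      filter(.data$end >= sg$peak_midpoint - radius,
             .data$start <= sg$peak_midpoint + radius) |>
      mutate(distance_bp = dplyr::case_when(
        .data$start <= sg$peak_midpoint & .data$end >= sg$peak_midpoint ~ 0,
        .data$end < sg$peak_midpoint ~ .data$end - sg$peak_midpoint,
        TRUE ~ .data$start - sg$peak_midpoint)) |>
      arrange(abs(.data$distance_bp)) |>
      select("gene_id", "product", "distance_bp")
  })
  signals |>
    mutate(genes = hits, n_genes = purrr::map_int(hits, nrow))
}

#' Genome scan for selection between two populations
#'
#' Convenience wrapper: Hudson components on contigs above a minimum length,
#' 1000-SNP windows, genome-wide mean threshold, run detection, gene
#' annotation.
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples1,samples2 Sample vectors of the two populations.
#' @param genes Gene feature tibble for annotation (optional).
#' @param contig_lengths Named vector of contig lengths; only contigs of at
#'   least `min_contig_bp` are scanned.
#' @param min_contig_bp Minimum contig length (default 2e6).
#' @param window_snps SNPs per window (default 1000).
#' @param min_run,threshold_mult,max_gap See [detect_signals()].
#' @param radius Gene search radius (default 100000).
#' @return List with `windows` (the series), `signals` (annotated tibble) and
#'   `genome_mean` Fst.
#' @export
fst_scan <- function(genotypes, samples1, samples2, genes = NULL,
                     contig_lengths = NULL, min_contig_bp = 2e6,
                     window_snps = 1000, min_run = 5, threshold_mult = 2.0,
                     max_gap = 0, radius = 100000) {
  g <- genotypes
  if (!is.null(contig_lengths)) {
    keep <- names(contig_lengths)[contig_lengths >= min_contig_bp]
    g <- gt_subset(g, sites = which(g$sites$contig %in% keep))
  }
  comp <- hudson_fst_components(g, samples1, samples2)
  win <- windowed_fst(comp, mode = "snp", window_snps = window_snps)
  signals <- detect_signals(win, min_run = min_run,
                            threshold_mult = threshold_mult, max_gap = max_gap)
  if (!is.null(genes) && nrow(signals) > 0) {
    signals <- annotate_signals(signals, genes, radius = radius)
  }
  list(windows = win, signals = signals, genome_mean = mean(win$fst))
}
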
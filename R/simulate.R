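#' Simulate structured diploid genotypes under the Balding-Nichols model
#'
#' For each variant site an ancestral allele frequency `p` is drawn uniformly
#' on `[0.05, 0.95]`; each population draws its own frequency from a Beta
#' distribution with mean `p` and variance `p(1-p)F` (so the population's
#' divergence parameter `F` equals its expected Fst contribution), and diploid
#' genotypes are binomial draws from that frequency. Planted
#' local-differentiation sweeps replace the target population's `F` by
#' `f_sweep` inside the sweep interval; each isolated outlier is drawn from
#' its own private population with divergence `outlier_f`; mislabelled
#' samples are genetically drawn from `mislabel_from` but recorded with the
#' collection metadata of `mislabel_as`. A configured fraction of segregating
#' sites is made multiallelic by splitting chromosomes carrying the alternate
#' allele across two (or, for the quadriallelic fraction, three) distinct
#' alternates, conserving the total allele count. Missing genotypes are
#' planted at `missing_rate`.
#'
#' @param cfg A [cohort_config()].
#' @param reference A `cohort_reference` from [build_reference()]; reference
#'   bases at variant positions are read from it.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (a `cohort_truth`: per-sample tibble plus sweep table).
#' @export
simulate_genotypes <- function(cfg, reference) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(reference, "cohort_reference"))
  contigs <- names(reference$sequences)
  truth <- make_cohort_truth(cfg)
  n_tot <- nrow(truth$samples)

  # sample columns grouped by drawing unit: populations (incl. mislabelled
  # extras appended to their source population), then private outlier units
  unit_of <- truth$samples$true_population
  unit_of[truth$samples$is_outlier] <-
    paste0("outlier_", seq_len(cfg$n_outliers))
  units <- unique(unit_of)
  unit_f <- stats::setNames(rep(cfg$outlier_f, length(units)), units)
  unit_f[cfg$pop_names] <- cfg$pop_f

  per_contig <- purrr::map(seq_along(contigs), function(ci) {
    ctg <- contigs[ci]
    withr::with_seed(substream_seed(cfg$seed, "genotypes", ci), {
      ns <- cfg$n_sites_per_contig
      pos <- sort(sample.int(cfg$contig_length_bp, ns))
      p_anc <- stats::runif(ns, 0.05, 0.95)

      a1 <- matrix(NA_integer_, ns, n_tot)
      a2 <- matrix(NA_integer_, ns, n_tot)
      for (u in units) {
        cols <- which(unit_of == u)
        f <- unname(unit_f[u])
        f_site <- rep(f, ns)
        if (!is.null(cfg$sweep_specs) && u %in% cfg$pop_names) {
          sw <- cfg$sweep_specs |>
            filter(.data$contig == ctg, .data$target_population == u)
          if (nrow(sw) > 0) {
            for (k in seq_len(nrow(sw))) {
              f_site[pos >= sw$start_bp[k] & pos <= sw$end_bp[k]] <- sw$f_sweep[k]
            }
          }
        }
        pk <- p_anc
        var_idx <- which(f_site > 0)
        if (length(var_idx) > 0) {
          fs <- f_site[var_idx]; pa <- p_anc[var_idx]
          pk[var_idx] <- stats::rbeta(length(var_idx),
                                      pa * (1 - fs) / fs,
                                      (1 - pa) * (1 - fs) / fs)
        }
        m <- length(cols)
        a1[, cols] <- stats::rbinom(ns * m, 1L, pk)
        a2[, cols] <- stats::rbinom(ns * m, 1L, pk)
      }

      # reference and alternate bases taken from / consistent with the contig
      ref_base <- strsplit(as.character(
        Biostrings::subseq(reference$sequences[[ci]], 1, cfg$contig_length_bp)
      ), "")[[1]][pos]
      alt_base <- vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1), USE.NAMES = FALSE)
      alts <- as.list(alt_base)

      # split a configured fraction of segregating sites into multiallelics
      alt_count <- rowSums(a1 == 1L) + rowSums(a2 == 1L)
      splittable <- which(alt_count >= 2L)
      n_multi <- round(cfg$multiallelic_fraction * sum(alt_count > 0L))
      if (n_multi > length(splittable)) n_multi <- length(splittable)
      if (n_multi > 0) {
        chosen <- sort(sample(splittable, n_multi))
        make_quad <- stats::runif(n_multi) < cfg$quad_fraction & alt_count[chosen] >= 3L
        for (j in seq_along(chosen)) {
          s <- chosen[j]
          n_alts <- if (make_quad[j]) 3L else 2L
          i1 <- which(a1[s, ] == 1L); i2 <- which(a2[s, ] == 1L)
          k <- length(i1) + length(i2)
          lab <- sample(c(seq_len(n_alts), sample.int(n_alts, k - n_alts, replace = TRUE)))
          if (length(i1) > 0) a1[s, i1] <- lab[seq_along(i1)]
          if (length(i2) > 0) a2[s, i2] <- lab[length(i1) + seq_along(i2)]
          pool <- setdiff(c("A", "C", "G", "T"), ref_base[s])
          alts[[s]] <- c(alts[[s]], sample(setdiff(pool, alts[[s]]), n_alts - 1L))
        }
      }

      if (cfg$missing_rate > 0) {
        miss <- matrix(stats::runif(ns * n_tot) < cfg$missing_rate, ns, n_tot)
        a1[miss] <- NA_integer_
        a2[miss] <- NA_integer_
      }

      list(a1 = a1, a2 = a2,
           sites = tibble(contig = ctg, pos = pos, ref = ref_base, alt = alts))
    })
  })

  gt <- genotype_matrix(
    do.call(rbind, purrr::map(per_contig, "a1")),
    do.call(rbind, purrr::map(per_contig, "a2")),
    purrr::map(per_contig, "sites") |> list_rbind(),
    truth$samples$sample_id
  )
  list(genotypes = gt, truth = truth)
}

# Ground truth for the synthetic cohort: true origin, recorded metadata
# (differs for mislabelled samples), outlier flags, sweep table.
make_cohort_truth <- function(cfg) {
  meta <- population_metadata_table(cfg$pop_names)
  rows <- list()
  for (i in seq_along(cfg$pop_names)) {
    pop <- cfg$pop_names[i]
    rows[[pop]] <- tibble(
      true_population = pop, recorded_population = pop,
      is_outlier = FALSE, is_mislabeled = FALSE
    )[rep(1, cfg$pop_sizes[i]), ]
  }
  if (cfg$n_mislabeled > 0) {
    rows[["mislabeled"]] <- tibble(
      true_population = cfg$mislabel_from, recorded_population = cfg$mislabel_as,
      is_outlier = FALSE, is_mislabeled = TRUE
    )[rep(1, cfg$n_mislabeled), ]
  }
  if (cfg$n_outliers > 0) {
    rows[["outliers"]] <- tibble(
      true_population = "outlier",
      recorded_population = sample_outlier_labels(cfg),
      is_outlier = TRUE, is_mislabeled = FALSE
    )
  }
  samples <- list_rbind(rows) |>
    mutate(sample_id = sprintf("AM%04d", dplyr::row_number()), .before = 1)

  rec <- meta[match(samples$recorded_population, meta$population), ]
  site <- withr::with_seed(substream_seed(cfg$seed, "metadata"), {
    vapply(seq_len(nrow(rec)), function(i) {
      s <- rec$sites[[i]]
      if (length(s) == 1) s else sample(s, 1)
    }, character(1))
  })
  samples <- samples |>
    mutate(recorded_site = site,
           recorded_province = rec$province,
           year = withr::with_seed(substream_seed(cfg$seed, "years"),
                                   sample(c(2010L, 2014L, 2015L, 2016L),
                                          nrow(samples), replace = TRUE)))
  structure(list(samples = samples, sweeps = cfg$sweep_specs %||% tibble()),
            class = "cohort_truth")
}

# Outliers carry plausible (existing) collection metadata: assign each a
# recorded population label proportional to cohort composition.
sample_outlier_labels <- function(cfg) {
  withr::with_seed(substream_seed(cfg$seed, "outlier-labels"), {
    sample(rep(cfg$pop_names, cfg$pop_sizes), cfg$n_outliers)
  })
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d samples (%d mislabeled, %d outliers), %d sweep(s)\n",
              nrow(x$samples), sum(x$samples$is_mislabeled),
              sum(x$samples$is_outlier), nrow(x$sweeps)))
  invisible(x)
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper: [build_reference()] then [simulate_genotypes()].
#'
#' @param cfg A [cohort_config()].
#' @return List with `reference`, `genotypes`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  reference <- build_reference(cfg)
  sim <- simulate_genotypes(cfg, reference)
  list(reference = reference, genotypes = sim$genotypes, truth = sim$truth)
}
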
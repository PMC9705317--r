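#' Configuration for the synthetic cohort generator
#'
#' Describes a structured mosquito cohort under the Balding-Nichols divergence
#' model. The defaults reproduce the study conditions the package is built
#' around: 302 field samples from five Cambodian collection sites, four
#' populations of 41/156/58/28 individuals (TD, PV, RK1, RK2), 9 samples drawn
#' from the RK2-analogue but recorded under Preah Vihear collection metadata,
#' 10 genetically isolated outliers, and ~13.4% multiallelic segregating
#' sites. Per-population divergence parameters `pop_f` are chosen so the
#' realised pairwise Hudson Fst matches the reported scale: ~0.003 between TD
#' and PV and ~0.03 between RK2 and every other population.
#'
#' @param n_contigs Number of reference contigs.
#' @param contig_length_bp Length of each contig in bp.
#' @param n_sites_per_contig Variant sites simulated per contig.
#' @param pop_names Population labels.
#' @param pop_sizes Diploid sample count per population (assigned members).
#' @param pop_f Balding-Nichols divergence parameter per population, each in
#'   `[0, 1)`. Expected pairwise Fst between populations i and j is
#'   `(pop_f[i] + pop_f[j]) / 2`.
#' @param multiallelic_fraction Fraction of segregating sites converted to
#'   multiallelic by splitting the alternate allele.
#' @param quad_fraction Among multiallelic sites, fraction split into three
#'   alternates (quadriallelic) rather than two; default matches the reported
#'   triallelic/quadriallelic ratio.
#' @param sweep_specs Optional tibble of planted local-differentiation sweeps
#'   with columns `contig`, `start_bp`, `end_bp`, `target_population`,
#'   `f_sweep`. Inside the interval the target population's F is replaced by
#'   `f_sweep` (which must exceed every background F).
#' @param n_outliers Isolated outlier individuals, each drawn from its own
#'   private population with divergence `outlier_f`.
#' @param outlier_f Divergence parameter of the outlier draws.
#' @param n_mislabeled Samples drawn from `mislabel_from` but recorded with
#'   the collection metadata of `mislabel_as`. These are extra draws on top of
#'   `pop_sizes`.
#' @param mislabel_from,mislabel_as Population names for the mislabelled group.
#' @param missing_rate Per-genotype missingness rate.
#' @param gene_fraction Approximate fraction of each contig covered by
#'   protein-coding gene models.
#' @param x_contigs Names of contigs to treat as X-linked (excluded from
#'   autosomal analyses); default none.
#' @param seed Integer master seed; all randomness derives substreams from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_contigs = 4,
                          contig_length_bp = 3e6,
                          n_sites_per_contig = 25000,
                          pop_names = c("TD", "PV", "RK1", "RK2"),
                          pop_sizes = c(41, 156, 58, 28),
                          pop_f = c(0.003, 0.003, 0.055, 0.055),
                          multiallelic_fraction = 0.134,
                          quad_fraction = 0.056,
                          sweep_specs = NULL,
                          n_outliers = 10,
                          outlier_f = 0.3,
                          n_mislabeled = 9,
                          mislabel_from = "RK2",
                          mislabel_as = "PV",
                          missing_rate = 0.01,
                          gene_fraction = 0.2,
                          x_contigs = character(0),
                          seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length_bp = as.integer(contig_length_bp),
    n_sites_per_contig = as.integer(n_sites_per_contig),
    pop_names = pop_names,
    pop_sizes = as.integer(pop_sizes),
    pop_f = pop_f,
    multiallelic_fraction = multiallelic_fraction,
    quad_fraction = quad_fraction,
    sweep_specs = if (is.null(sweep_specs)) NULL else as_tibble(sweep_specs),
    n_outliers = as.integer(n_outliers),
    outlier_f = outlier_f,
    n_mislabeled = as.integer(n_mislabeled),
    mislabel_from = mislabel_from,
    mislabel_as = mislabel_as,
    missing_rate = missing_rate,
    gene_fraction = gene_fraction,
    x_contigs = x_contigs,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_contigs < 1L || contig_length_bp < 1L) {
      abort("n_contigs and contig_length_bp must be positive")
    }
    if (length(pop_sizes) != length(pop_names) || length(pop_f) != length(pop_names)) {
      abort("pop_names, pop_sizes and pop_f must have equal length")
    }
    if (any(pop_f < 0 | pop_f >= 1)) abort("pop_f values must lie in [0, 1)")
    for (p in c(multiallelic_fraction, quad_fraction, missing_rate, gene_fraction)) {
      if (p < 0 || p >= 1) abort("proportions must lie in [0, 1)")
    }
    if (n_mislabeled > 0 &&
        (!mislabel_from %in% pop_names || !mislabel_as %in% pop_names)) {
      abort("mislabel_from / mislabel_as must name populations")
    }
    if (!is.null(sweep_specs) && nrow(sweep_specs) > 0) {
      needed <- c("contig", "start_bp", "end_bp", "target_population", "f_sweep")
      if (!all(needed %in% names(sweep_specs))) {
        abort("sweep_specs needs columns contig, start_bp, end_bp, target_population, f_sweep")
      }
      if (any(sweep_specs$f_sweep <= max(pop_f))) {
        abort("each f_sweep must exceed the largest background pop_f")
      }
      if (all(pop_f == 0) && any(sweep_specs$f_sweep == 0)) {
        abort("sweeps present but all divergence parameters are zero")
      }
      if (!all(sweep_specs$target_population %in% pop_names)) {
        abort("sweep target_population must name a population")
      }
    }
  })
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d pops (%s; n = %s), %d mislabeled, %d outliers, %d contigs x %d sites, seed %d\n",
    length(x$pop_names), paste(x$pop_names, collapse = "/"),
    paste(x$pop_sizes, collapse = "/"), x$n_mislabeled, x$n_outliers,
    x$n_contigs, x$n_sites_per_contig, x$seed))
  invisible(x)
}

#' Total number of simulated samples for a cohort configuration
#'
#' Assigned population members plus mislabelled extras plus isolated outliers.
#'
#' @param cfg A [cohort_config()].
#' @return Integer sample count.
#' @export
total_samples <- function(cfg) {
  sum(cfg$pop_sizes) + cfg$n_mislabeled + cfg$n_outliers
}

# Collection-site metadata for the default populations: five sites in three
# provinces; the two Ratanakiri populations share the same two collection
# sites (so province metadata cannot distinguish them, as in the field study).
population_metadata_table <- function(pop_names) {
  defaults <- tibble(
    population = c("TD", "PV", "RK1", "RK2"),
    province   = c("Pailin", "Preah Vihear", "Ratanakiri", "Ratanakiri"),
    sites      = list("Thmar Da", c("Chean Mok", "Preah Kleang"),
                      c("Sayas", "Chamkar San"), c("Sayas", "Chamkar San"))
  )
  if (all(pop_names %in% defaults$population)) {
    defaults[match(pop_names, defaults$population), ]
  } else {
    tibble(population = pop_names,
           province = paste0("province_", seq_along(pop_names)),
           sites = as.list(paste0("site_", seq_along(pop_names))))
  }
}
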
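#' Select sites for population-structure PCA
#'
#' Candidate sites are biallelic segregating sites on autosomal contigs whose
#' minor allele is carried by at least two chromosomes (non-singleton). When
#' more candidates exist than `n_target`, exactly `n_target` are drawn
#' uniformly without replacement (seeded); otherwise all candidates are
#' returned with a warning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param n_target Number of sites to draw (default 100000).
#' @param autosomes Character vector of autosomal contig names; default all
#'   contigs present.
#' @param seed Integer seed for the down-sampling draw.
#' @return Sorted integer vector of site indices.
#' @export
select_pca_sites <- function(genotypes, n_target = 100000,
                             autosomes = NULL, seed = 1L) {
  counts <- allele_counts(genotypes)
  k <- n_alleles(counts)
  on_autosome <- if (is.null(autosomes)) rep(TRUE, n_sites(genotypes))
                 else genotypes$sites$contig %in% autosomes
  # minor-allele chromosome count across the two observed alleles
  mac <- apply_minor_count(counts)
  candidates <- which(k == 2L & mac >= 2L & on_autosome)
  if (length(candidates) == 0) abort("no eligible PCA sites (biallelic, non-singleton)")
  if (length(candidates) > n_target) {
    withr::with_seed(substream_seed(seed, "pca-sites"),
                     sort(sample(candidates, n_target)))
  } else {
    if (length(candidates) < n_target) {
      warn(sprintf("only %d eligible PCA sites (target %d); using all",
                   length(candidates), n_target))
    }
    candidates
  }
}

# minor-allele chromosome count for biallelic sites: total minus the major
# allele's count (only meaningful where exactly two alleles are observed)
apply_minor_count <- function(counts) {
  major <- pmax(counts[, 1L], counts[, 2L], counts[, 3L], counts[, 4L])
  as.integer(rowSums(counts) - major)
}

#' Principal component analysis of a genotype matrix
#'
#' Alternate-allele dosages (0/1/2, missing imputed to the site mean) are
#' mean-centred per site and decomposed; sample coordinates are singular
#' vectors scaled by singular values, ordered by decreasing explained
#' variance. Component signs are arbitrary.
#'
#' @param genotypes A [genotype_matrix()].
#' @param sites Integer index of sites to use (e.g. from
#'   [select_pca_sites()]).
#' @param n_components Number of components to retain (default 10; truncated
#'   to what the data support).
#' @return Object of class `gt_pca`: `scores` (samples x components),
#'   `explained` (variance fractions), `samples`, `n_sites`.
#' @export
gt_pca <- function(genotypes, sites = seq_len(n_sites(genotypes)),
                   n_components = 10) {
  if (n_samples(genotypes) < 2 || length(sites) < 2) {
    abort("PCA needs at least two samples and two sites")
  }
  pca_core(dosage_sites_by_samples(genotypes, sites), genotypes$samples,
           length(sites), n_components)
}

# imputed dosage matrix kept sites x samples (no transpose): column j is a
# sample, so per-site centring is row centring and the sample-by-sample
# kernel is crossprod()
dosage_sites_by_samples <- function(genotypes, sites) {
  a1 <- genotypes$allele1[sites, , drop = FALSE]
  a2 <- genotypes$allele2[sites, , drop = FALSE]
  d <- (a1 > 0L) + (a2 > 0L)
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1L]]
  }
  colnames(d) <- genotypes$samples
  d
}

# eigendecomposition of the centred dosage kernel; d_ss is sites x samples.
# The kernel of the row-centred matrix X = D - m 1' is expanded as
# t(X)X = t(D)D - v1' - 1v' + sum(m^2) with v = t(D)m, avoiding a full-size
# centred copy of D.
pca_core <- function(d_ss, samples, n_used_sites, n_components) {
  n <- ncol(d_ss)
  m <- rowMeans(d_ss)
  v <- as.vector(crossprod(d_ss, m))
  kmat <- crossprod(d_ss) - matrix(v, n, n) - matrix(v, n, n, byrow = TRUE) +
    sum(m * m)
  eig <- eigen(kmat, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  n_avail <- sum(pos > max(pos) * 1e-12)
  k <- min(n_components, n_avail)
  if (k < n_components) {
    inform(sprintf("only %d informative components available (requested %d)", k, n_components))
  }
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos[seq_len(k)]), k)
  rownames(scores) <- samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, explained = pos[seq_len(k)] / sum(pos),
         samples = samples, n_sites = n_used_sites),
    class = "gt_pca"
  )
}

#' @export
print.gt_pca <- function(x, ...) {
  cat(sprintf("<gt_pca> %d samples, %d sites, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              length(x$samples), x$n_sites, ncol(x$scores),
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy PCA sample coordinates
#'
#' @param x A `gt_pca`.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `component`, `score`.
#' @export
tidy.gt_pca <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component", values_to = "score") |>
    mutate(component = as.integer(sub("^PC", "", .data$component)))
}

#' One-row PCA summary
#'
#' @param x A `gt_pca`.
#' @param ... Unused.
#' @return Tibble: sample count, site count, components, variance explained
#'   by PCs 1-2.
#' @export
glance.gt_pca <- function(x, ...) {
  tibble(n_samples = length(x$samples), n_sites = x$n_sites,
         n_components = ncol(x$scores),
         pve_pc1 = x$explained[1], pve_pc2 = x$explained[2])
}

#' Plot the first two principal components
#'
#' @param object A `gt_pca`.
#' @param labels Optional named vector or tibble (`sample_id`, `label`) used
#'   to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gt_pca <- function(object, labels = NULL, ...) {
  d <- as_tibble(object$scores[, 1:2, drop = FALSE], rownames = "sample_id")
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      d <- left_join(d, labels, by = "sample_id")
    } else {
      d$label <- labels[d$sample_id]
    }
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if ("label" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Iterative PCA outlier exclusion
#'
#' Repeats: run PCA on the remaining samples; on each of the top PCs flag
#' samples whose score lies more than `threshold_mads` median absolute
#' deviations from the per-PC median; exclude flagged samples; stop when an
#' iteration flags nothing (or after `max_iter`). Isolated outliers dominate
#' individual components, so flags on a PC are only accepted when the flagged
#' set is small (at most `max_flag_frac` of current samples); a larger flagged
#' set reflects genuine population structure along that axis and is ignored.
#'
#' @param genotypes A [genotype_matrix()].
#' @param sites Site index for PCA (from [select_pca_sites()]).
#' @param threshold_mads Flagging threshold in MADs (default 6).
#' @param top_pcs Number of leading components inspected (default 10).
#' @param max_iter Iteration cap (default 20).
#' @param max_flag_frac Largest fraction of samples a single PC may flag for
#'   those flags to count as isolated outliers (default 0.05).
#' @return Tibble of excluded samples: `sample_id`, `iteration`, `component`,
#'   `score`, `n_mads`. Zero rows when nothing is excluded.
#' @export
iterative_outlier_removal <- function(genotypes, sites,
                                      threshold_mads = 6, top_pcs = 10,
                                      max_iter = 20, max_flag_frac = 0.05) {
  remaining <- genotypes$samples
  excluded <- list()
  dosages <- dosage_sites_by_samples(genotypes, sites)
  for (it in seq_len(max_iter)) {
    fit <- pca_core(dosages[, remaining, drop = FALSE], remaining,
                    length(sites), min(top_pcs, length(remaining) - 1L))
    flags <- list()
    for (pc in seq_len(ncol(fit$scores))) {
      s <- fit$scores[, pc]
      md <- stats::median(s)
      sc <- stats::mad(s)
      if (sc == 0) next
      dev <- abs(s - md) / sc
      hit <- which(dev > threshold_mads)
      if (length(hit) == 0) next
      if (length(hit) > max_flag_frac * length(s)) next  # structure, not outliers
      flags[[length(flags) + 1L]] <- tibble(
        sample_id = names(s)[hit], iteration = it, component = pc,
        score = unname(s[hit]), n_mads = unname(dev[hit]))
    }
    if (length(flags) == 0) break
    flagged <- list_rbind(flags) |>
      group_by(.data$sample_id) |>
      slice_max(.data$n_mads, n = 1, with_ties = FALSE) |>
      ungroup()
    if (nrow(flagged) >= length(remaining)) {
      abort("outlier rule flagged every sample: degenerate threshold")
    }
    excluded[[it]] <- flagged
    remaining <- setdiff(remaining, flagged$sample_id)
  }
  if (length(excluded) == 0) {
    tibble(sample_id = character(), iteration = integer(),
           component = integer(), score = double(), n_mads = double())
  } else {
    list_rbind(excluded)
  }
}

#' Cluster samples and flag implausibly labelled groups
#'
#' Clusters the outlier-free samples by single linkage on the leading
#' principal-component coordinates, cutting the dendrogram at
#' `linkage_cutoff` times the largest pairwise distance. Each cluster takes
#' the majority recorded label of its members; a sample is flagged anomalous
#' when its recorded label disagrees with its cluster's majority label while
#' being the majority label of a different cluster (the signature of a
#' mislabelled group). Everything else is assigned its cluster.
#'
#' @param pca A `gt_pca` fitted after outlier removal.
#' @param labels Tibble with `sample_id` and `label` (recorded collection
#'   metadata, e.g. province) covering every sample in `pca`.
#' @param linkage_cutoff Dendrogram cut height as a fraction of the maximum
#'   pairwise distance (default 0.15).
#' @param n_pcs Number of leading PCs used for clustering (default 2).
#' @param expected_k Optional expected minimum number of clusters; a warning
#'   is raised if fewer are found.
#' @return Tibble: `sample_id`, `cluster` (e.g. `"cluster_1"` ordered by
#'   size), `cluster_label` (majority label), `status`
#'   (`"assigned"`/`"excluded_anomalous"`), `recorded_label`,
#'   `centroid_distance` (distance to own cluster centroid in the PC space
#'   used).
#' @export
assign_populations <- function(pca, labels, linkage_cutoff = 0.15,
                               n_pcs = 2, expected_k = NULL) {
  stopifnot(inherits(pca, "gt_pca"))
  labels <- as_tibble(labels)
  coords <- pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE]
  if (!all(rownames(coords) %in% labels$sample_id)) {
    abort("labels must cover every sample in the PCA")
  }
  d <- stats::dist(coords)
  if (max(d) == 0) {
    cl <- rep(1L, nrow(coords))
  } else {
    hc <- stats::hclust(d, method = "single")
    cl <- stats::cutree(hc, h = linkage_cutoff * max(d))
  }
  if (!is.null(expected_k) && length(unique(cl)) < expected_k) {
    warn(sprintf("found %d cluster(s) but %d expected", length(unique(cl)), expected_k))
  }
  # rename clusters by decreasing size
  sizes <- sort(table(cl), decreasing = TRUE)
  newid <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- unname(newid[as.character(cl)])

  out <- tibble(sample_id = rownames(coords), cluster_idx = cl) |>
    left_join(labels |> select("sample_id", recorded_label = "label"),
              by = "sample_id")
  majority <- out |>
    count(.data$cluster_idx, .data$recorded_label) |>
    group_by(.data$cluster_idx) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("cluster_idx", majority_label = "recorded_label")
  out <- out |> left_join(majority, by = "cluster_idx")
  label_home <- unique(majority$majority_label)
  out <- out |>
    mutate(
      status = ifelse(
        .data$recorded_label != .data$majority_label &
          .data$recorded_label %in% label_home,
        "excluded_anomalous", "assigned"),
      cluster = paste0("cluster_", .data$cluster_idx),
      cluster_label = .data$majority_label
    )
  cent <- rowsum(coords, cl) / as.vector(table(cl))
  out |>
    mutate(centroid_distance = sqrt(rowSums((coords - cent[.data$cluster_idx, , drop = FALSE])^2))) |>
    select("sample_id", "cluster", "cluster_label", "status",
           "recorded_label", "centroid_distance")
}

#' Run the full structure stage: PCA, outlier loop, assignment
#'
#' Convenience wrapper reproducing the cohort-analysis workflow: select PCA
#' sites, iteratively exclude isolated outliers, re-fit the PCA, cluster and
#' flag mislabelled groups. Excluded outliers receive status
#' `"excluded_outlier"`.
#'
#' @inheritParams select_pca_sites
#' @inheritParams iterative_outlier_removal
#' @inheritParams assign_populations
#' @param labels Tibble `sample_id`, `label` of recorded collection metadata.
#' @return List with `assignment` (tibble over all input samples), `pca`
#'   (final `gt_pca`), `outliers` (exclusion tibble), `sites` (site index).
#' @export
population_structure <- function(genotypes, labels, n_target = 100000,
                                 autosomes = NULL, seed = 1L,
                                 threshold_mads = 6, top_pcs = 10,
                                 linkage_cutoff = 0.15, n_pcs = 2,
                                 expected_k = NULL) {
  sites <- select_pca_sites(genotypes, n_target = n_target,
                            autosomes = autosomes, seed = seed)
  outliers <- iterative_outlier_removal(genotypes, sites,
                                        threshold_mads = threshold_mads,
                                        top_pcs = top_pcs)
  keep <- setdiff(genotypes$samples, outliers$sample_id)
  fit <- gt_pca(gt_subset(genotypes, samples = keep), sites,
                n_components = top_pcs)
  assignment <- assign_populations(fit, labels, linkage_cutoff = linkage_cutoff,
                                   n_pcs = n_pcs, expected_k = expected_k)
  if (nrow(outliers) > 0) {
    assignment <- bind_rows(
      assignment,
      tibble(sample_id = outliers$sample_id, cluster = NA_character_,
             cluster_label = NA_character_, status = "excluded_outlier",
             recorded_label = labels$label[match(outliers$sample_id, labels$sample_id)],
             centroid_distance = NA_real_))
  }
  list(assignment = assignment, pca = fit, outliers = outliers, sites = sites)
}

#' Thin biallelic SNPs for external structure tools
#'
#' Retains biallelic sites with minor-allele frequency strictly above
#' `maf_min` (computed over all non-missing chromosomes) and thins each
#' contig's passing sites to exactly `n_per_contig` by evenly spaced
#' rank-based selection when supply exceeds the target.
#'
#' @param genotypes A [genotype_matrix()].
#' @param maf_min Minimum minor-allele frequency, strict (default 0.01).
#' @param n_per_contig Sites to keep per contig (default 50000).
#' @return Tibble: `contig`, `pos`, `site_index`, ordered by contig and
#'   position.
#' @export
thin_snps_for_structure <- function(genotypes, maf_min = 0.01,
                                    n_per_contig = 50000) {
  counts <- allele_counts(genotypes)
  k <- n_alleles(counts)
  n <- rowSums(counts)
  mac <- apply_minor_count(counts)
  maf <- ifelse(n > 0, mac / n, 0)
  pass <- which(k == 2L & maf > maf_min)
  tibble(contig = genotypes$sites$contig[pass],
         pos = genotypes$sites$pos[pass],
         site_index = pass) |>
    arrange(.data$contig, .data$pos) |>
    group_by(.data$contig) |>
    group_modify(function(d, g) {
      if (nrow(d) > n_per_contig) d[thin_ranks(nrow(d), n_per_contig), ] else d
    }) |>
    ungroup()
}
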
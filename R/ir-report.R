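#' Read insecticide-resistance gene regions
#'
#' Accepts either a 4-column BED file (0-based half-open: contig, start, end,
#' gene name) or a YAML file with a `genes` list of `{name, contig, start,
#' end}` entries in 1-based inclusive coordinates.
#'
#' @param path BED or YAML file.
#' @return Tibble: `gene`, `contig`, `start`, `end` (1-based inclusive).
#' @export
read_ir_regions <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    purrr::map(y$genes, function(g) {
      tibble(gene = g$name, contig = g$contig,
             start = as.integer(g$start), end = as.integer(g$end))
    }) |> list_rbind()
  } else {
    readr::read_tsv(path, col_names = c("contig", "start", "end", "gene"),
                    col_types = "ciic", progress = FALSE) |>
      transmute(.data$gene, .data$contig, start = .data$start + 1L, .data$end)
  }
}

#' Per-population allele frequencies inside gene regions
#'
#' For every variant falling inside any configured region, computes the
#' frequency of each alternate allele per assigned population over
#' non-missing chromosomes. Multiallelic variants are decomposed into one
#' record per alternate allele. Populations with no called chromosome at a
#' site get `NA` frequency.
#'
#' @param genotypes A [genotype_matrix()].
#' @param assignment Tibble `sample_id`, `population` of assigned samples.
#' @param regions Tibble from [read_ir_regions()] (or equivalent):
#'   `gene`, `contig`, `start`, `end`, 1-based inclusive.
#' @return Long tibble: `gene`, `contig`, `pos`, `ref`, `alt`, `allele_index`,
#'   `population`, `frequency`, `n_chrom`.
#' @export
population_allele_frequencies <- function(genotypes, assignment, regions) {
  assignment <- as_tibble(assignment)
  regions <- as_tibble(regions)
  st <- genotypes$sites
  in_region <- purrr::map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    idx <- which(st$contig == r$contig & st$pos >= r$start & st$pos <= r$end)
    if (length(idx) == 0) {
      inform(sprintf("no variants in region %s", r$gene))
      return(NULL)
    }
    tibble(gene = r$gene, site_index = idx)
  }) |> list_rbind()
  if (is.null(in_region) || nrow(in_region) == 0) {
    return(tibble(gene = character(), contig = character(), pos = integer(),
                  ref = character(), alt = character(), allele_index = integer(),
                  population = character(), frequency = double(),
                  n_chrom = integer()))
  }
  pops <- sort(unique(assignment$population))
  counts_by_pop <- purrr::map(pops, function(p) {
    allele_counts(genotypes, assignment$sample_id[assignment$population == p])
  })
  names(counts_by_pop) <- pops

  purrr::map(seq_len(nrow(in_region)), function(i) {
    s <- in_region$site_index[i]
    alts <- st$alt[[s]]
    purrr::map(seq_along(alts), function(a) {
      purrr::map(pops, function(p) {
        cnt <- counts_by_pop[[p]][s, ]
        n <- sum(cnt)
        tibble(gene = in_region$gene[i], contig = st$contig[s],
               pos = st$pos[s], ref = st$ref[s], alt = alts[a],
               allele_index = a,
               population = p,
               frequency = if (n > 0) unname(cnt[a + 1L]) / n else NA_real_,
               n_chrom = as.integer(n))
      }) |> list_rbind()
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Filter the resistance-variant report
#'
#' Retains alternate-allele records whose frequency exceeds `min_freq`
#' (strictly) in at least one population with called chromosomes, and
#' presents one row per variant allele with per-population frequency columns,
#' sorted by gene then position.
#'
#' @param records Long tibble from [population_allele_frequencies()].
#' @param min_freq Frequency threshold, strict (default 0.02).
#' @return Wide tibble: `gene`, `contig`, `pos`, `ref`, `alt`,
#'   `freq_<population>` and `n_<population>` columns, `max_frequency`.
#' @export
filter_ir_variants <- function(records, min_freq = 0.02) {
  if (nrow(records) == 0) return(records)
  keep <- records |>
    group_by(.data$gene, .data$contig, .data$pos, .data$alt) |>
    mutate(max_frequency = max(.data$frequency, na.rm = TRUE)) |>
    ungroup() |>
    filter(.data$max_frequency > min_freq)
  if (nrow(keep) == 0) {
    return(tibble(gene = character(), contig = character(), pos = integer(),
                  ref = character(), alt = character(), max_frequency = double()))
  }
  keep |>
    tidyr::pivot_wider(
      id_cols = c("gene", "contig", "pos", "ref", "alt", "max_frequency"),
      names_from = "population",
      values_from = c("frequency", "n_chrom"),
      names_glue = "{ifelse(.value == 'frequency', 'freq', 'n')}_{population}") |>
    arrange(.data$gene, .data$pos) |>
    relocate("max_frequency", .after = dplyr::last_col())
}

#' Full insecticide-resistance report
#'
#' @inheritParams population_allele_frequencies
#' @inheritParams filter_ir_variants
#' @return Wide report tibble (see [filter_ir_variants()]).
#' @export
ir_report <- function(genotypes, assignment, regions, min_freq = 0.02) {
  filter_ir_variants(
    population_allele_frequencies(genotypes, assignment, regions),
    min_freq = min_freq)
}
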
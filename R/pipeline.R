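#' Read and validate a pipeline run configuration
#'
#' A single YAML file drives the whole workflow. It contains either a
#' `simulate` block (fields of [cohort_config()]) or an `inputs` block with
#' paths (`vcf`, `fasta`, `gff3`, `metadata`, `ir_regions`), plus optional
#' `parameters` overriding stage defaults and a `seed`. Unknown keys are
#' rejected. Every statistical default equals the study's printed value:
#' 10x/80% sample QC, 100,000 PCA sites, 50,000 thinned SNPs per contig, MAF
#' 0.01, downsampling to the smallest population, 100 bootstrap replicates,
#' 20-kb and 1000-SNP windows, runs of >= 5 windows above 2x the genome mean,
#' 100-kb gene radius and a 2% resistance-report threshold.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("simulate", "inputs", "parameters", "seed", "stages")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  defaults <- default_parameters()
  params <- utils::modifyList(defaults, y$parameters %||% list())
  extra_p <- setdiff(names(params), names(defaults))
  if (length(extra_p) > 0) {
    abort(sprintf("unknown parameter(s): %s", paste(extra_p, collapse = ", ")))
  }
  structure(list(
    simulate = y$simulate,
    inputs = y$inputs,
    parameters = params,
    seed = as.integer(y$seed %||% 1L),
    stages = y$stages %||% c("simulate", "qc", "structure", "diversity",
                             "fst_scan", "ir_report")
  ), class = "run_config")
}

default_parameters <- function() {
  list(
    qc_min_median = 10, qc_min_breadth = 0.8,
    pca_sites = 100000, top_pcs = 10, threshold_mads = 6,
    linkage_cutoff = 0.15, assign_n_pcs = 2, min_cluster_size = 5,
    thin_maf = 0.01, thin_per_contig = 50000,
    min_contig_bp = 2e6, n_boot = 100, ci_level = 0.95,
    window_bp = 20000, window_snps = 1000,
    min_run = 5, threshold_mult = 2.0, gene_radius = 100000,
    ir_min_freq = 0.02
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate (or load
#' inputs), sample QC and site census, population structure, diversity
#' statistics, Fst selection scans, and the insecticide-resistance report —
#' writing each stage's tables under `out_dir` and a JSON manifest with
#' parameter snapshot, seed and per-file checksums. Re-running with the same
#' config and seed reproduces identical checksums.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  p <- config$parameters
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  stage_failed <- function(stage, e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # ---- simulate or load -----------------------------------------------------
  if ("simulate" %in% config$stages && !is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    if (!is.null(sim_args$sweep_specs)) {
      sim_args$sweep_specs <- purrr::map(sim_args$sweep_specs, as_tibble) |> list_rbind()
    }
    cfg <- tryCatch(do.call(cohort_config, sim_args),
                    error = function(e) stage_failed("simulate", e))
    cohort <- simulate_cohort(cfg)
    sim_dir <- file.path(out_dir, "cohort")
    files <- write_cohort(cohort$genotypes, cohort$truth, cohort$reference, sim_dir)
    written <- c(written, files)
    note("simulate: %d samples, %d sites", n_samples(cohort$genotypes),
         n_sites(cohort$genotypes))
    genotypes <- cohort$genotypes
    metadata <- read_cohort_metadata(files[["metadata"]])
    genes <- cohort$reference$genes
    contig_lengths <- stats::setNames(Biostrings::width(cohort$reference$sequences),
                                      names(cohort$reference$sequences))
    sequences <- cohort$reference$sequences
    ir_regions <- cohort$reference$ir_genes |>
      select("gene", "contig", "start", "end")
    autosomes <- setdiff(names(sequences), cfg$x_contigs)
  } else {
    inp <- config$inputs
    if (is.null(inp$vcf)) abort("config must provide a simulate block or inputs$vcf")
    genotypes <- read_vcf_genotypes(inp$vcf)
    metadata <- read_cohort_metadata(inp$metadata)
    sequences <- if (!is.null(inp$fasta)) Biostrings::readDNAStringSet(inp$fasta) else NULL
    if (!is.null(sequences)) {
      names(sequences) <- sub("\\s.*$", "", names(sequences))
    }
    genes <- if (!is.null(inp$gff3)) read_gene_models(inp$gff3) else NULL
    contig_lengths <- if (!is.null(sequences)) {
      stats::setNames(Biostrings::width(sequences), names(sequences))
    } else {
      tapply(genotypes$sites$pos, genotypes$sites$contig, max)
    }
    ir_regions <- if (!is.null(inp$ir_regions)) read_ir_regions(inp$ir_regions) else NULL
    autosomes <- setdiff(names(contig_lengths), inp$x_contigs %||% character(0))
  }

  results <- list()

  # ---- qc -------------------------------------------------------------------
  if ("qc" %in% config$stages) {
    qc <- tryCatch(
      sample_qc(metadata, min_median = p$qc_min_median,
                min_breadth = p$qc_min_breadth, samples = genotypes$samples),
      error = function(e) stage_failed("qc", e))
    census <- classify_sites(genotypes)
    f <- file.path(out_dir, "qc_report.tsv")
    readr::write_tsv(qc, f); written <- c(written, qc_report = f)
    f2 <- file.path(out_dir, "site_census.tsv")
    readr::write_tsv(census, f2); written <- c(written, site_census = f2)
    failed <- qc$sample_id[!qc$qc_pass]
    for (s in failed) note("qc: excluded %s (%s)", s, qc$reason[qc$sample_id == s])
    genotypes <- gt_subset(genotypes,
                           samples = intersect(genotypes$samples,
                                               qc$sample_id[qc$qc_pass]))
    results$qc <- qc
    results$census <- census
  }

  # ---- structure ------------------------------------------------------------
  assignment <- NULL
  if ("structure" %in% config$stages) {
    labels <- metadata |> transmute(.data$sample_id, label = .data$province)
    struct <- tryCatch(
      population_structure(genotypes, labels, n_target = p$pca_sites,
                           autosomes = autosomes, seed = config$seed,
                           threshold_mads = p$threshold_mads,
                           top_pcs = p$top_pcs,
                           linkage_cutoff = p$linkage_cutoff,
                           n_pcs = p$assign_n_pcs),
      error = function(e) stage_failed("structure", e))
    f <- file.path(out_dir, "assignment.tsv")
    readr::write_tsv(struct$assignment, f); written <- c(written, assignment = f)
    f2 <- file.path(out_dir, "pc_coordinates.tsv")
    readr::write_tsv(tidy(struct$pca), f2); written <- c(written, pcs = f2)
    excl <- struct$assignment |> filter(.data$status != "assigned")
    for (i in seq_len(nrow(excl))) {
      note("structure: excluded %s (%s)", excl$sample_id[i], excl$status[i])
    }
    thin <- thin_snps_for_structure(genotypes, maf_min = p$thin_maf,
                                    n_per_contig = p$thin_per_contig)
    f3 <- file.path(out_dir, "thinned_sites.txt")
    readr::write_tsv(thin |> select("contig", "pos"), f3, col_names = FALSE)
    written <- c(written, thinned = f3)
    # populations are keyed by cluster id: recorded provinces cannot separate
    # sympatric clusters (the two Ratanakiri populations share their sites);
    # clusters too small to support population statistics are left out of the
    # per-population analyses
    assignment <- struct$assignment |>
      filter(.data$status == "assigned") |>
      transmute(.data$sample_id, population = .data$cluster)
    sizes <- assignment |> count(.data$population)
    small <- sizes$population[sizes$n < p$min_cluster_size]
    if (length(small) > 0) {
      note("structure: %d cluster(s) below %d samples excluded from population analyses (%s)",
           length(small), p$min_cluster_size, paste(small, collapse = ", "))
      assignment <- assignment |> filter(!.data$population %in% small)
    }
    results$structure <- struct
  }

  # ---- diversity ------------------------------------------------------------
  if ("diversity" %in% config$stages && !is.null(assignment) &&
      !is.null(sequences) && !is.null(genes) && nrow(genes) > 0) {
    big <- names(contig_lengths)[contig_lengths >= p$min_contig_bp]
    big <- intersect(big, autosomes)
    cds <- genes |> mutate(phase = 0L)
    mask <- fourfold_degenerate_mask(sequences[big], cds |> filter(.data$contig %in% big))
    site_idx <- which(purrr::map2_lgl(genotypes$sites$contig, genotypes$sites$pos,
                                      function(ctg, pos) {
                                        ctg %in% big && mask[[ctg]][pos]
                                      }))
    accessible <- sum(vapply(mask, sum, numeric(1)))
    div <- tryCatch(
      population_diversity(genotypes, assignment, sites = site_idx,
                           accessible = accessible, n_boot = p$n_boot,
                           level = p$ci_level, seed = config$seed),
      error = function(e) stage_failed("diversity", e))
    f <- file.path(out_dir, "diversity.tsv")
    readr::write_tsv(div, f); written <- c(written, diversity = f)
    f2 <- file.path(out_dir, "fourfold_mask.bed")
    mask_to_bed(mask, f2); written <- c(written, fourfold_mask = f2)
    results$diversity <- div
  }

  # ---- fst scan -------------------------------------------------------------
  if ("fst_scan" %in% config$stages && !is.null(assignment)) {
    pops <- sort(unique(assignment$population))
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    scans <- purrr::map(pairs, function(pr) {
      scan <- tryCatch(
        fst_scan(genotypes,
                 assignment$sample_id[assignment$population == pr[1]],
                 assignment$sample_id[assignment$population == pr[2]],
                 genes = genes, contig_lengths = contig_lengths,
                 min_contig_bp = p$min_contig_bp, window_snps = p$window_snps,
                 min_run = p$min_run, threshold_mult = p$threshold_mult,
                 radius = p$gene_radius),
        error = function(e) stage_failed("fst_scan", e))
      comparison <- paste(pr, collapse = "_v_")
      f <- file.path(out_dir, sprintf("fst_windows_%s.tsv", comparison))
      readr::write_tsv(scan$windows, f)
      sig <- scan$signals
      if (nrow(sig) > 0 && "genes" %in% names(sig)) {
        sig <- sig |>
          mutate(gene_ids = purrr::map_chr(.data$genes, ~ paste(.x$gene_id, collapse = ",")),
                 products = purrr::map_chr(.data$genes, ~ paste(.x$product, collapse = ";"))) |>
          select(-"genes")
      }
      f2 <- file.path(out_dir, sprintf("fst_signals_%s.tsv", comparison))
      readr::write_tsv(sig, f2)
      written <<- c(written, stats::setNames(c(f, f2),
                                             paste0(c("fst_windows_", "fst_signals_"), comparison)))
      list(comparison = comparison, scan = scan)
    })
    results$fst <- scans
  }

  # ---- ir report ------------------------------------------------------------
  if ("ir_report" %in% config$stages && !is.null(assignment) &&
      !is.null(ir_regions) && nrow(ir_regions) > 0) {
    rep <- tryCatch(
      ir_report(genotypes, assignment, ir_regions, min_freq = p$ir_min_freq),
      error = function(e) stage_failed("ir_report", e))
    f <- file.path(out_dir, "ir_report.tsv")
    readr::write_tsv(rep, f); written <- c(written, ir_report = f)
    results$ir <- rep
  }

  # ---- manifest -------------------------------------------------------------
  log_file <- file.path(out_dir, "pipeline_log.txt")
  writeLines(log_lines, log_file)
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = p,
    files = purrr::map(stats::setNames(written, names(written) %||% basename(written)),
                       function(f) list(path = basename(f),
                                        md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
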
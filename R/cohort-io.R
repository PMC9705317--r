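#' Write a simulated cohort to disk
#'
#' Emits the full file set the analysis pipeline consumes: reference FASTA,
#' GFF3 gene models, a GT-only multi-sample VCF 4.2 (contigs declared in the
#' header, sample order identical to the metadata table), a sample-metadata
#' TSV with synthetic coverage summaries, a ground-truth TSV, and a BED of
#' the insecticide-resistance gene analogues.
#'
#' @param genotypes A [genotype_matrix()].
#' @param truth A `cohort_truth`.
#' @param reference A `cohort_reference`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(genotypes, truth, reference, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) abort(sprintf("output directory not writable: %s", dir))
  paths <- c(
    fasta = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "cohort.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv"),
    ir_bed = file.path(dir, "ir_genes.bed")
  )
  write_reference(reference, paths[["fasta"]], paths[["gff3"]])
  write_vcf_genotypes(genotypes, paths[["vcf"]],
                      contig_lengths = stats::setNames(
                        Biostrings::width(reference$sequences),
                        names(reference$sequences)))

  cfg <- reference$config
  meta <- withr::with_seed(substream_seed(cfg$seed, "coverage"), {
    n <- nrow(truth$samples)
    truth$samples |>
      transmute(.data$sample_id, site = .data$recorded_site,
                province = .data$recorded_province, .data$year,
                median_coverage = round(pmax(12, stats::rnorm(n, 35, 6)), 1),
                breadth_1x = round(stats::runif(n, 0.85, 0.99), 3))
  })
  readr::write_tsv(meta, paths[["metadata"]])
  readr::write_tsv(truth$samples, paths[["truth"]])

  ir <- reference$ir_genes
  if (nrow(ir) > 0) {
    readr::write_tsv(
      ir |> transmute(.data$contig, start = .data$start - 1L, end = .data$end,
                      name = .data$gene),
      paths[["ir_bed"]], col_names = FALSE)
  }
  invisible(paths)
}

#' Write genotypes as a GT-only VCF 4.2 file
#'
#' @param x A [genotype_matrix()].
#' @param path Output path (plain text).
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header; defaults to the maximum observed position per contig.
#' @return Invisibly, `path`.
#' @export
write_vcf_genotypes <- function(x, path, contig_lengths = NULL) {
  st <- x$sites
  if (is.null(contig_lengths)) {
    contig_lengths <- st |>
      group_by(.data$contig) |>
      summarise(len = max(.data$pos)) |>
      (\(d) stats::setNames(d$len, d$contig))()
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=minpop",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  g1 <- x$allele1; g2 <- x$allele2
  gt <- matrix(paste(ifelse(is.na(g1), ".", g1), ifelse(is.na(g2), ".", g2),
                     sep = "/"), nrow = nrow(g1))
  body <- paste(
    st$contig, st$pos, ".", st$ref,
    vapply(st$alt, paste, character(1), collapse = ","),
    ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses diploid GT fields (phased or unphased); `./.` becomes missing.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  first <- sub("^([0-9.]+)[/|].*$", "\\1", gt_chr)
  second <- sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", gt_chr)
  to_int <- function(m) {
    out <- suppressWarnings(matrix(as.integer(m), nrow = nrow(m)))
    out
  }
  sites <- tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",")
  )
  genotype_matrix(to_int(first), to_int(second), sites, colnames(gt_chr))
}

#' Read the cohort sample-metadata table
#'
#' @param path Metadata TSV with columns sample_id, site, province, year,
#'   median_coverage, breadth_1x.
#' @return Tibble.
#' @export
read_cohort_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
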
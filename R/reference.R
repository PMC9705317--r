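#' Build a synthetic reference genome with gene models
#'
#' Generates random nucleotide contigs plus non-overlapping single-CDS
#' protein-coding gene models on both strands (lengths divisible by three,
#' phase 0), covering roughly `gene_fraction` of each contig. Four genes are
#' designated as analogues of the canonical insecticide-resistance loci
#' (Ace1, Rdl, Kdr, GSTe2) so the resistance report can be exercised on a
#' purely synthetic annotation.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `cohort_reference` with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `genes` (tibble: gene_id, contig, start,
#'   end, strand, product), `ir_genes` (tibble subset naming the resistance
#'   analogues) and `config`.
#' @export
build_reference <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  contig_names <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
  len <- cfg$contig_length_bp

  seqs <- withr::with_seed(substream_seed(cfg$seed, "reference"), {
    vapply(contig_names, function(ctg) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  })
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- contig_names

  mean_gene <- 900L  # bp, codon-multiple gene lengths drawn around this
  n_genes_per_contig <- as.integer(floor(cfg$gene_fraction * len / mean_gene))
  if (cfg$gene_fraction > 0 && n_genes_per_contig < 1L) {
    abort("contig too short for the requested gene density")
  }

  genes <- withr::with_seed(substream_seed(cfg$seed, "genes"), {
    purrr::map(seq_len(cfg$n_contigs), function(ci) {
      ng <- n_genes_per_contig
      if (ng == 0L) return(NULL)
      # lay genes on an even grid with jitter so they never overlap
      slot <- len %/% ng
      gl <- 3L * sample(100:500, ng, replace = TRUE)   # 300..1500 bp
      if (any(gl + 10L > slot)) gl <- pmin(gl, slot - 12L - (slot %% 3L))
      offset <- vapply(slot - gl - 1L, function(m) sample.int(m, 1L), integer(1))
      start <- (seq_len(ng) - 1L) * slot + offset
      tibble(
        gene_id = sprintf("MIN%02d%04d", ci, seq_len(ng)),
        contig = sprintf("ctg%02d", ci),
        start = start,
        end = start + gl - 1L,
        strand = sample(c("+", "-"), ng, replace = TRUE),
        product = sprintf("hypothetical protein %02d-%04d", ci, seq_len(ng))
      )
    }) |> list_rbind()
  })

  ir_genes <- NULL
  if (nrow(genes %||% tibble()) >= 4) {
    ir_names <- c("Ace1", "Rdl", "Kdr", "GSTe2")
    ir_products <- c("acetylcholinesterase", "GABA-gated chloride channel subunit",
                     "voltage-gated sodium channel", "glutathione S-transferase epsilon 2")
    # spread the four loci across contigs, away from contig edges
    pick <- genes |>
      group_by(.data$contig) |>
      slice(ceiling(n() / 2)) |>
      ungroup() |>
      slice_head(n = 4)
    if (nrow(pick) < 4) pick <- genes |> slice(thin_ranks(nrow(genes), 4))
    genes$product[match(pick$gene_id, genes$gene_id)] <- ir_products[seq_len(nrow(pick))]
    ir_genes <- genes |>
      filter(.data$gene_id %in% pick$gene_id) |>
      mutate(gene = ir_names[seq_len(nrow(pick))], .before = 1)
  }

  structure(
    list(sequences = sequences, genes = genes %||% tibble(),
         ir_genes = ir_genes %||% tibble(), config = cfg),
    class = "cohort_reference"
  )
}

#' @export
print.cohort_reference <- function(x, ...) {
  cat(sprintf("<cohort_reference> %d contig(s) x %s bp, %d gene model(s)\n",
              length(x$sequences), format(x$config$contig_length_bp, big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Write reference FASTA and GFF3 gene models
#'
#' @param reference A `cohort_reference` from [build_reference()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(reference$sequences, fasta_path)
  g <- reference$genes
  lines <- c("##gff-version 3")
  contig_len <- Biostrings::width(reference$sequences)
  lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                            names(reference$sequences), contig_len))
  if (nrow(g) > 0) {
    feat <- function(type, id, parent, row, phase = ".") {
      attrs <- if (is.na(parent)) sprintf("ID=%s;product=%s", id, row$product)
               else sprintf("ID=%s;Parent=%s", id, parent)
      sprintf("%s\tminpop\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              row$contig, type, row$start, row$end, row$strand, phase, attrs)
    }
    body <- purrr::map(seq_len(nrow(g)), function(i) {
      row <- g[i, ]
      c(feat("gene", row$gene_id, NA, row),
        feat("mRNA", paste0(row$gene_id, ".t1"), row$gene_id, row),
        feat("CDS", paste0(row$gene_id, ".c1"), paste0(row$gene_id, ".t1"), row,
             phase = "0"))
    }) |> unlist()
    lines <- c(lines, body)
  }
  writeLines(lines, gff3_path)
  invisible(c(fasta_path, gff3_path))
}

#' Read gene models from a GFF3 file
#'
#' CDS features (one per gene model in files written by [write_reference()])
#' are returned as a tibble compatible with the annotation operations.
#'
#' @param path GFF3 file path.
#' @param feature Feature type to extract, default `"CDS"`.
#' @return Tibble: contig, start, end, strand, phase, gene_id, product.
#' @export
read_gene_models <- function(path, feature = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(gr))
  products <- d |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$ID,
              product = if ("product" %in% names(d)) .data$product else NA_character_)
  d |>
    filter(.data$type == feature) |>
    transmute(
      contig = as.character(.data$seqnames),
      .data$start, .data$end, strand = as.character(.data$strand),
      phase = if ("phase" %in% names(d)) as.integer(.data$phase) else 0L,
      gene_id = sub("\\.(t|c)1$", "",
                    dplyr::coalesce(as.character(.data$ID), as.character(.data$Parent)))
    ) |>
    left_join(products, by = "gene_id")
}
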
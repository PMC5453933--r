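#' Read and write the study's file formats
#'
#' Thin wrappers over rtracklayer, Biostrings and readr for the formats the
#' pipeline consumes: GFF3 gene annotation, BLAST outfmt-6 homology tables,
#' 7-column per-cytosine methylation reports, expression tables and CDS
#' FASTA. All tabular readers return tibbles.
#'
#' @name dupmeth-io
NULL

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

cx_cols <- c("chrom", "pos", "strand", "count_methylated",
             "count_unmethylated", "context", "trinucleotide")

#' @rdname dupmeth-io
#' @param catalog Gene-catalog tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`, `is_te`).
#' @param path Output/input file path.
#' @export
write_gff3 <- function(catalog, path) {
  if (nrow(catalog) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(catalog$start, catalog$end),
    strand = catalog$strand)
  S4Vectors::mcols(gr)$source <- "dupmeth"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- catalog$gene_id
  S4Vectors::mcols(gr)$is_te <- ifelse(catalog$is_te, "true", "false")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname dupmeth-io
#' @return `read_gene_catalog()`: a gene-catalog tibble with per-chromosome
#'   rank recomputed from gene order.
#' @export
read_gene_catalog <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) > 0 && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  rank = integer(), is_te = logical()))
  }
  mc <- S4Vectors::mcols(gr)
  is_te <- if ("is_te" %in% names(mc)) {
    tolower(as.character(mc$is_te)) %in% c("true", "1", "yes")
  } else rep(FALSE, length(gr))
  tibble(
    gene_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_te = is_te
  ) |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    arrange(.data$chrom, .data$rank)
}

#' @rdname dupmeth-io
#' @param hits Homology-hit tibble with outfmt-6 columns.
#' @export
write_blast_hits <- function(hits, path) {
  assert_cols(hits, outfmt6_cols, "homology table")
  readr::write_tsv(hits[outfmt6_cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname dupmeth-io
#' @export
read_blast_hits <- function(path) {
  readr::read_tsv(path, col_names = outfmt6_cols,
                  col_types = "ccdiiiiiiidd", progress = FALSE)
}

#' @rdname dupmeth-io
#' @param calls Cytosine-report tibble (`chrom`, `pos`, `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`).
#' @export
write_cx_report <- function(calls, path) {
  assert_cols(calls, cx_cols, "cytosine report")
  readr::write_tsv(calls[cx_cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname dupmeth-io
#' @export
read_cx_report <- function(path) {
  out <- readr::read_tsv(path, col_names = cx_cols, col_types = "ciciicc",
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed cytosine report line %d in %s: %s",
                  probs$row[1], path, probs$expected[1]))
  }
  bad <- which(!(out$context %in% c("CG", "CHG", "CHH")) |
                 out$count_methylated < 0 | out$count_unmethylated < 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed cytosine report line %d in %s", bad[1], path))
  }
  out
}

#' @rdname dupmeth-io
#' @param expression Expression tibble (`gene_id`, `genotype`, `replicate`,
#'   `count`, `fpkm`, `library_size`, `gene_length`).
#' @export
write_expression <- function(expression, path) {
  assert_cols(expression, c("gene_id", "genotype", "replicate", "count",
                            "fpkm", "library_size", "gene_length"),
              "expression table")
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname dupmeth-io
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", genotype = "c", replicate = "i", count = "d",
    fpkm = "d", library_size = "d", gene_length = "i"), progress = FALSE)
}

#' @rdname dupmeth-io
#' @param cds Named character vector of coding sequences.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' @rdname dupmeth-io
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname dupmeth-io
#' @param pairs Pair tibble (`gene_a`, `gene_b`, `category`).
#' @export
write_pairs <- function(pairs, path) {
  assert_cols(pairs, c("gene_a", "gene_b", "category"), "pair table")
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname dupmeth-io
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", category = "c", .default = "?"),
    progress = FALSE)
}

#' Write a simulated study to a directory
#'
#' Serializes every component of a [simulate_study()] result to plain-text
#' files: `annotation.gff3`, `homology.tsv` (BLAST outfmt 6), `cx_wt.tsv` /
#' `cx_mut.tsv` (7-column cytosine reports), `expression.tsv`, `cds.fasta`,
#' `pairs_truth.tsv` and `truth.json` (ground-truth levels, roles and
#' substitution counts).
#'
#' @param study A `dupmeth_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dupmeth_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3(study$catalog, p("annotation.gff3"))
  write_blast_hits(study$homology, p("homology.tsv"))
  write_cx_report(study$methylomes$wt, p("cx_wt.tsv"))
  write_cx_report(study$methylomes$mut, p("cx_mut.tsv"))
  write_expression(study$expression, p("expression.tsv"))
  if (length(study$cds) > 0) write_cds_fasta(study$cds, p("cds.fasta"))
  write_pairs(study$truth$pairs, p("pairs_truth.tsv"))
  jsonlite::write_json(
    list(gene_levels = study$truth$gene_levels,
         gene_expression = study$truth$gene_expression,
         substitutions = study$substitutions),
    p("truth.json"), digits = NA)
  invisible(dir)
}
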
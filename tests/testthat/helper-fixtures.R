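# Shared small-scale fixtures, built once per test run.

small_config <- function(seed = 42, ...) {
  simulation_config(
    n_chromosomes = 4, genes_per_chromosome = 60,
    category_counts = c(WGD = 12, tandem = 8, proximal = 8, transposed = 12),
    sites_per_gene = c(CG = 15, CHG = 20, CHH = 40),
    codons_per_cds = 100, n_decoys = 40, seed = seed, ...)
}

.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(small_config())
  }
  .fixture_env$study
}

small_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- suppressWarnings(run_pipeline(small_study()))
  }
  .fixture_env$report
}

# a catalog whose genes sit at prescribed ranks on given chromosomes
toy_catalog <- function(chrom, rank, is_te = FALSE) {
  n <- length(chrom)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom,
    start = 1000L * rank,
    end = 1000L * rank + 500L,
    strand = "+",
    rank = as.integer(rank),
    is_te = rep_len(is_te, n))
}

toy_hit <- function(q, s, evalue, bitscore = 500) {
  n <- max(length(q), length(s), length(evalue))
  tibble::tibble(
    qseqid = rep_len(q, n), sseqid = rep_len(s, n),
    pident = 90, length = 300L, mismatch = 10L, gapopen = 0L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = rep_len(evalue, n), bitscore = rep_len(bitscore, n))
}
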
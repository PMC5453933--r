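#' Flag expressed genes and retained pairs
#'
#' A gene is expressed in a genotype when its replicate-mean FPKM strictly
#' exceeds `threshold`. A duplicate pair is retained for expression analyses
#' when at least one copy is expressed in at least one genotype.
#'
#' @param expression Expression tibble (`gene_id`, `genotype`, `replicate`,
#'   `count`, `fpkm`, ...), both genotypes present.
#' @param threshold FPKM expression threshold (strict `>`).
#' @return Tibble `gene_id`, `genotype`, `mean_fpkm`, `expressed`.
#' @export
call_expressed <- function(expression, threshold = 0.1) {
  assert_cols(expression, c("gene_id", "genotype", "fpkm"),
              "expression table")
  gts <- unique(expression$genotype)
  if (!all(c("wt", "mut") %in% gts)) {
    abort(sprintf("expression table must contain genotypes 'wt' and 'mut', found: %s",
                  paste(gts, collapse = ", ")))
  }
  expression |>
    group_by(.data$gene_id, .data$genotype) |>
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    mutate(expressed = .data$mean_fpkm > threshold)
}

#' @rdname call_expressed
#' @param pairs Pair tibble.
#' @param expressed_flags Output of [call_expressed()].
#' @return `filter_expressed_pairs()`: `pairs` with logical `retained`.
#' @export
filter_expressed_pairs <- function(pairs, expressed_flags) {
  ex <- expressed_flags |>
    group_by(.data$gene_id) |>
    summarise(any_expressed = any(.data$expressed), .groups = "drop")
  pairs |>
    left_join(rename(ex, ex_a = "any_expressed"), by = c(gene_a = "gene_id")) |>
    left_join(rename(ex, ex_b = "any_expressed"), by = c(gene_b = "gene_id")) |>
    mutate(retained = dplyr::coalesce(.data$ex_a, FALSE) |
             dplyr::coalesce(.data$ex_b, FALSE)) |>
    select(-"ex_a", -"ex_b")
}

#' Exact conditional count test
#'
#' Conditional binomial test for two pooled counts: given t = a + b, under
#' the null a ~ Bin(t, w_a / (w_a + w_b)) where the weights are the library
#' sizes (same gene, two conditions) or library-size x gene-length products
#' (two genes, same libraries). Two-sided p by the doubled smaller one-sided
#' tail, capped at 1. Vectorized; zero totals give `NA`.
#'
#' @param counts_a,counts_b Non-negative integer count vectors.
#' @param lib_a,lib_b Positive weights (recycled).
#' @return Numeric vector of two-sided p-values.
#' @export
exact_count_test <- function(counts_a, counts_b, lib_a = 1, lib_b = 1) {
  n <- max(length(counts_a), length(counts_b))
  a <- rep_len(counts_a, n); b <- rep_len(counts_b, n)
  wa <- rep_len(lib_a, n); wb <- rep_len(lib_b, n)
  if (any(a < 0 | b < 0, na.rm = TRUE)) abort("counts must be non-negative")
  if (any(wa <= 0 | wb <= 0)) abort("library weights must be positive")
  t <- a + b
  pr <- wa / (wa + wb)
  lower <- pbinom(a, t, pr)
  upper <- pbinom(a - 1, t, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[t == 0] <- NA_real_
  p
}

#' Differential expression between genotypes, per gene
#'
#' Pools replicate counts by summation, applies the exact conditional count
#' test with the genotypes' total library sizes as weights, BH-corrects
#' across genes, and reports the mutant/wild-type log2 fold change of mean
#' FPKM (pseudocount-guarded). Direction is `none` iff q >= `alpha`,
#' otherwise `up`/`down` for higher/lower expression in the mutant.
#'
#' @param expression Expression tibble.
#' @param alpha q-value threshold.
#' @param pseudocount FPKM pseudocount for fold changes.
#' @return Tibble `gene_id`, `wt_fpkm`, `mut_fpkm`, `log2_fold_change`,
#'   `p_value`, `q_value`, `direction`.
#' @export
de_between_genotypes <- function(expression, alpha = 0.05,
                                 pseudocount = 0.01) {
  x <- expression |>
    group_by(.data$gene_id, .data$genotype) |>
    summarise(count = sum(.data$count), lib = sum(.data$library_size),
              fpkm = mean(.data$fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "genotype",
                       values_from = c("count", "lib", "fpkm"))
  x$p_value <- exact_count_test(x$count_mut, x$count_wt,
                                x$lib_mut, x$lib_wt)
  x$q_value <- p.adjust(x$p_value, method = "BH")
  x$log2_fold_change <- log2((x$fpkm_mut + pseudocount) /
                               (x$fpkm_wt + pseudocount))
  x$direction <- dplyr::case_when(
    is.na(x$q_value) | x$q_value >= alpha ~ "none",
    x$log2_fold_change > 0 ~ "up",
    TRUE ~ "down")
  x |>
    select("gene_id", wt_fpkm = "fpkm_wt", mut_fpkm = "fpkm_mut",
           "log2_fold_change", "p_value", "q_value", "direction")
}

#' Differential expression between the two copies of each pair
#'
#' Within one genotype, the two copies share libraries, so the conditional
#' null proportion is the gene-length share: a ~ Bin(t, len_a/(len_a+len_b))
#' under equal FPKM. Replicates are pooled by summation; BH across pairs.
#'
#' @param pairs Pair tibble.
#' @param expression Expression tibble.
#' @param genotype `"wt"` or `"mut"`.
#' @param alpha q-value threshold.
#' @param pseudocount FPKM pseudocount.
#' @return Tibble per pair: `gene_a`, `gene_b`, `fpkm_a`, `fpkm_b`,
#'   `log2_fold_change` (a over b), `p_value`, `q_value`, `direction`.
#' @export
de_between_copies <- function(pairs, expression, genotype = "wt",
                              alpha = 0.05, pseudocount = 0.01) {
  gt <- genotype
  g <- expression |>
    filter(.data$genotype == gt) |>
    group_by(.data$gene_id) |>
    summarise(count = sum(.data$count), fpkm = mean(.data$fpkm),
              gene_length = .data$gene_length[1], .groups = "drop")
  x <- pairs |>
    inner_join(rename(g, count_a = "count", fpkm_a = "fpkm",
                      len_a = "gene_length"), by = c(gene_a = "gene_id")) |>
    inner_join(rename(g, count_b = "count", fpkm_b = "fpkm",
                      len_b = "gene_length"), by = c(gene_b = "gene_id"))
  x$p_value <- exact_count_test(x$count_a, x$count_b, x$len_a, x$len_b)
  x$q_value <- p.adjust(x$p_value, method = "BH")
  x$log2_fold_change <- log2((x$fpkm_a + pseudocount) /
                               (x$fpkm_b + pseudocount))
  x$direction <- dplyr::case_when(
    is.na(x$q_value) | x$q_value >= alpha ~ "none",
    x$log2_fold_change > 0 ~ "up",
    TRUE ~ "down")
  select(x, "gene_a", "gene_b", "fpkm_a", "fpkm_b", "log2_fold_change",
         "p_value", "q_value", "direction")
}

#' Between-copy expression divergence
#'
#' Absolute log2 ratio of the copies' mean FPKM in one genotype,
#' pseudocount-guarded so silent copies stay finite. Invariant to copy
#' relabeling.
#'
#' @inheritParams de_between_copies
#' @return `pairs` with `fpkm_a`, `fpkm_b`, `divergence` columns.
#' @export
expression_divergence <- function(pairs, expression, genotype = "wt",
                                  pseudocount = 0.01) {
  gt <- genotype
  g <- expression |>
    filter(.data$genotype == gt) |>
    group_by(.data$gene_id) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop")
  pairs |>
    inner_join(rename(g, fpkm_a = "fpkm"), by = c(gene_a = "gene_id")) |>
    inner_join(rename(g, fpkm_b = "fpkm"), by = c(gene_b = "gene_id")) |>
    mutate(divergence = abs(log2((.data$fpkm_a + pseudocount) /
                                   (.data$fpkm_b + pseudocount))))
}

#' Flag expression-affected duplicate pairs
#'
#' A pair is expression-affected when at least one copy changed
#' significantly between wild type and mutant (q < `alpha` in the per-gene
#' genotype contrast).
#'
#' @param pairs Pair tibble.
#' @param de_genotypes Output of [de_between_genotypes()].
#' @param alpha q-value threshold.
#' @return `pairs` with logical `affected`.
#' @export
flag_affected_pairs <- function(pairs, de_genotypes, alpha = 0.05) {
  sig <- de_genotypes$gene_id[!is.na(de_genotypes$q_value) &
                                de_genotypes$q_value < alpha]
  mutate(pairs, affected = .data$gene_a %in% sig | .data$gene_b %in% sig)
}
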
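#' Assign cytosine sites to gene bodies and apply the coverage filter
#'
#' Sites with fewer than `min_reads` total reads are dropped; remaining sites
#' are assigned to every gene body (annotated start..end, both strands
#' pooled) they fall in.
#'
#' @param calls Cytosine-report tibble.
#' @param catalog Gene catalog.
#' @param min_reads Minimum total reads for a site to be used.
#' @return The filtered calls with a `gene_id` column (sites outside any gene
#'   are dropped; genes are non-overlapping in this design, so assignment is
#'   unique).
#' @export
annotate_sites <- function(calls, catalog, min_reads = 4) {
  assert_cols(calls, c("chrom", "pos", "strand", "count_methylated",
                       "count_unmethylated", "context"), "cytosine report")
  calls <- filter(calls,
                  .data$count_methylated + .data$count_unmethylated >=
                    min_reads)
  if (nrow(calls) == 0 || nrow(catalog) == 0) {
    return(mutate(calls[0, ], gene_id = character()))
  }
  site_gr <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, calls$pos))
  gene_gr <- GenomicRanges::GRanges(catalog$chrom,
                                    IRanges::IRanges(catalog$start,
                                                     catalog$end))
  ov <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  out <- calls[S4Vectors::queryHits(ov), ]
  out$gene_id <- catalog$gene_id[S4Vectors::subjectHits(ov)]
  out
}

#' Flag methylated cytosine sites
#'
#' A covered site is called methylated when its methylated-read count is
#' implausible under the bisulfite error rate: one-sided binomial
#' P(X >= count_methylated | n = total reads, p = `error_rate`) < `alpha`.
#'
#' @param calls Cytosine calls (any tibble with `count_methylated` and
#'   `count_unmethylated`).
#' @param error_rate Bisulfite non-conversion / sequencing error rate.
#' @param alpha Site-level significance threshold.
#' @return `calls` with logical column `methylated` added.
#' @export
call_methylated_sites <- function(calls, error_rate = 0.005, alpha = 0.01) {
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate <= 0 || error_rate >= 1) {
    abort("`error_rate` must be a single number strictly inside (0, 1)")
  }
  total <- calls$count_methylated + calls$count_unmethylated
  p <- pbinom(calls$count_methylated - 1L, total, error_rate,
              lower.tail = FALSE)
  mutate(calls, methylated = p < alpha & total > 0)
}

#' Compute per-gene, per-context body methylation profiles
#'
#' Pools reads over all coverage-passing sites inside each gene body and
#' context. The body level is the weighted (read-pooled) level
#' `total_meth_reads / total_reads`. Genes with no covered site in a context
#' have no row (level undefined, distinct from 0).
#'
#' @inheritParams annotate_sites
#' @inheritParams call_methylated_sites
#' @return Profile tibble: `gene_id`, `context`, `n_covered_sites`,
#'   `n_methylated_sites`, `total_meth_reads`, `total_reads`, `body_level`.
#' @export
compute_body_levels <- function(calls, catalog, min_reads = 4,
                                error_rate = 0.005, alpha = 0.01) {
  sites <- annotate_sites(calls, catalog, min_reads)
  sites <- call_methylated_sites(sites, error_rate, alpha)
  sites |>
    group_by(.data$gene_id, .data$context) |>
    summarise(n_covered_sites = n(),
              n_methylated_sites = sum(.data$methylated),
              total_meth_reads = sum(.data$count_methylated),
              total_reads = sum(.data$count_methylated) +
                sum(.data$count_unmethylated),
              .groups = "drop") |>
    mutate(body_level = .data$total_meth_reads / .data$total_reads)
}

#' Genome-background methylated-site proportions
#'
#' Pools site-level methylation calls over all non-TE gene bodies: for each
#' context, `p` = methylated covered sites / covered sites. This is the null
#' rate for the body-methylation binomial test.
#'
#' @param profiles Profile tibble from [compute_body_levels()].
#' @param catalog Gene catalog (identifies TE genes).
#' @return Tibble `context`, `p`, `n_sites`. A context with zero covered
#'   sites gets `p = NA` with a warning.
#' @export
compute_background <- function(profiles, catalog) {
  non_te <- catalog$gene_id[!catalog$is_te]
  out <- profiles |>
    filter(.data$gene_id %in% non_te) |>
    group_by(.data$context) |>
    summarise(n_sites = sum(.data$n_covered_sites),
              p = sum(.data$n_methylated_sites) /
                sum(.data$n_covered_sites),
              .groups = "drop")
  out <- tibble(context = c("CG", "CHG", "CHH")) |>
    left_join(out, by = "context")
  if (anyNA(out$p)) {
    warn(sprintf("no covered sites in context(s): %s; classification disabled there",
                 paste(out$context[is.na(out$p)], collapse = ", ")))
  }
  out
}

#' Classify body-methylated genes per context
#'
#' For each gene with at least `min_sites` covered sites in a context, tests
#' the count of methylated sites k among n covered sites against the genome
#' background rate. Under the default rule a gene is body-methylated in a
#' context iff its level is NOT significantly lower than background:
#' lower-tail p = P(Bin(n, p_ctx) <= k), BH-corrected across genes within
#' context, methylated iff q >= `alpha`. The alternative `"enrichment"` rule
#' uses the upper tail and calls methylated iff q < `alpha`.
#'
#' @param profiles Profile tibble from [compute_body_levels()].
#' @param background Background rates from [compute_background()].
#' @param alpha Significance threshold on BH q-values.
#' @param min_sites Minimum covered sites for a defined status.
#' @param rule `"not_lower"` (default, see above) or `"enrichment"`.
#' @return Tibble `gene_id`, `context`, `n_covered_sites`,
#'   `n_methylated_sites`, `p_value`, `q_value`, `methylated`.
#' @export
classify_body_methylation <- function(profiles, background, alpha = 0.05,
                                      min_sites = 5,
                                      rule = c("not_lower", "enrichment")) {
  rule <- match.arg(rule)
  x <- profiles |>
    filter(.data$n_covered_sites >= min_sites) |>
    left_join(select(background, "context", bg_p = "p"), by = "context") |>
    filter(!is.na(.data$bg_p))
  if (nrow(x) == 0) {
    return(tibble(gene_id = character(), context = character(),
                  n_covered_sites = integer(), n_methylated_sites = integer(),
                  p_value = numeric(), q_value = numeric(),
                  methylated = logical()))
  }
  x$p_value <- if (rule == "not_lower") {
    pbinom(x$n_methylated_sites, x$n_covered_sites, x$bg_p)
  } else {
    pbinom(x$n_methylated_sites - 1L, x$n_covered_sites, x$bg_p,
           lower.tail = FALSE)
  }
  x <- x |>
    group_by(.data$context) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup()
  x$methylated <- if (rule == "not_lower") x$q_value >= alpha else
    x$q_value < alpha
  select(x, "gene_id", "context", "n_covered_sites", "n_methylated_sites",
         "p_value", "q_value", "methylated")
}

# wide per-gene flags from a classification table
status_flags <- function(statuses) {
  statuses |>
    select("gene_id", "context", "methylated") |>
    tidyr::pivot_wider(names_from = "context", values_from = "methylated") |>
    (\(d) {
      for (cx in c("CG", "CHG", "CHH")) if (!cx %in% names(d)) d[[cx]] <- NA
      d
    })()
}

#' Partition duplicate pairs into methylation-context classes
#'
#' Using wild-type statuses: a pair is `CG_only` when at least one copy is
#' body-CG-methylated and neither copy is body-CHG- or body-CHH-methylated;
#' `all_context` when at least one copy is body-CG-methylated and some copy
#' carries CHG or CHH body methylation; `unmethylated` otherwise. Pairs with
#' a missing status in any context for either copy are excluded
#' (`meth_class = NA`, `exclusion_reason` set).
#'
#' @param pairs Pair tibble (`gene_a`, `gene_b`, ...).
#' @param statuses Wild-type classification from
#'   [classify_body_methylation()].
#' @return `pairs` with `meth_class` and `exclusion_reason` columns.
#' @export
partition_pairs <- function(pairs, statuses) {
  flags <- status_flags(statuses)
  x <- pairs |>
    left_join(flags, by = c(gene_a = "gene_id")) |>
    rename(cg_a = "CG", chg_a = "CHG", chh_a = "CHH") |>
    left_join(flags, by = c(gene_b = "gene_id")) |>
    rename(cg_b = "CG", chg_b = "CHG", chh_b = "CHH")
  has_all <- complete.cases(x[, c("cg_a", "chg_a", "chh_a",
                                  "cg_b", "chg_b", "chh_b")])
  any_bcgm <- x$cg_a | x$cg_b
  any_noncg <- x$chg_a | x$chh_a | x$chg_b | x$chh_b
  x$meth_class <- dplyr::case_when(
    !has_all ~ NA_character_,
    any_bcgm & !any_noncg ~ "CG_only",
    any_bcgm & any_noncg ~ "all_context",
    TRUE ~ "unmethylated")
  x$exclusion_reason <- if_else(has_all, NA_character_,
                                "missing body-methylation status")
  select(x, dplyr::all_of(names(pairs)), "meth_class", "exclusion_reason")
}

#' Test wild-type versus mutant differential body methylation per gene
#'
#' Fisher's exact test on the 2x2 table of pooled body reads
#' (methylated/unmethylated x genotype), per gene and context, BH-corrected
#' across genes within context. Direction is `loss` when the mutant level is
#' below wild type and the test is significant.
#'
#' @param profile_wt,profile_mut Profile tibbles from
#'   [compute_body_levels()] for the two genotypes.
#' @param context Context to test (default CG).
#' @param alpha Significance threshold on q-values.
#' @return Tibble `gene_id`, `wt_level`, `mut_level`, `p_value`, `q_value`,
#'   `direction` (`loss`/`gain`/`none`).
#' @export
test_differential_methylation <- function(profile_wt, profile_mut,
                                          context = "CG", alpha = 0.05) {
  ctx <- context
  w <- filter(profile_wt, .data$context == ctx)
  m <- filter(profile_mut, .data$context == ctx)
  x <- inner_join(
    select(w, "gene_id", wt_meth = "total_meth_reads",
           wt_total = "total_reads", wt_level = "body_level"),
    select(m, "gene_id", mut_meth = "total_meth_reads",
           mut_total = "total_reads", mut_level = "body_level"),
    by = "gene_id") |>
    filter(.data$wt_total > 0, .data$mut_total > 0)
  if (nrow(x) == 0) {
    return(tibble(gene_id = character(), wt_level = numeric(),
                  mut_level = numeric(), p_value = numeric(),
                  q_value = numeric(), direction = character()))
  }
  x$p_value <- vapply(seq_len(nrow(x)), function(i) {
    tab <- matrix(c(x$wt_meth[i], x$wt_total[i] - x$wt_meth[i],
                    x$mut_meth[i], x$mut_total[i] - x$mut_meth[i]),
                  nrow = 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  x$q_value <- p.adjust(x$p_value, method = "BH")
  x$direction <- dplyr::case_when(
    x$q_value >= alpha ~ "none",
    x$mut_level < x$wt_level ~ "loss",
    TRUE ~ "gain")
  select(x, "gene_id", "wt_level", "mut_level", "p_value", "q_value",
         "direction")
}

#' Flag duplicate pairs with significant body-CG-methylation loss
#'
#' A pair is BCGM-reduced when at least one copy shows a significant
#' methylation difference with mutant level below wild type.
#'
#' @param pairs Pair tibble.
#' @param diffmeth Per-gene results from [test_differential_methylation()].
#' @return `pairs` with logical `bcgm_reduced` column.
#' @export
flag_bcgm_reduced <- function(pairs, diffmeth) {
  loss <- diffmeth$gene_id[diffmeth$direction == "loss"]
  mutate(pairs, bcgm_reduced = .data$gene_a %in% loss |
           .data$gene_b %in% loss)
}

#' Between-copy body methylation divergence
#'
#' Absolute difference of the two copies' body levels in one genotype and
#' context. Pairs where either copy has an undefined level are dropped.
#'
#' @param pairs Pair tibble.
#' @param profiles Profile tibble for one genotype.
#' @param context Methylation context.
#' @return `pairs` with `level_a`, `level_b`, `divergence` columns (rows with
#'   defined levels only).
#' @export
bcgm_divergence <- function(pairs, profiles, context = "CG") {
  ctx <- context
  lv <- profiles |>
    filter(.data$context == ctx, .data$total_reads > 0) |>
    select("gene_id", "body_level")
  pairs |>
    inner_join(rename(lv, level_a = "body_level"),
               by = c(gene_a = "gene_id")) |>
    inner_join(rename(lv, level_b = "body_level"),
               by = c(gene_b = "gene_id")) |>
    mutate(divergence = abs(.data$level_a - .data$level_b))
}
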
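#' Run the full duplicate-methylation analysis pipeline
#'
#' Executes every stage in dependency order: duplicate classification from
#' homology, body-methylation profiling and classification, wild-type versus
#' mutant differential methylation, expression filtering and differential
#' expression, between-copy divergence comparisons, copy-group dynamics (the
#' 10-group convergent/divergent taxonomy), and dS/dN estimation with
#' affected-versus-unaffected stratification. Statistics that the study
#' design reports separately for pairs with CG-only methylation and pairs
#' with all-context methylation are computed per class.
#'
#' @param study A `dupmeth_study` from [simulate_study()], or a list of file
#'   paths with elements `gff`, `blast`, `cx_wt`, `cx_mut`, `expression`,
#'   and optionally `cds` (read with the package readers).
#' @param min_reads Minimum reads per cytosine site.
#' @param fpkm_threshold Expressed-gene FPKM threshold (strict `>`).
#' @param alpha Significance threshold for all q-value decisions.
#' @param max_ds dS validity cutoff for dS/dN results.
#' @param top_k,max_evalue Homology candidate filter parameters.
#' @param min_block_anchors,max_rank_gap,proximal_max_gap Collinearity and
#'   classification parameters.
#' @param stages Character vector of stages to run (subset of `"classify"`,
#'   `"methylation"`, `"expression"`, `"dynamics"`, `"kaks"`); later stages
#'   require earlier ones.
#' @return A list of class `dupmeth_report`; see the package vignette for
#'   the component tables. When `study` carries ground truth, a `recovery`
#'   table compares classified categories with planted truth.
#' @export
run_pipeline <- function(study,
                         min_reads = 4, fpkm_threshold = 0.1, alpha = 0.05,
                         max_ds = 3, top_k = 5, max_evalue = 1e-10,
                         min_block_anchors = 5, max_rank_gap = 25,
                         proximal_max_gap = 10,
                         stages = c("classify", "methylation", "expression",
                                    "dynamics", "kaks")) {
  stages <- match.arg(stages, several.ok = TRUE)
  log <- list()
  note <- function(stage, msg, n_in = NA, n_out = NA) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, message = msg,
                                       n_in = n_in, n_out = n_out)
  }
  if (inherits(study, "dupmeth_study")) {
    catalog <- study$catalog
    homology <- study$homology
    cx_wt <- study$methylomes$wt
    cx_mut <- study$methylomes$mut
    expression <- study$expression
    cds <- study$cds
    truth <- study$truth
  } else {
    needed <- c("gff", "blast", "cx_wt", "cx_mut", "expression")
    missing <- setdiff(needed, names(study))
    if (length(missing) > 0) {
      abort(sprintf("input list is missing: %s",
                    paste(missing, collapse = ", ")))
    }
    catalog <- read_gene_catalog(study$gff)
    homology <- read_blast_hits(study$blast)
    cx_wt <- read_cx_report(study$cx_wt)
    cx_mut <- read_cx_report(study$cx_mut)
    expression <- read_expression(study$expression)
    cds <- if (!is.null(study$cds)) read_cds_fasta(study$cds) else character()
    truth <- NULL
  }
  report <- list(params = list(
    min_reads = min_reads, fpkm_threshold = fpkm_threshold, alpha = alpha,
    max_ds = max_ds, top_k = top_k, max_evalue = max_evalue,
    min_block_anchors = min_block_anchors, max_rank_gap = max_rank_gap,
    proximal_max_gap = proximal_max_gap))
  report$n_genes <- nrow(catalog)

  ## -- classify -------------------------------------------------------
  cls <- classify_from_homology(homology, catalog, top_k, max_evalue,
                                min_block_anchors, max_rank_gap,
                                proximal_max_gap)
  note("classify", "homology hits -> candidate pairs",
       nrow(homology), nrow(cls$candidates))
  pairs <- cls$pairs
  report$candidates <- cls$candidates
  report$blocks <- cls$blocks
  report$pairs <- pairs
  report$table1 <- pairs |>
    group_by(category = .data$category) |>
    summarise(n_pairs = n(),
              n_distinct_genes = dplyr::n_distinct(c(.data$gene_a,
                                                     .data$gene_b)),
              .groups = "drop")
  if (!is.null(truth) && nrow(truth$pairs) > 0) {
    tr <- truth$pairs |>
      mutate(key = pair_key(.data$gene_a, .data$gene_b)) |>
      select("key", true_category = "category")
    got <- pairs |>
      mutate(key = pair_key(.data$gene_a, .data$gene_b)) |>
      select("key", "category")
    joined <- left_join(tr, got, by = "key")
    report$recovery <- joined |>
      group_by(category = .data$true_category) |>
      summarise(n_true = n(),
                n_recovered = sum(!is.na(.data$category) &
                                    .data$category == .data$true_category),
                .groups = "drop") |>
      mutate(rate = .data$n_recovered / .data$n_true)
  }
  if (!"methylation" %in% stages) {
    report$log <- bind_rows(log)
    return(structure(report, class = "dupmeth_report"))
  }

  ## -- methylation ----------------------------------------------------
  prof_wt <- compute_body_levels(cx_wt, catalog, min_reads)
  prof_mut <- compute_body_levels(cx_mut, catalog, min_reads)
  background <- compute_background(prof_wt, catalog)
  statuses_wt <- classify_body_methylation(prof_wt, background,
                                           alpha = alpha)
  pairs_m <- partition_pairs(pairs, statuses_wt)
  note("methylation", "pairs with a defined methylation class",
       nrow(pairs), sum(!is.na(pairs_m$meth_class)))
  pair_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  diffmeth <- test_differential_methylation(
    filter(prof_wt, .data$gene_id %in% pair_genes),
    filter(prof_mut, .data$gene_id %in% pair_genes),
    context = "CG", alpha = alpha)
  pairs_m <- flag_bcgm_reduced(pairs_m, diffmeth)
  div_wt <- bcgm_divergence(pairs_m, prof_wt)
  div_mut <- bcgm_divergence(pairs_m, prof_mut)
  meth_div <- bind_rows(mutate(div_wt, genotype = "wt"),
                        mutate(div_mut, genotype = "mut"))
  meth_div_tests <- divergence_ks_table(meth_div)
  report$methylation <- list(
    background = background,
    statuses_wt = statuses_wt,
    class_counts = count(pairs_m, .data$meth_class),
    diffmeth = diffmeth,
    divergence = meth_div,
    divergence_tests = meth_div_tests)
  report$pairs_annotated <- pairs_m
  if (!"expression" %in% stages) {
    report$log <- bind_rows(log)
    return(structure(report, class = "dupmeth_report"))
  }

  ## -- expression -----------------------------------------------------
  expressed <- call_expressed(expression, fpkm_threshold)
  pairs_e <- filter_expressed_pairs(pairs_m, expressed)
  de_gt <- de_between_genotypes(
    filter(expression, .data$gene_id %in% pair_genes), alpha = alpha)
  pairs_e <- flag_affected_pairs(pairs_e, de_gt, alpha = alpha)
  # the analysis set: methylation-classified, expressed, BCGM-reduced pairs
  analysis <- filter(pairs_e, !is.na(.data$meth_class),
                     .data$meth_class != "unmethylated",
                     .data$retained, .data$bcgm_reduced)
  note("expression", "analysis set (classified, expressed, BCGM-reduced)",
       nrow(pairs_e), nrow(analysis))
  de_copies <- bind_rows(
    mutate(de_between_copies(analysis, expression, "wt", alpha),
           genotype = "wt"),
    mutate(de_between_copies(analysis, expression, "mut", alpha),
           genotype = "mut"))
  expr_div <- bind_rows(
    mutate(expression_divergence(analysis, expression, "wt"),
           genotype = "wt"),
    mutate(expression_divergence(analysis, expression, "mut"),
           genotype = "mut"))
  expr_div_tests <- divergence_ks_table(expr_div)
  correlations <- expr_copy_correlations(analysis, expression)
  report$expression <- list(
    expressed = expressed, de_genotypes = de_gt, de_copies = de_copies,
    divergence = expr_div, divergence_tests = expr_div_tests,
    correlations = correlations)
  report$analysis_pairs <- pairs_e
  report$table2 <- table2_counts(pairs_e)
  if (!"dynamics" %in% stages) {
    report$log <- bind_rows(log)
    return(structure(report, class = "dupmeth_report"))
  }

  ## -- dynamics -------------------------------------------------------
  dyn <- list()
  for (cl in c("CG_only", "all_context")) {
    set <- filter(analysis, .data$meth_class == cl)
    if (nrow(set) == 0) next
    roles <- assign_roles(set, expression)
    cats <- categorize_changes(roles, de_gt)
    dyn[[cl]] <- list(
      categories = cats,
      shift_higher = group_shift_test(cats, de_gt, "higher"),
      shift_lower = group_shift_test(cats, de_gt, "lower"),
      convergence = convergence_summary(cats))
  }
  report$dynamics <- dyn
  if (!"kaks" %in% stages || length(cds) == 0) {
    report$log <- bind_rows(log)
    return(structure(report, class = "dupmeth_report"))
  }

  ## -- kaks -----------------------------------------------------------
  dnds <- ng86_pairs(select(pairs_e, "gene_a", "gene_b", "category"),
                     cds, max_ds = max_ds)
  note("kaks", "pairs with valid dS/dN", nrow(dnds), sum(dnds$valid))
  ds_by_cat <- filter(dnds, .data$valid)
  anova_ds <- if (nrow(ds_by_cat) > 0 &&
                  dplyr::n_distinct(ds_by_cat$category) >= 2) {
    compare_groups_anova(ds_by_cat$ds, ds_by_cat$category, alpha)
  } else NULL
  strat <- stratify_by_affect(dnds, pairs_e)
  report$kaks <- list(dnds = dnds, anova_ds = anova_ds,
                      stratification = strat)
  report$log <- bind_rows(log)
  structure(report, class = "dupmeth_report")
}

# KS comparison of wild-type vs mutant divergence distributions, per
# methylation class and duplication category (plus pooled categories).
divergence_ks_table <- function(div) {
  out <- list()
  classes <- unique(div$meth_class[!is.na(div$meth_class) &
                                     div$meth_class != "unmethylated"])
  for (cl in classes) {
    d <- filter(div, .data$meth_class == cl)
    for (cat in c(sort(unique(d$category)), "all")) {
      dd <- if (cat == "all") d else filter(d, .data$category == cat)
      w <- dd$divergence[dd$genotype == "wt"]
      m <- dd$divergence[dd$genotype == "mut"]
      ks <- if (length(w) >= 3 && length(m) >= 3) {
        suppressWarnings(ks.test(w, m))
      } else list(statistic = NA_real_, p.value = NA_real_)
      out[[length(out) + 1L]] <- tibble(
        meth_class = cl, category = cat,
        n = length(w), wt_mean = mean(w), mut_mean = mean(m),
        reduced = mean(m) < mean(w),
        statistic = unname(ks$statistic), p_value = ks$p.value)
    }
  }
  bind_rows(out)
}

# Pearson correlation of between-copy log2 expression per genotype/class.
expr_copy_correlations <- function(analysis, expression, pseudocount = 0.01) {
  out <- list()
  for (cl in unique(analysis$meth_class)) {
    set <- filter(analysis, .data$meth_class == cl)
    for (gt in c("wt", "mut")) {
      d <- expression_divergence(set, expression, gt, pseudocount)
      if (nrow(d) < 4) next
      ct <- correlate(log2(d$fpkm_a + pseudocount),
                      log2(d$fpkm_b + pseudocount))
      out[[length(out) + 1L]] <- bind_cols(
        tibble(meth_class = cl, genotype = gt), ct)
    }
  }
  bind_rows(out)
}

# Table-2-style audit: per category and methylation class, how many pairs
# are expressed, BCGM-reduced, and expression-affected.
table2_counts <- function(pairs_e) {
  pairs_e |>
    filter(!is.na(.data$meth_class), .data$meth_class != "unmethylated") |>
    group_by(.data$meth_class, .data$category) |>
    summarise(
      n_identified = n(),
      n_expressed = sum(.data$retained),
      n_bcgm_reduced = sum(.data$retained & .data$bcgm_reduced),
      pct_bcgm_reduced = 100 * sum(.data$retained & .data$bcgm_reduced) /
        pmax(1, sum(.data$retained)),
      n_affected = sum(.data$retained & .data$bcgm_reduced & .data$affected),
      pct_affected = 100 *
        sum(.data$retained & .data$bcgm_reduced & .data$affected) /
        pmax(1, sum(.data$retained & .data$bcgm_reduced)),
      .groups = "drop")
}

#' @export
print.dupmeth_report <- function(x, ...) {
  cat("dupmeth pipeline report\n")
  cat(sprintf("  genes: %d; candidate pairs: %d\n",
              x$n_genes, nrow(x$candidates)))
  if (!is.null(x$table1)) {
    cat("  duplicate pairs by category:\n")
    for (i in seq_len(nrow(x$table1))) {
      cat(sprintf("    %-10s %6d pairs, %6d genes\n",
                  x$table1$category[i], x$table1$n_pairs[i],
                  x$table1$n_distinct_genes[i]))
    }
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-category recovery: %.1f%%\n",
                100 * sum(x$recovery$n_recovered) / sum(x$recovery$n_true)))
  }
  if (!is.null(x$methylation)) {
    cc <- x$methylation$class_counts
    cat(sprintf("  methylation classes: %s\n",
                paste(sprintf("%s=%s", cc$meth_class, cc$n), collapse = ", ")))
  }
  if (!is.null(x$dynamics) && length(x$dynamics) > 0) {
    for (cl in names(x$dynamics)) {
      cs <- x$dynamics[[cl]]$convergence$tests
      ov <- cs[cs$comparison == "convergent vs divergent", ]
      cat(sprintf("  %s: convergent %d vs divergent %d (binomial p = %.3g)\n",
                  cl, ov$n_a, ov$n_b, ov$p_value))
    }
  }
  invisible(x)
}

#' Tidy the headline statistics of a pipeline report
#'
#' @param x A `dupmeth_report`.
#' @param ... Unused.
#' @return A long tibble (`stage`, `meth_class`, `category`, `statistic`,
#'   `value`) of the report's divergence tests, copy-group shift tests and
#'   convergence tests.
#' @export
#' @importFrom generics tidy
tidy.dupmeth_report <- function(x, ...) {
  out <- list()
  grab_ks <- function(tbl, stage) {
    if (is.null(tbl)) return(NULL)
    tbl |>
      tidyr::pivot_longer(c("wt_mean", "mut_mean", "statistic", "p_value"),
                          names_to = "statistic_name",
                          values_to = "value") |>
      transmute(stage = stage, meth_class = .data$meth_class,
                category = .data$category,
                statistic = .data$statistic_name, value = .data$value)
  }
  if (!is.null(x$methylation)) {
    out[[length(out) + 1L]] <- grab_ks(x$methylation$divergence_tests,
                                       "methylation_divergence")
  }
  if (!is.null(x$expression)) {
    out[[length(out) + 1L]] <- grab_ks(x$expression$divergence_tests,
                                       "expression_divergence")
  }
  for (cl in names(x$dynamics)) {
    d <- x$dynamics[[cl]]
    out[[length(out) + 1L]] <- bind_rows(d$shift_higher, d$shift_lower) |>
      transmute(stage = "copy_group_shift", meth_class = cl,
                category = .data$role, statistic = "p_value",
                value = .data$p_value)
    out[[length(out) + 1L]] <- d$convergence$tests |>
      transmute(stage = "convergence", meth_class = cl,
                category = .data$comparison, statistic = "p_value",
                value = .data$p_value)
  }
  bind_rows(out)
}

#' One-row summary of a pipeline report
#'
#' @inheritParams tidy.dupmeth_report
#' @return One-row tibble: pair counts, recovery rate, share of analysis
#'   pairs that are BCGM-reduced and expression-affected, and the pooled
#'   convergent fraction (CG-only class).
#' @export
#' @importFrom generics glance
glance.dupmeth_report <- function(x, ...) {
  t2 <- x$table2
  cg <- if (!is.null(t2)) filter(t2, .data$meth_class == "CG_only") else NULL
  conv_frac <- NA_real_
  if (!is.null(x$dynamics$CG_only)) {
    cnt <- x$dynamics$CG_only$convergence$counts
    conv_frac <- sum(cnt$n[cnt$class == "convergent"]) / max(1, sum(cnt$n))
  }
  tibble(
    n_genes = x$n_genes,
    n_pairs = nrow(x$pairs),
    recovery_rate = if (!is.null(x$recovery)) {
      sum(x$recovery$n_recovered) / sum(x$recovery$n_true)
    } else NA_real_,
    pct_bcgm_reduced_cg_only = if (!is.null(cg) && nrow(cg) > 0) {
      100 * sum(cg$n_bcgm_reduced) / max(1, sum(cg$n_expressed))
    } else NA_real_,
    pct_affected_cg_only = if (!is.null(cg) && nrow(cg) > 0) {
      100 * sum(cg$n_affected) / max(1, sum(cg$n_bcgm_reduced))
    } else NA_real_,
    convergent_fraction_cg_only = conv_frac)
}
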
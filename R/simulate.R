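#' Configuration for a synthetic duplicate-methylation study
#'
#' Builds the parameter set for [simulate_study()]. Defaults describe the
#' study conditions the package emulates: a rice-like genome of 12
#' chromosomes, four duplicate-origin categories in roughly the proportions
#' observed for rice duplicates, a mutant genotype retaining 9% of wild-type
#' gene-body CG methylation (i.e. ~91% loss) with CHG and CHH untouched, and
#' expression of the two copies of a pair coupled to the amount of body CG
#' methylation each copy loses: the higher-expressed copy tends down, the
#' lower-expressed copy tends up.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes placed on each chromosome (0 allowed).
#' @param category_counts Named integer vector with elements `WGD`, `tandem`,
#'   `proximal`, `transposed`: duplicate pairs to plant per origin category.
#' @param cg_retention_mutant Fraction of each gene's wild-type CG body
#'   methylation level retained in the mutant (0.09 = 91% loss).
#' @param mean_coverage Poisson mean read coverage per cytosine site.
#' @param sites_per_gene Named vector (`CG`, `CHG`, `CHH`): cytosine sites
#'   simulated inside each gene body per context.
#' @param bcgm_expression_coupling Log2-units of expression change per unit
#'   of body CG methylation lost; applied with negative sign to the
#'   higher-expressed copy of a pair and positive sign to the lower one.
#' @param nb_dispersion Negative-binomial dispersion of read counts
#'   (variance = mu + dispersion * mu^2).
#' @param n_replicates RNA-seq replicates per genotype.
#' @param seed Master seed; every stage draws from a named substream derived
#'   from it, so outputs are byte-identical for identical configurations.
#' @param prob_bcgm Probability that a gene is body-CG-methylated.
#' @param prob_noncg Probability that a gene also carries CHG/CHH body
#'   methylation (such genes make a pair "all-context").
#' @param te_fraction Fraction of genes flagged as transposable-element
#'   related (never planted in pairs, excluded from background rates).
#' @param wgd_block_size Anchors per planted collinear block.
#' @param proximal_max_gap Maximum rank gap for a proximal pair.
#' @param max_rank_gap Chaining gap bound, used here to keep transposed
#'   anchors out of planted block corridors.
#' @param n_decoys Decoy homology hits between non-duplicate genes.
#' @param decoy_hard_mode If `TRUE`, decoy E-values fall below the candidate
#'   threshold so they survive filtering and stress the classifier.
#' @param expression_log2_mean,expression_log2_sd Log2 mean-count
#'   distribution across pairs.
#' @param copy_log2_delta_sd SD of the half-normal between-copy log2
#'   expression difference planted in wild type.
#' @param expression_noise_sd Per-gene log2 noise added to the mutant mean.
#' @param codons_per_cds Codons per simulated coding sequence.
#' @param chromosome_length Optional fixed chromosome length (bp). When
#'   supplied and too short for the requested gene count an error is raised;
#'   by default length is sized to fit.
#'
#' @return A list of class `dupmeth_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 40,
#'                          category_counts = c(WGD = 6, tandem = 3,
#'                                              proximal = 3, transposed = 4),
#'                          seed = 1)
simulation_config <- function(n_chromosomes = 12,
                              genes_per_chromosome = 400,
                              category_counts = c(WGD = 470, tandem = 290,
                                                  proximal = 340,
                                                  transposed = 900),
                              cg_retention_mutant = 0.09,
                              mean_coverage = 20,
                              sites_per_gene = c(CG = 40, CHG = 80, CHH = 150),
                              bcgm_expression_coupling = 1.2,
                              nb_dispersion = 0.05,
                              n_replicates = 2,
                              seed = 1,
                              prob_bcgm = 0.55,
                              prob_noncg = 0.35,
                              te_fraction = 0.05,
                              wgd_block_size = 10,
                              proximal_max_gap = 10,
                              max_rank_gap = 25,
                              n_decoys = 200,
                              decoy_hard_mode = FALSE,
                              expression_log2_mean = 5,
                              expression_log2_sd = 1.5,
                              copy_log2_delta_sd = 2,
                              expression_noise_sd = 0.15,
                              codons_per_cds = 300,
                              chromosome_length = NULL) {
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(genes_per_chromosome, "genes_per_chromosome", positive = FALSE)
  assert_fraction(cg_retention_mutant, "cg_retention_mutant")
  assert_fraction(prob_bcgm, "prob_bcgm")
  assert_fraction(prob_noncg, "prob_noncg")
  assert_fraction(te_fraction, "te_fraction")
  if (mean_coverage <= 0) abort("`mean_coverage` must be positive")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive")
  assert_count(n_replicates, "n_replicates")
  assert_count(seed, "seed", positive = FALSE)
  needed <- c("WGD", "tandem", "proximal", "transposed")
  if (!all(needed %in% names(category_counts))) {
    abort(sprintf("`category_counts` must name all of: %s",
                  paste(needed, collapse = ", ")))
  }
  category_counts <- vapply(category_counts[needed], function(x)
    assert_count(x, "category_counts", positive = FALSE), integer(1))
  if (!all(c("CG", "CHG", "CHH") %in% names(sites_per_gene))) {
    abort("`sites_per_gene` must name CG, CHG and CHH")
  }
  total_genes <- n_chromosomes * genes_per_chromosome
  n_usable <- floor(total_genes * (1 - te_fraction))
  if (2 * sum(category_counts) > n_usable) {
    abort(sprintf(paste0("infeasible config: %d pairs need %d non-TE genes ",
                         "but only ~%d are available"),
                  sum(category_counts), 2 * sum(category_counts), n_usable))
  }
  structure(list(
    n_chromosomes = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    category_counts = category_counts,
    cg_retention_mutant = cg_retention_mutant,
    mean_coverage = mean_coverage,
    sites_per_gene = sites_per_gene[c("CG", "CHG", "CHH")],
    bcgm_expression_coupling = bcgm_expression_coupling,
    nb_dispersion = nb_dispersion,
    n_replicates = n_replicates,
    seed = as.integer(seed),
    prob_bcgm = prob_bcgm,
    prob_noncg = prob_noncg,
    te_fraction = te_fraction,
    wgd_block_size = as.integer(wgd_block_size),
    proximal_max_gap = as.integer(proximal_max_gap),
    max_rank_gap = as.integer(max_rank_gap),
    n_decoys = as.integer(n_decoys),
    decoy_hard_mode = isTRUE(decoy_hard_mode),
    expression_log2_mean = expression_log2_mean,
    expression_log2_sd = expression_log2_sd,
    copy_log2_delta_sd = copy_log2_delta_sd,
    expression_noise_sd = expression_noise_sd,
    codons_per_cds = as.integer(codons_per_cds),
    chromosome_length = chromosome_length
  ), class = "dupmeth_sim_config")
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping, strand-assigned genes on each chromosome with
#' 1-based inclusive coordinates. Gene rank is the ordinal position on its
#' chromosome; a configurable fraction of genes is flagged TE-related.
#'
#' @param config A [simulation_config()] object.
#' @return A gene-catalog tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`, `is_te`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "dupmeth_sim_config"))
  n_chr <- config$n_chromosomes
  n_g <- config$genes_per_chromosome
  if (n_g == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  rank = integer(), is_te = logical()))
  }
  with_substream(config$seed, "annotation", {
    per_chr <- lapply(seq_len(n_chr), function(chr) {
      len <- sample(1500:3500, n_g, replace = TRUE)
      gap <- sample(200:2000, n_g, replace = TRUE)
      start <- cumsum(gap) + cumsum(c(0L, head(len, -1L)))
      end <- start + len - 1L
      if (!is.null(config$chromosome_length) &&
          max(end) > config$chromosome_length) {
        abort(sprintf(paste0("infeasible config: %d genes do not fit on a ",
                             "chromosome of length %d (need %d bp)"),
                      n_g, config$chromosome_length, max(end)))
      }
      tibble(
        gene_id = sprintf("LOC_Os%02dg%05d", chr, seq_len(n_g) * 10L),
        chrom = sprintf("Chr%02d", chr),
        start = as.integer(start),
        end = as.integer(end),
        strand = sample(c("+", "-"), n_g, replace = TRUE),
        rank = seq_len(n_g)
      )
    })
    catalog <- bind_rows(per_chr)
    n_te <- floor(nrow(catalog) * config$te_fraction)
    catalog$is_te <- FALSE
    if (n_te > 0) {
      catalog$is_te[sample(nrow(catalog), n_te)] <- TRUE
    }
    catalog
  })
}

# Find all start offsets of runs of >= size consecutive TRUEs.
run_starts <- function(free, size) {
  if (size == 0 || length(free) < size) return(integer())
  ok <- vapply(seq_len(length(free) - size + 1L),
               function(i) all(free[i:(i + size - 1L)]), logical(1))
  which(ok)
}

#' Plant duplicate pairs of the four origin categories
#'
#' Selects non-TE genes from the catalog and plants: tandem pairs (rank
#' adjacent), proximal pairs (rank gap 2..`proximal_max_gap`), WGD pairs (as
#' runs of consecutive rank-collinear anchors spanning two chromosomes, half
#' of the blocks inverted), and transposed pairs (dispersed cross-chromosome
#' singleton anchors, kept out of block gap-corridors so they cannot chain
#' into a planted block). Emits a BLAST outfmt-6-style homology table
#' containing every planted pair below the candidate E-value threshold plus
#' decoy hits between non-duplicate genes.
#'
#' @param catalog Gene catalog from [generate_annotation()].
#' @param config A [simulation_config()].
#' @return A list with `pairs` (tibble `gene_a`, `gene_b`, `category`,
#'   `block_id`), and `homology` (outfmt-6 tibble).
#' @export
plant_duplicates <- function(catalog, config) {
  stopifnot(inherits(config, "dupmeth_sim_config"))
  counts <- config$category_counts
  empty_pairs <- tibble(gene_a = character(), gene_b = character(),
                        category = character(), block_id = integer())
  with_substream(config$seed, "duplicates", {
    chroms <- unique(catalog$chrom)
    # eligibility per chromosome: rank -> gene row; free & non-TE
    by_chr <- split(catalog, catalog$chrom)
    free <- lapply(by_chr, function(df) {
      f <- rep(FALSE, max(df$rank))
      f[df$rank[!df$is_te]] <- TRUE
      f
    })
    id_of <- lapply(by_chr, function(df) {
      ids <- character(max(df$rank)); ids[df$rank] <- df$gene_id; ids
    })
    pairs <- list()
    corridors <- list()  # per planted block: chr pair + rank ranges
    fail <- function(cat) {
      abort(sprintf("infeasible placement for category '%s'", cat))
    }

    ## WGD blocks
    n_wgd <- counts[["WGD"]]
    block_id <- 0L
    if (n_wgd > 0) {
      if (length(chroms) < 2) fail("WGD")
      if (n_wgd < 5) {
        abort("infeasible placement for category 'WGD': at least 5 pairs are needed to form one collinear block")
      }
      bs <- max(config$wgd_block_size, 5L)
      n_blocks <- max(1L, n_wgd %/% bs)
      sizes <- rep(n_wgd %/% n_blocks, n_blocks)
      extra <- n_wgd - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      stopifnot(sum(sizes) == n_wgd, all(sizes >= 5))
      for (sz in sizes) {
        placed <- FALSE
        for (attempt in seq_len(200)) {
          cc <- sample(chroms, 2)
          s1 <- run_starts(free[[cc[1]]], sz)
          s2 <- run_starts(free[[cc[2]]], sz)
          if (length(s1) == 0 || length(s2) == 0) next
          r1 <- s1[sample.int(length(s1), 1)]
          r2 <- s2[sample.int(length(s2), 1)]
          ranks1 <- r1:(r1 + sz - 1L)
          ranks2 <- r2:(r2 + sz - 1L)
          if (runif(1) < 0.5) ranks2 <- rev(ranks2)  # inverted block
          block_id <- block_id + 1L
          pairs[[length(pairs) + 1L]] <- tibble(
            gene_a = id_of[[cc[1]]][ranks1],
            gene_b = id_of[[cc[2]]][ranks2],
            category = "WGD", block_id = block_id)
          free[[cc[1]]][ranks1] <- FALSE
          free[[cc[2]]][ranks2] <- FALSE
          corridors[[length(corridors) + 1L]] <- list(
            c1 = cc[1], c2 = cc[2],
            r1 = range(ranks1), r2 = range(ranks2))
          placed <- TRUE
          break
        }
        if (!placed) fail("WGD")
      }
    }

    ## tandem
    for (i in seq_len(counts[["tandem"]])) {
      placed <- FALSE
      for (attempt in seq_len(500)) {
        cc <- sample(chroms, 1)
        f <- free[[cc]]
        cand <- which(f & c(f[-1], FALSE))
        if (length(cand) == 0) next
        r <- cand[sample.int(length(cand), 1)]
        pairs[[length(pairs) + 1L]] <- tibble(
          gene_a = id_of[[cc]][r], gene_b = id_of[[cc]][r + 1L],
          category = "tandem", block_id = NA_integer_)
        free[[cc]][c(r, r + 1L)] <- FALSE
        placed <- TRUE
        break
      }
      if (!placed) fail("tandem")
    }

    ## proximal
    for (i in seq_len(counts[["proximal"]])) {
      placed <- FALSE
      for (attempt in seq_len(500)) {
        cc <- sample(chroms, 1)
        g <- sample(2:config$proximal_max_gap, 1)
        f <- free[[cc]]
        n <- length(f)
        if (n <= g) next
        cand <- which(f[seq_len(n - g)] & f[(1L + g):n])
        if (length(cand) == 0) next
        r <- cand[sample.int(length(cand), 1)]
        pairs[[length(pairs) + 1L]] <- tibble(
          gene_a = id_of[[cc]][r], gene_b = id_of[[cc]][r + g],
          category = "proximal", block_id = NA_integer_)
        free[[cc]][c(r, r + g)] <- FALSE
        placed <- TRUE
        break
      }
      if (!placed) fail("proximal")
    }

    ## transposed: cross-chromosome, outside block corridors
    gap <- config$max_rank_gap
    in_corridor <- function(c1, r1, c2, r2) {
      for (co in corridors) {
        hit <- (co$c1 == c1 && co$c2 == c2 &&
                  r1 >= co$r1[1] - gap && r1 <= co$r1[2] + gap &&
                  r2 >= co$r2[1] - gap && r2 <= co$r2[2] + gap) ||
          (co$c1 == c2 && co$c2 == c1 &&
             r2 >= co$r1[1] - gap && r2 <= co$r1[2] + gap &&
             r1 >= co$r2[1] - gap && r1 <= co$r2[2] + gap)
        if (hit) return(TRUE)
      }
      FALSE
    }
    for (i in seq_len(counts[["transposed"]])) {
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        if (length(chroms) < 2) fail("transposed")
        cc <- sample(chroms, 2)
        f1 <- which(free[[cc[1]]]); f2 <- which(free[[cc[2]]])
        if (length(f1) == 0 || length(f2) == 0) next
        r1 <- f1[sample.int(length(f1), 1)]
        r2 <- f2[sample.int(length(f2), 1)]
        if (in_corridor(cc[1], r1, cc[2], r2)) next
        pairs[[length(pairs) + 1L]] <- tibble(
          gene_a = id_of[[cc[1]]][r1], gene_b = id_of[[cc[2]]][r2],
          category = "transposed", block_id = NA_integer_)
        free[[cc[1]]][r1] <- FALSE
        free[[cc[2]]][r2] <- FALSE
        placed <- TRUE
        break
      }
      if (!placed) fail("transposed")
    }

    pairs <- if (length(pairs) > 0) order_pair(bind_rows(pairs)) else empty_pairs
    homology <- make_homology(pairs, catalog, config)
    list(pairs = pairs, homology = homology)
  })
}

# BLAST outfmt-6 hit rows for planted pairs (both directions) plus decoys.
make_homology <- function(pairs, catalog, config) {
  outfmt6 <- function(q, s, evalue) {
    n <- length(q)
    len <- sample(150:900, n, replace = TRUE)
    tibble(qseqid = q, sseqid = s,
           pident = round(runif(n, 70, 98), 2),
           length = len,
           mismatch = as.integer(round(len * runif(n, 0.02, 0.25))),
           gapopen = sample(0:4, n, replace = TRUE),
           qstart = 1L, qend = len, sstart = 1L, send = len,
           evalue = evalue,
           bitscore = round(runif(n, 200, 1500), 1))
  }
  true_hits <- if (nrow(pairs) > 0) {
    ev <- 10 ^ -runif(nrow(pairs), 20, 180)
    bind_rows(outfmt6(pairs$gene_a, pairs$gene_b, ev),
              outfmt6(pairs$gene_b, pairs$gene_a, ev))
  } else NULL
  decoys <- NULL
  eligible <- catalog$gene_id[!catalog$is_te]
  if (config$n_decoys > 0 && length(eligible) >= 2) {
    planted <- if (nrow(pairs) > 0) pair_key(pairs$gene_a, pairs$gene_b) else character()
    q <- sample(eligible, config$n_decoys, replace = TRUE)
    s <- sample(eligible, config$n_decoys, replace = TRUE)
    keep <- q != s & !(pair_key(q, s) %in% planted)
    q <- q[keep]; s <- s[keep]
    ev <- if (config$decoy_hard_mode) {
      10 ^ -runif(length(q), 10.1, 30)
    } else {
      10 ^ -runif(length(q), 0, 9.9)
    }
    if (length(q) > 0) decoys <- outfmt6(q, s, ev)
  }
  hits <- bind_rows(true_hits, decoys)
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- outfmt6(character(), character(), numeric())
  }
  arrange(hits, .data$qseqid, .data$evalue)
}

#' Draw per-gene true methylation levels and expression means
#'
#' Assigns every catalog gene a true body methylation level per context and
#' genotype (mutant CG = wild-type CG x `cg_retention_mutant`; CHG/CHH equal
#' across genotypes), designates the higher/lower-expressed copy of every
#' planted pair in wild type, and couples each copy's mutant expression to
#' its own true CG methylation loss (sign opposite for the two roles).
#'
#' @param catalog Gene catalog.
#' @param pairs Planted pair table from [plant_duplicates()].
#' @param config A [simulation_config()].
#' @return A list of class `dupmeth_truth`: `pairs`, `gene_levels` (long
#'   tibble gene/context/genotype true levels), `gene_expression`
#'   (per-gene role, true log2 means per genotype, true CG loss).
#' @export
draw_ground_truth <- function(catalog, pairs, config) {
  stopifnot(inherits(config, "dupmeth_sim_config"))
  with_substream(config$seed, "truth", {
    n <- nrow(catalog)
    bcgm <- runif(n) < config$prob_bcgm
    noncg <- runif(n) < config$prob_noncg
    # TE genes: heavily methylated in all contexts (excluded from analyses)
    bcgm[catalog$is_te] <- TRUE
    noncg[catalog$is_te] <- TRUE
    cg_wt <- if_else(bcgm, rbeta(n, 7.5, 2.5), runif(n, 0.005, 0.03))
    chg_wt <- if_else(noncg, rbeta(n, 4, 6), runif(n, 0.004, 0.02))
    chh_wt <- if_else(noncg, rbeta(n, 2, 8), runif(n, 0.005, 0.025))
    gene_levels <- bind_rows(
      tibble(gene_id = catalog$gene_id, context = "CG",
             wt_level = cg_wt, mut_level = cg_wt * config$cg_retention_mutant),
      tibble(gene_id = catalog$gene_id, context = "CHG",
             wt_level = chg_wt, mut_level = chg_wt),
      tibble(gene_id = catalog$gene_id, context = "CHH",
             wt_level = chh_wt, mut_level = chh_wt)
    )
    cg_loss <- setNames(cg_wt * (1 - config$cg_retention_mutant),
                        catalog$gene_id)

    ## expression truth
    expr <- tibble(gene_id = catalog$gene_id,
                   pair_id = NA_character_, role = NA_character_,
                   wt_log2 = rnorm(n, config$expression_log2_mean,
                                   config$expression_log2_sd))
    if (nrow(pairs) > 0) {
      pid <- pair_key(pairs$gene_a, pairs$gene_b)
      base <- rnorm(nrow(pairs), config$expression_log2_mean,
                    config$expression_log2_sd)
      delta <- abs(rnorm(nrow(pairs), 0, config$copy_log2_delta_sd))
      a_higher <- runif(nrow(pairs)) < 0.5
      hi <- if_else(a_higher, pairs$gene_a, pairs$gene_b)
      lo <- if_else(a_higher, pairs$gene_b, pairs$gene_a)
      idx_hi <- match(hi, expr$gene_id)
      idx_lo <- match(lo, expr$gene_id)
      expr$pair_id[idx_hi] <- pid; expr$pair_id[idx_lo] <- pid
      expr$role[idx_hi] <- "higher"; expr$role[idx_lo] <- "lower"
      expr$wt_log2[idx_hi] <- base + delta / 2
      expr$wt_log2[idx_lo] <- base - delta / 2
    }
    sgn <- dplyr::case_when(expr$role == "higher" ~ -1,
                            expr$role == "lower" ~ 1,
                            TRUE ~ 0)
    loss <- unname(cg_loss[expr$gene_id])
    expr$cg_loss <- loss
    expr$mut_log2 <- expr$wt_log2 +
      sgn * config$bcgm_expression_coupling * loss +
      rnorm(n, 0, config$expression_noise_sd)

    structure(list(pairs = pairs, gene_levels = gene_levels,
                   gene_expression = expr),
              class = "dupmeth_truth")
  })
}

#' Simulate per-cytosine methylation reports for both genotypes
#'
#' Places cytosine sites inside each gene body (both strands), draws coverage
#' Poisson(`mean_coverage`) per site and genotype, and methylated counts
#' binomially at the gene's true level for that context and genotype.
#' Zero-coverage sites are emitted with 0/0 counts. Site positions are shared
#' between genotypes (same genome).
#'
#' @param catalog Gene catalog.
#' @param truth Ground truth from [draw_ground_truth()].
#' @param config A [simulation_config()].
#' @return List with cytosine-report tibbles `wt` and `mut` (columns `chrom`,
#'   `pos`, `strand`, `count_methylated`, `count_unmethylated`, `context`,
#'   `trinucleotide`), sorted by position.
#' @export
simulate_methylomes <- function(catalog, truth, config) {
  stopifnot(inherits(config, "dupmeth_sim_config"),
            inherits(truth, "dupmeth_truth"))
  spg <- config$sites_per_gene
  n_per_gene <- sum(spg)
  if (nrow(catalog) == 0 || n_per_gene == 0) {
    empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                    count_methylated = integer(),
                    count_unmethylated = integer(),
                    context = character(), trinucleotide = character())
    return(list(wt = empty, mut = empty))
  }
  sites <- with_substream(config$seed, "sites", {
    n_genes <- nrow(catalog)
    span <- catalog$end - catalog$start + 1L
    if (any(span < n_per_gene)) {
      abort("gene bodies too short for the requested sites_per_gene")
    }
    offs <- lapply(seq_len(n_genes),
                   function(i) sort(sample.int(span[i], n_per_gene)))
    ctx <- rep(c(rep("CG", spg[["CG"]]), rep("CHG", spg[["CHG"]]),
                 rep("CHH", spg[["CHH"]])), n_genes)
    tri_pool <- list(CG = c("CGA", "CGT", "CGC", "CGG"),
                     CHG = c("CAG", "CTG", "CCG"),
                     CHH = c("CAT", "CTA", "CAA", "CTT", "CCA"))
    n_sites <- n_genes * n_per_gene
    tri <- character(n_sites)
    for (cx in names(tri_pool)) {
      idx <- which(ctx == cx)
      tri[idx] <- sample(tri_pool[[cx]], length(idx), replace = TRUE)
    }
    tibble(
      gene_id = rep(catalog$gene_id, each = n_per_gene),
      chrom = rep(catalog$chrom, each = n_per_gene),
      pos = rep(catalog$start, each = n_per_gene) + unlist(offs) - 1L,
      strand = sample(c("+", "-"), n_sites, replace = TRUE),
      context = ctx,
      trinucleotide = tri
    )
  })
  draw <- function(genotype, stream) {
    lvl_col <- if (genotype == "wt") "wt_level" else "mut_level"
    lv <- truth$gene_levels |>
      select("gene_id", "context", level = dplyr::all_of(lvl_col))
    s <- left_join(sites, lv, by = c("gene_id", "context"))
    with_substream(config$seed, stream, {
      cov <- rpois(nrow(s), config$mean_coverage)
      meth <- rbinom(nrow(s), cov, s$level)
      s |>
        mutate(count_methylated = meth,
               count_unmethylated = cov - meth) |>
        select("chrom", "pos", "strand", "count_methylated",
               "count_unmethylated", "context", "trinucleotide") |>
        arrange(.data$chrom, .data$pos)
    })
  }
  list(wt = draw("wt", "methylome_wt"), mut = draw("mut", "methylome_mut"))
}

#' Simulate replicate RNA-seq counts and FPKM for both genotypes
#'
#' Draws negative-binomial counts around each gene's true mean
#' (2^`wt_log2` / 2^`mut_log2` from the ground truth) for `n_replicates`
#' replicates per genotype, and computes FPKM from count, gene length, and
#' the replicate's realized library size.
#'
#' @param catalog Gene catalog.
#' @param truth Ground truth from [draw_ground_truth()].
#' @param config A [simulation_config()].
#' @return Expression tibble: `gene_id`, `genotype` (`wt`/`mut`),
#'   `replicate`, `count`, `fpkm`, `library_size`, `gene_length`.
#' @export
simulate_expression <- function(catalog, truth, config) {
  stopifnot(inherits(config, "dupmeth_sim_config"),
            inherits(truth, "dupmeth_truth"))
  ge <- truth$gene_expression
  len <- setNames(catalog$end - catalog$start + 1L, catalog$gene_id)
  with_substream(config$seed, "expression", {
    reps <- expand.grid(gene_id = ge$gene_id,
                        genotype = c("wt", "mut"),
                        replicate = seq_len(config$n_replicates),
                        stringsAsFactors = FALSE) |>
      as_tibble() |>
      left_join(select(ge, "gene_id", "wt_log2", "mut_log2"), by = "gene_id") |>
      mutate(mu = 2 ^ if_else(.data$genotype == "wt",
                              .data$wt_log2, .data$mut_log2),
             count = rnbinom(n(), mu = .data$mu,
                             size = 1 / config$nb_dispersion),
             gene_length = unname(len[.data$gene_id])) |>
      group_by(.data$genotype, .data$replicate) |>
      mutate(library_size = sum(.data$count)) |>
      ungroup() |>
      mutate(fpkm = .data$count /
               ((.data$gene_length / 1e3) * (.data$library_size / 1e6))) |>
      select("gene_id", "genotype", "replicate", "count", "fpkm",
             "library_size", "gene_length")
    arrange(reps, .data$gene_id, .data$genotype, .data$replicate)
  })
}

#' Generate paired coding sequences with controlled substitution counts
#'
#' For each planted pair an ancestral coding sequence (start codon plus
#' random sense codons) is copied, and the second copy receives a target
#' number of synonymous and nonsynonymous single-nucleotide substitutions
#' (never creating stop codons). Targets derive from a per-category dS range
#' and a dN/dS ratio drawn per pair; realized counts are recorded.
#'
#' @param truth Ground truth from [draw_ground_truth()].
#' @param config A [simulation_config()].
#' @param ds_ranges Named list of c(min, max) target dS per category.
#' @param dnds_range Range of target dN/dS per pair.
#' @return List with `cds` (named character vector of CDS, one per paired
#'   gene) and `substitutions` (tibble `gene_a`, `gene_b`, `syn_subs`,
#'   `nonsyn_subs`, `target_ds`, `target_dnds`).
#' @export
generate_cds_pairs <- function(truth, config,
                               ds_ranges = list(WGD = c(0.5, 0.85),
                                                tandem = c(0.23, 0.63),
                                                proximal = c(0.22, 0.64),
                                                transposed = c(0.4, 1.0)),
                               dnds_range = c(0.1, 0.5)) {
  stopifnot(inherits(config, "dupmeth_sim_config"),
            inherits(truth, "dupmeth_truth"))
  pairs <- truth$pairs
  if (nrow(pairs) == 0) {
    return(list(cds = character(),
                substitutions = tibble(gene_a = character(),
                                       gene_b = character(),
                                       syn_subs = integer(),
                                       nonsyn_subs = integer(),
                                       target_ds = numeric(),
                                       target_dnds = numeric())))
  }
  nb <- codon_neighbors()
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[
                     Biostrings::GENETIC_CODE == "*"])
  n_codons <- config$codons_per_cds
  # rough site totals for converting a target dS into a substitution count
  s_sites <- 0.25 * 3 * n_codons
  n_sites <- 0.75 * 3 * n_codons
  p_from_d <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  with_substream(config$seed, "cds", {
    cds <- character(0)
    res <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      anc <- c("ATG", sample(sense, n_codons - 1L, replace = TRUE))
      ds_r <- ds_ranges[[pairs$category[i]]]
      target_ds <- runif(1, ds_r[1], ds_r[2])
      target_dnds <- runif(1, dnds_range[1], dnds_range[2])
      syn_n <- max(1L, round(p_from_d(target_ds) * s_sites))
      nonsyn_n <- round(p_from_d(target_ds * target_dnds) * n_sites)
      mutated <- mutate_codons(anc, syn_n, nonsyn_n, nb)
      cds[[pairs$gene_a[i]]] <- paste(anc, collapse = "")
      cds[[pairs$gene_b[i]]] <- paste(mutated$codons, collapse = "")
      res[[i]] <- tibble(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
                         syn_subs = mutated$syn, nonsyn_subs = mutated$nonsyn,
                         target_ds = target_ds, target_dnds = target_dnds)
    }
    list(cds = cds, substitutions = bind_rows(res))
  })
}

# Precomputed single-nucleotide codon neighbourhoods (synonymous and
# nonsynonymous-non-stop), keyed by codon.
codon_neighbors <- function() {
  cache <- .dupmeth_cache$codon_neighbors
  if (!is.null(cache)) return(cache)
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc_tab)
  syn <- list(); nonsyn <- list()
  for (cd in codons) {
    s <- character(0); ns <- character(0)
    for (p in 1:3) for (b in bases) {
      if (substr(cd, p, p) == b) next
      alt <- cd
      substr(alt, p, p) <- b
      if (gc_tab[[alt]] == "*") next
      if (gc_tab[[alt]] == gc_tab[[cd]]) s <- c(s, alt) else ns <- c(ns, alt)
    }
    syn[[cd]] <- s; nonsyn[[cd]] <- ns
  }
  out <- list(syn = syn, nonsyn = nonsyn)
  .dupmeth_cache$codon_neighbors <- out
  out
}

# Apply n_syn synonymous then n_nonsyn nonsynonymous random single-nt
# substitutions to a codon vector; errors if a request cannot be met.
mutate_codons <- function(codons, n_syn, n_nonsyn, nb = codon_neighbors()) {
  apply_k <- function(codons, k, pool) {
    applied <- 0L
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(50)) {
        pos <- sample.int(length(codons), 1)
        cand <- pool[[codons[pos]]]
        if (length(cand) == 0) next
        codons[pos] <- cand[sample.int(length(cand), 1)]
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf("could not place requested substitution %d of %d", j, k))
      }
      applied <- applied + 1L
    }
    list(codons = codons, applied = applied)
  }
  s <- apply_k(codons, n_syn, nb$syn)
  n <- apply_k(s$codons, n_nonsyn, nb$nonsyn)
  list(codons = n$codons, syn = s$applied, nonsyn = n$applied)
}

#' Simulate a complete synthetic study
#'
#' Runs all generator stages in order: annotation, duplicate planting and
#' homology, ground truth, methylomes for both genotypes, expression tables,
#' and paired coding sequences. Deterministic given the config (one master
#' seed, named substreams per stage).
#'
#' @param config A [simulation_config()].
#' @return A list of class `dupmeth_study` with elements `config`, `catalog`,
#'   `truth`, `homology`, `methylomes` (list `wt`/`mut`), `expression`,
#'   `cds`, `substitutions`.
#' @export
#' @examples
#' cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 30,
#'                          category_counts = c(WGD = 5, tandem = 2,
#'                                              proximal = 2, transposed = 3),
#'                          sites_per_gene = c(CG = 10, CHG = 10, CHH = 15),
#'                          codons_per_cds = 60, seed = 7)
#' study <- simulate_study(cfg)
#' study$truth$pairs
simulate_study <- function(config) {
  stopifnot(inherits(config, "dupmeth_sim_config"))
  catalog <- generate_annotation(config)
  planted <- plant_duplicates(catalog, config)
  truth <- draw_ground_truth(catalog, planted$pairs, config)
  methylomes <- simulate_methylomes(catalog, truth, config)
  expression <- simulate_expression(catalog, truth, config)
  cds <- generate_cds_pairs(truth, config)
  structure(list(config = config, catalog = catalog, truth = truth,
                 homology = planted$homology, methylomes = methylomes,
                 expression = expression, cds = cds$cds,
                 substitutions = cds$substitutions),
            class = "dupmeth_study")
}
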
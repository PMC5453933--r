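test_that("configuration validation rejects infeasible designs", {
  expect_error(simulation_config(cg_retention_mutant = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_chromosomes = 1,
                                 genes_per_chromosome = 10,
                                 category_counts = c(WGD = 50, tandem = 0,
                                                     proximal = 0,
                                                     transposed = 0)),
               "infeasible")
  expect_error(simulation_config(nb_dispersion = 0), "positive")
  expect_error(
    generate_annotation(simulation_config(n_chromosomes = 1,
                                          genes_per_chromosome = 30,
                                          category_counts = c(WGD = 0,
                                                              tandem = 1,
                                                              proximal = 1,
                                                              transposed = 0),
                                          chromosome_length = 5000)),
    "infeasible")
})

test_that("an empty gene count yields an empty catalog and a header-only GFF3", {
  cfg <- simulation_config(n_chromosomes = 1, genes_per_chromosome = 0,
                           category_counts = c(WGD = 0, tandem = 0,
                                               proximal = 0, transposed = 0))
  cat0 <- generate_annotation(cfg)
  expect_equal(nrow(cat0), 0)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(cat0, f)
  lines <- readLines(f)
  expect_true(grepl("^##gff-version 3", lines[1]))
  expect_true(all(grepl("^#", lines)))
})

test_that("annotation is deterministic, ranked, and non-overlapping", {
  cfg <- simulation_config(n_chromosomes = 2, genes_per_chromosome = 50,
                           category_counts = c(WGD = 5, tandem = 2,
                                               proximal = 2, transposed = 2))
  cat1 <- generate_annotation(cfg)
  cat2 <- generate_annotation(cfg)
  expect_identical(cat1, cat2)
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(cat1, f1)
  write_gff3(cat2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(cat1), 100)
  for (chr in unique(cat1$chrom)) {
    g <- cat1[cat1$chrom == chr, ]
    expect_equal(sort(g$rank), 1:50)
    # pairwise interval scan: no overlaps
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    expect_true(all(g$start <= g$end))
  }
})

test_that("planted pairs satisfy their category geometry", {
  study <- small_study()
  catalog <- study$catalog
  pairs <- study$truth$pairs
  info <- setNames(paste(catalog$chrom, catalog$rank), catalog$gene_id)
  chrom_of <- setNames(catalog$chrom, catalog$gene_id)
  rank_of <- setNames(catalog$rank, catalog$gene_id)

  tandem <- pairs[pairs$category == "tandem", ]
  expect_true(all(chrom_of[tandem$gene_a] == chrom_of[tandem$gene_b]))
  expect_true(all(abs(rank_of[tandem$gene_a] - rank_of[tandem$gene_b]) == 1))

  prox <- pairs[pairs$category == "proximal", ]
  gaps <- abs(rank_of[prox$gene_a] - rank_of[prox$gene_b])
  expect_true(all(chrom_of[prox$gene_a] == chrom_of[prox$gene_b]))
  expect_true(all(gaps >= 2 & gaps <= 10))

  transp <- pairs[pairs$category == "transposed", ]
  expect_true(all(chrom_of[transp$gene_a] != chrom_of[transp$gene_b]))

  # no TE genes and no gene reused across pairs
  genes <- c(pairs$gene_a, pairs$gene_b)
  expect_false(any(catalog$is_te[match(genes, catalog$gene_id)]))
  expect_equal(anyDuplicated(genes), 0)

  # planted WGD blocks are recoverable by the block detector
  cand <- filter_candidates(study$homology, catalog)
  blocks <- detect_collinear_blocks(cand, catalog)
  wgd_keys <- with(pairs[pairs$category == "WGD", ],
                   paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b)))
  block_keys <- with(blocks, paste(pmin(gene_a, gene_b),
                                   pmax(gene_a, gene_b)))
  expect_true(all(wgd_keys %in% block_keys))
})

test_that("methylome simulation respects retention and conservation", {
  cfg <- small_config()
  study <- small_study()
  wt <- study$methylomes$wt
  mut <- study$methylomes$mut
  # conservation and shared site positions
  expect_true(all(wt$count_methylated >= 0 & wt$count_unmethylated >= 0))
  expect_identical(wt[c("chrom", "pos", "context")],
                   mut[c("chrom", "pos", "context")])

  # retention 0: every mutant CG site fully unmethylated
  cfg0 <- small_config(seed = 7, cg_retention_mutant = 0)
  st0 <- simulate_study(cfg0)
  cg_mut <- st0$methylomes$mut
  expect_true(all(cg_mut$count_methylated[cg_mut$context == "CG"] == 0))
  # CHG/CHH untouched by the mutation: same true levels by construction
  gl <- st0$truth$gene_levels
  expect_equal(gl$wt_level[gl$context != "CG"],
               gl$mut_level[gl$context != "CG"])
})

test_that("estimated mutant body level matches binomial expectation", {
  # one gene, true WT CG level 0.8, retention 0.09 -> mutant truth 0.072;
  # 200 CG sites at coverage 20 must estimate it within 3 binomial SEs
  cfg <- simulation_config(
    n_chromosomes = 1, genes_per_chromosome = 1,
    category_counts = c(WGD = 0, tandem = 0, proximal = 0, transposed = 0),
    cg_retention_mutant = 0.09, mean_coverage = 20,
    sites_per_gene = c(CG = 200, CHG = 0, CHH = 0),
    te_fraction = 0, seed = 3)
  catalog <- generate_annotation(cfg)
  truth <- structure(list(
    pairs = tibble::tibble(gene_a = character(), gene_b = character(),
                           category = character(), block_id = integer()),
    gene_levels = tibble::tibble(
      gene_id = rep(catalog$gene_id, 3),
      context = c("CG", "CHG", "CHH"),
      wt_level = c(0.8, 0.01, 0.01),
      mut_level = c(0.8 * 0.09, 0.01, 0.01)),
    gene_expression = tibble::tibble(gene_id = catalog$gene_id)),
    class = "dupmeth_truth")
  meth <- simulate_methylomes(catalog, truth, cfg)
  prof <- compute_body_levels(meth$mut, catalog)
  lvl <- prof$body_level[prof$context == "CG"]
  se <- sqrt(0.072 * (1 - 0.072) / (200 * 20))
  expect_lt(abs(lvl - 0.072), 3 * se)
})

test_that("expression truth couples to methylation loss as configured", {
  # coupling 0 and no noise: identical genotype means
  cfg0 <- small_config(seed = 5, bcgm_expression_coupling = 0,
                       expression_noise_sd = 0)
  catalog <- generate_annotation(cfg0)
  planted <- plant_duplicates(catalog, cfg0)
  truth0 <- draw_ground_truth(catalog, planted$pairs, cfg0)
  expect_equal(truth0$gene_expression$mut_log2,
               truth0$gene_expression$wt_log2)

  # positive coupling: higher copies shift down, lower copies up
  study <- small_study()
  ge <- study$truth$gene_expression
  shift <- ge$mut_log2 - ge$wt_log2
  hi <- shift[!is.na(ge$role) & ge$role == "higher" & ge$cg_loss > 0.3]
  lo <- shift[!is.na(ge$role) & ge$role == "lower" & ge$cg_loss > 0.3]
  expect_lt(mean(hi), 0)
  expect_gt(mean(lo), 0)
})

test_that("FPKM is consistent with counts, length and library size", {
  expr <- small_study()$expression
  recomputed <- expr$count /
    ((expr$gene_length / 1e3) * (expr$library_size / 1e6))
  expect_equal(expr$fpkm, recomputed)
  # scaling counts and library size together leaves FPKM unchanged
  scaled <- expr$count * 2 /
    ((expr$gene_length / 1e3) * (expr$library_size * 2 / 1e6))
  expect_equal(scaled, expr$fpkm)
})

test_that("CDS pair generation controls substitutions and avoids stops", {
  nb <- dupmeth:::codon_neighbors()
  anc <- c("ATG", "GCT", "CGA", "TTA", "GGG", "CCC")
  same <- dupmeth:::mutate_codons(anc, 0, 0, nb)
  expect_identical(same$codons, anc)

  study <- small_study()
  gc_tab <- Biostrings::GENETIC_CODE
  for (s in study$cds[1:4]) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(gc_tab[codons] == "*"))
  }

  # synonymous-only divergence gives dS > 0, dN = 0
  set.seed(9)
  anc300 <- c("ATG", sample(names(gc_tab)[gc_tab != "*"], 299, TRUE))
  mutd <- dupmeth:::mutate_codons(anc300, 10, 0, nb)
  aln <- structure(list(codons_a = anc300, codons_b = mutd$codons),
                   class = "codon_alignment")
  res <- compute_ng86(aln)
  expect_equal(res$dn, 0)
  expect_gt(res$ds, 0)
})

test_that("the study is byte-identical under a repeated seed", {
  s1 <- simulate_study(small_config(seed = 99))
  s2 <- simulate_study(small_config(seed = 99))
  s1$config <- s2$config <- NULL
  expect_identical(s1[names(s1) != "truth"], s2[names(s2) != "truth"])
  expect_identical(s1$truth$pairs, s2$truth$pairs)
  expect_identical(s1$truth$gene_levels, s2$truth$gene_levels)
})
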
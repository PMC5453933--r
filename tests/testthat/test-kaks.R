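test_that("global alignment matches expectations and the exhaustive oracle", {
  b62 <- dupmeth:::blosum62()
  # identical sequences: gapless, score = sum of diagonal entries
  aln <- align_pair("MKV", "MKV")
  expect_equal(aln$a, "MKV")
  expect_equal(aln$b, "MKV")
  expect_equal(aln$score, b62["M", "M"] + b62["K", "K"] + b62["V", "V"])
  # classic one-gap case
  aln2 <- align_pair("ACD", "AD")
  expect_equal(aln2$a, "ACD")
  expect_equal(aln2$b, "A-D")
  # empty input errors
  expect_error(align_pair("", "MKV"), "empty")
  # exhaustive enumeration oracle on short sequences
  set.seed(11)
  aas <- c("A", "C", "D", "E", "G", "K", "M", "V", "W", "Y")
  for (i in 1:12) {
    a <- paste(sample(aas, sample(2:6, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:6, 1), TRUE), collapse = "")
    got <- align_pair(a, b)$score
    want <- oracle_align_score(a, b, b62)
    expect_equal(got, want, label = sprintf("%s vs %s", a, b))
  }
})

test_that("backtranslation expands codons and round-trips", {
  aln <- list(a = "MK-V", b = "MKAV")
  cds_a <- "ATGAAAGTT"
  cds_b <- "ATGAAAGCTGTT"
  got <- backtranslate(aln, cds_a, cds_b)
  expect_equal(got$codons_a, c("ATG", "AAA", "---", "GTT"))
  expect_equal(got$codons_b, c("ATG", "AAA", "GCT", "GTT"))
  # protein gap at column k becomes codon gap at that column
  expect_equal(which(got$codons_a == "---"), 3L)
  # round trip: translating the codon columns reproduces the alignment
  tr <- dupmeth:::translate_codons(got$codons_b)
  expect_equal(paste(tr, collapse = ""), aln$b)
  # violations are caught and name the gene
  expect_error(backtranslate(aln, "ATGAAA", cds_b, id_a = "geneX"), "geneX")
  expect_error(backtranslate(aln, "ATGAAAGCA", cds_b, id_a = "geneX"),
               "translate")
})

test_that("NG86 structural properties hold", {
  # identical sequences: zero divergence, undefined ratio
  same <- structure(list(codons_a = c("ATG", "GCT", "CGA"),
                         codons_b = c("ATG", "GCT", "CGA")),
                    class = "codon_alignment")
  got <- compute_ng86(same)
  expect_equal(got$ds, 0)
  expect_equal(got$dn, 0)
  expect_true(is.na(got$dn_ds))
  # site conservation: S + N = 3 x codons, with or without differences
  expect_equal(got$S_sites + got$N_sites, 9)
  # symmetry under sequence swap
  p <- random_codon_pair(30, 12)
  a1 <- structure(list(codons_a = p$a, codons_b = p$b),
                  class = "codon_alignment")
  a2 <- structure(list(codons_a = p$b, codons_b = p$a),
                  class = "codon_alignment")
  r1 <- compute_ng86(a1); r2 <- compute_ng86(a2)
  expect_equal(r1$Sd, r2$Sd)
  expect_equal(r1$Nd, r2$Nd)
  expect_equal(r1$ds, r2$ds)
  # monotonicity: one extra synonymous difference cannot decrease dS
  base <- structure(list(codons_a = c("TTA", "GCT", "GGA"),
                         codons_b = c("TTA", "GCT", "GGA")),
                    class = "codon_alignment")
  plus <- structure(list(codons_a = c("TTA", "GCT", "GGA"),
                         codons_b = c("TTG", "GCT", "GGA")),
                    class = "codon_alignment")
  expect_gte(compute_ng86(plus)$ds, compute_ng86(base)$ds)
  # gap and ambiguity columns are dropped and counted
  amb <- structure(list(codons_a = c("ATG", "---", "GNA", "GGA"),
                        codons_b = c("ATG", "GCT", "GGA", "GGA")),
                   class = "codon_alignment")
  expect_equal(compute_ng86(amb)$n_dropped, 2)
  expect_error(compute_ng86(structure(list(codons_a = "---",
                                           codons_b = "GCT"),
                                      class = "codon_alignment")),
               "no ungapped")
})

test_that("NG86 agrees with the independent brute-force oracle", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_codon_pair(sample(3:10, 1), sample(0:6, 1))
    got <- compute_ng86(structure(list(codons_a = p$a, codons_b = p$b),
                                  class = "codon_alignment"))
    want <- oracle_ng86(p$a, p$b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-9)
    expect_equal(got$N_sites, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$ds, want$ds, tolerance = 1e-9)
    expect_equal(got$dn, want$dn, tolerance = 1e-9)
  }
})

test_that("realized substitution counts track NG86 estimates", {
  # 100 simulated 300-codon pairs spanning a wide divergence range
  set.seed(10)
  nb <- dupmeth:::codon_neighbors()
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  n <- 100
  syn <- integer(n); nonsyn <- integer(n); ds <- numeric(n); dn <- numeric(n)
  for (i in seq_len(n)) {
    anc <- c("ATG", sample(sense, 299, TRUE))
    m <- dupmeth:::mutate_codons(anc, sample(5:110, 1), sample(0:40, 1), nb)
    r <- compute_ng86(structure(list(codons_a = anc, codons_b = m$codons),
                                class = "codon_alignment"))
    syn[i] <- m$syn; nonsyn[i] <- m$nonsyn
    ds[i] <- r$ds; dn[i] <- r$dn
  }
  expect_gt(cor(syn, ds, method = "spearman"), 0.9)
  expect_gt(cor(nonsyn, dn, method = "spearman"), 0.9)
  # pipeline-scale check: the dS validity filter flags rather than drops
  dnds <- ng86_pairs(small_study()$truth$pairs, small_study()$cds)
  expect_true(any(dnds$valid))
  high <- dnds[!dnds$valid & !is.na(dnds$ds), ]
  if (nrow(high) > 0) expect_true(all(high$ds > 3 | high$ps >= 0.75))
})

test_that("affected-vs-unaffected stratification runs KS per category", {
  set.seed(5)
  dnds <- tibble::tibble(
    gene_a = sprintf("a%02d", 1:40), gene_b = sprintf("b%02d", 1:40),
    category = rep(c("WGD", "tandem"), each = 20),
    ds = c(runif(20, 0.4, 0.9), runif(20, 0.2, 0.6)),
    dn_ds = runif(40, 0.1, 0.5), valid = TRUE)
  flags <- tibble::tibble(gene_a = dnds$gene_a, gene_b = dnds$gene_b,
                          affected = rep(c(TRUE, FALSE), 20))
  got <- stratify_by_affect(dnds, flags)
  expect_equal(nrow(got), 4)
  expect_true(all(got$n_affected == 10 & got$n_unaffected == 10))
  # identical distributions in both arms -> D = 0, p = 1
  dnds2 <- dnds; dnds2$ds <- rep(rep(c(0.3, 0.5), 10), 2)
  dnds2$dn_ds <- 0.2
  flags2 <- flags; flags2$affected <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  got2 <- stratify_by_affect(dnds2, flags2)
  ks_dnds <- got2[got2$measure == "dn_ds", ]
  expect_true(all(ks_dnds$statistic == 0))
  expect_true(all(ks_dnds$p_value == 1))
  # undersized groups are skipped with a warning
  expect_warning(
    stratify_by_affect(dnds[1:4, ],
                       dplyr::mutate(flags[1:4, ], affected = c(TRUE, FALSE,
                                                                FALSE, FALSE))),
    "too small")
})
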
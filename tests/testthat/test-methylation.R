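mk_calls <- function(pos, meth, unmeth, context = "CG", chrom = "Chr01") {
  n <- max(length(pos), length(meth), length(unmeth))
  tibble::tibble(chrom = chrom, pos = rep_len(pos, n), strand = "+",
                 count_methylated = rep_len(meth, n),
                 count_unmethylated = rep_len(unmeth, n),
                 context = rep_len(context, n), trinucleotide = "CGA")
}

one_gene <- toy_catalog("Chr01", 1)  # body 1000..1500

test_that("body levels pool reads with the coverage filter", {
  # single site 10/10 -> level 0.5
  p <- compute_body_levels(mk_calls(1100, 10, 10), one_gene)
  expect_equal(p$body_level, 0.5)
  # a 3-read site is excluded everywhere
  p2 <- compute_body_levels(mk_calls(c(1100, 1200), c(10, 2), c(10, 1)),
                            one_gene)
  expect_equal(p2$n_covered_sites, 1)
  expect_equal(p2$total_reads, 20)
  # hand sum: {8/2, 0/10, 5/5} -> 13/30 over 3 sites
  p3 <- compute_body_levels(mk_calls(c(1100, 1200, 1300),
                                     c(8, 0, 5), c(2, 10, 5)), one_gene)
  expect_equal(p3$n_covered_sites, 3)
  expect_equal(p3$body_level, 13 / 30)
  # aggregation conservation
  expect_equal(p3$total_reads, 8 + 2 + 0 + 10 + 5 + 5)
  # scale invariance of the level
  p3x <- compute_body_levels(mk_calls(c(1100, 1200, 1300),
                                      c(8, 0, 5) * 3, c(2, 10, 5) * 3),
                             one_gene)
  expect_equal(p3x$body_level, p3$body_level)
  # undefined is distinct from zero: no CG site -> no row
  p4 <- compute_body_levels(mk_calls(1100, 0, 10, context = "CHH"), one_gene)
  expect_false("CG" %in% p4$context)
})

test_that("malformed cytosine reports fail with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr01\t100\t+\t3\t4\tCG\tCGA",
               "Chr01\t101\t+\tbad\t4\tCG\tCGA"), f)
  expect_error(read_cx_report(f), "line")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Chr01\t100\t+\t3\t4\tCXX\tCGA", f2)
  expect_error(read_cx_report(f2), "line 1")
})

test_that("site-level methylation calls match the exact binomial tail", {
  calls <- mk_calls(c(1100, 1150, 1200), c(0, 20, 2), c(20, 0, 8))
  got <- call_methylated_sites(calls, error_rate = 0.005, alpha = 0.01)
  expect_false(got$methylated[1])   # 0 of 20
  expect_true(got$methylated[2])    # 20 of 20: p = 0.005^20
  # 2 of 10: brute-force tail sum
  tail_p <- sum(sapply(2:10, function(k)
    choose(10, k) * 0.005^k * 0.995^(10 - k)))
  expect_equal(got$methylated[3], tail_p < 0.01)
  expect_error(call_methylated_sites(calls, error_rate = 0), "\\(0, 1\\)")
})

test_that("background rates pool methylated sites over non-TE genes", {
  profiles <- tibble::tibble(
    gene_id = c("g01", "g02", "gTE"), context = "CG",
    n_covered_sites = c(70L, 50L, 100L),
    n_methylated_sites = c(20L, 10L, 100L),
    total_meth_reads = 1, total_reads = 2, body_level = 0.5)
  catalog <- toy_catalog(rep("Chr01", 3), 1:3,
                         is_te = c(FALSE, FALSE, TRUE))
  catalog$gene_id <- c("g01", "g02", "gTE")
  bg <- suppressWarnings(compute_background(profiles, catalog))
  expect_equal(bg$p[bg$context == "CG"], 30 / 120)  # TE gene excluded
  expect_true(all(is.na(bg$p[bg$context != "CG"])))
  expect_warning(compute_background(profiles, catalog), "CHG")
})

test_that("the binomial body-methylation rule follows its two readings", {
  bg <- tibble::tibble(context = "CG", p = 0.3, n_sites = 1000L)
  prof <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), context = "CG",
    n_covered_sites = c(20L, 50L, 4L),
    n_methylated_sites = c(15L, 0L, 2L),
    total_meth_reads = 1, total_reads = 2, body_level = 0.5)
  got <- classify_body_methylation(prof, bg, alpha = 0.05, min_sites = 5)
  # n=20, k=15 at p=0.3: lower-tail p ~ 1 -> body-methylated
  expect_true(got$methylated[got$gene_id == "gA"])
  expect_equal(got$p_value[got$gene_id == "gA"], pbinom(15, 20, 0.3))
  # n=50, k=0: p = 0.7^50, significantly lower -> not body-methylated
  expect_equal(got$p_value[got$gene_id == "gB"], 0.7^50)
  expect_false(got$methylated[got$gene_id == "gB"])
  # n=4 < min_sites: no status at all
  expect_false("gC" %in% got$gene_id)
  # enrichment mode flips the tail
  enr <- classify_body_methylation(prof, bg, alpha = 0.05, min_sites = 5,
                                   rule = "enrichment")
  expect_true(enr$methylated[enr$gene_id == "gA"])
  expect_false(enr$methylated[enr$gene_id == "gB"])
})

test_that("classifier calibration under a null at the background rate", {
  set.seed(77)
  n_genes <- 1500
  bg <- tibble::tibble(context = "CG", p = 0.3, n_sites = 100000L)
  prof <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n_genes), context = "CG",
    n_covered_sites = 40L,
    n_methylated_sites = rbinom(n_genes, 40, 0.3),
    total_meth_reads = 1, total_reads = 2, body_level = 0.5)
  # default rule: almost everything is "not significantly lower"
  got <- classify_body_methylation(prof, bg, alpha = 0.05)
  expect_gte(mean(got$methylated), 0.95)
  # enrichment rule: false-positive rate bounded by alpha (BH conservative)
  enr <- classify_body_methylation(prof, bg, alpha = 0.05,
                                   rule = "enrichment")
  se2 <- 2 * sqrt(0.05 * 0.95 / n_genes)
  expect_lte(mean(enr$methylated), 0.05 + se2)
})

test_that("pairs partition into CG-only / all-context / unmethylated", {
  status <- function(g, cg, chg, chh) {
    tibble::tibble(gene_id = g, context = c("CG", "CHG", "CHH"),
                   n_covered_sites = 10L, n_methylated_sites = 5L,
                   p_value = 0.5, q_value = 0.5,
                   methylated = c(cg, chg, chh))
  }
  statuses <- dplyr::bind_rows(
    status("a1", TRUE, FALSE, FALSE), status("a2", FALSE, FALSE, FALSE),
    status("b1", TRUE, TRUE, FALSE), status("b2", FALSE, FALSE, FALSE),
    status("c1", FALSE, FALSE, FALSE), status("c2", FALSE, FALSE, FALSE))
  pairs <- tibble::tibble(gene_a = c("a1", "b1", "c1", "d1"),
                          gene_b = c("a2", "b2", "c2", "d2"),
                          category = "tandem")
  got <- partition_pairs(pairs, statuses)
  expect_equal(got$meth_class,
               c("CG_only", "all_context", "unmethylated", NA))
  expect_equal(got$exclusion_reason[4], "missing body-methylation status")
})

test_that("differential methylation matches the hypergeometric oracle", {
  prof <- function(meth, total, gt) {
    tibble::tibble(gene_id = "g1", context = "CG", n_covered_sites = 10L,
                   n_methylated_sites = 5L, total_meth_reads = meth,
                   total_reads = total, body_level = meth / total)
  }
  got <- test_differential_methylation(prof(50, 100), prof(5, 100))
  # oracle: two-sided Fisher p by summing hypergeometric point masses
  d_obs <- dhyper(50, 55, 145, 100)
  p_oracle <- sum(dhyper(0:55, 55, 145, 100)[
    dhyper(0:55, 55, 145, 100) <= d_obs * (1 + 1e-7)])
  expect_equal(got$p_value, p_oracle, tolerance = 1e-9)
  expect_lt(got$q_value, 0.05)
  expect_equal(got$direction, "loss")
  # identical tables: p = 1
  same <- test_differential_methylation(prof(30, 60), prof(30, 60))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
})

test_that("between-copy divergence is symmetric, bounded, zero iff equal", {
  profiles <- tibble::tibble(
    gene_id = c("x", "y", "z"), context = "CG", n_covered_sites = 10L,
    n_methylated_sites = 5L, total_meth_reads = c(90, 20, 90),
    total_reads = 100, body_level = c(0.9, 0.2, 0.9))
  pairs <- tibble::tibble(gene_a = c("x", "x"), gene_b = c("y", "z"),
                          category = "tandem")
  got <- bcgm_divergence(pairs, profiles)
  expect_equal(got$divergence, c(0.7, 0))
  swapped <- bcgm_divergence(
    tibble::tibble(gene_a = c("y", "z"), gene_b = c("x", "x"),
                   category = "tandem"), profiles)
  expect_equal(swapped$divergence, got$divergence)
  expect_true(all(got$divergence >= 0 & got$divergence <= 1))
})
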
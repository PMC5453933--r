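---
title: "Methods: linking gene-body CG methylation to duplicate-gene expression divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gene-body CG methylation to duplicate-gene expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dupmeth)
```

`dupmeth` studies a causal question: when a genome loses most of its
gene-body CG methylation (BCGM) — as in a null mutant of the major CG
methyltransferase — does the expression *difference* between the two copies
of a duplicated gene shrink? The package provides the full analysis chain
for a two-genotype (wild type vs mutant) design and a synthetic-study
generator with known ground truth, so that every statistical step can be
validated against planted signal before it is pointed at real data.

This vignette documents the model, the defaults and why they were chosen,
the numerical conventions, and the limits of what the synthetic validation
shows.

# The analysis chain

## Duplicate classification

Candidate duplicate pairs come from an all-vs-all protein homology table
(BLAST outfmt 6). A hit is retained when the subject is among the query's
top 5 subjects by ascending E-value (ties by descending bit score, then
id) **and** the E-value is strictly below 1e-10; self-hits and TE-related
genes are removed and the pair set is symmetrized.

Origin categories are assigned from gene *ranks* (ordinal position along
the chromosome) with a simplified collinearity search in place of a full
synteny pipeline:

* anchors on each chromosome pair are chained by a longest-chain dynamic
  program in which consecutive anchors must advance 1–25 ranks on the
  first chromosome and move monotonically (either direction) with the same
  gap bound on the second; chains of ≥ 5 anchors are blocks, extracted
  greedily by size with each anchor used at most once;
* precedence: block anchor → `WGD`; same chromosome and rank gap 1 →
  `tandem`; rank gap 2–10 → `proximal`; everything else → `transposed`.

Two choices deserve emphasis. First, same-chromosome hits with rank gap
≤ 10 are never used as block anchors: they are local (tandem-array-type)
hits, and admitting them lets dense runs of tandem/proximal pairs chain
into spurious "blocks". The classification rules still give genuine block
anchors precedence over adjacency. Second, `transposed` is a residual
category — no ancestral-locus dating is attempted — so its counts are
upper bounds in the presence of unusual block geometries.

The chaining DP is count-scored and deterministic (ties resolved by first
anchor position). On instances small enough to enumerate every anchor
subset, the DP provably returns a maximum-size chain; the test suite
verifies this equivalence on random instances.

## Body methylation

From a 7-column per-cytosine report (chromosome, 1-based position, strand,
methylated count, unmethylated count, context, trinucleotide), sites with
fewer than 4 total reads are discarded; the rest are assigned to the
annotated gene body (full start..end span, strands pooled). The body level
is the *read-pooled* proportion `total_meth / total_reads`, not the mean of
per-site levels — this matches the 2×2 pooling used by the Fisher test and
is robust to uneven coverage. A gene with no covered site in a context has
an *undefined* level, which is never conflated with level 0.

A site is called methylated when its methylated-read count is implausible
under the bisulfite error rate (one-sided binomial against
`error_rate = 0.005` at α = 0.01). The genome background `p_ctx` is the
proportion of methylated covered sites pooled over all non-TE gene bodies,
per context.

The body-methylated gene call tests the count of methylated sites `k`
among `n ≥ 5` covered sites against `p_ctx`. The default rule follows the
design's wording — a gene is body-methylated iff its level is **not
significantly lower** than background (lower-tail `P(Bin(n, p_ctx) ≤ k)`,
BH across genes, methylated iff q ≥ 0.05). The alternative reading — an
*enrichment* call (upper tail, methylated iff q < 0.05) — is available via
`rule = "enrichment"`, because the two readings produce different gene
sets: the default is permissive (a gene must be demonstrably hypomethylated
to lose the label), the enrichment rule conservative. Note a consequence of
the default rule: its discriminating power depends on `n` — with few
covered sites nothing can be "significantly lower", so min_sites and
realistic per-context site counts matter.

Pairs partition by wild-type statuses: `CG_only` (≥ 1 copy
body-CG-methylated, neither copy CHG- nor CHH-body-methylated),
`all_context` (≥ 1 CG-methylated copy plus some non-CG body methylation),
`unmethylated` (excluded). All downstream statistics are reported for the
CG-only and all-context classes separately, since non-CG methylation blurs
the CG-specific contrast.

Genotype differences use Fisher's exact test on the pooled 2×2 body-read
table per gene, BH-corrected; a pair is *BCGM-reduced* when at least one
copy is significant (q < 0.05) with the mutant level below wild type.
Between-copy BCGM divergence is the absolute difference of the copies'
body levels — symmetric, zero iff equal, bounded by 1.

## Expression

A gene is expressed when its replicate-mean FPKM strictly exceeds 0.1; a
pair stays in the analysis when ≥ 1 copy is expressed in ≥ 1 genotype
(so copies activated only in the mutant are retained — that is part of the
phenomenon). Differential expression uses an exact conditional binomial
test on pooled counts: given the total `t = a + b`, under the null
`a ~ Bin(t, w_a/(w_a + w_b))` with weights equal to library sizes (same
gene, two genotypes) or library × gene-length products (two genes, same
libraries). Two-sidedness is the *doubled smaller one-sided tail, capped
at 1* — stated explicitly because exact-test conventions differ; for
symmetric nulls it coincides with the minimum-likelihood convention.
Replicates are pooled by summation because the conditional test is defined
on totals.

The test is exactly calibrated under its own conditional model (verified
in the suite under Poisson noise) but, like any binomial-conditional test,
is anticonservative under strong overdispersion; per-gene calls should be
read accordingly. The package's conclusions do not rest on individual
calls: they rest on *symmetric group-level contrasts* (up vs down counts,
convergent vs divergent counts), which stay null-calibrated under
overdispersion — the null-specificity check below confirms this at the
pipeline level.

Between-copy expression divergence is `|log2((fpkm_a + 0.01) /
(fpkm_b + 0.01))|`. The 0.01 pseudocount keeps silence-to-activation
transitions finite without dominating ranks; log2 fold change rather than
an FPKM difference was chosen because the divergence comparisons are
distribution tests (KS), for which any monotone transform of the ratio is
equivalent.

## Copy dynamics: the 10-group taxonomy

Within each pair the copy with the larger wild-type mean FPKM
(pseudocount-adjusted) is the `higher` copy; roles are frozen from wild
type even if the ranking inverts in the mutant. Exact FPKM ties are broken
deterministically (lexicographically smaller id becomes higher) and
flagged.

Each copy's WT→mutant change is `up`, `down`, or `none` (`none` iff
q ≥ 0.05 — a significance rule, not a fold-change window, matching the
differential-expression definition). The pair then maps to exactly one of
ten codes: the 3 × 3 direction grid minus the no-change/no-change cell
gives eight cells, and the two same-direction cells each split by which
copy moved with the larger |log2 FC| — ten total. Five codes reduce the
between-copy difference (convergent: NH/UL, DH/NL, UH\<UL, DH\>DL, DH/UL)
and five augment it (divergent: NH/DL, UH/NL, UH\>UL, DH\<DL, UH/DL).
Exact magnitude ties in same-direction pairs are assigned to the
convergent member and flagged; the choice is arbitrary but deterministic,
and ties have measure zero for continuous fold changes.

Group-level inference is by exact binomial tests: up vs down within each
copy-group, each conjugate code pair, convergent vs divergent overall, and
one-copy-changed vs both-copies-changed.

## Sequence evolution

Protein sequences are aligned globally (Needleman–Wunsch affine via
Biostrings: BLOSUM62, gap open 10, extend 0.5 — a gap of length L costs
open + L·extend) and back-translated to codon alignments. dS and dN follow
Nei–Gojobori (1986): per-codon synonymous site fractions by single-step
mutation enumeration against the universal code, averaged over both
sequences; observed differences averaged over all minimal substitution
orders. Two conventions are fixed deliberately:

* single-step changes *to stop codons* count as nonsynonymous when
  counting sites, which keeps `S + N = 3 ×` codon columns exactly;
* substitution paths passing through a stop codon are excluded from the
  difference average (all paths are used only if every path hits a stop).

Proportions are Jukes–Cantor corrected, `d = -3/4 · ln(1 - 4p/3)`;
a result is invalid when `p ≥ 3/4` (correction undefined) or dS > 3
(saturated pairs, excluded from distribution comparisons). Codon columns
containing gaps or ambiguous bases are dropped and counted. NG86 was
chosen over counting-method variants because it is fully specifiable and
oracle-testable; the downstream use — KS comparisons of dS and dN/dS
distributions between expression-affected and -unaffected pairs — is
robust to the estimator choice.

# The synthetic-study generator

The generator emulates the two-genotype design: the mutant retains
`cg_retention_mutant = 0.09` of each gene's wild-type CG body level (~91%
loss) while CHG and CHH true levels are identical across genotypes, and
expression of the two copies couples to the methylation each copy loses,
with opposite signs for the higher- and lower-expressed copy.

Defaults define the study conditions and were chosen once:

| parameter | default | rationale |
|---|---|---|
| chromosomes × genes | 12 × 400 | rice-like karyotype at tractable scale |
| pairs (WGD/transposed/proximal/tandem) | 470/900/340/290 | category proportions of the rice duplicate catalog, scaled to 2,000 pairs |
| `cg_retention_mutant` | 0.09 | ~91% gene-body CG loss in the mutant |
| sites per gene (CG/CHG/CHH) | 40/80/150 | realistic context densities for 1.5–3.5 kb bodies; enough sites that the lower-tail call can discriminate |
| coverage | Poisson(20) | typical WGBS depth; 0-coverage sites emitted as 0/0 |
| P(gene body-CG-methylated) | 0.55 | bimodal body-methylation landscape |
| P(non-CG body methylation) | 0.35 | yields a CG-only : all-context split near 42:58 |
| coupling | 1.2 log2 / unit BCGM lost | strong enough that group-level signatures emerge at n = 2,000 with NB noise |
| NB dispersion | 0.05 | standard RNA-seq overdispersion |
| replicates | 2 per genotype | typical minimal design; configurable |
| CDS length | 300 codons | median-protein scale; target dS drawn per category (WGD 0.5–0.85, tandem 0.23–0.63, proximal 0.22–0.64, transposed 0.4–1.0) |

Placement is constructive: WGD pairs as runs of consecutive rank-collinear
anchors across two chromosomes (half inverted), tandem pairs rank-adjacent,
proximal pairs at gaps 2–10, transposed pairs dispersed across chromosomes
— and explicitly kept out of the gap-corridor of any planted block, so a
stray anchor cannot be absorbed into a chain. Decoy homology hits sit above
the E-value threshold by default (`decoy_hard_mode` drops them below it to
stress the classifier). One master seed feeds named substreams per stage,
so adding a stage never perturbs earlier outputs and identical
configurations are byte-identical end to end.

**What passing tests show — and what they do not.** Recovery of planted
categories, reduction of divergence distributions, the copy-group
asymmetry, and the convergent excess demonstrate that the pipeline detects
these signals when they exist and (via the null runs) does not invent them
when they do not. The generator does not simulate read-level artifacts
(mapping bias, bisulfite non-conversion beyond an error-rate parameter),
intergenic methylation, correlated methylation between neighbouring genes,
TE-driven methylation spreading, isoform complexity, or homology noise
between gene families. Results on real data therefore inherit all the
usual caveats of the upstream processing that produced its inputs.

# Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF3, cytosine reports,
  internal tables) — the R/Bioconductor convention; no 0-based layer.
* All multiple-testing correction is Benjamini–Hochberg, applied within
  the natural family (per context for methylation; per tested gene or pair
  family for expression).
* KS tests use `stats::ks.test` (exact or asymptotic p per its sample-size
  rule); samples under 3 are skipped with a warning, never an error.
* The Tukey compact letter display uses insert-and-absorb on the
  significant-pair list; degenerate (zero-variance) input warns and
  returns a single shared letter.
* Genes/pairs with undefined levels, zero totals, or missing statuses are
  excluded from the affected statistic with the reason recorded, and the
  pipeline log tracks counts in/out at each filter.
* Validation problem sizes: the classifier-calibration checks run at
  2,000 genes; null-specificity runs 20 seeds of a reduced study (6
  chromosomes × 150 genes, 200 pairs) with retention 1 and coupling 0 —
  specificity is a rate property and does not depend on scale.

# Interface choices

The package is a set of pipeable functions over tibbles; `run_pipeline()`
orchestrates the stages and returns a report object with `print()`,
`tidy()`, `glance()` and `autoplot()` methods. No shell entry point is
shipped: the natural driver for this analysis is an R session or script
(`scripts/acceptance.R` is a worked example of exactly that), and every
stage boundary in the design is an exported function.

# Known limitations

* Gene bodies are the full annotated span; a CDS-restricted body
  definition is a planned option and can shift levels for genes with long
  UTRs or introns with distinct methylation.
* The transposed category is residual (no parent-locus dating); block
  detection is count-scored, not E-value-scored.
* The exact conditional expression test is anticonservative under strong
  overdispersion (see above); treat per-gene q-values as screening
  statistics and group-level contrasts as the inferential layer.
* Only the universal genetic code is supported; multi-copy families are
  analysed as pairs, not as families.
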
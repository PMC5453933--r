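#' Global protein alignment for a duplicate pair
#'
#' Deterministic Needleman-Wunsch global alignment with BLOSUM62 and affine
#' gaps (open 10, extend 0.5), via Biostrings. A gap of length L costs
#' open + L x extend.
#'
#' @param protein_a,protein_b Amino-acid sequence strings.
#' @return List with aligned strings `a` and `b` (equal length, `-` gaps)
#'   and the alignment `score`.
#' @export
align_pair <- function(protein_a, protein_b) {
  if (!nzchar(protein_a) || !nzchar(protein_b)) {
    abort("cannot align an empty protein sequence")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each amino-acid column to its source codon; protein gap columns
#' become 3-column codon gaps (`---`). The CDS must be exactly 3x the
#' ungapped protein length and translate to the aligned protein.
#'
#' @param alignment List with aligned protein strings `a` and `b` (from
#'   [align_pair()]).
#' @param cds_a,cds_b Coding sequences of the two copies.
#' @param id_a,id_b Identifiers used in error messages.
#' @return List of class `codon_alignment`: character vectors `codons_a`,
#'   `codons_b` of equal length (codons or `---`).
#' @export
backtranslate <- function(alignment, cds_a, cds_b, id_a = "a", id_b = "b") {
  expand_one <- function(aln, cds, id) {
    aa <- strsplit(aln, "")[[1]]
    n_res <- sum(aa != "-")
    if (nchar(cds) != 3 * n_res) {
      abort(sprintf("CDS of '%s' has %d nt but the aligned protein has %d residues",
                    id, nchar(cds), n_res))
    }
    codons <- substring(cds, seq(1, nchar(cds), by = 3),
                        seq(3, nchar(cds), by = 3))
    tr <- paste(translate_codons(codons), collapse = "")
    if (gsub("-", "", aln) != tr) {
      abort(sprintf("CDS of '%s' does not translate to its aligned protein", id))
    }
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    out
  }
  structure(list(codons_a = expand_one(alignment$a, cds_a, id_a),
                 codons_b = expand_one(alignment$b, cds_b, id_b)),
            class = "codon_alignment")
}

.dupmeth_cache <- new.env(parent = emptyenv())

# direct genetic-code lookup; non-standard codons become "X"
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codons)])
  aa[is.na(aa)] <- "X"
  aa
}

# BLOSUM62 scoring matrix, loaded once per session.
blosum62 <- function() {
  if (is.null(.dupmeth_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .dupmeth_cache$blosum62 <- get("BLOSUM62", envir = e)
  }
  .dupmeth_cache$blosum62
}

# Cached Nei-Gojobori codon tables: per-codon synonymous site counts, and
# 64x64 path-averaged synonymous/nonsynonymous difference matrices.
ng86_tables <- function() {
  cache <- .dupmeth_cache$ng86_tables
  if (!is.null(cache)) return(cache)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  bases <- c("A", "C", "G", "T")
  # synonymous sites per codon; changes to stop codons are nonsynonymous
  syn_sites <- vapply(codons, function(cd) {
    s <- 0
    for (p in 1:3) {
      syn <- 0
      for (b in bases) {
        if (substr(cd, p, p) == b) next
        alt <- cd; substr(alt, p, p) <- b
        if (gc_tab[[alt]] != "*" && gc_tab[[alt]] == gc_tab[[cd]]) syn <- syn + 1
      }
      s <- s + syn / 3
    }
    s
  }, numeric(1))
  # path-averaged differences
  sd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_along(codons)) for (j in seq_along(codons)) {
    if (i == j) next
    c1 <- codons[i]; c2 <- codons[j]
    diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(diff_pos)
    path_sd <- numeric(); path_nd <- numeric(); path_ok <- logical()
    for (ord in perms[[as.character(k)]]) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in diff_pos[ord]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc_tab[[nxt]] == "*" && nxt != c2) ok <- FALSE
        if (gc_tab[[cur]] == gc_tab[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
      path_ok <- c(path_ok, ok)
    }
    use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
    sd_mat[i, j] <- mean(path_sd[use])
    nd_mat[i, j] <- mean(path_nd[use])
  }
  out <- list(codons = codons, syn_sites = syn_sites,
              sd = sd_mat, nd = nd_mat)
  .dupmeth_cache$ng86_tables <- out
  out
}

#' Nei-Gojobori (1986) dS and dN from a codon alignment
#'
#' Synonymous/nonsynonymous site fractions per codon by single-step mutation
#' enumeration against the universal genetic code (changes to stop codons
#' count as nonsynonymous, so S + N = 3 x codon count exactly), averaged
#' over the two sequences. Observed differences are averaged over all
#' minimal substitution orders, excluding paths through stop codons (all
#' paths are used if every path hits a stop). Proportions are
#' Jukes-Cantor-corrected: d = -3/4 ln(1 - 4p/3). The result is invalid
#' when a correction is undefined (p >= 3/4) or dS exceeds `max_ds`.
#' Gap columns and codons with ambiguous bases are dropped (counted).
#'
#' @param alignment A `codon_alignment` from [backtranslate()].
#' @param max_ds Pairs with dS above this are flagged invalid (excluded
#'   downstream).
#' @return One-row tibble: `n_codons`, `n_dropped`, `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `ps`, `pn`, `ds`, `dn`, `dn_ds`, `valid`.
#' @export
compute_ng86 <- function(alignment, max_ds = 3) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tab <- ng86_tables()
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  keep <- ca %in% tab$codons & cb %in% tab$codons
  n_dropped <- sum(!keep)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) {
    abort("no ungapped, unambiguous codon columns in the alignment")
  }
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ds <- jc(ps)
  dn <- jc(pn)
  valid <- !is.na(ds) && !is.na(dn) && ds <= max_ds
  tibble(n_codons = length(ca), n_dropped = n_dropped,
         S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
         ds = ds, dn = dn,
         dn_ds = if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_,
         valid = valid)
}

#' dS/dN for a table of duplicate pairs
#'
#' Translates each pair's CDS, aligns the proteins, back-translates to a
#' codon alignment, and applies [compute_ng86()].
#'
#' @param pairs Pair tibble (`gene_a`, `gene_b`).
#' @param cds Named character vector of coding sequences.
#' @param max_ds dS validity cutoff.
#' @return `pairs` with the [compute_ng86()] columns appended; pairs with a
#'   missing CDS are dropped.
#' @export
ng86_pairs <- function(pairs, cds, max_ds = 3) {
  have <- pairs$gene_a %in% names(cds) & pairs$gene_b %in% names(cds)
  pairs <- pairs[have, ]
  if (nrow(pairs) == 0) {
    return(bind_cols(pairs, compute_ng86(structure(
      list(codons_a = "ATG", codons_b = "ATG"),
      class = "codon_alignment"))[0, ]))
  }
  seq_a <- Biostrings::DNAStringSet(unname(cds[pairs$gene_a]))
  seq_b <- Biostrings::DNAStringSet(unname(cds[pairs$gene_b]))
  prot_a <- as.character(Biostrings::translate(seq_a, if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
  prot_b <- as.character(Biostrings::translate(seq_b, if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
  # one batched elementwise alignment call: far cheaper than per-pair calls
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(prot_a), Biostrings::AAStringSet(prot_b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  aln_a <- as.character(Biostrings::alignedPattern(al))
  aln_b <- as.character(Biostrings::alignedSubject(al))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cdn <- backtranslate(list(a = aln_a[i], b = aln_b[i]),
                         cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]],
                         pairs$gene_a[i], pairs$gene_b[i])
    compute_ng86(cdn, max_ds = max_ds)
  })
  bind_cols(pairs, bind_rows(res))
}

#' Compare dS and dN/dS distributions of affected vs unaffected pairs
#'
#' Per duplication category, two-sample Kolmogorov-Smirnov tests of the dS
#' and dN/dS distributions between expression-affected and -unaffected
#' pairs (valid dS/dN results only). Groups with fewer than 3 members in
#' either arm are skipped with a warning.
#'
#' @param dnds Output of [ng86_pairs()] with a `category` column.
#' @param affected_pairs Pair tibble with logical `affected` (from
#'   [flag_affected_pairs()]).
#' @return Tibble `category`, `measure` (`ds`/`dn_ds`), `n_affected`,
#'   `n_unaffected`, `statistic`, `p_value` (NA when skipped).
#' @export
stratify_by_affect <- function(dnds, affected_pairs) {
  x <- dnds |>
    filter(.data$valid) |>
    inner_join(select(affected_pairs, "gene_a", "gene_b", "affected"),
               by = c("gene_a", "gene_b"))
  out <- list()
  for (cat in sort(unique(x$category))) {
    for (measure in c("ds", "dn_ds")) {
      v <- x[x$category == cat, ]
      a <- v[[measure]][v$affected]
      u <- v[[measure]][!v$affected]
      a <- a[!is.na(a)]; u <- u[!is.na(u)]
      if (length(a) < 3 || length(u) < 3) {
        warn(sprintf("skipping %s / %s: group too small", cat, measure))
        ks <- list(statistic = NA_real_, p.value = NA_real_)
      } else {
        ks <- suppressWarnings(ks.test(a, u))
      }
      out[[length(out) + 1L]] <- tibble(
        category = cat, measure = measure,
        n_affected = length(a), n_unaffected = length(u),
        statistic = unname(ks$statistic), p_value = ks$p.value)
    }
  }
  bind_rows(out)
}
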
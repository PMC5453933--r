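# Independent brute-force oracles used to validate the implementation.
# These are deliberately written as plain, direct computations with no
# shared code paths (no lookup tables, no DP).

# --- Nei-Gojobori oracle -------------------------------------------------

.oracle_code <- function() {
  # universal genetic code, spelled out independently of Biostrings
  aas <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aas
}

# synonymous site count of one codon (stop mutations count nonsynonymous)
oracle_syn_sites <- function(codon, code = .oracle_code()) {
  total <- 0
  for (pos in 1:3) {
    for (base in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == base) next
      alt <- codon
      substr(alt, pos, pos) <- base
      if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) {
        total <- total + 1 / 3
      }
    }
  }
  total
}

# all permutations of a vector, by recursion
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# path-averaged synonymous/nonsynonymous differences between two codons
oracle_codon_diffs <- function(c1, c2, code = .oracle_code()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  sds <- c(); nds <- c(); oks <- c()
  for (order in .perms(pos)) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*" && nxt != c2) ok <- FALSE
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    sds <- c(sds, sd); nds <- c(nds, nd); oks <- c(oks, ok)
  }
  use <- if (any(oks)) oks else rep(TRUE, length(oks))
  c(sd = mean(sds[use]), nd = mean(nds[use]))
}

# full NG86 on two equal-length codon vectors (no gaps)
oracle_ng86 <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  code <- .oracle_code()
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    S <- S + (oracle_syn_sites(codons_a[i], code) +
                oracle_syn_sites(codons_b[i], code)) / 2
    d <- oracle_codon_diffs(codons_a[i], codons_b[i], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(codons_a) - S
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ds = jc(ps), dn = jc(pn))
}

# random sense-codon sequence and a mutated partner
random_codon_pair <- function(n_codons, n_mut) {
  code <- .oracle_code()
  sense <- names(code)[code != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  placed <- 0
  while (placed < n_mut) {
    i <- sample.int(n_codons, 1)
    pos <- sample.int(3, 1)
    base <- sample(c("A", "C", "G", "T"), 1)
    alt <- b[i]
    substr(alt, pos, pos) <- base
    if (alt == b[i] || code[[alt]] == "*") next
    b[i] <- alt
    placed <- placed + 1
  }
  list(a = a, b = b)
}

# --- exhaustive chain oracle --------------------------------------------

# is a set of anchors (rank pairs) orderable into a valid gap-bounded chain?
.chain_valid <- function(r1, r2, max_gap) {
  o <- order(r1)
  r1 <- r1[o]; r2 <- r2[o]
  n <- length(r1)
  if (n == 1) return(TRUE)
  d1 <- diff(r1)
  if (any(d1 < 1 | d1 > max_gap)) return(FALSE)
  d2 <- diff(r2)
  up <- all(d2 >= 1 & d2 <= max_gap)
  down <- all(d2 <= -1 & d2 >= -max_gap)
  up || down
}

# largest valid chain by exhaustive subset enumeration (n <= ~15)
oracle_max_chain <- function(r1, r2, max_gap) {
  n <- length(r1)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    if (.chain_valid(r1[idx], r2[idx], max_gap)) best <- length(idx)
  }
  best
}

# --- exhaustive global alignment oracle ---------------------------------

# maximum affine-gap global alignment score by full enumeration of move
# sequences (gap of length L costs open + L * extend)
oracle_align_score <- function(a, b, mat, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, mat[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(a)) {
      cost <- if (state == "D") extend else open + extend
      best <- max(best, -cost + rec(i + 1, j, "D"))
    }
    if (j <= length(b)) {
      cost <- if (state == "I") extend else open + extend
      best <- max(best, -cost + rec(i, j + 1, "I"))
    }
    best
  }
  rec(1, 1, "M")
}
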
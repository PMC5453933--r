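#' Filter homology hits to candidate duplicate pairs
#'
#' Keeps hit (q, s) when s is among q's `top_k` subjects by ascending
#' E-value (ties broken by descending bitscore, then subject id) and the
#' E-value is strictly below `max_evalue`. Self-hits and hits involving
#' TE-related genes are removed; the surviving pair set is symmetrized
#' (unordered pairs) and de-duplicated, keeping each pair's best E-value.
#'
#' @param hits Homology tibble with outfmt-6 columns (at least `qseqid`,
#'   `sseqid`, `evalue`, `bitscore`).
#' @param catalog Gene catalog; all hit ids must be present.
#' @param top_k Number of best subjects retained per query.
#' @param max_evalue Strict E-value cutoff.
#' @return Tibble of candidate pairs: `gene_a`, `gene_b` (ordered ids),
#'   `evalue`, `bitscore`.
#' @export
filter_candidates <- function(hits, catalog, top_k = 5, max_evalue = 1e-10) {
  assert_cols(hits, c("qseqid", "sseqid", "evalue", "bitscore"),
              "homology table")
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), catalog$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("homology hits reference %d gene id(s) absent from the catalog: %s",
                  length(unknown),
                  paste(head(unknown, 5), collapse = ", ")))
  }
  te <- catalog$gene_id[catalog$is_te]
  kept <- hits |>
    filter(.data$qseqid != .data$sseqid,
           !(.data$qseqid %in% te), !(.data$sseqid %in% te)) |>
    group_by(.data$qseqid) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$sseqid,
            .by_group = TRUE) |>
    distinct(.data$sseqid, .keep_all = TRUE) |>
    slice(seq_len(top_k)) |>
    ungroup() |>
    filter(.data$evalue < max_evalue)
  kept |>
    transmute(gene_a = pmin(.data$qseqid, .data$sseqid),
              gene_b = pmax(.data$qseqid, .data$sseqid),
              evalue = .data$evalue, bitscore = .data$bitscore) |>
    group_by(.data$gene_a, .data$gene_b) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$gene_a, .data$gene_b)
}

# Max-anchor chain by gap-bounded DP on anchors of one chromosome pair and
# one orientation. `r1`, `r2` are rank coordinates sorted by r1.
# Returns indices (into the supplied vectors) of the best chain.
chain_dp <- function(r1, r2, max_gap, decreasing = FALSE) {
  n <- length(r1)
  if (n == 0) return(integer())
  L <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d1 <- r1[i] - r1[j]
      d2 <- if (decreasing) r2[j] - r2[i] else r2[i] - r2[j]
      if (d1 >= 1 && d1 <= max_gap && d2 >= 1 && d2 <= max_gap &&
          L[j] + 1L > L[i]) {
        L[i] <- L[j] + 1L
        prev[i] <- j
      }
    }
  }
  # tie-break: longest chain; among ties the one whose first anchor (then
  # whole chain) comes earliest in r1
  ends <- which(L == max(L))
  trace <- function(e) {
    idx <- integer()
    while (!is.na(e)) { idx <- c(e, idx); e <- prev[e] }
    idx
  }
  chains <- lapply(ends, trace)
  starts <- vapply(chains, function(ix) r1[ix[1]], numeric(1))
  chains[[order(starts, ends)[1]]]
}

#' Detect collinear blocks among candidate pairs
#'
#' For each chromosome pair, anchors (candidate pairs with rank coordinates)
#' are chained into blocks by a gap-bounded longest-chain dynamic program:
#' consecutive anchors must advance by 1..`max_rank_gap` ranks on the first
#' chromosome and move monotonically (either direction, gap-bounded) on the
#' second. Chains are extracted greedily by size (ties by first anchor
#' position), each anchor joining at most one block; chains shorter than
#' `min_block_anchors` are discarded. Same-chromosome hits closer than
#' `self_min_gap` ranks are never used as anchors (they are local
#' tandem/proximal-type hits, not collinearity evidence).
#'
#' @param candidates Candidate pairs from [filter_candidates()].
#' @param catalog Gene catalog (provides chromosome and rank per gene).
#' @param min_block_anchors Minimum anchors per reported block.
#' @param max_rank_gap Maximum rank gap between consecutive anchors.
#' @param self_min_gap Minimum rank separation for same-chromosome anchors.
#' @return Tibble with one row per anchor: `block_id`, `gene_a`, `gene_b`,
#'   `chrom_a`, `chrom_b`, `rank_a`, `rank_b`, `orientation`
#'   (`same`/`inverted`), `n_anchors`.
#' @export
detect_collinear_blocks <- function(candidates, catalog,
                                    min_block_anchors = 5,
                                    max_rank_gap = 25,
                                    self_min_gap = 11) {
  empty <- tibble(block_id = integer(), gene_a = character(),
                  gene_b = character(), chrom_a = character(),
                  chrom_b = character(), rank_a = integer(),
                  rank_b = integer(), orientation = character(),
                  n_anchors = integer())
  if (nrow(candidates) == 0) return(empty)
  info <- select(catalog, "gene_id", "chrom", "rank")
  anchors <- candidates |>
    left_join(info, by = c(gene_a = "gene_id")) |>
    rename(chrom_a = "chrom", rank_a = "rank") |>
    left_join(info, by = c(gene_b = "gene_id")) |>
    rename(chrom_b = "chrom", rank_b = "rank")
  if (anyNA(anchors$rank_a) || anyNA(anchors$rank_b)) {
    abort("candidate pair references gene absent from catalog")
  }
  # orient each anchor: first coordinate on the lexicographically smaller
  # chromosome; for self-pairs, smaller rank first
  flip <- anchors$chrom_b < anchors$chrom_a |
    (anchors$chrom_b == anchors$chrom_a & anchors$rank_b < anchors$rank_a)
  for (col in c("gene", "chrom", "rank")) {
    a <- anchors[[paste0(col, "_a")]]; b <- anchors[[paste0(col, "_b")]]
    anchors[[paste0(col, "_a")]] <- ifelse(flip, b, a)
    anchors[[paste0(col, "_b")]] <- ifelse(flip, a, b)
  }
  anchors <- anchors |>
    filter(!(.data$chrom_a == .data$chrom_b &
               abs(.data$rank_a - .data$rank_b) < self_min_gap))
  if (nrow(anchors) == 0) return(empty)

  out <- list()
  block_id <- 0L
  for (cp in split(anchors, paste(anchors$chrom_a, anchors$chrom_b))) {
    cp <- arrange(cp, .data$rank_a, .data$rank_b)
    repeat {
      if (nrow(cp) < min_block_anchors) break
      up <- chain_dp(cp$rank_a, cp$rank_b, max_rank_gap, decreasing = FALSE)
      down <- chain_dp(cp$rank_a, cp$rank_b, max_rank_gap, decreasing = TRUE)
      if (length(up) >= length(down)) {
        best <- up; orient <- "same"
      } else {
        best <- down; orient <- "inverted"
      }
      if (length(best) < min_block_anchors) break
      block_id <- block_id + 1L
      blk <- cp[best, ] |>
        mutate(block_id = block_id, orientation = orient,
               n_anchors = length(best))
      out[[length(out) + 1L]] <- blk
      cp <- cp[-best, ]
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |>
    select("block_id", "gene_a", "gene_b", "chrom_a", "chrom_b",
           "rank_a", "rank_b", "orientation", "n_anchors") |>
    arrange(.data$block_id, .data$rank_a)
}

#' Classify candidate duplicate pairs by origin
#'
#' Applies the precedence rules: (1) pair is a collinear-block anchor ->
#' `WGD`; (2) same chromosome, rank gap 1 -> `tandem`; (3) same chromosome,
#' rank gap 2..`proximal_max_gap` -> `proximal`; (4) everything else ->
#' `transposed`. Classification is symmetric in the two genes and every
#' candidate pair receives exactly one category.
#'
#' @param candidates Candidate pairs from [filter_candidates()].
#' @param blocks Anchor table from [detect_collinear_blocks()].
#' @param catalog Gene catalog.
#' @param proximal_max_gap Largest rank gap called proximal.
#' @return Tibble `gene_a`, `gene_b`, `category`.
#' @export
classify_duplicates <- function(candidates, blocks, catalog,
                                proximal_max_gap = 10) {
  if (nrow(candidates) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  category = character()))
  }
  info <- select(catalog, "gene_id", "chrom", "rank")
  x <- order_pair(candidates) |>
    left_join(info, by = c(gene_a = "gene_id")) |>
    rename(chrom_a = "chrom", rank_a = "rank") |>
    left_join(info, by = c(gene_b = "gene_id")) |>
    rename(chrom_b = "chrom", rank_b = "rank")
  if (anyNA(x$rank_a) || anyNA(x$rank_b)) {
    abort("candidate pair references gene absent from catalog")
  }
  anchor_keys <- if (nrow(blocks) > 0) {
    pair_key(blocks$gene_a, blocks$gene_b)
  } else character()
  x |>
    mutate(
      same_chrom = .data$chrom_a == .data$chrom_b,
      gap = abs(.data$rank_a - .data$rank_b),
      category = dplyr::case_when(
        pair_key(.data$gene_a, .data$gene_b) %in% anchor_keys ~ "WGD",
        .data$same_chrom & .data$gap == 1 ~ "tandem",
        .data$same_chrom & .data$gap >= 2 &
          .data$gap <= proximal_max_gap ~ "proximal",
        TRUE ~ "transposed")) |>
    select("gene_a", "gene_b", "category") |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Run homology filtering, block detection and classification in one call
#'
#' @inheritParams filter_candidates
#' @inheritParams detect_collinear_blocks
#' @inheritParams classify_duplicates
#' @return List with `candidates`, `blocks`, and classified `pairs`.
#' @export
classify_from_homology <- function(hits, catalog, top_k = 5,
                                   max_evalue = 1e-10,
                                   min_block_anchors = 5, max_rank_gap = 25,
                                   proximal_max_gap = 10) {
  candidates <- filter_candidates(hits, catalog, top_k, max_evalue)
  blocks <- detect_collinear_blocks(candidates, catalog, min_block_anchors,
                                    max_rank_gap,
                                    self_min_gap = proximal_max_gap + 1)
  pairs <- classify_duplicates(candidates, blocks, catalog, proximal_max_gap)
  list(candidates = candidates, blocks = blocks, pairs = pairs)
}
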
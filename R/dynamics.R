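#' The 10-group change taxonomy
#'
#' Enumerates every wild-type-to-mutant change pattern of a duplicate pair:
#' each copy (higher- or lower-expressed in wild type) is up-regulated (U),
#' down-regulated (D) or unchanged (N) in the mutant; both-unchanged pairs
#' are not expression-changed and carry no category; same-direction pairs
#' are split by which copy changed with the larger magnitude. This yields
#' exactly ten codes, five convergent (reducing the between-copy expression
#' difference) and five divergent (augmenting it).
#'
#' @param dir_higher,dir_lower Change direction of the higher-/
#'   lower-expressed copy: `"up"`, `"down"` or `"none"`.
#' @param mag_higher,mag_lower Absolute log2 fold-change magnitudes, used
#'   only when both copies move in the same direction.
#' @return `change_categories()`: tibble of the ten codes with their
#'   roman-numeral order and class. `change_code()`: character vector of
#'   codes (`NA` where both copies are unchanged).
#' @export
change_categories <- function() {
  grid <- expand.grid(dir_higher = c("up", "down", "none"),
                      dir_lower = c("up", "down", "none"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    dh <- grid$dir_higher[i]; dl <- grid$dir_lower[i]
    if (dh == "none" && dl == "none") next
    if (dh == dl) {
      # same direction: split by relative magnitude of the higher copy
      rows[[length(rows) + 1L]] <-
        data.frame(dir_higher = dh, dir_lower = dl, higher_magnitude = "smaller",
                   code = change_code(dh, dl, 0, 1))
      rows[[length(rows) + 1L]] <-
        data.frame(dir_higher = dh, dir_lower = dl, higher_magnitude = "larger",
                   code = change_code(dh, dl, 1, 0))
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(dir_higher = dh, dir_lower = dl, higher_magnitude = NA,
                   code = change_code(dh, dl, 1, 1))
    }
  }
  out <- as_tibble(bind_rows(rows))
  order10 <- c("NH/UL", "NH/DL", "DH/NL", "UH/NL", "UH<UL",
               "UH>UL", "DH>DL", "DH<DL", "DH/UL", "UH/DL")
  convergent <- c("NH/UL", "DH/NL", "UH<UL", "DH>DL", "DH/UL")
  out$group <- match(out$code, order10)
  out$roman <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii",
                 "ix", "x")[out$group]
  out$class <- if_else(out$code %in% convergent, "convergent", "divergent")
  arrange(out, .data$group)
}

#' @rdname change_categories
#' @export
change_code <- function(dir_higher, dir_lower, mag_higher = NA_real_,
                        mag_lower = NA_real_) {
  n <- max(length(dir_higher), length(dir_lower))
  dh <- rep_len(dir_higher, n); dl <- rep_len(dir_lower, n)
  mh <- rep_len(mag_higher, n); ml <- rep_len(mag_lower, n)
  dplyr::case_when(
    dh == "none" & dl == "up" ~ "NH/UL",
    dh == "none" & dl == "down" ~ "NH/DL",
    dh == "down" & dl == "none" ~ "DH/NL",
    dh == "up" & dl == "none" ~ "UH/NL",
    dh == "up" & dl == "up" & mh < ml ~ "UH<UL",
    dh == "up" & dl == "up" & mh > ml ~ "UH>UL",
    # exact magnitude tie: assigned to the convergent member, flagged upstream
    dh == "up" & dl == "up" ~ "UH<UL",
    dh == "down" & dl == "down" & mh > ml ~ "DH>DL",
    dh == "down" & dl == "down" & mh < ml ~ "DH<DL",
    dh == "down" & dl == "down" ~ "DH>DL",
    dh == "down" & dl == "up" ~ "DH/UL",
    dh == "up" & dl == "down" ~ "UH/DL",
    TRUE ~ NA_character_)
}

#' Assign higher/lower expression roles within each pair
#'
#' The copy with the larger wild-type mean FPKM (pseudocount-adjusted) is
#' the `higher` copy; roles are frozen from wild type. Exact ties are broken
#' deterministically (lexicographically smaller gene id becomes higher) and
#' flagged.
#'
#' @param pairs Pair tibble.
#' @param expression Expression tibble.
#' @param pseudocount FPKM pseudocount.
#' @return `pairs` with `higher`, `lower` gene-id columns and `role_tie`
#'   flag.
#' @export
assign_roles <- function(pairs, expression, pseudocount = 0.01) {
  g <- expression |>
    filter(.data$genotype == "wt") |>
    group_by(.data$gene_id) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop")
  x <- pairs |>
    inner_join(rename(g, fpkm_a = "fpkm"), by = c(gene_a = "gene_id")) |>
    inner_join(rename(g, fpkm_b = "fpkm"), by = c(gene_b = "gene_id"))
  fa <- x$fpkm_a + pseudocount
  fb <- x$fpkm_b + pseudocount
  tie <- fa == fb
  a_higher <- fa > fb | (tie & x$gene_a < x$gene_b)
  x$higher <- if_else(a_higher, x$gene_a, x$gene_b)
  x$lower <- if_else(a_higher, x$gene_b, x$gene_a)
  x$role_tie <- tie
  select(x, -"fpkm_a", -"fpkm_b")
}

#' Categorize each pair's change pattern into the 10-group taxonomy
#'
#' Joins per-copy wild-type-versus-mutant differential-expression calls onto
#' the role assignment and maps each pair to one of the ten codes. Pairs
#' where both copies are unchanged get `NA` (not expression-changed).
#' Exact magnitude ties in same-direction pairs are assigned to the
#' convergent member of the code pair and flagged `magnitude_tie`.
#'
#' @param roles Output of [assign_roles()].
#' @param de_genotypes Output of [de_between_genotypes()].
#' @return `roles` with `dir_higher`, `dir_lower`, `mag_higher`,
#'   `mag_lower`, `code`, `class`, `magnitude_tie` columns.
#' @export
categorize_changes <- function(roles, de_genotypes) {
  de <- select(de_genotypes, "gene_id", "direction", "log2_fold_change")
  x <- roles |>
    inner_join(rename(de, dir_higher = "direction", lfc_h = "log2_fold_change"),
               by = c(higher = "gene_id")) |>
    inner_join(rename(de, dir_lower = "direction", lfc_l = "log2_fold_change"),
               by = c(lower = "gene_id"))
  if (anyNA(x$dir_higher) || anyNA(x$dir_lower)) {
    abort("missing change direction for some copies")
  }
  x$mag_higher <- abs(x$lfc_h)
  x$mag_lower <- abs(x$lfc_l)
  x$code <- change_code(x$dir_higher, x$dir_lower, x$mag_higher, x$mag_lower)
  cls <- change_categories() |> distinct(.data$code, .data$class)
  x <- left_join(x, cls, by = "code")
  x$magnitude_tie <- !is.na(x$code) & x$dir_higher == x$dir_lower &
    x$mag_higher == x$mag_lower
  select(x, -"lfc_h", -"lfc_l")
}

#' Directional-shift test for a copy-group
#'
#' Counts up- versus down-regulated copies in the higher or lower expression
#' copy-group and tests the split against 0.5 with a two-sided exact
#' binomial test.
#'
#' @param categories Output of [categorize_changes()].
#' @param de_genotypes Output of [de_between_genotypes()].
#' @param role `"higher"` or `"lower"`.
#' @return One-row tibble: `role`, `n_up`, `n_down`, `p_value` (NA when no
#'   directional changes exist).
#' @export
group_shift_test <- function(categories, de_genotypes,
                             role = c("higher", "lower")) {
  role <- match.arg(role)
  ids <- categories[[role]]
  de <- de_genotypes[match(ids, de_genotypes$gene_id), ]
  n_up <- sum(de$direction == "up", na.rm = TRUE)
  n_down <- sum(de$direction == "down", na.rm = TRUE)
  p <- if (n_up + n_down == 0) NA_real_ else
    stats::binom.test(n_up, n_up + n_down, 0.5)$p.value
  tibble(role = role, n_up = n_up, n_down = n_down, p_value = p)
}

#' Convergence-versus-divergence summary of the 10 groups
#'
#' Tabulates pairs per code and runs the group-level exact binomial tests:
#' one per conjugate code pair (i vs ii, iii vs iv, v vs vi, vii vs viii,
#' ix vs x), the overall convergent-versus-divergent split, and the
#' one-copy-changed (i-iv) versus both-copies-changed (v-x) split.
#'
#' @param categories Output of [categorize_changes()].
#' @return List with `counts` (per-code tibble) and `tests` (tibble
#'   `comparison`, `n_a`, `n_b`, `p_value`).
#' @export
convergence_summary <- function(categories) {
  cat10 <- change_categories()
  codes <- cat10$code
  n_of <- vapply(codes, function(cd)
    sum(categories$code == cd, na.rm = TRUE), integer(1))
  counts <- cat10 |>
    select("group", "roman", "code", "class") |>
    mutate(n = unname(n_of))
  btest <- function(a, b) {
    if (a + b == 0) NA_real_ else stats::binom.test(a, a + b, 0.5)$p.value
  }
  conj <- tibble(
    comparison = c("i vs ii", "iii vs iv", "v vs vi", "vii vs viii",
                   "ix vs x"),
    n_a = unname(n_of[c(1, 3, 5, 7, 9)]),
    n_b = unname(n_of[c(2, 4, 6, 8, 10)]))
  n_conv <- sum(counts$n[counts$class == "convergent"])
  n_div <- sum(counts$n[counts$class == "divergent"])
  n_one <- sum(counts$n[1:4])
  n_both <- sum(counts$n[5:10])
  tests <- bind_rows(
    conj,
    tibble(comparison = "convergent vs divergent", n_a = n_conv, n_b = n_div),
    tibble(comparison = "one-copy vs both-copies", n_a = n_one, n_b = n_both))
  tests$p_value <- mapply(btest, tests$n_a, tests$n_b)
  list(counts = counts, tests = tests)
}
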
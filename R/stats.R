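#' Two-sample distribution comparison
#'
#' Two-sample Kolmogorov-Smirnov test (exact or asymptotic p per
#' stats::ks.test's sample-size rule). Undersized samples are skipped with
#' a warning rather than an error.
#'
#' @param x,y Numeric samples.
#' @param min_n Minimum size per sample.
#' @return One-row tibble: `n_x`, `n_y`, `statistic`, `p_value` (NA when
#'   skipped).
#' @export
compare_distributions <- function(x, y, min_n = 3) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < min_n || length(y) < min_n) {
    warn("sample too small for a distribution comparison; skipped")
    return(tibble(n_x = length(x), n_y = length(y),
                  statistic = NA_real_, p_value = NA_real_))
  }
  ks <- suppressWarnings(ks.test(x, y))
  tibble(n_x = length(x), n_y = length(y),
         statistic = unname(ks$statistic), p_value = ks$p.value)
}

# compact letter display by insert-and-absorb on a significant-pair list
letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  # order letter sets by the first group they contain
  first <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first)]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Fits `values ~ group`, reports the ANOVA F-test, all Tukey honestly-
#' significant-difference pairwise comparisons, and a compact letter display
#' in which groups sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level for the letter display.
#' @return List: `anova_p`, `tukey` (tibble `a`, `b`, `diff`, `p_adj`),
#'   `letters` (named character vector per group).
#' @export
compare_groups_anova <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort("need >= 2 groups with >= 2 values each")
  }
  if (stats::var(values) == 0) {
    warn("zero variance; groups indistinguishable")
    lv <- levels(groups)
    return(list(anova_p = NA_real_,
                tukey = tibble(a = character(), b = character(),
                               diff = numeric(), p_adj = numeric()),
                letters = setNames(rep("a", length(lv)), lv)))
  }
  fit <- aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble(a = vapply(nm, `[`, character(1), 1),
                  b = vapply(nm, `[`, character(1), 2),
                  diff = tk[, "diff"], p_adj = tk[, "p adj"])
  sig <- filter(tukey, .data$p_adj < alpha)
  list(anova_p = anova_p, tukey = tukey,
       letters = letter_display(levels(groups), sig))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (pairwise-complete, n >= 4 required).
#' @param conf_level Confidence level.
#' @return One-row tibble: `n`, `r`, `p_value`, `conf_low`, `conf_high`.
#'   Zero-variance input gives NA estimates with a warning.
#' @export
correlate <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) abort("need at least 4 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warn("zero variance; correlation undefined")
    return(tibble(n = length(x), r = NA_real_, p_value = NA_real_,
                  conf_low = NA_real_, conf_high = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble(n = length(x), r = unname(ct$estimate), p_value = ct$p.value,
         conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}

#' Contingency-table test
#'
#' Fisher's exact test for 2x2 tables; chi-squared (the documented fallback)
#' for larger tables.
#'
#' @param table Non-negative integer matrix.
#' @return One-row tibble: `method`, `p_value`.
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("contingency table entries must be non-negative")
  if (all(dim(table) == c(2, 2))) {
    tibble(method = "fisher", p_value = fisher.test(table)$p.value)
  } else {
    tibble(method = "chisq",
           p_value = suppressWarnings(chisq.test(table)$p.value))
  }
}
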
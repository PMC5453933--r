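#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols n row_number
#'   distinct rename pull across if_else count slice transmute first
#' @importFrom stats pbinom dbinom rbinom rpois rnbinom rnorm runif rbeta
#'   p.adjust ks.test fisher.test chisq.test aov TukeyHSD cor.test setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

# Derived, named RNG substreams: one master seed; each generator stage draws
# from seed = f(master, name) so adding a stage never perturbs earlier output.
# Polynomial string hash mod (2^31 - 1); all intermediates exact in doubles.
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a derived substream, restoring the caller's RNG state.
with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master, name))
  expr
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s integer",
                  name, if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Canonical unordered pair key: lexicographically ordered ids.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

order_pair <- function(df, col_a = "gene_a", col_b = "gene_b") {
  a <- df[[col_a]]
  b <- df[[col_b]]
  df[[col_a]] <- pmin(a, b)
  df[[col_b]] <- pmax(a, b)
  df
}
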
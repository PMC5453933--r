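#' Plot between-copy divergence by category and genotype
#'
#' Boxplots of between-copy divergence (body CG methylation level or
#' absolute log2 expression fold change) for each duplication category,
#' wild type beside mutant, faceted by methylation class.
#'
#' @param report A `dupmeth_report`.
#' @param what `"methylation"` or `"expression"`.
#' @return A ggplot object.
#' @export
plot_divergence <- function(report, what = c("methylation", "expression")) {
  what <- match.arg(what)
  div <- switch(what,
                methylation = report$methylation$divergence,
                expression = report$expression$divergence)
  if (is.null(div) || nrow(div) == 0) abort("no divergence data in report")
  div <- filter(div, !is.na(.data$meth_class),
                .data$meth_class != "unmethylated")
  div$genotype <- factor(div$genotype, levels = c("wt", "mut"))
  ggplot2::ggplot(div, ggplot2::aes(x = .data$category,
                                    y = .data$divergence,
                                    fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~meth_class) +
    ggplot2::labs(
      x = "duplication category",
      y = if (what == "methylation") "between-copy BCGM divergence"
      else "between-copy |log2 FC| expression divergence",
      fill = "genotype") +
    ggplot2::theme_bw()
}

#' Plot the 10-group change taxonomy counts
#'
#' Bar chart of pair counts per change code, colored by convergent versus
#' divergent class, for one methylation class.
#'
#' @param report A `dupmeth_report`.
#' @param meth_class `"CG_only"` or `"all_context"`.
#' @return A ggplot object.
#' @export
plot_change_groups <- function(report, meth_class = "CG_only") {
  d <- report$dynamics[[meth_class]]
  if (is.null(d)) abort(sprintf("no dynamics for class '%s'", meth_class))
  counts <- d$convergence$counts
  counts$code <- factor(counts$code, levels = counts$code)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$code, y = .data$n,
                                       fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "change group", y = "duplicate pairs",
                  fill = NULL, title = meth_class) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
#' @rdname plot_divergence
#' @param object A `dupmeth_report`.
#' @param ... Passed on to the specific plot function.
autoplot.dupmeth_report <- function(object,
                                    what = c("methylation", "expression",
                                             "change_groups"), ...) {
  what <- match.arg(what)
  if (what == "change_groups") plot_change_groups(object, ...)
  else plot_divergence(object, what)
}
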
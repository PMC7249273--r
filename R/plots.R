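# ggplot2 views of the result objects and broom-style summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the template-multiplicity histogram of a panel summary
#'
#' @param x a `panel_summary`.
#' @param ... unused.
#' @return tibble `n_templates_per_locus`, `n_loci`.
#' @method tidy panel_summary
#' @export
tidy.panel_summary <- function(x, ...) {
  x$multiplicity
}

#' One-row overview of a probe panel
#'
#' @param x a `panel_summary`.
#' @param ... unused.
#' @return one-row tibble `n_loci`, `n_templates`, `n_probes`.
#' @method glance panel_summary
#' @export
glance.panel_summary <- function(x, ...) {
  x$totals
}

#' Plot the template-multiplicity histogram of a panel
#'
#' @param object a `panel_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot panel_summary
#' @export
autoplot.panel_summary <- function(object, ...) {
  ggplot2::ggplot(object$multiplicity,
                  ggplot2::aes(x = factor(.data$n_templates_per_locus),
                               y = .data$n_loci)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "templates per locus", y = "loci",
                  title = sprintf("%d templates across %d loci",
                                  object$totals$n_templates,
                                  object$totals$n_loci)) +
    ggplot2::theme_minimal()
}

#' Identity vs. recovered length across templates
#'
#' Scatter of gapped percent identity against recovered sequence length for
#' each sample x template, colored by template source class when available —
#' the capture-evaluation view that shows own-clade templates recovering
#' longer, higher-identity sequences than cross-clade ones.
#'
#' @param template_stats tibble from [run_evaluate()]`$template_stats`.
#' @param templates optional template tibble supplying `source_class`.
#' @return a ggplot.
#' @export
plot_recovery <- function(template_stats, templates = NULL) {
  d <- template_stats[template_stats$recovered, , drop = FALSE]
  if (!is.null(templates)) {
    d <- left_join(d, templates[, c("template_id", "source_class")],
                   by = "template_id")
  } else {
    d$source_class <- "template"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$identity_pct,
                                  y = .data$recovered_len,
                                  colour = .data$source_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "percent identity (gapped)", y = "recovered length (bp)",
                  colour = "template source") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
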
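#' Tidy an enrichment run
#'
#' @param x A `her_enrichment` object from [run_enrichment()].
#' @param what `"records"` (one row per genome x anchor x domain test) or
#'   `"summaries"` (one row per domain).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy her_enrichment
#' @export
tidy.her_enrichment <- function(x, what = c("records", "summaries"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of an enrichment run
#'
#' @param x A `her_enrichment` object.
#' @param ... Unused.
#' @return Tibble with `n_genomes_eligible`, `n_loci`, `n_tests`,
#'   `n_domains`, `n_selected`, `fdr_alpha`, `prevalence_min`.
#' @method glance her_enrichment
#' @export
glance.her_enrichment <- function(x, ...) {
  tibble(
    n_genomes_eligible = x$n_genomes_eligible,
    n_loci = sum(x$loci$eligible),
    n_tests = nrow(x$records),
    n_domains = nrow(x$summaries),
    n_selected = sum(x$summaries$selected),
    fdr_alpha = x$config$fdr_alpha,
    prevalence_min = x$config$prevalence_min
  )
}

#' Plot an enrichment run
#'
#' Shows, for the domains most often significant across genomes, the
#' fraction of eligible genomes in which they are significant, against the
#' selection threshold.
#'
#' @param object A `her_enrichment` object.
#' @param n_max Domains to show (most prevalent first).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot her_enrichment
#' @export
autoplot.her_enrichment <- function(object, n_max = 20, ...) {
  s <- object$summaries |>
    mutate(frac = .data$n_genomes_significant / .data$n_genomes_eligible) |>
    arrange(desc(.data$frac), .data$accession) |>
    head(n_max)
  ggplot2::ggplot(s, ggplot2::aes(
    x = .data$frac,
    y = stats::reorder(.data$accession, .data$frac),
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$config$prevalence_min,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "fraction of eligible genomes with FDR-significant enrichment",
      y = NULL, fill = "selected"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a gene neighborhood
#'
#' Draws the anchor and its neighbors as strand-aware arrows along the
#' contig, the usual gene-context diagram.
#'
#' @param object A `her_neighborhood` from [extract_neighborhood()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot her_neighborhood
#' @export
autoplot.her_neighborhood <- function(object, ...) {
  g <- bind_rows(
    mutate(object$anchor, role = "anchor"),
    mutate(object$members, role = "neighbor")
  ) |>
    mutate(
      xstart = ifelse(.data$strand == "+", .data$start, .data$end),
      xend = ifelse(.data$strand == "+", .data$end, .data$start)
    )
  ggplot2::ggplot(g) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$xstart, xend = .data$xend, y = 0, yend = 0,
                   colour = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 2, lineend = "butt"
    ) +
    ggplot2::scale_colour_manual(values = c(anchor = "#D55E00",
                                            neighbor = "grey40")) +
    ggplot2::labs(x = paste0("position on ", object$anchor$contig_id, " (bp)"),
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
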
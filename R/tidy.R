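#' Tidy and glance methods for cascade results
#'
#' `tidy()` returns the long audit trace (one row per variant per evaluated
#' stage); `glance()` one row with the funnel counts (`n_input`,
#' one column per stage, `n_survivors`).
#'
#' @param x A `coseg_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coseg_cascade
#' @export
tidy.coseg_cascade <- function(x, ...) {
  as_tibble(x$trace)
}

#' @rdname tidy.coseg_cascade
#' @method glance coseg_cascade
#' @export
glance.coseg_cascade <- function(x, ...) {
  wide <- pivot_wider(select(x$counts, "stage", "n_out"),
                      names_from = "stage", values_from = "n_out")
  bind_cols(tibble(n_input = x$counts$n_in[1]), wide,
            tibble(n_survivors = nrow(x$survivors)))
}

#' Tidy and glance methods for region scans
#'
#' @param x A `coseg_scan` from [scan_regions()].
#' @param ... Unused.
#' @return A tibble: `tidy()` the regions, `glance()` one row with
#'   `n_regions`, `total_bp` (end − start lengths summed) and `n_chromosomes`.
#' @method tidy coseg_scan
#' @export
tidy.coseg_scan <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "params") <- NULL
  out
}

#' @rdname tidy.coseg_scan
#' @method glance coseg_scan
#' @export
glance.coseg_scan <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    total_bp = if (nrow(x)) sum(x$end - x$start) else 0,
    n_chromosomes = length(unique(x$chrom))
  )
}

#' Funnel plot of a cascade audit trail
#'
#' @param object A `coseg_cascade`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coseg_cascade
#' @export
autoplot.coseg_cascade <- function(object, ...) {
  d <- bind_rows(
    tibble(stage = "input", n = object$counts$n_in[1]),
    select(object$counts, stage, n = "n_out")
  )
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants remaining",
                  title = "Filter cascade funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Chromosome map of scanned regions
#'
#' @param object A `coseg_scan` (or any regions tibble with a `coseg_scan`
#'   class).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coseg_scan
#' @export
autoplot.coseg_scan <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom, yend = .data$chrom),
      linewidth = 3, colour = "firebrick"
    ) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome",
                  title = "Cosegregation-compatible regions") +
    ggplot2::theme_minimal()
}

#' Heatmap of developmental expression profiles
#'
#' Genes by samples (ordered by age), log2 z-scores per gene, with the query
#' window marked.
#'
#' @param expr A long expression tibble from [read_expression()].
#' @param genes Genes to draw (default all).
#' @param window Optional age window to outline.
#' @param pseudocount Added before log2.
#' @return A ggplot.
#' @export
plot_expression_profile <- function(expr, genes = NULL, window = NULL,
                                    pseudocount = 1) {
  genes <- genes %||% unique(expr$gene)
  d <- expr |>
    filter(.data$gene %in% genes) |>
    group_by(.data$gene) |>
    mutate(z = {
      y <- log2(.data$value + pseudocount)
      s <- sd(y)
      if (is.na(s) || s == 0) 0 * y else (y - mean(y)) / s
    }) |>
    ungroup() |>
    arrange(.data$age) |>
    mutate(sample = factor(.data$sample, levels = unique(.data$sample)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$gene,
                                       fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred") +
    ggplot2::labs(x = "sample (ordered by age)", y = NULL, fill = "z(log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6))
  p
}
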
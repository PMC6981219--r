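#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a consensus grid into one long table
#'
#' @param x A `consensus_grid`.
#' @param ... Unused.
#' @return A tibble with one row per gene per cell: `normalization`,
#'   `model`, `gene_id`, `log2_fc`, `stat`, `p_value`, `q_value`, `flag`.
#' @export
tidy.consensus_grid <- function(x, ...) {
  purrr::map_dfr(names(x$cells), function(key) {
    cell <- x$cells[[key]]
    dplyr::bind_cols(
      tibble::tibble(
        normalization = attr(cell, "normalization"),
        model = attr(cell, "model")
      ),
      tibble::as_tibble(cell)
    )
  })
}

#' @rdname tidy.consensus_grid
#' @export
glance.consensus_grid <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_normalizations = length(x$normalizations),
    n_models = length(x$models),
    n_cells = length(x$cells)
  )
}

#' Tidy consensus calls
#'
#' @param x A `consensus_calls` object.
#' @param ... Unused.
#' @return `tidy()`: the per-gene calls tibble joined with per-model mean
#'   q-values. `glance()`: one row with DEG counts and rule parameters.
#' @export
tidy.consensus_calls <- function(x, ...) {
  dplyr::left_join(x$calls, x$mean_q, by = "gene_id")
}

#' @rdname tidy.consensus_calls
#' @export
glance.consensus_calls <- function(x, ...) {
  called <- x$calls[x$calls$called, ]
  tibble::tibble(
    n_genes = nrow(x$calls),
    n_deg = nrow(called),
    n_up = sum(called$direction == "up"),
    n_down = sum(called$direction == "down"),
    n_ambiguous = sum(called$direction == "ambiguous"),
    threshold = x$threshold,
    k_required = x$k_required
  )
}

#' Tidy a dispersion fit
#' @param x A `dispersion_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-gene tibble. `glance()`: the trend
#'   parameters of `phi(mu) = a / mu + b`.
#' @export
tidy.dispersion_fit <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble::tibble(trend_a = attr(x, "trend_a"), trend_b = attr(x, "trend_b"),
                 median_final = stats::median(x$final))
}

#' Volcano plot of one grid cell
#'
#' @param cell A [de_result()] (or an already classified tibble from
#'   [classify_volcano()]).
#' @param q_cutoff Cutoff used for the up/down classification.
#' @return A ggplot object.
#' @export
plot_volcano <- function(cell, q_cutoff = 0.01) {
  tab <- if ("label" %in% names(cell)) cell else classify_volcano(cell, q_cutoff)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_q,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(down = "#3366cc", ns = "grey70", up = "#cc3333"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.de_result <- function(object, q_cutoff = 0.01, ...) {
  plot_volcano(object, q_cutoff = q_cutoff)
}

#' Per-cell significant-gene counts as a grid heatmap
#'
#' @param object A `consensus_grid`.
#' @param q_cutoff Per-cell q-value cutoff for counting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_grid <- function(object, q_cutoff = 0.05, ...) {
  tab <- tidy(object) |>
    dplyr::group_by(.data$normalization, .data$model) |>
    dplyr::summarise(n_significant = sum(.data$q_value < q_cutoff), .groups = "drop")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$model, y = .data$normalization,
                                    fill = .data$n_significant)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_significant), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#cc3333") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("genes q < %g", q_cutoff)) +
    ggplot2::theme_minimal()
}

#' Per-model target-set sizes and the consensus
#'
#' @param object A `consensus_calls` object.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.consensus_calls <- function(object, ...) {
  tab <- tibble::tibble(
    set = c(names(object$targets), "consensus"),
    n = c(lengths(object$targets), sum(object$calls$called))
  )
  tab$set <- factor(tab$set, levels = tab$set)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = NULL, y = sprintf("genes with mean q < %g", object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
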
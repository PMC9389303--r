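# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer table: per-category cluster counts
#'
#' @param x A transfer table from [transfer_identifications()].
#' @param ... Unused.
#' @return The [category_counts()] tibble.
#' @export
tidy.transfer_tbl <- function(x, ...) category_counts(x)

#' One-row summary of a transfer table
#'
#' @param x A transfer table.
#' @param ... Unused.
#' @return One-row tibble: scan, direct, transferred and entity counts,
#'   PSM gain percentage and ambiguous-cluster fraction.
#' @export
glance.transfer_tbl <- function(x, ...) {
  glob <- summarize_transfers(x)
  glob <- glob[glob$batch_id == "(all)", ]
  amb <- ambiguous_cluster_fraction(x)
  tibble::tibble(
    n_scans = glob$n_scans, n_direct = glob$n_direct,
    n_transferred = glob$n_transferred,
    psm_gain_percent = glob$psm_gain_percent,
    n_peptides = glob$n_peptides, n_proteins = glob$n_proteins,
    n_clusters = dplyr::n_distinct(x$cluster_id),
    ambiguous_fraction = amb$fraction
  )
}

#' Plot a batch-presence curve
#'
#' @param object A `presence_curve` tibble (possibly several row-bound
#'   curves, e.g. with and without transfers).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.presence_curve <- function(object, ...) {
  object$with_transfers <- ifelse(object$include_transfers,
                                  "with transfers", "direct only")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_batches, y = .data$count,
                                       colour = .data$with_transfers)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "found in at least n batches", y = "entities",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot masking precision and recall across the threshold ladder
#'
#' @param object Row-bound `masking_report` tibble (e.g. from
#'   [run_masking()]).
#' @param ... Unused.
#' @return A ggplot of recall vs precision, labelled by threshold.
#' @export
autoplot.masking_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       label = .data$threshold_label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-category cluster counts
#'
#' @param table Categorized merged tibble.
#' @return A ggplot.
#' @export
plot_category_counts <- function(table) {
  counts <- category_counts(table)
  counts$label <- paste0("(", counts$category_letter, ") ",
                         counts$cluster_category)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n_clusters)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
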
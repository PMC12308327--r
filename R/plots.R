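# ggplot2 views of fitted objects.

#' Plot Akaike weights of a fitted model set
#'
#' Bar chart of the top models' Akaike weights; failed fits are omitted
#' (they carry no weight) but are listed in the selection table.
#'
#' @param object An `mk_model_set`.
#' @param top_n How many models to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_model_set <- function(object, top_n = 10, ...) {
  tab <- dplyr::filter(object$table, !is.na(.data$weight)) |>
    utils::head(top_n)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$model, -.data$weight), y = .data$weight)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "model", y = "Akaike weight") +
    ggplot2::theme_minimal()
}

#' Plot fitted transition rates
#'
#' Heatmap of the MLE instantaneous rates; structural zeros are blank.
#'
#' @param object An `mk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(title = paste("Model", object$model, "MLE rates"),
                  x = "to state", y = "from state", fill = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot marginal ancestral states
#'
#' Heatmap of the per-node marginal state probabilities for the internal
#' nodes, ordered by node depth (root first), so recent state origins
#' show up near the bottom.
#'
#' @param object An `mk_asr`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_asr <- function(object, ...) {
  tree <- attr(object, "tree")
  depths <- ape::node.depth.edgelength(tree)
  df <- dplyr::filter(tibble::as_tibble(object), .data$type == "internal") |>
    dplyr::mutate(depth = depths[.data$node])
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$state, levels = combined_states()),
    y = stats::reorder(factor(.data$node), .data$depth),
    fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "state", y = "internal node (root at top)",
                  fill = "marginal\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot realized transition counts
#'
#' Heatmap of mean realized transition counts over the sampled
#' histories. Crepuscular paths — estimated from very few species — are
#' shown desaturated to flag their low credibility.
#'
#' @param object An `mk_simmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_simmap <- function(object, ...) {
  counts <- count_transitions(object)
  counts <- dplyr::mutate(
    counts,
    from = factor(.data$from, levels = combined_states()),
    to = factor(.data$to, levels = combined_states())
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$to, y = .data$from,
                                       fill = .data$mean_count,
                                       alpha = !.data$low_credibility)) +
    ggplot2::geom_tile() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "to state", y = "from state",
                  fill = "mean realized\ntransitions",
                  caption = "crepuscular paths desaturated (low credibility)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
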
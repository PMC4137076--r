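#' Plot methods
#'
#' `autoplot.topic_selection()` draws the criterion curve over the K grid
#' with the chosen K marked; `autoplot.recovery_report()` draws the histogram
#' of recovered `p(i|d)` values split at the random-chance threshold, the
#' standard diagnostic for a masked-indication experiment; and
#' `autoplot.lda_model()` shows the per-topic phenotype distributions as a
#' tile map (top terms only, for legibility).
#'
#' @param object the fitted object.
#' @param bin_width histogram bin width for recovery reports.
#' @param n_terms top terms per topic to display for models.
#' @param ... unused.
#' @return a ggplot object.
#' @name phenorepo-plots
NULL

#' @rdname phenorepo-plots
#' @export
autoplot.topic_selection <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = k, y = mean_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::labs(
      x = "number of topics K",
      y = paste0("mean ", object$criterion),
      title = paste0("Topic-count selection (chosen K = ",
                     object$chosen_k, ")")
    )
}

#' @rdname phenorepo-plots
#' @export
autoplot.recovery_report <- function(object, bin_width = 0.005, ...) {
  r <- object$results
  q <- object$criteria$q
  ggplot2::ggplot(r, ggplot2::aes(x = probability,
                                  fill = probability > q)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0) +
    ggplot2::geom_vline(xintercept = q, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = "above chance"
    ) +
    ggplot2::labs(
      x = "recovered p(i|d) for masked known pairs", y = "pairs",
      title = "Masked-indication recovery probabilities"
    )
}

#' @rdname phenorepo-plots
#' @export
autoplot.lda_model <- function(object, n_terms = 10L, ...) {
  top <- tidy(object, matrix = "phi") |>
    group_by(topic) |>
    arrange(dplyr::desc(probability), .by_group = TRUE) |>
    slice(seq_len(n_terms)) |>
    ungroup()
  ggplot2::ggplot(top, ggplot2::aes(x = topic, y = term_id,
                                    fill = probability)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "topic", y = "phenotype",
                  title = "Top phenotypes per topic, p(ph|t)")
}
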
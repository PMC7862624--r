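#' Plot a ROC curve
#'
#' @param object An `fscm_roc` (from [roc_auc()]) or `fscm_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fscm_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)",
      y = "True positive rate (Sn)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fscm_roc
#' @export
autoplot.fscm_eval <- function(object, ...) {
  autoplot.fscm_roc(object$roc) +
    ggplot2::labs(subtitle = sprintf(
      "%s | Ac %.3f, MCC %.3f at threshold %.1f",
      object$region, object$metrics$ac, object$metrics$mcc,
      object$metrics$threshold))
}

#' Plot a scorecard
#'
#' Dipeptide cards are drawn as a 20 x 20 heatmap (first residue on rows,
#' second on columns); amino-acid cards as a ranked bar chart.
#'
#' @param object An `fscm_scorecard`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fscm_scorecard <- function(object, ...) {
  df <- tidy(object)
  if (object$granularity == "dipeptide") {
    df$first <- substr(df$symbol, 1, 1)
    df$second <- substr(df$symbol, 2, 2)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$second, y = .data$first,
                                       fill = .data$score)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                      high = "#b2182b", midpoint = 500,
                                      name = "Propensity") +
        ggplot2::scale_y_discrete(limits = rev(AA_ALPHABET_20)) +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "Second residue", y = "First residue",
                      title = sprintf("%s dipeptide propensity scores",
                                      object$region$name)) +
        ggplot2::theme_minimal()
    )
  }
  df$symbol <- stats::reorder(df$symbol, df$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$symbol, y = .data$score)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Propensity score (0-1000)",
                  title = "Amino-acid propensity scores") +
    ggplot2::theme_minimal()
}

#' Plot a GA fitness trace
#'
#' @param object An `fscm_optimization`.
#' @param ... Unused.
#' @return A ggplot object showing the (non-decreasing) best fitness per
#'   generation.
#' @export
autoplot.fscm_optimization <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation,
                               y = .data$best_fitness)) +
    ggplot2::geom_step(colour = "#b2182b") +
    ggplot2::labs(x = "Generation", y = "Best fitness (w1*AUC + w2*R)",
                  title = sprintf("GA refinement, seed %d", object$run_seed)) +
    ggplot2::theme_minimal()
}
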
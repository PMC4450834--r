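# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for ROC results
#'
#' `tidy()` returns the ROC curve points; `glance()` returns a one-row
#' summary with the AUROC, its Hanley-McNeil standard error and confidence
#' interval, and the class sizes.
#'
#' @param x A `roc_result` from [roc_auroc()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auroc = x$auroc, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    conf_level = x$conf_level, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Tidiers for AUROC comparisons
#'
#' Both `tidy()` and `glance()` return the one-row summary of a DeLong
#' comparison of two correlated AUROCs.
#'
#' @param x A `roc_comparison` from [compare_auroc()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy roc_comparison
#' @export
tidy.roc_comparison <- function(x, ...) {
  tibble(
    auroc_a = x$auroc_a, auroc_b = x$auroc_b, difference = x$difference,
    se = x$se, z = x$z, p_value = x$p_value,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname tidy.roc_comparison
#' @method glance roc_comparison
#' @export
glance.roc_comparison <- tidy.roc_comparison

#' Tidiers for regularization sweeps
#'
#' `tidy()` returns the per-k AUROC table; `glance()` the chosen k and the
#' maximum AUROC.
#'
#' @param x A `k_sweep` from [sweep_k()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy k_sweep
#' @export
tidy.k_sweep <- function(x, ...) {
  x$results
}

#' @rdname tidy.k_sweep
#' @method glance k_sweep
#' @export
glance.k_sweep <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, max_auroc = max(x$results$auroc),
         plateau_tol = x$plateau_tol)
}

#' Plot an ROC curve
#'
#' @param object A `roc_result` from [roc_auroc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUROC %.3f (%d%% CI %.3f-%.3f)", object$auroc,
                      round(100 * object$conf_level), object$ci_low,
                      object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot AUROC against the regularization exponent k
#'
#' @param object A `k_sweep` from [sweep_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_sweep
#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$k, y = .data$auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dotted") +
    ggplot2::labs(x = "k  (delta = 10^-k)", y = "AUROC",
                  title = sprintf("Chosen k = %d", object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Plot similarity score distributions by pair label
#'
#' Density view of match vs mismatch pair scores; the separation of the two
#' distributions is what the AUROC quantifies.
#'
#' @param scores A score tibble (`id_a`, `id_b`, `score`).
#' @param labels A label tibble from [label_pairs()].
#' @return A ggplot object.
#' @export
plot_score_separation <- function(scores, labels) {
  merged <- align_scores(scores, labels)
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Similarity score", y = "Density", fill = "Pair") +
    ggplot2::theme_minimal()
}
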
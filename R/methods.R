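#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a grown tree into its node table
#'
#' @param x A `mashdx_tree`. @param ... Unused.
#' @return The node tibble (one row per node).
#' @export
tidy.mashdx_tree <- function(x, ...) x$nodes

#' @rdname tidy.mashdx_tree
#' @return For `glance`: a one-row tibble with `n_splits`, `n_leaves`,
#'   `depth`, `root_variable`, `root_threshold`, `root_logworth`.
#' @export
glance.mashdx_tree <- function(x, ...) {
  tibble::tibble(
    n_splits = sum(!x$nodes$leaf),
    n_leaves = sum(x$nodes$leaf),
    depth = max(x$nodes$depth),
    root_variable = x$nodes$split_variable[1],
    root_threshold = x$nodes$threshold[1],
    root_logworth = x$nodes$logworth[1]
  )
}

#' Tidy cross-validation results
#'
#' @param x A `mashdx_cv`. @param ... Unused.
#' @return For `tidy`: per-repetition metrics; for `glance`: one row per data
#'   part with macro-averaged metrics plus the settings.
#' @export
tidy.mashdx_cv <- function(x, ...) x$folds

#' @rdname tidy.mashdx_cv
#' @export
glance.mashdx_cv <- function(x, ...) {
  dplyr::mutate(x$means, k = x$k, train_fraction = x$train_fraction)
}

#' Tidy a logistic fit
#'
#' @param x A `mashdx_logistic`. @param ... Unused.
#' @return For `tidy`: the per-term coefficient table with Wald statistics
#'   and LogWorth; for `glance`: convergence/separation flags, n, deviance
#'   and AIC.
#' @export
tidy.mashdx_logistic <- function(x, ...) x$coefficients

#' @rdname tidy.mashdx_logistic
#' @export
glance.mashdx_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged, separation = x$separation,
                 deviance = x$fit$deviance, aic = x$fit$aic,
                 selected = paste(x$selected, collapse = "+"))
}

#' Tidy a group comparison
#'
#' @param x A `mashdx_comparison`. @param ... Unused.
#' @return For `tidy`: the pairwise table with raw and adjusted p-values;
#'   for `glance`: the omnibus test.
#' @export
tidy.mashdx_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, variable = x$variable, .before = 1)
}

#' @rdname tidy.mashdx_comparison
#' @export
glance.mashdx_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, test = x$test,
                 omnibus_p = x$omnibus_p)
}

# ---- autoplot methods --------------------------------------------------------

#' Plot a simulated or measured spectrum
#'
#' Real intensity against chemical shift, with the ppm axis reversed as is
#' conventional for NMR.
#'
#' @param object A `mashdx_spectrum`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mashdx_spectrum <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)",
                  title = sprintf("TE = %g ms", object$te)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Sensitivity against 1 - specificity with the chance diagonal and the AUC
#' in the subtitle.
#'
#' @param object A `mashdx_roc`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mashdx_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = (100 - object$specificity) / 100,
                       tpr = object$sensitivity / 100)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.4f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a biomarker screen
#'
#' AUC per screened variable, coloured by the retention rule.
#'
#' @param object A `mashdx_screen`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mashdx_screen <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$auc))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$auc, y = stats::reorder(.data$variable, .data$auc),
    fill = .data$retained
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "auc_min"),
                        linetype = "dashed") +
    ggplot2::labs(x = "AUC", y = NULL, fill = "retained") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metrics
#'
#' Per-repetition metric distributions by data part.
#'
#' @param object A `mashdx_cv`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mashdx_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds,
                            c("sensitivity", "specificity", "accuracy",
                              "auc"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   colour = .data$part)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.7)) +
    ggplot2::labs(x = NULL, y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}
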
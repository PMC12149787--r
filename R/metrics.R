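#' Prevalence-adjusted estimated accuracy
#'
#' \deqn{Accuracy = Sens \times Prev + Spec \times (1 - Prev)} — the expected
#' proportion of correct classifications in a population with the given
#' disease prevalence. Linear in prevalence, with endpoints equal to the
#' specificity (prev = 0) and the sensitivity (prev = 1).
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\]
#'   (vectorized).
#' @return Accuracy as a proportion.
#' @examples
#' accuracy_at_prevalence(0.8185, 0.984, 0.40)  # 0.9178
#' @export
accuracy_at_prevalence <- function(sensitivity, specificity, prevalence) {
  check_proportions(sensitivity, specificity, prevalence)
  sensitivity * prevalence + specificity * (1 - prevalence)
}

#' Prevalence-adjusted positive predictive value
#'
#' Bayes PPV at a target population prevalence:
#' \deqn{PPV = \frac{Sens \times Prev}{(1-Spec)(1-Prev) + Sens \times Prev}}
#' Strictly increasing in prevalence whenever 0 < sens and spec < 1. The
#' shipped prevalence scenarios are 40% (post-liver-transplant population)
#' and 5.8% (general population).
#'
#' @inheritParams accuracy_at_prevalence
#' @return PPV as a proportion.
#' @examples
#' ppv_at_prevalence(0.9412, 0.8727, 0.40)   # ~0.83
#' ppv_at_prevalence(0.8185, 0.984, 0.058)   # ~0.76
#' @export
ppv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  check_proportions(sensitivity, specificity, prevalence)
  num <- sensitivity * prevalence
  den <- (1 - specificity) * (1 - prevalence) + num
  if (any(den == 0)) {
    stop("PPV undefined (0/0): no positive calls at this operating point",
         call. = FALSE)
  }
  num / den
}

check_proportions <- function(...) {
  vals <- c(...)
  if (any(vals < 0 | vals > 1)) {
    stop("sensitivity, specificity and prevalence must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Named prevalence scenarios
#'
#' The two populations the prevalence-adjusted metrics are reported for:
#' post-transplant (40%) and general population (5.8%).
#'
#' @return Named numeric vector of prevalences.
#' @export
prevalence_scenarios <- function() {
  c(transplant = 0.40, general = 0.058)
}

#' Confusion-matrix performance metrics
#'
#' Counts TP/FN/TN/FP with MASH as the positive class and derives sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`.
#'
#' @param predicted Logical (or coercible) predicted classes.
#' @param truth Logical truth; both classes must be present.
#' @return One-row tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  stopifnot(length(predicted) == length(truth))
  if (!any(truth) || all(truth)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth); fp <- sum(predicted & !truth)
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp))
}

#' Prevalence-adjusted performance table
#'
#' Expands one or more (sensitivity, specificity) operating points over the
#' requested prevalence scenarios, mirroring the standard performance-table
#' layout (method, sensitivity, specificity, estimated accuracy, prevalence,
#' PPV).
#'
#' @param perf Data frame with columns `method`, `sensitivity`, `specificity`
#'   (proportions).
#' @param prevalences Named numeric vector of prevalences
#'   (default [prevalence_scenarios()]).
#' @return A tibble with one row per operating point x prevalence:
#'   `method`, `sensitivity`, `specificity`, `prevalence`, `scenario`,
#'   `accuracy`, `ppv`.
#' @examples
#' performance_table(tibble::tibble(method = "ROC", sensitivity = 0.9412,
#'                                  specificity = 0.8727))
#' @export
performance_table <- function(perf, prevalences = prevalence_scenarios()) {
  stopifnot(all(c("method", "sensitivity", "specificity") %in% names(perf)))
  tidyr::crossing(perf,
                  tibble::tibble(scenario = names(prevalences),
                                 prevalence = unname(prevalences))) |>
    dplyr::mutate(
      accuracy = accuracy_at_prevalence(.data$sensitivity, .data$specificity,
                                        .data$prevalence),
      ppv = ppv_at_prevalence(.data$sensitivity, .data$specificity,
                              .data$prevalence)
    ) |>
    dplyr::arrange(.data$method, dplyr::desc(.data$prevalence))
}
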
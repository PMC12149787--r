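#' Empirical ROC curve
#'
#' Computes the empirical ROC over thresholds at midpoints between consecutive
#' distinct sorted score values, plus the two infinite endpoints. The positive
#' direction (higher-is-positive vs lower-is-positive) is chosen so that the
#' AUC is >= 0.5 and recorded in the result; classification at a threshold `t`
#' is strict (`score > t` positive for direction `">"`, `score < t` for
#' `"<"`).
#'
#' @param scores Numeric scores, one per subject (NAs dropped with their
#'   labels).
#' @param labels Logical (or coercible) vector, `TRUE` for the positive class.
#' @return A tibble of class `mashdx_roc`: `threshold`, `sensitivity`,
#'   `specificity` (percent scales); attributes `direction` (">" or "<"),
#'   `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("ROC needs both a positive and a negative class", call. = FALSE)
  }
  a_up <- roc_auc_direction(scores, labels)
  direction <- if (a_up >= 0.5) ">" else "<"
  s <- if (direction == ">") scores else -scores
  v <- sort(unique(s))
  thr <- c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
  if (length(v) == 1) thr <- c(-Inf, Inf)
  npos <- sum(labels); nneg <- sum(!labels)
  sens <- vapply(thr, function(t) sum(s[labels] > t) / npos, numeric(1))
  spec <- vapply(thr, function(t) sum(s[!labels] <= t) / nneg, numeric(1))
  out <- tibble::tibble(
    threshold = if (direction == ">") thr else -thr,
    sensitivity = 100 * sens,
    specificity = 100 * spec
  )
  class(out) <- c("mashdx_roc", class(out))
  attr(out, "direction") <- direction
  attr(out, "auc") <- max(a_up, 1 - a_up)
  attr(out, "n_pos") <- npos
  attr(out, "n_neg") <- nneg
  out
}

# Mann-Whitney concordance of "higher score is positive", ties counted 1/2.
roc_auc_direction <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance statistic \eqn{U/(n_1 n_2)} with ties counted
#' one half; identical to the trapezoidal area under the empirical ROC curve.
#' By default the orientation follows [roc_curve()] (AUC >= 0.5); set
#' `direction = ">"` to force the higher-is-positive orientation.
#'
#' @inheritParams roc_curve
#' @param direction `"auto"` (orient so AUC >= 0.5) or `">"`.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
roc_auc <- function(scores, labels, direction = c("auto", ">")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("AUC needs both a positive and a negative class", call. = FALSE)
  }
  a <- roc_auc_direction(scores, labels)
  if (direction == ">") a else max(a, 1 - a)
}

# Trapezoidal area under an empirical ROC curve (oracle route used in tests
# and exposed for the equivalence property).
#' Trapezoidal AUC from a fitted ROC curve
#'
#' Integrates sensitivity against (1 - specificity) by the trapezoid rule.
#' Equals the rank-based [roc_auc()] exactly, ties included.
#'
#' @param curve A `mashdx_roc` from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc_trapezoid <- function(curve) {
  fpr <- (100 - curve$specificity) / 100
  tpr <- curve$sensitivity / 100
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden-optimal operating point
#'
#' Maximizes the Youden index (sensitivity + specificity - 100) over the ROC
#' curve's thresholds. Ties are broken toward the cut-off that maximizes
#' sensitivity (the lower threshold for direction `">"`, the higher for
#' `"<"`); infinite endpoints are not reported as cut-offs unless they are the
#' unique optimum.
#'
#' @param curve A `mashdx_roc` from [roc_curve()].
#' @return One-row tibble: `cutoff`, `direction`, `sensitivity`,
#'   `specificity`, `youden` (all percent scales), `tie` (logical; TRUE when
#'   several thresholds attained the maximum).
#' @examples
#' youden_optimal(roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)))
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "mashdx_roc"))
  j <- curve$sensitivity + curve$specificity - 100
  cand <- which(j == max(j))
  # prefer finite cut-offs, then maximise sensitivity among ties
  if (any(is.finite(curve$threshold[cand]))) {
    cand <- cand[is.finite(curve$threshold[cand])]
  }
  direction <- attr(curve, "direction")
  best <- cand[which.max(curve$sensitivity[cand])]
  tibble::tibble(
    cutoff = curve$threshold[best],
    direction = direction,
    sensitivity = curve$sensitivity[best],
    specificity = curve$specificity[best],
    youden = j[best],
    tie = length(cand) > 1
  )
}

#' Screen candidate variables by ROC against a group contrast
#'
#' Runs a per-variable ROC analysis of the configured contrast (default MASH
#' vs NoS + MASLD), reports AUC, the Youden-optimal cut-off with its
#' direction, sensitivity and specificity, applies the AUC retention rule
#' (variables with AUC below `auc_min` are flagged excluded), and sorts by
#' AUC descending. Missing values are dropped per variable (complete-case per
#' variable); the per-variable n after removal is reported.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] / [read_cohort()]).
#' @param variables Character vector of column names to screen.
#' @param contrast List with elements `positive` and `negative`, each a set of
#'   group labels.
#' @param auc_min Retention threshold on AUC (default 0.7).
#' @return A tibble of class `mashdx_screen`: `variable`, `auc`, `cutoff`,
#'   `direction`, `sensitivity`, `specificity`, `youden`, `n_pos`, `n_neg`,
#'   `retained`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' screen_variables(cohort, c("ff", "insulinemia", "age"))
#' @export
screen_variables <- function(cohort, variables,
                             contrast = contrast_mash_vs_rest(),
                             auc_min = 0.7) {
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars)) {
    stop("variables not present in cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  sub <- cohort[cohort$group %in% c(contrast$positive, contrast$negative), ]
  labels <- sub$group %in% contrast$positive
  rows <- purrr::map(variables, function(v) {
    x <- sub[[v]]
    ok <- !is.na(x)
    if (!any(ok) || length(unique(labels[ok])) < 2) {
      return(tibble::tibble(variable = v, auc = NA_real_, cutoff = NA_real_,
                            direction = NA_character_, sensitivity = NA_real_,
                            specificity = NA_real_, youden = NA_real_,
                            n_pos = sum(labels & ok), n_neg = sum(!labels & ok),
                            retained = FALSE,
                            note = "no usable observations"))
    }
    curve <- roc_curve(x[ok], labels[ok])
    opt <- youden_optimal(curve)
    tibble::tibble(variable = v, auc = attr(curve, "auc"),
                   cutoff = opt$cutoff, direction = opt$direction,
                   sensitivity = opt$sensitivity, specificity = opt$specificity,
                   youden = opt$youden,
                   n_pos = attr(curve, "n_pos"), n_neg = attr(curve, "n_neg"),
                   retained = NA, note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$retained <- !is.na(out$auc) & out$auc >= auc_min
  out <- dplyr::arrange(out, dplyr::desc(.data$auc))
  class(out) <- c("mashdx_screen", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "auc_min") <- auc_min
  out
}

#' Standard group contrasts
#'
#' The four contrasts of the analysis: MASH vs the pooled non-MASH groups
#' (primary), MASH vs NoS, MASH vs MASLD, and MASLD vs NoS.
#'
#' @return A list with `positive` and `negative` label sets.
#' @export
contrast_mash_vs_rest <- function() {
  list(positive = "MASH", negative = c("NoS", "MASLD"))
}

#' @rdname contrast_mash_vs_rest
#' @export
contrast_mash_vs_nos <- function() list(positive = "MASH", negative = "NoS")

#' @rdname contrast_mash_vs_rest
#' @export
contrast_mash_vs_masld <- function() {
  list(positive = "MASH", negative = "MASLD")
}

#' @rdname contrast_mash_vs_rest
#' @export
contrast_masld_vs_nos <- function() list(positive = "MASLD", negative = "NoS")
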
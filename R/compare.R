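#' @importFrom stats aov coef glm kruskal.test lm median pchisq pf
#'   quantile sd shapiro.test t.test
NULL

# Holm-Sidak step-down adjustment of a vector of raw p-values:
# order ascending, p_adj_(i) = 1 - (1 - p_(i))^(m - i + 1), enforced monotone.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dunn's rank-based pairwise z tests following a Kruskal-Wallis omnibus,
# with the usual tie correction; returns raw two-sided p per pair.
dunn_pairwise <- function(x, g) {
  g <- droplevels(as.factor(g))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i <- g == pr[1]; j <- g == pr[2]
    z <- (mean(r[i]) - mean(r[j])) / sqrt(v0 * (1 / sum(i) + 1 / sum(j)))
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
}

# Pairwise Welch t tests; returns raw two-sided p per pair.
t_pairwise <- function(x, g) {
  g <- droplevels(as.factor(g))
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    tt <- t.test(x[g == pr[1]], x[g == pr[2]])
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = unname(tt$statistic),
                   p_raw = tt$p.value)
  })
}

#' Three-group comparison of one variable
#'
#' Summarises a variable per diagnostic group as median (Q1-Q3) and tests for
#' group differences. The parametric branch (one-way ANOVA followed by
#' pairwise t tests with Holm-Sidak step-down adjustment) is taken when every
#' group passes a Shapiro-Wilk normality check at `alpha_normality`;
#' otherwise the nonparametric branch is used (Kruskal-Wallis followed by
#' Dunn's rank tests, Holm-adjusted). Missing values are dropped.
#'
#' @param cohort Cohort tibble with a `group` column.
#' @param variable Column name to compare.
#' @param alpha_normality Per-group Shapiro-Wilk significance level gating the
#'   parametric branch (default 0.05).
#' @return A list of class `mashdx_comparison`: `variable`, `test`
#'   ("parametric"/"nonparametric"), `summary` (per-group median/Q1/Q3/n),
#'   `omnibus_p`, `pairwise` (tibble with raw and adjusted p per pair).
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' compare_groups(cohort, "ff")
#' @export
compare_groups <- function(cohort, variable, alpha_normality = 0.05) {
  stopifnot(variable %in% names(cohort), "group" %in% names(cohort))
  ok <- !is.na(cohort[[variable]])
  x <- cohort[[variable]][ok]
  g <- droplevels(as.factor(cohort$group[ok]))
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 3)) {
    stop("compare_groups needs at least two groups with >= 3 observations",
         call. = FALSE)
  }
  summary_tbl <- tibble::tibble(
    group = levels(g),
    n = as.integer(sizes[levels(g)]),
    median = vapply(levels(g), function(l) median(x[g == l]), numeric(1)),
    q1 = vapply(levels(g), function(l) quantile(x[g == l], 0.25, names = FALSE),
                numeric(1)),
    q3 = vapply(levels(g), function(l) quantile(x[g == l], 0.75, names = FALSE),
                numeric(1))
  )
  normal <- all(vapply(levels(g), function(l) {
    xi <- x[g == l]
    if (length(unique(xi)) < 3) return(FALSE)
    shapiro.test(xi)$p.value >= alpha_normality
  }, logical(1)))
  if (normal) {
    fit <- aov(x ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- t_pairwise(x, g)
    pw$p_adj <- holm_sidak(pw$p_raw)
    test <- "parametric"
  } else {
    omnibus_p <- kruskal.test(x, g)$p.value
    pw <- dunn_pairwise(x, g)
    pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
    test <- "nonparametric"
  }
  structure(list(variable = variable, test = test, summary = summary_tbl,
                 omnibus_p = omnibus_p, pairwise = pw),
            class = "mashdx_comparison")
}

#' @export
print.mashdx_comparison <- function(x, ...) {
  cat("<mashdx_comparison> ", x$variable, " (", x$test, "), omnibus p = ",
      format.pval(x$omnibus_p, digits = 3), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Binary logistic fit with Wald inference and optional forward stepwise
#'
#' Maximum-likelihood logistic regression of the MASH outcome on the given
#' effects via iteratively reweighted least squares (`stats::glm`), reporting
#' per-effect Wald statistics, p-values and LogWorth (`-log10 p`), ordered by
#' LogWorth. With `stepwise = TRUE`, effects are entered forward one at a
#' time, each step adding the candidate with the smallest Wald p-value while
#' that p-value is below `alpha_enter`. (Quasi-)complete separation is
#' detected from the IRLS warnings and fitted probabilities and flagged.
#'
#' @param cohort Data frame. @param effects Character vector of predictor
#'   columns.
#' @param outcome Logical outcome column (default `"mash"`).
#' @param stepwise Forward-selection flag (default `FALSE` fits all effects).
#' @param alpha_enter Wald entry threshold for stepwise (default 0.05).
#' @return A list of class `mashdx_logistic`: `coefficients` (tibble with
#'   `term`, `estimate`, `std_error`, `wald`, `p`, `logworth`, sorted by
#'   LogWorth; intercept last), `selected` (effects in entry order when
#'   stepwise), `converged`, `separation`, and the underlying `fit`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' logistic_fit(cohort, c("ff", "insulinemia"), stepwise = TRUE)$selected
#' @export
logistic_fit <- function(cohort, effects, outcome = "mash", stepwise = FALSE,
                         alpha_enter = 0.05) {
  stopifnot(all(effects %in% names(cohort)), outcome %in% names(cohort))
  dat <- cohort[stats::complete.cases(cohort[c(outcome, effects)]), ]
  y <- as.logical(dat[[outcome]])
  stopifnot(length(effects) < length(y))

  fit_once <- function(terms) {
    f <- stats::reformulate(if (length(terms)) terms else "1",
                            response = outcome)
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(f, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    mu <- stats::fitted(fit)
    sep <- sep || any(mu < 1e-10) || any(mu > 1 - 1e-10)
    list(fit = fit, separation = sep)
  }

  wald_p <- function(fit, term) {
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf)) return(NA_real_)
    cf[term, "Pr(>|z|)"]
  }

  selected <- effects
  if (stepwise) {
    selected <- character()
    remaining <- effects
    while (length(remaining)) {
      ps <- vapply(remaining, function(e) {
        wald_p(fit_once(c(selected, e))$fit, e)
      }, numeric(1))
      best <- names(ps)[which.min(ps)]
      if (!length(best) || is.na(min(ps, na.rm = TRUE)) ||
          min(ps, na.rm = TRUE) >= alpha_enter) break
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    }
    if (!length(selected)) {
      selected <- character()
    }
  }
  res <- fit_once(selected)
  cf <- summary(res$fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    wald = cf[, "z value"]^2,
    p = cf[, "Pr(>|z|)"],
    logworth = -log10(cf[, "Pr(>|z|)"])
  )
  coefs <- dplyr::arrange(coefs, .data$term == "(Intercept)",
                          dplyr::desc(.data$logworth))
  structure(
    list(coefficients = coefs, selected = selected,
         converged = res$fit$converged, separation = res$separation,
         fit = res$fit, n = length(y)),
    class = "mashdx_logistic"
  )
}

#' @export
print.mashdx_logistic <- function(x, ...) {
  cat("<mashdx_logistic> n = ", x$n,
      if (x$separation) " [separation detected]" else "",
      if (!x$converged) " [did not converge]" else "", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
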
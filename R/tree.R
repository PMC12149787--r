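#' G-squared likelihood-ratio statistic for a 2x2 table
#'
#' \deqn{G^2 = 2 \sum O \ln(O/E)} with the convention `0 ln 0 = 0`; the
#' p-value comes from the chi-square distribution with one degree of freedom
#' and LogWorth is \eqn{-\log_{10}(p)}, computed on the log scale so very
#' strong splits do not underflow. A table with an empty margin carries no
#' evidence: G2 = 0, p = 1. A Pearson X-squared variant is available for
#' comparison.
#'
#' @param table 2x2 matrix of non-negative counts (rows: split side, columns:
#'   class), positive grand total.
#' @param statistic `"g2"` (likelihood ratio, default) or `"pearson"`.
#' @return One-row tibble: `g2`, `p`, `logworth`.
#' @examples
#' g2_statistic(matrix(c(10, 0, 0, 10), 2))  # 40 * log(2)
#' @export
g2_statistic <- function(table, statistic = c("g2", "pearson")) {
  statistic <- match.arg(statistic)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0), sum(table) > 0)
  n <- sum(table)
  E <- outer(rowSums(table), colSums(table)) / n
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble::tibble(g2 = 0, p = 1, logworth = 0))
  }
  if (statistic == "g2") {
    terms <- ifelse(table > 0, table * log(table / E), 0)
    stat <- 2 * sum(terms)
  } else {
    stat <- sum((table - E)^2 / E)
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  lw <- -stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  tibble::tibble(g2 = stat, p = p, logworth = lw)
}

# Vectorised G2 scan over all candidate thresholds of one variable.
# x: numeric; y: logical outcome. Returns tibble of candidates (possibly empty).
g2_scan <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (n < 2) return(tibble::tibble())
  # boundaries after which the value changes
  cut_idx <- which(diff(x) > 0)
  if (!length(cut_idx)) return(tibble::tibble())
  cpos <- cumsum(y)
  P <- cpos[n]; N <- n
  if (P == 0 || P == N) {
    return(tibble::tibble(threshold = (x[cut_idx] + x[cut_idx + 1]) / 2,
                          g2 = 0, p = 1, logworth = 0,
                          n_left = cut_idx, n_right = n - cut_idx))
  }
  nL <- cut_idx
  a <- cpos[cut_idx]          # left positives
  b <- nL - a                 # left negatives
  cc <- P - a                 # right positives
  d <- N - nL - cc            # right negatives
  xlogx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g2 <- 2 * (xlogx(a, nL * P / N) + xlogx(b, nL * (N - P) / N) +
               xlogx(cc, (N - nL) * P / N) + xlogx(d, (N - nL) * (N - P) / N))
  g2 <- pmax(g2, 0)
  tibble::tibble(
    threshold = (x[cut_idx] + x[cut_idx + 1]) / 2,
    g2 = g2,
    p = stats::pchisq(g2, 1, lower.tail = FALSE),
    logworth = -stats::pchisq(g2, 1, lower.tail = FALSE, log.p = TRUE) / log(10),
    n_left = nL, n_right = n - nL
  )
}

#' Best binary split of one variable
#'
#' Evaluates candidate thresholds at the midpoints between consecutive
#' distinct sorted values of `variable` and returns the maximizer of the G2
#' statistic for the 2x2 split-by-outcome table. Missing values of the
#' variable are excluded at this node. Ties in G2 are broken toward the
#' smaller threshold. Records with `value <= threshold` fall on the left.
#'
#' @param data Data frame containing `variable` and the outcome column.
#' @param variable Name of the numeric splitting variable.
#' @param outcome Name of the logical outcome column (default `"mash"`).
#' @return One-row tibble `variable`, `threshold`, `g2`, `p`, `logworth`,
#'   `n_left`, `n_right`; zero rows when the variable is constant.
#' @examples
#' d <- tibble::tibble(x = 1:10, mash = rep(c(FALSE, TRUE), each = 5))
#' best_split(d, "x")
#' @export
best_split <- function(data, variable, outcome = "mash") {
  scan <- g2_scan(data[[variable]], as.logical(data[[outcome]]))
  if (!nrow(scan)) return(tibble::tibble())
  best <- which(scan$g2 == max(scan$g2))[1]  # smaller threshold on ties
  dplyr::bind_cols(tibble::tibble(variable = variable), scan[best, ])
}

#' Grow a G2/LogWorth recursive-partitioning tree
#'
#' Recursively applies [best_split()] over the candidate features, accepting a
#' split only when its LogWorth reaches `min_logworth` (default 1.3, i.e.
#' p <= 0.05), the node holds at least `min_node` records and the depth does
#' not exceed `max_depth`. Leaves carry class counts and the empirical MASH
#' probability. Growth is deterministic given the data.
#'
#' @param data Data frame with the outcome and feature columns.
#' @param features Character vector of candidate split variables.
#' @param outcome Logical outcome column name (default `"mash"`).
#' @param min_logworth Minimum LogWorth to retain a split (default 1.3).
#' @param min_node Minimum records in a node for it to be split (default 5).
#' @param max_depth Maximum number of split levels (default 4).
#' @return An object of class `mashdx_tree` holding a node table (`id`,
#'   `parent`, `depth`, `n`, `n_pos`, `n_neg`, `prob`, `leaf`,
#'   `split_variable`, `threshold`, `g2`, `logworth`, `left`, `right`).
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' tree <- grow_tree(cohort, c("ff", "insulinemia", "elastography"))
#' tree
#' @export
grow_tree <- function(data, features, outcome = "mash", min_logworth = 1.3,
                      min_node = 5, max_depth = 4) {
  stopifnot(length(features) >= 1, all(features %in% names(data)),
            outcome %in% names(data))
  y <- as.logical(data[[outcome]])
  stopifnot(!anyNA(y))
  nodes <- new.env()
  nodes$tab <- list()
  nodes$next_id <- 1L

  add_node <- function(rows, depth, parent) {
    id <- nodes$next_id
    nodes$next_id <- id + 1L
    yy <- y[rows]
    n_pos <- sum(yy); n <- length(yy)
    rec <- list(id = id, parent = parent, depth = depth, n = n,
                n_pos = n_pos, n_neg = n - n_pos, prob = n_pos / n,
                leaf = TRUE, split_variable = NA_character_,
                threshold = NA_real_, g2 = NA_real_, logworth = NA_real_,
                left = NA_integer_, right = NA_integer_)
    can_split <- n >= min_node && depth < max_depth &&
      n_pos > 0 && n_pos < n
    if (can_split) {
      cands <- purrr::map(features, function(f) {
        best_split(data[rows, , drop = FALSE], f, outcome)
      })
      cands <- dplyr::bind_rows(cands)
      if (nrow(cands)) {
        best <- cands[order(-cands$g2, cands$threshold), ][1, ]
        if (is.finite(best$logworth) && best$logworth >= min_logworth) {
          go_left <- data[[best$variable]][rows] <= best$threshold
          go_left[is.na(go_left)] <- FALSE  # NA cannot satisfy <=
          rec$leaf <- FALSE
          rec$split_variable <- best$variable
          rec$threshold <- best$threshold
          rec$g2 <- best$g2
          rec$logworth <- best$logworth
          nodes$tab[[id]] <- rec  # reserve slot before recursing
          rec$left <- add_node(rows[go_left], depth + 1L, id)
          rec$right <- add_node(rows[!go_left], depth + 1L, id)
        }
      }
    }
    nodes$tab[[id]] <- rec
    id
  }
  add_node(seq_along(y), 0L, NA_integer_)
  tab <- dplyr::bind_rows(purrr::map(nodes$tab, tibble::as_tibble))
  structure(
    list(nodes = tab, outcome = outcome, features = features,
         params = list(min_logworth = min_logworth, min_node = min_node,
                       max_depth = max_depth)),
    class = "mashdx_tree"
  )
}

#' @export
print.mashdx_tree <- function(x, ...) {
  cat("<mashdx_tree> ", sum(!x$nodes$leaf), " split(s), ",
      sum(x$nodes$leaf), " leaf/leaves\n", sep = "")
  print_node <- function(id, indent) {
    nd <- x$nodes[x$nodes$id == id, ]
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(pad, "leaf: n=", nd$n, " (MASH ", nd$n_pos, ") p=",
          round(nd$prob, 3), "\n", sep = "")
    } else {
      cat(pad, nd$split_variable, " <= ", signif(nd$threshold, 4),
          "  [G2=", signif(nd$g2, 4), ", LogWorth=", signif(nd$logworth, 3),
          "]\n", sep = "")
      print_node(nd$left, indent + 1)
      print_node(nd$right, indent + 1)
    }
  }
  print_node(1L, 1)
  invisible(x)
}

#' Predict MASH probability with a grown tree
#'
#' Routes each record down the tree by threshold comparisons (values equal to
#' a threshold go to the left, `<=`, side). A missing value on the path sends
#' the record to the larger child and sets the `imputed_route` flag.
#'
#' @param object A `mashdx_tree`. @param newdata Data frame of records.
#' @param type `"prob"` for probabilities, `"class"` for the 0.5-threshold
#'   classification.
#' @param ... Unused.
#' @return A tibble with `prob`, `class` (logical), `leaf_id`,
#'   `imputed_route`.
#' @export
predict.mashdx_tree <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  nodes <- object$nodes
  route <- function(i) {
    id <- 1L
    flagged <- FALSE
    repeat {
      nd <- nodes[nodes$id == id, ]
      if (nd$leaf) return(c(nd$prob, id, flagged))
      v <- newdata[[nd$split_variable]][i]
      if (is.na(v)) {
        flagged <- TRUE
        l <- nodes[nodes$id == nd$left, ]; r <- nodes[nodes$id == nd$right, ]
        id <- if (l$n >= r$n) nd$left else nd$right
      } else {
        id <- if (v <= nd$threshold) nd$left else nd$right
      }
    }
  }
  res <- vapply(seq_len(nrow(newdata)), route, numeric(3))
  out <- tibble::tibble(prob = res[1, ], class = res[1, ] > 0.5,
                        leaf_id = as.integer(res[2, ]),
                        imputed_route = as.logical(res[3, ]))
  if (type == "class") out$class else out
}

#' Column contributions of a grown tree
#'
#' Importance of each feature as its share of the total G2 accumulated over
#' the tree's retained splits, normalized to sum to one.
#'
#' @param tree A `mashdx_tree`.
#' @return Tibble `variable`, `g2_total`, `contribution`, sorted descending;
#'   zero rows for a tree with no splits.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' column_contributions(grow_tree(cohort, c("ff", "insulinemia")))
#' @export
column_contributions <- function(tree) {
  stopifnot(inherits(tree, "mashdx_tree"))
  splits <- tree$nodes[!tree$nodes$leaf, ]
  if (!nrow(splits)) {
    return(tibble::tibble(variable = character(), g2_total = numeric(),
                          contribution = numeric()))
  }
  splits |>
    dplyr::group_by(variable = .data$split_variable) |>
    dplyr::summarise(g2_total = sum(.data$g2), .groups = "drop") |>
    dplyr::mutate(contribution = .data$g2_total / sum(.data$g2_total)) |>
    dplyr::arrange(dplyr::desc(.data$contribution))
}

# Confusion-derived metrics of tree predictions on one data part.
part_metrics <- function(tree, data, outcome) {
  truth <- as.logical(data[[outcome]])
  pred <- predict(tree, data)
  cm <- confusion_metrics(pred$class, truth)
  auc <- if (length(unique(pred$prob)) > 1) {
    roc_auc(pred$prob, truth, direction = ">")
  } else 0.5
  tibble::tibble(sensitivity = cm$sensitivity, specificity = cm$specificity,
                 accuracy = (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn),
                 auc = auc)
}

#' Repeated stratified train/validation cross-validation of the tree
#'
#' Performs `k` repetitions of stratified random splits at the configured
#' training fraction (70:30 primary, 50:50 secondary), grows a tree on each
#' training part, and evaluates sensitivity, specificity, accuracy and AUC on
#' both parts. Stratification preserves the MASH proportion; a repetition
#' whose training part lost a class is redrawn (and counted). Means are
#' macro-averages over repetitions. Reproducible from `seed`.
#'
#' @inheritParams grow_tree
#' @param k Number of repetitions (default 10).
#' @param train_fraction Training proportion (default 0.7).
#' @param seed Integer seed.
#' @return An object of class `mashdx_cv`: `folds` (per-repetition metrics on
#'   `part` "training"/"validation"), `means` (macro-averaged), plus the
#'   settings.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' cv <- cross_validate(cohort, c("ff", "insulinemia"), k = 3, seed = 1)
#' cv$means
#' @export
cross_validate <- function(data, features, outcome = "mash", k = 10,
                           train_fraction = 0.7, seed = 1, min_logworth = 1.3,
                           min_node = 5, max_depth = 4) {
  stopifnot(k >= 2, train_fraction > 0, train_fraction < 1)
  y <- as.logical(data[[outcome]])
  set.seed(seed)
  redraws <- 0L
  folds <- purrr::map(seq_len(k), function(fold) {
    repeat {
      idx_pos <- which(y); idx_neg <- which(!y)
      n_tr_pos <- min(max(round(train_fraction * length(idx_pos)), 1),
                      length(idx_pos) - 1)
      n_tr_neg <- min(max(round(train_fraction * length(idx_neg)), 1),
                      length(idx_neg) - 1)
      train_idx <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
      train <- data[train_idx, , drop = FALSE]
      valid <- data[-train_idx, , drop = FALSE]
      if (length(unique(as.logical(train[[outcome]]))) == 2 &&
          length(unique(as.logical(valid[[outcome]]))) == 2) break
      redraws <<- redraws + 1L
    }
    tree <- grow_tree(train, features, outcome, min_logworth, min_node,
                      max_depth)
    dplyr::bind_rows(
      dplyr::mutate(part_metrics(tree, train, outcome), part = "training"),
      dplyr::mutate(part_metrics(tree, valid, outcome), part = "validation")
    ) |>
      dplyr::mutate(fold = fold, .before = 1)
  })
  folds <- dplyr::bind_rows(folds)
  means <- folds |>
    dplyr::group_by(.data$part) |>
    dplyr::summarise(dplyr::across(c("sensitivity", "specificity",
                                     "accuracy", "auc"), mean),
                     .groups = "drop")
  structure(
    list(folds = folds, means = means, k = k,
         train_fraction = train_fraction, seed = seed, redraws = redraws),
    class = "mashdx_cv"
  )
}

#' @export
print.mashdx_cv <- function(x, ...) {
  cat("<mashdx_cv> ", x$k, " stratified repetitions at ",
      round(100 * x$train_fraction), ":", round(100 * (1 - x$train_fraction)),
      " train:validation\n", sep = "")
  print(x$means)
  invisible(x)
}
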
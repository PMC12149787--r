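#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles the cohort generator configuration with the screening, tree,
#' cross-validation and prevalence settings of the full analysis flow.
#'
#' @param cohort A [cohort_config()].
#' @param features Candidate tree features; `NULL` (default) uses the
#'   variables retained by the ROC screen (AUC >= `auc_min`).
#' @param auc_min ROC retention threshold (default 0.7).
#' @param contrast Screening contrast (default MASH vs NoS + MASLD).
#' @param min_logworth,min_node,max_depth Tree growth settings.
#' @param k Cross-validation repetitions (default 10).
#' @param train_fractions Training proportions evaluated (default 0.7 primary
#'   and 0.5 secondary).
#' @param prevalences Named prevalence scenarios
#'   (default [prevalence_scenarios()]).
#' @param seed Integer seed fixed before any stochastic stage.
#' @param simulate_spectra If `TRUE`, simulate and re-quantify one spectrum
#'   per subject from their cohort fat fraction and hydrogen fractions
#'   (exercises the MRS stage; slower).
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @return A list of class `mashdx_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), features = NULL,
                            auc_min = 0.7, contrast = contrast_mash_vs_rest(),
                            min_logworth = 1.3, min_node = 5, max_depth = 4,
                            k = 10, train_fractions = c(0.7, 0.5),
                            prevalences = prevalence_scenarios(), seed = 1,
                            simulate_spectra = FALSE, out_dir = NULL) {
  structure(
    list(cohort = cohort, features = features, auc_min = auc_min,
         contrast = contrast, min_logworth = min_logworth,
         min_node = min_node, max_depth = max_depth, k = k,
         train_fractions = train_fractions, prevalences = prevalences,
         seed = seed, simulate_spectra = simulate_spectra, out_dir = out_dir),
    class = "mashdx_pipeline_config"
  )
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic MASH-diagnosis analysis
#'
#' Executes the analysis flow end to end on synthetic data: simulate the
#' cohort (optionally with per-subject spectra, re-quantified); screen all
#' candidate variables by ROC with the AUC retention rule; grow the
#' G2/LogWorth decision tree on the retained features and cross-validate it
#' at each configured train fraction; compute prevalence-adjusted accuracy
#' and PPV for the tree and the best single-variable ROC classifier; and
#' compare the diagnostic groups variable by variable. With `out_dir` set,
#' writes CSV/JSON tables, a Graphviz DOT tree and a JSON run log capturing
#' the seed and settings; a rerun with the same configuration is
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mashdx_bundle`: `cohort`, `screen`, `features`,
#'   `tree`, `contributions`, `cv` (one [cross_validate()] result per train
#'   fraction), `performance`, `comparisons`, `logistic`, `config`.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(pipeline_config(k = 3, seed = 1))
#' bundle$performance
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mashdx_pipeline_config"))
  cohort <- stage("simulate", simulate_cohort(config$cohort, config$seed))

  if (isTRUE(config$simulate_spectra)) {
    cohort <- stage("quantify", requantify_cohort(cohort, config$seed))
  }

  candidates <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                        c("id"))
  screen <- stage("screen", screen_variables(cohort, candidates,
                                             config$contrast, config$auc_min))
  features <- config$features
  if (is.null(features)) features <- screen$variable[screen$retained]

  tree <- stage("tree", grow_tree(cohort, features,
                                  min_logworth = config$min_logworth,
                                  min_node = config$min_node,
                                  max_depth = config$max_depth))
  contributions <- column_contributions(tree)
  cv <- stage("cross-validate", purrr::map(
    setNames(config$train_fractions,
             paste0("train_", round(100 * config$train_fractions))),
    function(fr) cross_validate(cohort, features, k = config$k,
                                train_fraction = fr, seed = config$seed,
                                min_logworth = config$min_logworth,
                                min_node = config$min_node,
                                max_depth = config$max_depth)
  ))

  cv1 <- cv[[1]]
  ff_row <- screen[screen$variable == "ff", ]
  perf_in <- dplyr::bind_rows(
    tibble::tibble(method = "tree training",
                   sensitivity = cv1$means$sensitivity[cv1$means$part == "training"],
                   specificity = cv1$means$specificity[cv1$means$part == "training"]),
    tibble::tibble(method = "tree validation",
                   sensitivity = cv1$means$sensitivity[cv1$means$part == "validation"],
                   specificity = cv1$means$specificity[cv1$means$part == "validation"]),
    tibble::tibble(method = "tree mean",
                   sensitivity = mean(cv1$means$sensitivity),
                   specificity = mean(cv1$means$specificity)),
    tibble::tibble(method = "ROC (ff)",
                   sensitivity = ff_row$sensitivity / 100,
                   specificity = ff_row$specificity / 100)
  )
  performance <- stage("metrics",
                       performance_table(perf_in, config$prevalences))

  comparisons <- stage("compare", purrr::map(
    setNames(candidates, candidates),
    function(v) compare_groups(cohort, v)
  ))
  logistic <- stage("logistic",
                    logistic_fit(cohort,
                                 intersect(c("ff", "insulinemia",
                                             "elastography"), features),
                                 stepwise = TRUE))

  bundle <- structure(
    list(cohort = cohort, screen = screen, features = features, tree = tree,
         contributions = contributions, cv = cv, performance = performance,
         comparisons = comparisons, logistic = logistic, config = config),
    class = "mashdx_bundle"
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Replace each subject's MRS-derived variables by the values re-quantified
# from a simulated spectrum at their generated operating point.
requantify_cohort <- function(cohort, seed) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    fr <- c(f_si = cohort$f_si[i], f_ui = cohort$f_ui[i],
            f_pui = cohort$f_pui[i])
    # project into the feasible amplitude region if the copula draw left it
    if (fr[["f_si"]] + 2 * fr[["f_ui"]] - fr[["f_pui"]] > 1) {
      fr[["f_si"]] <- 1 - 2 * fr[["f_ui"]] + fr[["f_pui"]]
    }
    sp <- simulate_spectrum(min(cohort$ff[i], 99), fr, snr = 200,
                            seed = seed * 1000L + i)
    quantify_spectrum(sp)[, c("ff", "f_si", "f_ui", "f_pui")]
  })
  q <- dplyr::bind_rows(rows)
  cohort$ff <- q$ff
  cohort$f_si <- q$f_si
  cohort$f_ui <- q$f_ui
  cohort$f_pui <- q$f_pui
  cohort
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(bundle$cohort, p("cohort.csv"))
  readr::write_csv(tibble::as_tibble(bundle$screen), p("screen.csv"), na = "")
  readr::write_csv(bundle$tree$nodes, p("tree_nodes.csv"), na = "")
  jsonlite::write_json(bundle$tree$nodes, p("tree.json"), digits = NA,
                       na = "null")
  write_tree_dot(bundle$tree, p("tree.dot"))
  readr::write_csv(bundle$contributions, p("column_contributions.csv"))
  for (nm in names(bundle$cv)) {
    readr::write_csv(bundle$cv[[nm]]$folds, p(paste0("cv_folds_", nm, ".csv")))
    readr::write_csv(bundle$cv[[nm]]$means, p(paste0("cv_means_", nm, ".csv")))
  }
  readr::write_csv(bundle$performance, p("performance.csv"))
  comp <- purrr::map_dfr(bundle$comparisons, function(cmp) {
    dplyr::mutate(cmp$pairwise, variable = cmp$variable, test = cmp$test,
                  omnibus_p = cmp$omnibus_p, .before = 1)
  })
  readr::write_csv(comp, p("comparisons.csv"))
  readr::write_csv(bundle$logistic$coefficients, p("logistic.csv"))
  log <- list(
    package = "mashdx",
    version = as.character(utils::packageVersion("mashdx")),
    r_version = R.version.string,
    seed = bundle$config$seed,
    auc_min = bundle$config$auc_min,
    min_logworth = bundle$config$min_logworth,
    min_node = bundle$config$min_node,
    max_depth = bundle$config$max_depth,
    k = bundle$config$k,
    train_fractions = bundle$config$train_fractions,
    prevalences = as.list(bundle$config$prevalences),
    features = bundle$features,
    n_per_group = setNames(as.list(bundle$config$cohort$groups$n),
                           bundle$config$cohort$groups$group)
  )
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mashdx_bundle <- function(x, ...) {
  cat("<mashdx_bundle> cohort n=", nrow(x$cohort), "; ",
      sum(x$screen$retained), "/", nrow(x$screen),
      " variables retained; tree root: ",
      x$tree$nodes$split_variable[1], " <= ",
      signif(x$tree$nodes$threshold[1], 4), "\n", sep = "")
  invisible(x)
}
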
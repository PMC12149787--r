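#' Write / read a spectrum as two-column text with a JSON sidecar
#'
#' The spectrum file is whitespace-delimited text with two columns (ppm, real
#' intensity) and no header; acquisition metadata (`te_ms`, `tr_ms`,
#' `field_T`) travels in a JSON sidecar at `<path>.json`. Writers and readers
#' round-trip bit-exactly (values serialized with 17 significant digits).
#'
#' @param spectrum A `mashdx_spectrum`. @param path Output file path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   a `mashdx_spectrum`.
#' @examples
#' f <- tempfile(fileext = ".dat")
#' write_spectrum(simulate_spectrum(ff = 5, snr = Inf, n_points = 64), f)
#' read_spectrum(f)
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mashdx_spectrum"))
  lines <- sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity)
  writeLines(lines, path)
  meta <- list(te_ms = spectrum$te, tr_ms = spectrum$tr,
               field_T = spectrum$field)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  m <- utils::read.table(path, col.names = c("ppm", "intensity"))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_spectrum(m$ppm, m$intensity, te = as.numeric(meta$te_ms),
               tr = as.numeric(meta$tr_ms),
               field = as.numeric(meta$field_T))
}

#' Write / read a cohort as CSV
#'
#' One row per subject, header row, UTF-8, decimal point, missing values as
#' empty fields. `id` and `group` are mandatory; group labels must be NoS,
#' MASLD or MASH. Unknown columns are preserved, and the round trip is
#' lossless (numbers written in shortest exact representation).
#'
#' @param cohort Cohort tibble. @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort tibble with `group` as a factor and the derived logical `mash`
#'   column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(seed = 1), f)
#' read_cohort(f)
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(c("id", "group") %in% names(cohort)))
  out <- dplyr::select(cohort, -dplyr::any_of("mash"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, na = "", show_col_types = FALSE,
                            progress = FALSE)
  mandatory <- setdiff(c("id", "group"), names(cohort))
  if (length(mandatory)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(mandatory, collapse = ", "), call. = FALSE)
  }
  bad <- which(!cohort$group %in% c("NoS", "MASLD", "MASH"))
  if (length(bad)) {
    stop("unknown group label(s) '",
         paste(unique(cohort$group[bad]), collapse = "', '"),
         "' in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  cohort$group <- factor(cohort$group, levels = c("NoS", "MASLD", "MASH"))
  dplyr::mutate(cohort, mash = .data$group == "MASH",
                .after = "group")
}

#' Export a grown tree as Graphviz DOT
#'
#' @param tree A `mashdx_tree`. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "mashdx_tree"))
  nd <- tree$nodes
  lab <- ifelse(
    nd$leaf,
    sprintf("n=%d\\nMASH %d / non-MASH %d\\np=%.3f", nd$n, nd$n_pos, nd$n_neg,
            nd$prob),
    sprintf("%s <= %.4g\\nG2=%.3g LogWorth=%.3g", nd$split_variable,
            nd$threshold, nd$g2, nd$logworth)
  )
  lines <- c("digraph mashdx_tree {",
             "  node [shape=box];",
             sprintf('  n%d [label="%s"];', nd$id, lab))
  for (i in which(!nd$leaf)) {
    lines <- c(lines,
               sprintf('  n%d -> n%d [label="yes"];', nd$id[i], nd$left[i]),
               sprintf('  n%d -> n%d [label="no"];', nd$id[i], nd$right[i]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
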
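#' @importFrom rlang .data
#' @importFrom stats qnorm pnorm rnorm setNames
NULL

# ---- Calibrated group summaries ----------------------------------------------

# Published median (Q1-Q3) summaries per diagnostic group for a 127-subject
# liver-transplant cohort (NoS n=90, MASLD n=20, MASH n=17). One MASLD
# bilirubin quartile is corrected for an evident transposition in the source
# table (upper quartile 17.23, not 7.23).
default_summaries <- function() {
  raw <- c(
  # variable,          NoS med, q1, q3,        MASLD,             MASH
  "age",               57.55, 46.40, 66.45,  58.90, 45.82, 65.76,  63.50, 51.30, 68.58,
  "post_lt_years",      1.14,  1.01,  2.19,   1.96,  1.02,  4.92,   1.22,  1.02,  3.52,
  "elastography",       6.50,  5.90,  7.40,   7.45,  6.45,  9.40,   8.20,  7.65, 10.25,
  "bmi",               25.25, 22.86, 29.48,  26.95, 24.02, 29.49,  29.94, 27.29, 32.96,
  "waist",             94.5,  85.8, 106.0,  100.5,  92.3, 106.8,  107.0, 104.0, 113.5,
  "bilirubin",         12.50,  9.20, 20.08,  12.45,  9.41, 17.23,  13.20,  8.35, 18.40,
  "ast",                0.38,  0.30,  0.46,   0.40,  0.34,  0.58,   0.41,  0.35,  0.56,
  "alt",                0.44,  0.35,  0.56,   0.51,  0.38,  0.64,   0.59,  0.45,  0.76,
  "alp",                1.45,  1.14,  1.90,   1.33,  1.03,  1.87,   1.69,  1.09,  2.27,
  "ggt",                0.36,  0.26,  0.61,   0.40,  0.31,  0.71,   0.64,  0.34,  1.44,
  "cholesterol",        4.55,  3.90,  5.10,   4.95,  4.00,  5.80,   5.10,  4.35,  5.90,
  "ldl",                2.70,  2.25,  3.05,   2.95,  2.23,  3.28,   3.20,  2.20,  3.50,
  "hdl",                1.31,  1.03,  1.48,   1.05,  0.88,  1.40,   1.11,  0.86,  1.47,
  "glycemia",           5.32,  4.97,  6.17,   5.22,  4.72,  7.53,   5.94,  5.59,  7.15,
  "hba1c",             36,    32,    40,     35,    33,    46,     43.0,  34.5,  48.0,
  "c_peptide",          0.83,  0.61,  1.14,   0.85,  0.70,  1.13,   1.37,  1.09,  1.54,
  "insulinemia",        6.54,  4.37, 10.48,   7.00,  4.60, 10.31,  14.43,  8.80, 20.63,
  "homa_ir",            1.55,  1.08,  2.61,   1.65,  1.08,  3.26,   4.20,  2.19,  6.06,
  "quicki",             0.36,  0.33,  0.38,   0.35,  0.32,  0.38,   0.31,  0.30,  0.34,
  "ff",                 1.10,  0.80,  1.83,   4.01,  2.29,  9.55,  14.81,  9.38, 25.31,
  "f_si",               0.83,  0.78,  0.87,   0.88,  0.85,  0.90,   0.89,  0.87,  0.90,
  "f_ui",               0.058, 0.041, 0.090,  0.042, 0.029, 0.049,  0.038, 0.018, 0.042,
  "f_pui",              0.022, 0.015, 0.045,  0.015, 0.009, 0.024,  0.010, 0.007, 0.018
  )
  m <- matrix(raw, ncol = 10, byrow = TRUE)
  tibble::tibble(
    variable = rep(m[, 1], each = 3),
    group = rep(c("NoS", "MASLD", "MASH"), nrow(m)),
    median = as.numeric(t(m[, c(2, 5, 8)])),
    q1 = as.numeric(t(m[, c(3, 6, 9)])),
    q3 = as.numeric(t(m[, c(4, 7, 10)]))
  )
}

# Near-symmetric variables drawn from a truncated normal; all others are
# strictly positive and right-skewed, hence log-normal.
default_families <- function(variables) {
  normal <- c("age", "bmi", "hba1c", "quicki", "f_si")
  setNames(ifelse(variables %in% normal, "normal", "lognormal"), variables)
}

# Alternating-projection (Higham-style) map of a symmetric matrix to the
# nearest correlation matrix: clip eigenvalues, restore the unit diagonal,
# iterate. Deterministic.
nearest_correlation <- function(R, eps = 1e-8, max_iter = 200) {
  for (i in seq_len(max_iter)) {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) >= -eps) break
    R <- ev$vectors %*% diag(pmax(ev$values, eps)) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    diag(R) <- 1
  }
  (R + t(R)) / 2
}

# Default rank-correlation (Spearman) structure: fat fraction moves with the
# metabolic/anthropometric block and against the unsaturation indices. The
# pairwise targets below are jointly infeasible as written (fat fraction
# cannot carry all of them at once), so the assembled matrix is projected to
# the nearest valid correlation matrix before use.
default_dependence <- function(variables) {
  p <- length(variables)
  R <- diag(p)
  dimnames(R) <- list(variables, variables)
  set_rho <- function(R, a, b, rho) {
    a <- intersect(a, variables); b <- intersect(b, variables)
    for (x in a) for (y in b) if (x != y) R[x, y] <- R[y, x] <- rho
    R
  }
  metabolic <- c("insulinemia", "c_peptide", "homa_ir", "glycemia", "hba1c",
                 "bmi", "waist", "elastography")
  R <- set_rho(R, metabolic, metabolic, 0.3)
  R <- set_rho(R, "ff", c("insulinemia", "c_peptide", "elastography",
                          "waist", "bmi"), 0.5)
  R <- set_rho(R, "ff", c("f_ui", "f_pui"), -0.6)
  R <- set_rho(R, "f_ui", "f_pui", 0.6)
  R <- nearest_correlation(R)
  dimnames(R) <- list(variables, variables)
  R
}

#' Configuration of the synthetic transplant cohort
#'
#' Assembles group sizes, per-group marginal summaries (median and quartiles),
#' marginal family flags and a rank-correlation (Spearman) dependence matrix
#' into a validated configuration for [simulate_cohort()]. Defaults reproduce
#' the calibrated three-group design: NoS/MASLD/MASH with 90/20/17 subjects and
#' published medians and quartiles for 23 clinical, laboratory and
#' MRS-derived variables.
#'
#' @param n_per_group Named integer vector of subject counts
#'   (`NoS`, `MASLD`, `MASH`).
#' @param summaries Tibble with columns `variable`, `group`, `median`, `q1`,
#'   `q3`. Extra variables (e.g. triglycerides, for which no published
#'   summaries exist) can be appended by the caller.
#' @param family Named character vector mapping each variable to `"lognormal"`
#'   (skewed, strictly positive) or `"normal"` (near-symmetric, truncated at
#'   zero). Defaults are filled in for unnamed variables.
#' @param dependence Symmetric positive semi-definite rank-correlation matrix
#'   with unit diagonal, rows/columns named by variable. Defaults couple fat
#'   fraction positively to the metabolic block and negatively to the
#'   unsaturation indices.
#' @return A list of class `mashdx_config`.
#' @examples
#' cfg <- cohort_config()
#' cfg$groups
#' @export
cohort_config <- function(n_per_group = c(NoS = 90, MASLD = 20, MASH = 17),
                          summaries = default_summaries(),
                          family = NULL,
                          dependence = NULL) {
  stopifnot(all(c("NoS", "MASLD", "MASH") %in% names(n_per_group)),
            all(n_per_group > 0))
  variables <- unique(summaries$variable)
  fam <- default_families(variables)
  if (!is.null(family)) fam[names(family)] <- family
  if (!all(fam %in% c("lognormal", "normal"))) {
    stop("family entries must be 'lognormal' or 'normal'", call. = FALSE)
  }
  if (is.null(dependence)) dependence <- default_dependence(variables)

  bad <- summaries$q1 > summaries$median | summaries$median > summaries$q3
  if (any(bad)) {
    off <- summaries[bad, c("variable", "group")]
    stop("quartile order violated (need q1 <= median <= q3) for: ",
         paste(off$variable, off$group, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  if (!isTRUE(all.equal(dependence, t(dependence))) ||
      !isTRUE(all.equal(unname(diag(dependence)), rep(1, nrow(dependence))))) {
    stop("dependence matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (!setequal(rownames(dependence), variables)) {
    stop("dependence matrix rows must be named by the config variables",
         call. = FALSE)
  }
  ev <- eigen(dependence, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("dependence matrix is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  structure(
    list(
      groups = tibble::tibble(group = names(n_per_group),
                              n = as.integer(n_per_group)),
      summaries = summaries,
      family = fam,
      dependence = dependence[variables, variables, drop = FALSE],
      variables = variables
    ),
    class = "mashdx_config"
  )
}

# Solve marginal parameters from median and quartiles. For the log-normal,
# mu = ln(median) and sigma averages the two log half-widths; for the normal,
# the analogue on the identity scale, truncated below at zero when sampling.
solve_marginal <- function(median, q1, q3, family) {
  z <- qnorm(0.75)
  if (family == "lognormal") {
    list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * z))
  } else {
    list(mu = median, sigma = (q3 - q1) / (2 * z))
  }
}

# Quantile transform of a copula uniform through the configured marginal.
marginal_quantile <- function(u, par, family) {
  if (family == "lognormal") {
    exp(par$mu + par$sigma * qnorm(u))
  } else {
    # truncated-at-zero normal quantile
    p0 <- pnorm(0, par$mu, par$sigma)
    qnorm(p0 + u * (1 - p0), par$mu, par$sigma)
  }
}

#' Simulate a synthetic transplant cohort
#'
#' Draws one record per subject with the configured group sizes. Each group's
#' variables are sampled from a Gaussian copula with the configured Spearman
#' rank-correlation matrix (converted to the latent Pearson scale via
#' \eqn{r = 2\sin(\pi\rho_S/6)}), with marginals solved from that group's
#' median and quartiles. Fully reproducible from `seed`.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `group` (factor NoS/MASLD/MASH), `mash`
#'   (logical outcome) and one column per configured variable.
#' @examples
#' cohort <- simulate_cohort(cohort_config(), seed = 1)
#' dplyr::count(cohort, group)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "mashdx_config"))
  set.seed(seed)
  vars <- config$variables
  # Spearman -> Pearson on the latent Gaussian scale
  R <- 2 * sin(pi * config$dependence / 6)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))

  pieces <- purrr::pmap(config$groups, function(group, n) {
    z <- matrix(rnorm(n * length(vars)), n) %*% t(L)
    u <- pnorm(z)
    cols <- purrr::imap(setNames(vars, vars), function(v, nm) {
      s <- config$summaries[config$summaries$variable == v &
                              config$summaries$group == group, ]
      if (nrow(s) != 1) {
        stop("no summary for variable '", v, "' in group '", group, "'",
             call. = FALSE)
      }
      par <- solve_marginal(s$median, s$q1, s$q3, config$family[[v]])
      marginal_quantile(u[, match(v, vars)], par, config$family[[v]])
    })
    tibble::tibble(group = group, !!!cols)
  })
  out <- dplyr::bind_rows(pieces)
  out$group <- factor(out$group, levels = c("NoS", "MASLD", "MASH"))
  out |>
    dplyr::mutate(id = sprintf("S%03d", dplyr::row_number()), .before = 1) |>
    dplyr::mutate(mash = .data$group == "MASH", .after = "group")
}

# ---- Spectrum simulation -----------------------------------------------------

# Split of the saturated amplitude pool over the four saturated resonances
# (methylene dominates in liver triglyceride).
saturated_weights <- function() {
  c(Lip09 = 0.12, Lip13 = 0.72, Lip16 = 0.09, Lip24 = 0.07)
}

# Solve TE=0 (T2-corrected scale) basis amplitudes that quantify back to the
# requested fat fraction and hydrogen fractions. Water is fixed at 100 a.u.
solve_amplitudes <- function(ff, f_si, f_ui, f_pui, ester_fraction = 0.02) {
  stopifnot(ff >= 0, ff < 100)
  if (any(c(f_si, f_ui, f_pui) < 0) || any(c(f_si, f_ui, f_pui) > 1) ||
      f_pui > f_ui + 1e-12) {
    stop("hydrogen fractions must lie in [0,1] with f_pui <= f_ui",
         call. = FALSE)
  }
  lip53 <- 1 - f_si - 2 * (f_ui - f_pui) - f_pui
  if (lip53 < -1e-12) {
    stop("infeasible hydrogen fractions: f_si + 2*f_ui - f_pui exceeds 1, ",
         "no non-negative amplitude solution exists", call. = FALSE)
  }
  water <- 100
  D <- water * ff / (100 - ff)
  amps <- c(saturated_weights() * f_si * D,
            Lip21 = 2 * (f_ui - f_pui) * D,
            Lip28 = f_pui * D,
            Lip53 = max(lip53, 0) * D,
            Lip42 = ester_fraction / 2 * D,
            Lip44 = ester_fraction / 2 * D,
            Water = water)
  amps
}

new_spectrum <- function(ppm, intensity, te, tr = 4500, field = 3,
                         truth = NULL) {
  stopifnot(length(ppm) == length(intensity), !is.unsorted(ppm, strictly = TRUE),
            te >= 0)
  structure(list(ppm = ppm, intensity = intensity, te = te, tr = tr,
                 field = field, truth = truth),
            class = "mashdx_spectrum")
}

#' @export
print.mashdx_spectrum <- function(x, ...) {
  cat("<mashdx_spectrum> ", length(x$ppm), " points, ",
      signif(min(x$ppm), 3), "-", signif(max(x$ppm), 3), " ppm, TE = ",
      x$te, " ms, TR = ", x$tr, " ms\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mashdx_spectrum <- function(x, ...) {
  data.frame(ppm = x$ppm, intensity = x$intensity)
}

#' Simulate a localized liver 1H-MR spectrum
#'
#' Builds a sum of area-normalised Lorentzian lines at the basis positions,
#' with lipid amplitudes solved so that noiseless quantification returns the
#' requested fat fraction and hydrogen fractions, attenuates every line by
#' \eqn{\exp(-TE/T_2)} with its signal-specific T2, and adds white Gaussian
#' noise on the real spectrum scaled so that the ratio of the water peak's
#' amplitude (its integrated intensity at the spectrum's TE, the quantity the
#' fit estimates) to the per-point noise SD equals `snr`.
#'
#' @param ff Target fat fraction in percent (0 <= ff < 100), defined on the
#'   T2-corrected scale.
#' @param fractions Named numeric vector `c(f_si=, f_ui=, f_pui=)` of target
#'   hydrogen fractions; must admit a non-negative amplitude solution
#'   (`f_si + 2*f_ui - f_pui <= 1`, `f_pui <= f_ui`).
#' @param te Echo time (ms). @param tr Repetition time (ms).
#' @param snr Water-amplitude-to-noise ratio; `Inf` for a noiseless spectrum.
#' @param seed Integer seed (ignored when `snr = Inf`).
#' @param basis Basis tibble, see [default_basis()].
#' @param n_points,ppm_range Sampling grid (defaults: 2048 points on 0-6 ppm).
#' @return A `mashdx_spectrum` (fields `ppm`, `intensity`, `te`, `tr`); the
#'   noiseless TE=0 amplitudes used are retained in `$truth`.
#' @examples
#' sp <- simulate_spectrum(ff = 15, snr = 200, seed = 1)
#' quantify_spectrum(sp)$ff
#' @export
simulate_spectrum <- function(ff,
                              fractions = c(f_si = 0.85, f_ui = 0.05,
                                            f_pui = 0.02),
                              te = 30, tr = 4500, snr = 200, seed = 1,
                              basis = default_basis(),
                              n_points = 2048, ppm_range = c(0, 6)) {
  validate_basis(basis)
  stopifnot(te >= 0, snr > 0)
  a0 <- solve_amplitudes(ff, fractions[["f_si"]], fractions[["f_ui"]],
                         fractions[["f_pui"]])
  a0 <- a0[basis$name]
  a_te <- a0 * exp(-te / basis$t2)
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  clean <- rowSums(vapply(seq_len(nrow(basis)), function(i) {
    a_te[i] * lorentzian(ppm, basis$center[i], basis$width[i])
  }, numeric(n_points)))
  if (is.finite(snr)) {
    set.seed(seed)
    clean <- clean + rnorm(n_points, sd = a_te[["Water"]] / snr)
  }
  new_spectrum(ppm, clean, te = te, tr = tr,
               truth = list(amplitudes0 = a0, ff = ff, fractions = fractions))
}

#' Simulate a multi-echo TE series
#'
#' Six spectra at the acquisition echo times 30, 50, 68, 135, 180 and 270 ms,
#' sharing one set of underlying TE=0 amplitudes and differing only in T2
#' decay and noise realization. Used to exercise mono-exponential T2
#' estimation.
#'
#' @inheritParams simulate_spectrum
#' @param te Echo times (ms) of the series.
#' @return A list of `mashdx_spectrum` objects, named by TE.
#' @examples
#' series <- simulate_te_series(ff = 10, snr = Inf)
#' length(series)
#' @export
simulate_te_series <- function(ff,
                               fractions = c(f_si = 0.85, f_ui = 0.05,
                                             f_pui = 0.02),
                               snr = 200, seed = 1,
                               te = c(30, 50, 68, 135, 180, 270), ...) {
  seeds <- seed * 1000L + seq_along(te)
  out <- purrr::map2(te, seeds, function(t, s) {
    simulate_spectrum(ff, fractions, te = t, snr = snr, seed = s, ...)
  })
  setNames(out, paste0("TE", te))
}
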
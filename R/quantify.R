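#' Fixed transverse-relaxation model
#'
#' Literature T2 values used for extrapolating fitted amplitudes to TE = 0
#' when the mono-exponential fit on a measured TE series is too unstable:
#' 27 ms for water and 60 ms for the lipid chain signals.
#'
#' @param t2_water,t2_lipids T2 values in ms (both > 0).
#' @return A named list with elements `t2_water`, `t2_lipids`.
#' @export
t2_model <- function(t2_water = 27, t2_lipids = 60) {
  stopifnot(t2_water > 0, t2_lipids > 0)
  list(t2_water = t2_water, t2_lipids = t2_lipids)
}

#' Linear-combination fit of a spectrum against a basis set
#'
#' Solves `intensity ~ sum_s amplitude_s * lineshape_s(ppm) + baseline` by
#' non-negative least squares; the constant baseline term enters the
#' non-negative solve alongside the amplitudes (a signed baseline is nearly
#' collinear with the summed Lorentzian tails and would inflate the amplitude
#' variance). The ester signals Lip42/Lip44 are fitted but flagged for
#' exclusion from downstream fat-fraction and hydrogen-fraction arithmetic.
#'
#' @param spectrum A `mashdx_spectrum` (or list with `ppm`, `intensity`).
#' @param basis Basis tibble, see [default_basis()].
#' @return A tibble with one row per basis signal: `name`, `amplitude`
#'   (integrated intensity, >= 0), `analysis` flag; attributes `baseline` and
#'   `residual_norm`.
#' @examples
#' sp <- simulate_spectrum(ff = 10, snr = Inf)
#' fit_spectrum(sp)
#' @export
fit_spectrum <- function(spectrum, basis = default_basis()) {
  validate_basis(basis)
  ppm <- spectrum$ppm
  stopifnot(length(ppm) == length(spectrum$intensity))
  A <- vapply(seq_len(nrow(basis)), function(i) {
    lorentzian(ppm, basis$center[i], basis$width[i])
  }, numeric(length(ppm)))
  A <- cbind(A, 1)  # non-negative constant baseline column
  if (qr(A)$rank < ncol(A)) {
    stop("fit matrix is rank-deficient: basis lineshapes are not ",
         "distinguishable on this ppm grid", call. = FALSE)
  }
  sol <- pracma::lsqnonneg(A, spectrum$intensity)
  amps <- sol$x[seq_len(nrow(basis))]
  baseline <- sol$x[nrow(basis) + 1]
  out <- tibble::tibble(name = basis$name, amplitude = amps,
                        analysis = basis$analysis)
  attr(out, "baseline") <- baseline
  attr(out, "residual_norm") <- sqrt(sum(sol$resid.norm))
  out
}

#' Mono-exponential T2 estimate from a TE series
#'
#' Fits \eqn{I(TE) = A \exp(-TE/T_2)} by least squares on the log scale
#' (`ln I` against TE). Non-positive amplitudes are dropped with a warning;
#' fewer than two usable points is an error. A non-negative slope (no decay)
#' yields `t2 = Inf`, flagged non-physical. The relative standard error lets
#' callers fall back to the fixed [t2_model()] when the fit is unstable.
#'
#' @param te Echo times (ms). @param amplitude Fitted amplitudes at each TE.
#' @return A tibble row: `t2` (ms), `se` (ms), `rel_se`, `a0` (amplitude at
#'   TE = 0), `n_used`, `physical` (logical).
#' @examples
#' estimate_t2(c(30, 90), c(60.653, 22.313))  # A = 100, T2 = 60
#' @export
estimate_t2 <- function(te, amplitude) {
  stopifnot(length(te) == length(amplitude))
  keep <- amplitude > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive amplitude(s) dropped from T2 fit")
  }
  te <- te[keep]; amplitude <- amplitude[keep]
  if (length(unique(te)) < 2) {
    stop("T2 estimation needs at least two distinct TEs with positive ",
         "amplitudes", call. = FALSE)
  }
  fit <- stats::lm(log(amplitude) ~ te)
  slope <- stats::coef(fit)[["te"]]
  se_slope <- if (length(te) > 2) {
    suppressWarnings(summary(fit)$coefficients["te", "Std. Error"])
  } else NA_real_
  if (slope >= -1e-12) {  # no measurable decay
    return(tibble::tibble(t2 = Inf, se = NA_real_, rel_se = NA_real_,
                          a0 = exp(stats::coef(fit)[[1]]),
                          n_used = length(te), physical = FALSE))
  }
  t2 <- -1 / slope
  se <- if (is.na(se_slope)) NA_real_ else se_slope / slope^2  # delta method
  tibble::tibble(t2 = t2, se = se, rel_se = se / t2,
                 a0 = exp(stats::coef(fit)[[1]]),
                 n_used = length(te), physical = TRUE)
}

#' T2 correction of a fitted amplitude
#'
#' Extrapolates a measured amplitude to TE = 0 by multiplying with
#' \eqn{\exp(+TE/T_2)}. The correction factor is >= 1 for TE >= 0 and the
#' operation is multiplicative and order-preserving.
#'
#' @param amplitude Amplitude (a.u., >= 0). @param te Echo time (ms, >= 0).
#' @param t2 Transverse relaxation time (ms, > 0).
#' @return Corrected amplitude.
#' @examples
#' t2_correct(100, te = 30, t2 = 60)  # 100 * exp(0.5)
#' @export
t2_correct <- function(amplitude, te, t2) {
  stopifnot(all(amplitude >= 0), all(te >= 0), all(t2 > 0))
  amplitude * exp(te / t2)
}

#' Fat fraction from T2-corrected intensities
#'
#' \deqn{FF\% = 100 \, I_F^{cor} / (I_F^{cor} + I_W^{cor})} where the lipid
#' total includes the vinylic 5.3 ppm signal and excludes the ester signals at
#' 4.2/4.4 ppm. Reported on the 0-100 percent scale.
#'
#' @param lipid Total corrected lipid intensity (a.u., >= 0).
#' @param water Corrected water intensity (a.u., >= 0).
#' @return Fat fraction in percent.
#' @examples
#' compute_ff(10, 90)  # 10
#' @export
compute_ff <- function(lipid, water) {
  stopifnot(all(lipid >= 0), all(water >= 0))
  if (any(lipid + water == 0)) {
    stop("fat fraction undefined: lipid and water intensities both zero",
         call. = FALSE)
  }
  100 * lipid / (lipid + water)
}

#' Hydrogen fractions in saturated, unsaturated and polyunsaturated bonds
#'
#' With denominator `D = Lip09 + Lip13 + Lip16 + Lip21 + Lip24 + Lip28 +
#' Lip53`:
#' \deqn{f_{SI} = (Lip09 + Lip13 + Lip16 + Lip24)/D}
#' \deqn{f_{UI} = (Lip21/2 + Lip28)/D}
#' \deqn{f_{PUI} = Lip28/D}
#' The closure identity `f_si + (Lip21 + Lip28 + Lip53)/D = 1` holds exactly.
#'
#' @param amplitudes Named numeric vector of lipid amplitudes (a.u., >= 0);
#'   must contain the seven analysis lipid names.
#' @return A tibble row with `f_si`, `f_ui`, `f_pui`.
#' @examples
#' compute_fractions(c(Lip09 = 0.1, Lip13 = 0.6, Lip16 = 0.1, Lip21 = 0.08,
#'                     Lip24 = 0.05, Lip28 = 0.04, Lip53 = 0.03))
#' @export
compute_fractions <- function(amplitudes) {
  need <- analysis_lipids()
  if (!all(need %in% names(amplitudes))) {
    stop("amplitudes must be named and include: ",
         paste(setdiff(need, names(amplitudes)), collapse = ", "),
         call. = FALSE)
  }
  a <- amplitudes[need]
  stopifnot(all(a >= 0))
  D <- sum(a)
  if (D == 0) stop("hydrogen fractions undefined: all lipid amplitudes zero",
                   call. = FALSE)
  tibble::tibble(
    f_si = (a[["Lip09"]] + a[["Lip13"]] + a[["Lip16"]] + a[["Lip24"]]) / D,
    f_ui = (a[["Lip21"]] / 2 + a[["Lip28"]]) / D,
    f_pui = a[["Lip28"]] / D
  )
}

#' Quantify one spectrum into a lipid profile
#'
#' Runs the linear-combination fit, applies T2 correction at the spectrum's
#' TE (fixed water/lipid T2 from `t2`), and derives the fat fraction, the
#' hydrogen fractions, and relative lipid intensities (each analysis lipid
#' over the seven-signal denominator).
#'
#' @param spectrum A `mashdx_spectrum`.
#' @param basis Basis tibble. @param t2 A [t2_model()].
#' @return A one-row tibble: `ff`, `f_si`, `f_ui`, `f_pui`, `water`,
#'   `lipid_total`, `residual_norm`, plus `rel_<Lip>` relative intensities;
#'   fitted raw and corrected amplitudes are attached as the `amplitudes`
#'   attribute (tibble with `name`, `amplitude`, `corrected`, `analysis`).
#' @examples
#' quantify_spectrum(simulate_spectrum(ff = 15, snr = Inf))
#' @export
quantify_spectrum <- function(spectrum, basis = default_basis(),
                              t2 = t2_model()) {
  fit <- fit_spectrum(spectrum, basis)
  t2_by_signal <- ifelse(fit$name == "Water", t2$t2_water, t2$t2_lipids)
  fit$corrected <- t2_correct(fit$amplitude, spectrum$te, t2_by_signal)
  corr <- setNames(fit$corrected, fit$name)
  lipid_total <- sum(corr[analysis_lipids()])
  water <- corr[["Water"]]
  fr <- compute_fractions(corr)
  rel <- corr[analysis_lipids()] / lipid_total
  out <- tibble::tibble(
    ff = compute_ff(lipid_total, water),
    f_si = fr$f_si, f_ui = fr$f_ui, f_pui = fr$f_pui,
    water = water, lipid_total = lipid_total,
    residual_norm = attr(fit, "residual_norm")
  )
  out[paste0("rel_", names(rel))] <- as.list(rel)
  attr(out, "amplitudes") <- fit
  out
}

#' Quantify a TE series with data-driven T2 estimation
#'
#' Fits every spectrum in the series, estimates water and lipid T2 from the
#' amplitude decay across TEs by [estimate_t2()], and falls back to the fixed
#' [t2_model()] whenever the estimate's relative standard error exceeds
#' `max_rel_se` (or is non-physical). The shortest-TE spectrum is then
#' quantified with the selected T2 values.
#'
#' @param series List of `mashdx_spectrum` at distinct TEs.
#' @param basis Basis tibble. @param fallback Fixed [t2_model()].
#' @param max_rel_se Relative-standard-error threshold for accepting the
#'   estimated T2 (default 0.3).
#' @return As [quantify_spectrum()], with extra columns `t2_water`,
#'   `t2_lipids`, `t2_source` ("estimated" or "fixed").
#' @export
quantify_te_series <- function(series, basis = default_basis(),
                               fallback = t2_model(), max_rel_se = 0.3) {
  stopifnot(length(series) >= 2)
  tes <- vapply(series, function(s) s$te, numeric(1))
  fits <- purrr::map(series, fit_spectrum, basis = basis)
  amp_of <- function(name) {
    vapply(fits, function(f) f$amplitude[f$name == name], numeric(1))
  }
  water_fit <- estimate_t2(tes, amp_of("Water"))
  lipid_amp <- rowSums(vapply(analysis_lipids(), amp_of,
                              numeric(length(series))))
  lipid_fit <- estimate_t2(tes, lipid_amp)
  pick <- function(est, fixed) {
    ok <- est$physical && !is.na(est$rel_se) && est$rel_se <= max_rel_se
    list(t2 = if (ok) est$t2 else fixed, source = if (ok) "estimated" else "fixed")
  }
  w <- pick(water_fit, fallback$t2_water)
  l <- pick(lipid_fit, fallback$t2_lipids)
  prof <- quantify_spectrum(series[[which.min(tes)]], basis,
                            t2_model(w$t2, l$t2))
  dplyr::mutate(prof, t2_water = w$t2, t2_lipids = l$t2,
                t2_source = paste(w$source, l$source, sep = "/"))
}
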
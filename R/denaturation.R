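# Per-residue two-state urea unfolding of native-peak intensities and
# aggregation into a global midpoint; chemical-shift perturbation helper.

#' Two-state urea unfolding fit for one residue
#'
#' In slow conformational exchange the native cross peak reports the native
#' population directly, so the normalized intensity follows the two-state
#' Boltzmann curve
#' \deqn{f_N(c) = \frac{1}{1 + e^{-(\Delta G_{H_2O} - m c)/RT}}}
#' with the linear extrapolation model `dG(c) = dG_H2O - m c` and midpoint
#' `C_1/2 = dG_H2O / m`.  Intensities are normalized per residue to the
#' 0 M point (an overall positive scale therefore cancels); no sloping
#' baselines are fitted.
#'
#' @param series a [peak_series()] with `axis_name == "urea_M"` and at
#'   least 6 concentrations bracketing the transition.
#' @param temperature_K temperature for RT.
#' @return list of class `"two_state_fit"`: `dG_H2O`, `m_value`, `C_half`
#'   (kcal/mol, kcal/mol/M, M) with standard errors, `converged`,
#'   `residual_sd`, and the normalized data.
#' @export
fit_two_state <- function(series, temperature_K = 300) {
  stopifnot(inherits(series, "peak_series"))
  if (series$axis_name != "urea_M")
    stop("fit_two_state requires axis_name == 'urea_M'")
  conc <- series$axis_values; y <- series$values
  if (length(conc) < 6L) stop("need at least 6 urea concentrations")
  if (conc[1] != 0) stop("series must include the 0 M reference point")
  ynorm <- y / y[1]
  # bracketing check: the data must actually cross the transition
  if (min(ynorm) > 0.6)
    stop("unbracketed transition: intensities never drop below 0.6")
  if (max(ynorm[-1]) < 0.4)
    stop("unbracketed transition: no native baseline beyond 0 M")
  RT <- .RGAS * temperature_K
  # starting values from the logit transform of the interior points
  yc <- pmin(pmax(ynorm, 1e-3), 1 - 1e-3)
  lf <- stats::lm(log(yc / (1 - yc)) ~ conc)
  m0 <- max(-stats::coef(lf)[2] * RT, 0.1)
  dg0 <- max(stats::coef(lf)[1] * RT, 0.1)
  fit <- tryCatch(
    stats::nls(ynorm ~ 1 / (1 + exp(-(dG - m * conc) / RT)),
               start = list(dG = dg0, m = m0),
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(residue = series$residue, dG_H2O = NA_real_,
                          m_value = NA_real_, C_half = NA_real_,
                          dG_err = NA_real_, m_err = NA_real_,
                          C_half_err = NA_real_, converged = FALSE,
                          residual_sd = NA_real_, f_native = ynorm,
                          conc = conc),
                     class = "two_state_fit"))
  cf <- summary(fit)$coefficients
  dG <- cf["dG", 1]; m <- cf["m", 1]
  if (m <= 0)
    return(structure(list(residue = series$residue, dG_H2O = dG, m_value = m,
                          C_half = NA_real_, dG_err = cf["dG", 2],
                          m_err = cf["m", 2], C_half_err = NA_real_,
                          converged = FALSE,
                          residual_sd = summary(fit)$sigma,
                          f_native = ynorm, conc = conc),
                     class = "two_state_fit"))
  C_half <- dG / m
  # first-order error propagation for the ratio (covariance included)
  V <- stats::vcov(fit)
  grad <- c(1 / m, -dG / m^2)
  C_err <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(residue = series$residue, dG_H2O = dG, m_value = m,
                 C_half = C_half, dG_err = cf["dG", 2], m_err = cf["m", 2],
                 C_half_err = C_err, converged = TRUE,
                 residual_sd = summary(fit)$sigma, f_native = ynorm,
                 conc = conc),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<two_state_fit> %s  dG_H2O = %.2f +/- %.2f kcal/mol, m = %.2f, C1/2 = %.2f M\n",
                format(x$residue), x$dG_H2O, x$dG_err, x$m_value, x$C_half))
  else cat(sprintf("<two_state_fit> %s  (not converged)\n", format(x$residue)))
  invisible(x)
}

#' Aggregate per-residue midpoints
#'
#' Unweighted mean and SD of `C_1/2` over converged fits.  When the
#' midpoints disperse by more than 10% of the mean, a heterogeneous-
#' unfolding flag is raised and the outlying residues (beyond 2 SD) are
#' listed -- uniform midpoints across the sequence are the signature of a
#' concerted two-state transition.
#'
#' @param fits list of [fit_two_state()] results.
#' @param dispersion_tol relative SD above which the cohort is flagged.
#' @return list with `mean_C_half`, `sd_C_half`, `n`, `heterogeneous`,
#'   `outliers` and the per-residue `table`.
#' @export
aggregate_midpoints <- function(fits, dispersion_tol = 0.10) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) < 2L) stop("need at least 2 converged fits")
  tab <- data.frame(
    residue_seq = vapply(conv, function(f) f$residue$seq_number, integer(1)),
    residue_code = vapply(conv, function(f) f$residue$residue_code, character(1)),
    C_half = vapply(conv, function(f) f$C_half, numeric(1)),
    C_half_err = vapply(conv, function(f) f$C_half_err, numeric(1)),
    dG_H2O = vapply(conv, function(f) f$dG_H2O, numeric(1)),
    m_value = vapply(conv, function(f) f$m_value, numeric(1)),
    stringsAsFactors = FALSE)
  mu <- mean(tab$C_half); s <- stats::sd(tab$C_half)
  het <- s / mu > dispersion_tol
  outliers <- tab$residue_seq[abs(tab$C_half - mu) > 2 * s]
  list(mean_C_half = mu, sd_C_half = s, n = nrow(tab), heterogeneous = het,
       outliers = outliers, table = tab)
}

#' Chemical-shift perturbation between two conditions
#'
#' Combined amide CSP
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with the community-standard nitrogen weighting `alpha = 0.154`.
#' Residues present in only one list are skipped with a warning.
#'
#' @param shifts_ref,shifts_cmp data.frames with columns `residue_seq`,
#'   `H_ppm`, `N_ppm`.
#' @param alpha 15N scale factor.
#' @param threshold_ppm residues with CSP above this are listed in the
#'   `"perturbed"` attribute.
#' @return data.frame `residue_seq`, `csp_ppm`, with attribute
#'   `"perturbed"`.
#' @export
chemical_shift_perturbation <- function(shifts_ref, shifts_cmp,
                                        alpha = 0.154, threshold_ppm = 0.1) {
  common <- intersect(shifts_ref$residue_seq, shifts_cmp$residue_seq)
  skipped <- union(setdiff(shifts_ref$residue_seq, common),
                   setdiff(shifts_cmp$residue_seq, common))
  if (length(skipped))
    warning("unmatched residues skipped: ", paste(skipped, collapse = ", "))
  a <- shifts_ref[match(common, shifts_ref$residue_seq), ]
  b <- shifts_cmp[match(common, shifts_cmp$residue_seq), ]
  csp <- sqrt((b$H_ppm - a$H_ppm)^2 + (alpha * (b$N_ppm - a$N_ppm))^2)
  out <- data.frame(residue_seq = common, csp_ppm = csp)
  # closed threshold, robust to floating-point cancellation in the deltas
  attr(out, "perturbed") <- common[csp >= threshold_ppm - 1e-9]
  out
}
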
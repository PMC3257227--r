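# Hydrogen/deuterium exchange kinetics: first-order decay fits, intrinsic
# (random-coil) rate prediction, protection factors and opening free
# energies, EX1/EX2 discrimination.

.hx_env <- new.env(parent = emptyenv())

# reference rates for poly-DL-alanine in D2O at 293 K (log10, per minute;
# acid and base terms are per molar of catalyst) and Arrhenius activation
# energies in cal/mol
.HX_REF <- list(logkA = 1.62, logkB = 10.05, logkW = -1.5,
                pKD = 15.05, Ea = c(acid = 14000, base = 17000, water = 19000),
                Rcal = 1.987, Tref = 293)

.load_hx_params <- function() {
  if (!is.null(.hx_env$params)) return(.hx_env$params)
  path <- system.file("extdata", "exchange_reference_params.tsv",
                      package = "ribodyn")
  p <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, na.strings = "NA")
  .hx_env$params <- p
  p
}

# effective side-chain factor on the linear scale, mixing charged/neutral
# variants of titratable side chains by the protonated fraction at pD
.hx_factor <- function(code, column, pD, cys_oxidized = TRUE) {
  p <- .load_hx_params()
  code <- aa_three(code)
  if (code == "CYS" && cys_oxidized) code <- "CYX"
  rows <- p[p$code == code, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no intrinsic-rate parameters for residue code ", code)
  if (nrow(rows) == 1L) return(10^rows[[column]])
  pKa <- rows$pKa[1]
  f_prot <- 1 / (1 + 10^(pD - pKa))
  # for Asp/Glu the protonated species is the neutral one; for His the
  # protonated species is the charged one
  ch <- rows[rows$variant == "charged", column]
  ne <- rows[rows$variant == "neutral", column]
  if (code %in% c("ASP", "GLU"))
    f_prot * 10^ne + (1 - f_prot) * 10^ch
  else
    f_prot * 10^ch + (1 - f_prot) * 10^ne
}

#' Intrinsic (random-coil) amide hydrogen-exchange rate
#'
#' Predicts the unstructured-reference exchange rate `k_rc` of a backbone
#' amide from poly-DL-alanine reference rates with acid-, base- and
#' water-catalysed terms, nearest-neighbour side-chain corrections (the
#' residue's own "L" factor and the preceding residue's "R" factor),
#' Arrhenius temperature correction, and the glass-electrode correction for
#' exchange into D2O (`pD = pH_read + 0.4`).  Titratable side chains
#' (Asp, Glu, His) are mixed between their charged and neutral parameter
#' sets by the protonation fraction at the working pD.
#'
#' @param residue_code three-letter code of the residue whose amide
#'   exchanges (proline has no backbone amide and is rejected).
#' @param left_neighbor_code three-letter code of the preceding residue.
#' @param pH_read glass-electrode pH reading, in (0, 14).
#' @param temperature_K temperature in kelvin.
#' @param medium only `"H2O_to_D2O"` (protonated amide exchanging into
#'   D2O) is implemented.
#' @param cys_oxidized treat cysteines as disulfide-bonded (cystine
#'   parameters)?  Default `TRUE`, appropriate for a four-disulfide
#'   ribonuclease.
#' @return intrinsic rate in 1/hr.
#' @export
intrinsic_rate <- function(residue_code, left_neighbor_code, pH_read,
                           temperature_K = 300, medium = "H2O_to_D2O",
                           cys_oxidized = TRUE) {
  medium <- match.arg(medium, "H2O_to_D2O")
  if (pH_read <= 0 || pH_read >= 14) stop("pH_read must be in (0, 14)")
  residue_code <- aa_three(residue_code)
  left_neighbor_code <- aa_three(left_neighbor_code)
  if (residue_code == "PRO")
    stop("proline has no backbone amide; intrinsic rate undefined")
  if (residue_code == "UNK" || left_neighbor_code == "UNK")
    stop("unknown residue code; cannot look up intrinsic-rate parameters")
  pD <- pH_read + 0.4
  FA <- .hx_factor(residue_code, "acidL", pD, cys_oxidized) *
    .hx_factor(left_neighbor_code, "acidR", pD, cys_oxidized)
  FB <- .hx_factor(residue_code, "baseL", pD, cys_oxidized) *
    .hx_factor(left_neighbor_code, "baseR", pD, cys_oxidized)
  arr <- function(which) {
    exp(-.HX_REF$Ea[[which]] / .HX_REF$Rcal *
          (1 / temperature_K - 1 / .HX_REF$Tref))
  }
  kA <- 10^.HX_REF$logkA * FA * 10^(-pD) * arr("acid")
  kB <- 10^.HX_REF$logkB * FB * 10^(pD - .HX_REF$pKD) * arr("base")
  kW <- 10^.HX_REF$logkW * FB * arr("water")
  unname((kA + kB + kW) * 60)   # per-minute reference -> per hour
}

#' Fit a first-order exchange decay
#'
#' Least-squares fit of `I(t) = I(0) exp(-k_obs t)` to a peak-intensity
#' time series (weighted by the series errors when present).  Reported
#' errors are the least-squares standard errors.  Series whose total decay
#' is below twice the noise level, or whose fitted half-life exceeds five
#' times the last sampled time, are flagged as too slow to quantify and an
#' upper bound on `k_obs` is reported instead; a negative fitted rate flags
#' the residue as non-exchanging rather than raising.
#'
#' @param series a [peak_series()] with `axis_name == "time_hr"` and at
#'   least 4 points.
#' @return list with `k_obs`, `k_obs_err`, `I0`, `I0_err` (1/hr and
#'   intensity units), `status` (one of `"ok"`, `"too_slow"`,
#'   `"non_exchanging"`, `"fit_failed"`), `k_upper_bound` (for too-slow
#'   series) and `residual_sd`.
#' @export
fit_exchange_decay <- function(series) {
  stopifnot(inherits(series, "peak_series"))
  if (series$axis_name != "time_hr")
    stop("fit_exchange_decay requires axis_name == 'time_hr'")
  t <- series$axis_values; y <- series$values
  if (length(t) < 4L) stop("need at least 4 time points")
  w <- if (!is.null(series$errors) && all(series$errors > 0))
    1 / series$errors^2 else rep(1, length(y))
  res <- list(residue = series$residue, k_obs = NA_real_, k_obs_err = NA_real_,
              I0 = NA_real_, I0_err = NA_real_, status = "ok",
              k_upper_bound = NA_real_, residual_sd = NA_real_)
  # noise level: declared errors if present, else scatter about a smooth fit
  noise <- if (!is.null(series$errors)) mean(series$errors)
           else stats::sd(stats::residuals(stats::lm(y ~ stats::poly(t, 2))))
  if (max(y) - y[length(y)] < 2 * noise && diff(range(y)) < 2 * noise) {
    res$status <- "too_slow"
    res$k_upper_bound <- log(2) / (5 * max(t))
    res$I0 <- mean(y)
    return(res)
  }
  # profile likelihood in k (I0 is linear and solved analytically), robust
  # for noiseless series where Gauss-Newton iterations stall on zero
  # residuals; k < 0 is allowed so growing series flag as non-exchanging
  prof_I0 <- function(k) sum(w * y * exp(-k * t)) / sum(w * exp(-2 * k * t))
  sse <- function(k) { b <- prof_I0(k); sum(w * (y - b * exp(-k * t))^2) }
  kk <- c(-10^seq(-6, 0, length.out = 30), 10^seq(-6, 3, length.out = 200))
  kk <- sort(kk)
  ss <- vapply(kk, sse, numeric(1))
  ib <- which.min(ss)
  lo <- kk[max(1L, ib - 1L)]; hi <- kk[min(length(kk), ib + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  k_hat <- opt$minimum
  I0_hat <- prof_I0(k_hat)
  # least-squares standard errors from the analytic Jacobian
  e <- exp(-k_hat * t)
  J <- cbind(I0 = e, k = -I0_hat * t * e)
  JTJ <- crossprod(J * sqrt(w))
  n <- length(y)
  s2 <- opt$objective / max(n - 2L, 1L)
  cov <- tryCatch(s2 * solve(JTJ), error = function(e2) NULL)
  if (is.null(cov)) { res$status <- "fit_failed"; return(res) }
  res$I0 <- I0_hat; res$I0_err <- sqrt(cov[1, 1])
  res$k_obs <- k_hat; res$k_obs_err <- sqrt(cov[2, 2])
  res$residual_sd <- sqrt(s2)
  if (res$k_obs <= 0) {
    res$status <- "non_exchanging"
  } else if (log(2) / res$k_obs > 5 * max(t)) {
    res$status <- "too_slow"
    res$k_upper_bound <- log(2) / (5 * max(t))
  }
  res
}

#' Protection factor and opening free energy
#'
#' Under the EX2 limit the opening equilibrium constant is
#' `k_op = k_obs / k_rc`, the protection factor is `P = k_rc / k_obs`, and
#' the free energy of the opening event is
#' `dG_op = -RT ln(k_op) = RT ln(P)` with `R = 1.987e-3` kcal/(mol K).
#' The error is propagated from the `k_obs` standard error
#' (`sd(dG) = RT sd(k)/k`).  A protection factor below 1 (exchange faster
#' than the unstructured reference) triggers a warning but the value is
#' still returned.
#'
#' @param k_obs observed rate, 1/hr.
#' @param k_rc intrinsic rate, 1/hr (same units as `k_obs`).
#' @param temperature_K temperature for RT.
#' @param k_obs_err optional standard error of `k_obs`.
#' @return list with `P`, `dG_op` (kcal/mol) and `dG_op_err`.
#' @export
protection_and_energy <- function(k_obs, k_rc, temperature_K = 300,
                                  k_obs_err = NA_real_) {
  stopifnot(k_obs > 0, k_rc > 0)
  P <- k_rc / k_obs
  if (P < 1) warning("protection factor < 1: exchange faster than intrinsic")
  RT <- .RGAS * temperature_K
  dG <- RT * log(P)
  dG_err <- if (is.finite(k_obs_err)) RT * k_obs_err / k_obs else NA_real_
  list(P = P, dG_op = dG, dG_op_err = dG_err)
}

#' Classify the hydrogen-exchange regime from a pH pair
#'
#' In the EX2 (bimolecular) limit the observed rate is proportional to the
#' hydroxide concentration, so raising the pH by `delta_pH` multiplies the
#' rate by `10^delta_pH`; in the EX1 (unimolecular, opening-limited) limit
#' the rate is pH independent.  The observed ratio is compared with both
#' limiting predictions within a multiplicative tolerance band spanning a
#' total factor of `band` (default 3, i.e. within sqrt(3) on either side),
#' which cleanly separates 1 from `10^delta_pH` for `delta_pH ~ 1`.
#'
#' @param k_ex_low_pH,k_ex_high_pH observed rates at the two pH values.
#' @param delta_pH pH difference (> 0).
#' @param band total multiplicative width of the acceptance band.
#' @return `"EX1"`, `"EX2"` or `"undetermined"`.
#' @export
classify_regime <- function(k_ex_low_pH, k_ex_high_pH, delta_pH, band = 3) {
  stopifnot(k_ex_low_pH > 0, k_ex_high_pH > 0, delta_pH > 0, band > 1)
  r <- k_ex_high_pH / k_ex_low_pH
  within <- function(x, target) abs(log(x / target)) <= log(band) / 2
  ex2 <- within(r, 10^delta_pH)
  ex1 <- within(r, 1)
  if (ex2 && !ex1) "EX2" else if (ex1 && !ex2) "EX1" else "undetermined"
}

#' Run the full hydrogen-exchange pipeline
#'
#' Fits every time series, predicts intrinsic rates from the sequence
#' context, and assembles protection factors and opening free energies in a
#' per-residue table mirroring the standard HX summary (residue, k_obs with
#' error, P, dG_op with error, status).
#'
#' @param series_list list of [peak_series()] with `axis_name "time_hr"`.
#' @param sequence protein sequence as a one-letter string (1-based; used
#'   for the left-neighbour context of each residue).
#' @param pH_read glass-electrode pH.
#' @param temperature_K temperature.
#' @return data.frame of class `"exchange_results"`.
#' @export
hx_pipeline <- function(series_list, sequence, pH_read = 5.65,
                        temperature_K = 300) {
  seq1 <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  rows <- lapply(series_list, function(s) {
    f <- fit_exchange_decay(s)
    i <- s$residue$seq_number
    out <- data.frame(residue_seq = i, residue_code = s$residue$residue_code,
                      k_obs = f$k_obs, k_obs_err = f$k_obs_err,
                      k_rc = NA_real_, P = NA_real_,
                      dG_op = NA_real_, dG_op_err = NA_real_,
                      status = f$status, stringsAsFactors = FALSE)
    ok_context <- i >= 2 && i <= length(seq1) &&
      out$residue_code != "PRO" && seq1[i] != "X"
    if (f$status == "ok" && ok_context) {
      krc <- intrinsic_rate(seq1[i], seq1[i - 1], pH_read, temperature_K)
      pe <- protection_and_energy(f$k_obs, krc, temperature_K, f$k_obs_err)
      out$k_rc <- krc; out$P <- pe$P
      out$dG_op <- pe$dG_op; out$dG_op_err <- pe$dG_op_err
    } else if (f$status == "ok") {
      out$status <- "no_sequence_context"
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("exchange_results", "data.frame")
  res
}
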
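# TEMPOL surface-accessibility profiling: autoscaled peak volumes,
# paramagnetic attenuations A_i, hot-spot classification, and correlation
# with hydrogen-bond freedom from MD.

#' Autoscale peak volumes
#'
#' Mean-normalization: `v_i = V_i / mean(V)`, so the autoscaled volumes of
#' each spectrum average exactly 1.  This removes the arbitrary acquisition
#' gain of a spectrum, which is the point of autoscaling: attenuations
#' computed from autoscaled volumes are invariant under independent global
#' rescaling of the diamagnetic and paramagnetic spectra.  A
#' median-normalization variant is provided for profiles with heavy-tailed
#' volume distributions.
#'
#' @param volumes positive numeric vector, length >= 2.
#' @param center `"mean"` (default; output mean is exactly 1) or
#'   `"median"`.
#' @return autoscaled volumes; non-positive entries are excluded with a
#'   warning before scaling and returned as NA.
#' @export
autoscale <- function(volumes, center = c("mean", "median")) {
  center <- match.arg(center)
  bad <- !(volumes > 0) | !is.finite(volumes)
  if (any(bad)) {
    warning(sum(bad), " non-positive volume(s) excluded from autoscaling")
    volumes[bad] <- NA_real_
  }
  if (sum(!bad) < 2L) stop("need at least 2 positive volumes")
  ref <- if (center == "mean") mean(volumes, na.rm = TRUE)
         else stats::median(volumes, na.rm = TRUE)
  volumes / ref
}

#' Paramagnetic attenuation profile
#'
#' `A_i = v_i^d / v_i^p`, the ratio of the autoscaled diamagnetic to
#' autoscaled paramagnetic peak volume.  By construction the profile is
#' centred near 1; `A_i > 1` marks strong attenuation (probe-accessible
#' amides), `A_i < 1` relative protection.  A 10% volume-measurement error
#' is propagated to each attenuation
#' (`A_err = A * sqrt(2) * volume_error`).  Pairs with zero paramagnetic
#' volume are reported as censored-high and excluded from summary means.
#'
#' @param pairs a [volume_pairs()] table (>= 5 usable pairs).
#' @param volume_error fractional error of a single volume measurement.
#' @param center passed to [autoscale()].
#' @return data.frame of class `"attenuation_profile"`: `residue_seq`,
#'   `v_dia`, `v_para`, `A`, `A_err`, `censored`; attribute `n_usable`.
#' @export
attenuation <- function(pairs, volume_error = 0.10,
                        center = c("mean", "median")) {
  stopifnot(inherits(pairs, "volume_pairs"))
  center <- match.arg(center)
  censored <- pairs$V_para == 0
  if (sum(!censored) < 5L) stop("need at least 5 usable volume pairs")
  v_d <- autoscale(pairs$V_dia, center)
  v_p <- rep(NA_real_, nrow(pairs))
  v_p[!censored] <- autoscale(pairs$V_para[!censored], center)
  A <- v_d / v_p
  A[censored] <- Inf
  out <- data.frame(residue_seq = pairs$residue_seq,
                    residue_code = pairs$residue_code,
                    v_dia = v_d, v_para = v_p, A = A,
                    A_err = ifelse(censored, NA_real_,
                                   A * sqrt(2) * volume_error),
                    censored = censored, stringsAsFactors = FALSE)
  attr(out, "n_usable") <- sum(!censored)
  class(out) <- c("attenuation_profile", "data.frame")
  out
}

#' Classify surface hot spots from an attenuation profile
#'
#' Residues with `A_i` above the threshold (default 1.7, the bound that
#' selects the most strongly attenuated amides), sorted by decreasing
#' attenuation.  Censored (infinite) attenuations are included and sort
#' first.
#'
#' @param profile an [attenuation()] result.
#' @param threshold attenuation cutoff.
#' @return data.frame `residue_seq`, `residue_code`, `A`, descending.
#' @export
classify_hotspots <- function(profile, threshold = 1.7) {
  stopifnot(inherits(profile, "attenuation_profile"))
  hot <- profile[profile$A > threshold, c("residue_seq", "residue_code", "A")]
  hot[order(-hot$A), , drop = FALSE]
}

#' Correlate attenuations with hydrogen-bond freedom
#'
#' Ordinary least squares of `A_i` on the fractional freedom from
#' intramolecular hydrogen bonding (1 - lifetime/100, from
#' [hbond_lifetimes()]), with the Pearson correlation coefficient --
#' the standard diagnostic for whether probe accessibility tracks the
#' availability of backbone amides for intermolecular hydrogen bonding.
#'
#' @param profile an [attenuation()] result.
#' @param hb_freedom data.frame `residue_seq`, `freedom` (fractions in
#'   `[0, 1]`).
#' @return list with `slope`, `intercept`, `r`, `n`.
#' @export
correlate_with_hbond_freedom <- function(profile, hb_freedom) {
  stopifnot(inherits(profile, "attenuation_profile"))
  common <- intersect(profile$residue_seq[is.finite(profile$A)],
                      hb_freedom$residue_seq)
  if (length(common) < 5L) stop("need at least 5 residues common to both inputs")
  A <- profile$A[match(common, profile$residue_seq)]
  x <- hb_freedom$freedom[match(common, hb_freedom$residue_seq)]
  if (stats::sd(x) == 0) stop("undefined fit: zero-variance predictor")
  fit <- stats::lm(A ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, A), n = length(common))
}
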
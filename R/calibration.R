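## Calibration of the six surrogate measures against the reference ASAT
## volume: univariable ordinary least squares V_ASAT = S * m_s + b_s per
## surrogate and group (female, male, pooled), followed by agreement
## statistics between the estimated and the fully measured volume. The
## primary agreement metric is s_d%, the sample standard deviation of the
## percent differences (V_est - V_ref) / V_ref * 100; Bland-Altman limits
## are computed on the absolute differences at mean +/- 1.96 SD.

.SURROGATES <- c(awf_asis = "awf_asis_mm", hgf_asis = "hgf_asis_mm",
                 a_p_fh = "a_p_fh_cm2", a_p_asis = "a_p_asis_cm2",
                 v_p_fh = "v_p_fh_L", v_p_asis = "v_p_asis_L")

#' Fit the linear conversion equation of one surrogate
#'
#' Ordinary least squares of the reference volume on the surrogate:
#' `V = S * mS + bS`. Slope units are L/mm for length surrogates, L/cm^2
#' for areas and dimensionless for partial volumes.
#'
#' @param s numeric vector of surrogate values.
#' @param v numeric vector of reference volumes, litres.
#' @return A list with elements `mS` (slope) and `bS` (intercept, L).
#' @examples
#' fitConversion(c(1, 2, 3), c(3, 5, 7))  # mS = 2, bS = 1
#' @export
fitConversion <- function(s, v) {
  if (length(s) != length(v))
    validationError("surrogate and reference vectors differ in length")
  if (length(s) < 3L)
    insufficientDataError("need at least 3 subjects to fit, got %d", length(s))
  if (anyNA(s) || anyNA(v))
    validationError("missing values in fit input")
  if (stats::var(s) == 0)
    degeneratePredictorError("surrogate has zero variance; slope undefined")
  fit <- stats::lm(v ~ s)
  co <- stats::coef(fit)
  list(mS = unname(co[2L]), bS = unname(co[1L]))
}

#' Estimate ASAT volume from a surrogate value
#'
#' Applies the conversion equation `V_est = S * mS + bS`. Extreme inputs
#' can give negative estimates; these are returned as-is with a warning.
#'
#' @param s surrogate value(s).
#' @param mS,bS conversion slope and intercept from [fitConversion()].
#' @return Estimated ASAT volume(s) in litres.
#' @export
estimateVolume <- function(s, mS, bS) {
  est <- s * mS + bS
  if (any(est < 0, na.rm = TRUE))
    warning("negative estimated volume(s); reported as-is")
  est
}

#' Agreement statistics between estimated and reference volumes
#'
#' Computes Pearson correlation, R^2 (its square), the mean and sample
#' standard deviation of the percent differences
#' `(est - ref) / ref * 100`, and Bland-Altman limits of agreement on the
#' absolute differences (`mean(d) +/- 1.96 * sd(d)`, litres). Sample
#' (n - 1) standard deviations throughout.
#'
#' @param est estimated volumes, litres.
#' @param ref reference volumes, litres; all must be positive.
#' @return A list with `rP`, `rSquared`, `meanDpct`, `sDpct`, `loaLow`,
#'   `loaHigh`.
#' @export
agreementStats <- function(est, ref) {
  if (length(est) != length(ref))
    validationError("estimate and reference vectors differ in length")
  if (length(est) < 2L)
    insufficientDataError("need at least 2 pairs for agreement statistics")
  if (anyNA(est) || anyNA(ref))
    validationError("missing values in agreement input")
  if (any(ref <= 0))
    invalidReferenceError("reference volumes must all be positive")
  d <- est - ref
  dpct <- d / ref * 100
  rP <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
        else stats::cor(est, ref)
  sdD <- stats::sd(d)
  list(rP = rP,
       rSquared = if (is.na(rP)) NA_real_ else rP^2,
       meanDpct = mean(dpct),
       sDpct = stats::sd(dpct),
       loaLow = mean(d) - 1.96 * sdD,
       loaHigh = mean(d) + 1.96 * sdD)
}

#' Calibrate all surrogates on a cohort panel
#'
#' For each requested group (`female`, `male`, `total`) and each of the
#' six surrogates: fit the conversion equation on the group's subjects
#' with a defined reference volume, estimate within the same group
#' (in-sample, matching the study design) and compute agreement
#' statistics. Rows with a missing reference are excluded and counted; a
#' group with fewer than 3 usable subjects is skipped with a warning.
#'
#' @param panel a surrogate panel data.frame (see [measurePanel()]).
#' @param groups character vector among `"female"`, `"male"`, `"total"`.
#' @return A data.frame with one row per surrogate x group: `surrogate`,
#'   `group`, `n`, `m_s`, `b_s`, `r_p`, `r_squared`, `mean_dpct`,
#'   `s_dpct`, `loa_low`, `loa_high`. 18 rows for the default groups
#'   (12 sex-specific equations plus 6 pooled).
#' @export
calibrateCohort <- function(panel, groups = c("female", "male", "total")) {
  .validatePanel(panel)
  bad <- setdiff(groups, c("female", "male", "total"))
  if (length(bad))
    validationError("unknown group(s): %s", paste(bad, collapse = ", "))
  out <- list()
  for (g in groups) {
    sub <- if (g == "total") panel else panel[panel$sex == g, , drop = FALSE]
    nMissing <- sum(is.na(sub$v_asat_L))
    sub <- sub[!is.na(sub$v_asat_L), , drop = FALSE]
    if (nMissing)
      message(sprintf("group %s: excluded %d subject(s) without reference volume",
                      g, nMissing))
    if (nrow(sub) < 3L) {
      warning(sprintf("group %s skipped: only %d usable subject(s)", g, nrow(sub)))
      next
    }
    v <- sub$v_asat_L
    for (surr in names(.SURROGATES)) {
      s <- sub[[.SURROGATES[[surr]]]]
      fit <- fitConversion(s, v)
      ag <- agreementStats(estimateVolume(s, fit$mS, fit$bS), v)
      out[[length(out) + 1L]] <- data.frame(
        surrogate = surr, group = g, n = nrow(sub),
        m_s = fit$mS, b_s = fit$bS,
        r_p = ag$rP, r_squared = ag$rSquared,
        mean_dpct = ag$meanDpct, s_dpct = ag$sDpct,
        loa_low = ag$loaLow, loa_high = ag$loaHigh,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    insufficientDataError("no group had enough usable subjects to calibrate")
  do.call(rbind, out)
}
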
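#' Derive SNP-by-sex interaction statistics from sex-stratified GWAS
#'
#' Given male- and female-specific per-SNP estimates, the interaction
#' (GWIS-style) estimate is the half-difference
#' `b_gwis = (b_M - b_F) / 2` with standard error
#' `se = sqrt(se_M^2 + se_F^2) / 2`. All arguments vectorize over SNPs.
#'
#' @param beta_m,se_m Stratum-1 (male) effect estimates and standard errors.
#' @param beta_f,se_f Stratum-0 (female) effect estimates and standard errors.
#' @return A list with components `beta` and `se`.
#' @examples
#' gwis_from_stratified(0.340, 0.05, -0.273, 0.05)
#' @export
gwis_from_stratified <- function(beta_m, se_m, beta_f, se_f) {
  check_se(se_m, se_f)
  list(beta = (beta_m - beta_f) / 2,
       se = sqrt(se_m^2 + se_f^2) / 2)
}

#' Inverse-variance-weighted meta-combination of two strata
#'
#' Fixed-effect IVW combination of stratum-specific estimates, the rule used
#' to build a sex-combined GWAS from sex-stratified GWAS.
#'
#' @inheritParams gwis_from_stratified
#' @return A list with `beta`, `se`, and the Wald `p` recomputed from the
#'   combined z-score.
#' @export
meta_combine <- function(beta_m, se_m, beta_f, se_f) {
  check_se(se_m, se_f)
  wm <- 1 / se_m^2
  wf <- 1 / se_f^2
  beta <- (beta_m * wm + beta_f * wf) / (wm + wf)
  se <- sqrt(1 / (wm + wf))
  list(beta = beta, se = se, p = wald_p(beta, se))
}

#' Interaction effect from stratified causal estimates
#'
#' Converts a pair of stratum-specific causal estimates into an interaction
#' estimate on the standardized +1/-1 modifier scale:
#' `beta_I = (beta_M - beta_F) / 2`, `se = sqrt(se_M^2 + se_F^2) / 2`.
#' This is the comparator construction used with sex-stratified MR.
#'
#' @inheritParams gwis_from_stratified
#' @return A list with `beta`, `se`, and Wald `p`.
#' @export
stratified_interaction <- function(beta_m, se_m, beta_f, se_f) {
  check_se(se_m, se_f)
  beta <- (beta_m - beta_f) / 2
  se <- sqrt(se_m^2 + se_f^2) / 2
  list(beta = beta, se = se, p = wald_p(beta, se))
}

#' Stratum-specific causal effects from average and interaction effects
#'
#' With the modifier coded Male = +1, Female = -1, the stratum-specific
#' causal effects are `beta_M = beta_A + beta_I` and
#' `beta_F = beta_A - beta_I`. When applied to a [merlin()] fit, standard
#' errors use the joint posterior covariance of `(beta_A, beta_I)`
#' (`var(A) + var(I) +/- 2 cov`); otherwise supply `se_A`, `se_I` and
#' optionally `cov_AI`.
#'
#' @param object A `merlin_fit`, or the numeric `beta_A`.
#' @param ... Passed to methods.
#' @return A data frame with one row per stratum: `stratum`, `beta`, `se`,
#'   `p`.
#' @examples
#' sex_specific_effects(-0.0512, -0.1379)
#' @export
sex_specific_effects <- function(object, ...) UseMethod("sex_specific_effects")

#' @rdname sex_specific_effects
#' @param beta_I Interaction effect estimate.
#' @param se_A,se_I Standard errors (optional; needed for `se`/`p` output).
#' @param cov_AI Covariance of the two estimates; 0 if omitted.
#' @param coding `c(+1, -1)` puts stratum 1 (male) at +1; flip to reverse.
#' @export
sex_specific_effects.default <- function(object, beta_I, se_A = NA_real_,
                                         se_I = NA_real_, cov_AI = 0,
                                         coding = c(1, -1), ...) {
  beta_A <- object
  stopifnot(length(coding) == 2L, all(abs(coding) == 1))
  bm <- beta_A + coding[1] * beta_I
  bf <- beta_A + coding[2] * beta_I
  vm <- se_A^2 + se_I^2 + 2 * coding[1] * cov_AI
  vf <- se_A^2 + se_I^2 + 2 * coding[2] * cov_AI
  out <- data.frame(
    stratum = c("M", "F"),
    beta = c(bm, bf),
    se = sqrt(c(vm, vf)),
    row.names = NULL
  )
  out$p <- ifelse(is.finite(out$se) & out$se > 0, wald_p(out$beta, out$se),
                  NA_real_)
  out
}

#' @rdname sex_specific_effects
#' @export
sex_specific_effects.merlin_fit <- function(object, coding = c(1, -1), ...) {
  cv <- object$beta_AI_cov
  if (is.null(cv) || anyNA(cv)) {
    warning("fit carries no posterior covariance of (beta_A, beta_I); ",
            "assuming independence")
    cv <- 0
  }
  sex_specific_effects(object$beta_A_mean, object$beta_I_mean,
                       se_A = object$beta_A_sd, se_I = object$beta_I_sd,
                       cov_AI = cv, coding = coding)
}

#' Two-sided Wald P value
#'
#' `2 * pnorm(-|estimate / se|)`.
#'
#' @param mean Estimate (vectorized).
#' @param sd Standard error, > 0.
#' @return P value in (0, 1].
#' @export
wald_p <- function(mean, sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("`sd` must be positive")
  2 * stats::pnorm(-abs(mean / sd))
}

check_se <- function(...) {
  for (se in list(...)) {
    if (any(!is.finite(se)) && !all(is.infinite(se[!is.finite(se)]))) {
      stop("standard errors must be positive numbers")
    }
    if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be > 0")
  }
  invisible(TRUE)
}
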
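#' Inverse-variance-weighted (IVW) MR estimate
#'
#' Fixed-effect IVW: the zero-intercept regression of outcome effects on
#' exposure effects with weights `1 / se_Gamma^2`, equivalently the
#' precision-weighted average of the per-SNP ratio estimates
#' `Gamma_hat / gamma_hat`. Assumes independent instruments and no
#' horizontal pleiotropy.
#'
#' @param gamma_hat,se_gamma Exposure per-SNP effect estimates and SEs.
#' @param Gamma_hat,se_Gamma Outcome per-SNP effect estimates and SEs.
#' @return An object of class `mr_result`: list with `method`, `estimate`,
#'   `se`, `p`, `n_ivs` (and for Egger, `intercept`, `intercept_se`).
#' @examples
#' mr_ivw(0.5, 0.02, 0.15, 0.02)$estimate  # single-SNP ratio: 0.3
#' @export
mr_ivw <- function(gamma_hat, se_gamma, Gamma_hat, se_Gamma) {
  keep <- gamma_hat != 0
  if (!all(keep)) {
    warning(sum(!keep), " instrument(s) with zero exposure effect excluded")
    gamma_hat <- gamma_hat[keep]
    Gamma_hat <- Gamma_hat[keep]
    se_Gamma <- se_Gamma[keep]
  }
  if (length(gamma_hat) < 1L) stop("IVW needs at least one instrument")
  w <- 1 / se_Gamma^2
  est <- sum(w * gamma_hat * Gamma_hat) / sum(w * gamma_hat^2)
  se <- 1 / sqrt(sum(w * gamma_hat^2))
  structure(list(method = "IVW", estimate = est, se = se,
                 p = wald_p(est, se), n_ivs = length(gamma_hat)),
            class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept absorbing average directional pleiotropy; weights
#' `1 / se_Gamma^2`. Inputs are sign-oriented so that all exposure effects
#' are non-negative before fitting (the usual Egger convention). Standard
#' errors use the weighted-regression residual variance (multiplicative
#' random-effects convention).
#'
#' @inheritParams mr_ivw
#' @return An `mr_result` with `intercept` and `intercept_se` filled in.
#' @export
mr_egger <- function(gamma_hat, se_gamma, Gamma_hat, se_Gamma) {
  if (length(gamma_hat) < 3L) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(gamma_hat)
  flip[flip == 0] <- 1
  x <- gamma_hat * flip
  y <- Gamma_hat * flip
  w <- 1 / se_Gamma^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(method = "MR-Egger", estimate = cf["x", 1],
                 se = cf["x", 2], p = wald_p(cf["x", 1], cf["x", 2]),
                 intercept = cf["(Intercept)", 1],
                 intercept_se = cf["(Intercept)", 2],
                 n_ivs = length(x)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (se %.4f, P = %.3g), %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_ivs))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f)\n", x$intercept, x$intercept_se))
  }
  invisible(x)
}

#' Sex-stratified MR and the derived interaction estimate
#'
#' Applies a classical MR estimator separately to the two strata of
#' sex-stratified exposure/outcome summary statistics, selecting instruments
#' within each stratum (exposure GWAS `P < t_gwas`), and derives the
#' interaction estimate from the stratified causal estimates via
#' [stratified_interaction()].
#'
#' @param exp_m,out_m,exp_f,out_f `sumstats` tables (GWAS) for the male and
#'   female strata of the exposure and outcome.
#' @param method `"ivw"` or `"egger"`.
#' @param t_gwas Instrument P-value threshold applied within each stratum.
#' @return A list with `male`, `female` (each an `mr_result`) and
#'   `interaction` (list with `beta`, `se`, `p`).
#' @export
mr_stratified <- function(exp_m, out_m, exp_f, out_f, method = c("ivw", "egger"),
                          t_gwas = 5e-8) {
  method <- match.arg(method)
  fit1 <- function(expo, outc) {
    al <- align_pair(expo, outc)
    sel <- al$p_exp < t_gwas
    if (!any(sel)) stop("no instruments pass P < ", t_gwas, " in a stratum")
    f <- if (method == "ivw") mr_ivw else mr_egger
    f(al$beta_exp[sel], al$se_exp[sel], al$beta_out[sel], al$se_out[sel])
  }
  male <- fit1(exp_m, out_m)
  female <- fit1(exp_f, out_f)
  list(male = male, female = female,
       interaction = stratified_interaction(male$estimate, male$se,
                                            female$estimate, female$se))
}
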
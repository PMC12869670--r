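#' @name merlin_likelihood
#' @title Summary-statistics likelihood of the MERLIN model
#'
#' @description
#' The four observed effect-size vectors are modelled as multivariate
#' normal. With `S_k` the diagonal SE matrices (`S1`/`S2` exposure
#' GWAS/GWIS, `S3`/`S4` outcome GWAS/GWIS) and `R` the LD correlation
#' matrix among instruments, the block means are
#'
#' * exposure GWAS:  `S1 R S1^-1 gamma_G`, covariance `S1 R S1`;
#' * exposure GWIS:  `S2 R S2^-1 gamma_GI`, covariance `S2 R S2`;
#' * outcome GWAS:   `S3 R S3^-1 (Gamma_G + beta_I * gamma_GI)`;
#' * outcome GWIS:   `S4 R S4^-1 (Gamma_GI + mu3 * beta_I * gamma_GI)`;
#'
#' where `Gamma_G = beta_A gamma_G + beta_G` and
#' `Gamma_GI = beta_A gamma_GI + beta_I gamma_G` are the true outcome-scale
#' effects, and `mu3` is the skewness of the standardized modifier (zero
#' for a balanced binary or symmetric continuous modifier). The cross
#' terms arise from the second and third moments of E: since
#' `E[E^2] = 1`, part of the interaction-mediated signal
#' (`beta_I gamma_GI`) leaks into the additive outcome association for any
#' modifier, and for a standardized two-point modifier
#' `E^2 = 1 + mu3 * E`, so with unbalanced strata it also leaks back into
#' the interaction association. Both cross terms project through the same
#' marginal-association operator `S_k R S_k^-1` as the block's main term;
#' this form is verified against large-cohort per-SNP regressions by the
#' moment-structure tests.
#'
#' `params` is a list with elements `beta_A`, `beta_I`, `gamma_G`,
#' `gamma_GI`, `beta_G`.
NULL

# s * (R %*% (x / s)) without forming S R S^-1; identity R short-circuits
sr_sinv <- function(x, s, R) {
  if (is.null(R)) return(x)
  s * as.vector(R %*% (x / s))
}

#' @rdname merlin_likelihood
#' @param gamma True effect vector for the block.
#' @param s Vector of per-SNP standard errors (diagonal of `S_k`).
#' @param R LD correlation matrix, or `NULL` for independent instruments.
#' @return The block mean vector.
#' @export
exposure_block_mean <- function(gamma, s, R = NULL) {
  stopifnot(length(gamma) == length(s), all(s > 0))
  sr_sinv(gamma, s, R)
}

#' @rdname merlin_likelihood
#' @param params Parameter list (see Description).
#' @param s3,s4 Outcome GWAS/GWIS standard-error vectors.
#' @param mod A [modifier_spec()].
#' @export
outcome_gwas_mean <- function(params, s3, s4, R = NULL,
                              mod = modifier_spec("binary")) {
  Gamma_G <- params$beta_A * params$gamma_G + params$beta_G
  sr_sinv(Gamma_G + params$beta_I * params$gamma_GI, s3, R)
}

#' @rdname merlin_likelihood
#' @export
outcome_gwis_mean <- function(params, s3, s4, R = NULL,
                              mod = modifier_spec("binary")) {
  Gamma_GI <- params$beta_A * params$gamma_GI + params$beta_I * params$gamma_G
  sr_sinv(Gamma_GI + mod$mu3 * params$beta_I * params$gamma_GI, s4, R)
}

# multivariate normal log density with covariance S R S, via chol(R)
mvn_block_logdens <- function(obs, mean, s, cholR = NULL) {
  m <- length(obs)
  z <- (obs - mean) / s
  if (is.null(cholR)) {
    quad <- sum(z^2)
    logdet <- 2 * sum(log(s))
  } else {
    w <- backsolve(cholR, z, transpose = TRUE)
    quad <- sum(w^2)
    logdet <- 2 * sum(log(s)) + 2 * sum(log(diag(cholR)))
  }
  -0.5 * (m * log(2 * pi) + logdet + quad)
}

#' @rdname merlin_likelihood
#' @param panel A `harmonized_panel` of observed summary statistics.
#' @param blocks Which blocks to include (subset of 1:4; 1 = exposure GWAS,
#'   2 = exposure GWIS, 3 = outcome GWAS, 4 = outcome GWIS).
#' @return `merlin_loglik()`: the joint Gaussian log likelihood (scalar).
#' @export
merlin_loglik <- function(params, panel, R = NULL,
                          mod = modifier_spec("binary"), blocks = 1:4) {
  stopifnot(all(blocks %in% 1:4))
  cholR <- if (is.null(R)) NULL else chol(R)
  ll <- 0
  if (1 %in% blocks) {
    ll <- ll + mvn_block_logdens(panel$gamma_G,
                                 exposure_block_mean(params$gamma_G, panel$s1, R),
                                 panel$s1, cholR)
  }
  if (2 %in% blocks) {
    ll <- ll + mvn_block_logdens(panel$gamma_GI,
                                 exposure_block_mean(params$gamma_GI, panel$s2, R),
                                 panel$s2, cholR)
  }
  if (3 %in% blocks) {
    ll <- ll + mvn_block_logdens(panel$Gamma_G,
                                 outcome_gwas_mean(params, panel$s3, panel$s4, R, mod),
                                 panel$s3, cholR)
  }
  if (4 %in% blocks) {
    ll <- ll + mvn_block_logdens(panel$Gamma_GI,
                                 outcome_gwis_mean(params, panel$s3, panel$s4, R, mod),
                                 panel$s4, cholR)
  }
  if (!is.finite(ll)) stop("non-finite log likelihood")
  ll
}
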
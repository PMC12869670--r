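#' Fit the MERLIN model: average causal effect and causal interaction
#'
#' Jointly estimates the average causal effect `beta_A` of the exposure on
#' the outcome and the causal interaction `beta_I` (modification of that
#' effect by the standardized environment E) from harmonized four-way
#' summary statistics, by blocked Gibbs sampling of the Bayesian
#' hierarchical model: Gaussian summary-statistics likelihood (see
#' [merlin_loglik()]), normal priors `gamma_G ~ N(0, sigma1^2 I)`,
#' `beta_G ~ N(0, sigma2^2 I)` (horizontal pleiotropy),
#' `gamma_GI ~ N(0, sigma3^2 I)`, inverse-gamma hyperpriors
#' `InvGamma(hyper_a, hyper_b)` on each variance component, and flat priors
#' on `(beta_A, beta_I)`. Every full conditional is conjugate (Gaussian or
#' inverse-gamma), so the sampler needs no tuning.
#'
#' With `R = NULL` (or an identity matrix) instruments are treated as
#' independent and the sampler factorizes over SNPs (fast path); a dense
#' LD matrix uses a matrix-variate sampler suited to panels of modest size.
#'
#' @param panel A `harmonized_panel` (see [harmonize()] or
#'   [simulate_scenario()]).
#' @param R LD correlation matrix among the panel SNPs, or `NULL` for
#'   independent instruments.
#' @param modifier A [modifier_spec()] describing E.
#' @param n_iter,n_burnin Total and discarded iterations per chain.
#' @param n_chains Number of chains (pooled after burn-in).
#' @param seed Optional integer seed; identical seed + config gives
#'   bit-identical chains.
#' @param hyper_a,hyper_b Inverse-gamma hyperparameters (weakly
#'   informative defaults 0.01, 0.01).
#' @param fix_beta_I Fix the interaction at this value instead of sampling
#'   it (e.g. 0 for a no-interaction fit); `NULL` estimates it.
#' @param outcome_gwis Set `FALSE` to fit without the outcome-GWIS block
#'   (see [fit_merlin_no_outcome_gwis()]).
#' @return An object of class `merlin_fit` with posterior summaries
#'   (`beta_A_mean`, `beta_A_sd`, `beta_A_ci95`, `beta_A_p`, likewise for
#'   `beta_I`), the posterior covariance `beta_AI_cov`, variance-component
#'   means `sigma2_means`, split-Rhat diagnostics `rhat`, the retained
#'   `chains`, and bookkeeping fields.
#' @seealso [sex_specific_effects()], [merlin_loglik()], [mr_ivw()]
#' @export
merlin <- function(panel, R = NULL, modifier = modifier_spec("binary"),
                   n_iter = 5000, n_burnin = 2000, n_chains = 2,
                   seed = NULL, hyper_a = 0.01, hyper_b = 0.01,
                   fix_beta_I = NULL, outcome_gwis = TRUE) {
  stopifnot(n_iter > n_burnin, n_burnin >= 0, n_chains >= 1)
  M <- panel_size(panel)
  if (M < 2L) stop("panel must contain at least 2 SNPs")
  if (!is.null(seed)) set.seed(seed)
  use4 <- isTRUE(outcome_gwis) && !is.null(panel$Gamma_GI)
  s4 <- if (!is.null(panel$s4)) panel$s4 else panel$s3
  y4 <- if (use4) panel$Gamma_GI else numeric(M)
  identR <- is.null(R) ||
    (nrow(R) == M && max(abs(R - diag(M))) < 1e-12)
  if (!identR && !all(is.finite(chol(R)))) stop("R is not positive definite")

  # interaction leakage weights from the moments of E: E[E^2] = 1 puts
  # beta_I * gamma_GI into the outcome-GWAS mean; E[E^3] = mu3 puts
  # mu3 * beta_I * gamma_GI into the outcome-GWIS mean
  w3 <- rep(1, M)
  w4 <- rep(modifier$mu3, M)
  fixI <- !is.null(fix_beta_I)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (identR) {
      dr <- .merlin_gibbs_diag_cpp(panel$gamma_G, panel$gamma_GI,
                                   panel$Gamma_G, y4,
                                   panel$s1, panel$s2, panel$s3, s4,
                                   w3, w4, use4, hyper_a, hyper_b,
                                   as.integer(n_iter), as.integer(n_burnin),
                                   fixI, if (fixI) fix_beta_I else 0)
    } else {
      dr <- merlin_gibbs_dense(panel, R, y4, s4, modifier$mu3,
                               use4, hyper_a, hyper_b, n_iter, n_burnin,
                               fixI, if (fixI) fix_beta_I else 0)
    }
    colnames(dr) <- c("beta_A", "beta_I", "sigma2_1", "sigma2_2", "sigma2_3")
    chains[[ch]] <- dr
  }
  fit <- summarize_chains(chains, fixI)
  fit$modifier <- modifier
  fit$n_ivs <- M
  fit$n_iter <- n_iter
  fit$n_burnin <- n_burnin
  fit$experimental <- !use4
  fit$call <- match.call()
  class(fit) <- "merlin_fit"
  if (any(is.finite(fit$rhat) & fit$rhat > 1.1)) {
    fit$convergence_ok <- FALSE
    warning("possible non-convergence: split-Rhat > 1.1 for ",
            paste(names(fit$rhat)[is.finite(fit$rhat) & fit$rhat > 1.1],
                  collapse = ", "))
  } else {
    fit$convergence_ok <- TRUE
  }
  if (!use4 && !fixI && 1.96 * fit$beta_I_sd > 0.5) {
    warning("beta_I is weakly identified without the outcome GWIS ",
            "(posterior sd ", signif(fit$beta_I_sd, 3), ")")
  }
  fit
}

#' Fit MERLIN without the outcome GWIS block
#'
#' Drops the outcome-GWIS likelihood block; the interaction is then
#' identified only through the interaction-mediated leakage term in the
#' outcome-GWAS mean (`beta_I * gamma_GI`), which requires genuine exposure
#' GWIS signal. The returned fit is flagged `experimental` and a warning is
#' raised when `beta_I` is weakly identified.
#'
#' @inheritParams merlin
#' @param ... Passed on to [merlin()].
#' @return A `merlin_fit`.
#' @export
fit_merlin_no_outcome_gwis <- function(panel, ...) {
  merlin(panel, ..., outcome_gwis = FALSE)
}

# Dense-LD blocked Gibbs sampler (pure R). Same model as the C++ fast path
# but with full matrix conditionals; intended for panels of modest size.
merlin_gibbs_dense <- function(panel, R, y4, s4, mu3, use4,
                               a0, b0, n_iter, n_burnin, fixI, betaI_fix) {
  M <- panel_size(panel)
  y1 <- panel$gamma_G; y2 <- panel$gamma_GI; y3 <- panel$Gamma_G
  s1 <- panel$s1; s2 <- panel$s2; s3 <- panel$s3
  Rinv <- chol2inv(chol(R))
  Amat <- function(s) (s %o% (1 / s)) * R          # S R S^-1
  Omega <- function(s) ((1 / s) %o% (1 / s)) * Rinv
  Qmat <- function(s) ((1 / s) %o% (1 / s)) * R    # S^-1 R S^-1
  A1 <- Amat(s1); A2 <- Amat(s2); A3 <- Amat(s3); A4 <- Amat(s4)
  O3 <- Omega(s3); O4 <- Omega(s4)
  Q1 <- Qmat(s1); Q2 <- Qmat(s2); Q3 <- Qmat(s3); Q4 <- Qmat(s4)
  D1 <- 1 / s1^2; D2 <- 1 / s2^2; D3 <- 1 / s3^2; D4 <- 1 / s4^2
  # interaction-leakage operators (same marginal projection as each block)
  W3 <- A3
  W4 <- mu3 * A4
  W3tO3 <- crossprod(W3, O3)
  W3tO3W3 <- W3tO3 %*% W3
  W4tO4 <- crossprod(W4, O4)
  W4tO4W4 <- W4tO4 %*% W4
  D4W4 <- D4 * W4
  IM <- diag(M)

  draw_mvn_prec <- function(P, rhs) {
    U <- chol(P)
    mean <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
    mean + backsolve(U, stats::rnorm(M))
  }

  g <- y1; h <- y2; b <- numeric(M)
  sig1 <- mean(y1^2) + 1e-6; sig3 <- mean(y2^2) + 1e-6; sig2 <- 1e-3
  bA <- 0; bI <- if (fixI) betaI_fix else 0
  keep <- n_iter - n_burnin
  draws <- matrix(NA_real_, keep, 5)

  for (it in seq_len(n_iter)) {
    # g | rest
    P <- Q1 + bA^2 * Q3 + IM / sig1
    rhs <- D1 * y1 + bA * D3 * (y3 - A3 %*% b - bI * W3 %*% h)
    if (use4) {
      P <- P + bI^2 * Q4
      rhs <- rhs + bI * D4 * (y4 - bA * A4 %*% h - bI * W4 %*% h)
    }
    g <- draw_mvn_prec(P, rhs)
    # h | rest
    P <- Q2 + bI^2 * W3tO3W3 + IM / sig3
    rhs <- D2 * y2 + bI * W3tO3 %*% (y3 - A3 %*% (bA * g + b))
    if (use4) {
      P <- P + bA^2 * Q4 + bA * bI * (D4W4 + t(D4W4)) + bI^2 * W4tO4W4
      r4 <- y4 - bI * A4 %*% g
      rhs <- rhs + bA * D4 * r4 + bI * W4tO4 %*% r4
    }
    h <- draw_mvn_prec(P, rhs)
    # b | rest
    P <- Q3 + IM / sig2
    rhs <- D3 * (y3 - bA * A3 %*% g - bI * W3 %*% h)
    b <- draw_mvn_prec(P, rhs)
    # (bA, bI) | rest
    u3 <- A3 %*% g; v3 <- W3 %*% h; e3 <- y3 - A3 %*% b
    T11 <- crossprod(u3, O3 %*% u3); T12 <- crossprod(u3, O3 %*% v3)
    T22 <- crossprod(v3, O3 %*% v3)
    R1 <- crossprod(u3, O3 %*% e3); R2 <- crossprod(v3, O3 %*% e3)
    if (use4) {
      u4 <- A4 %*% h; v4 <- A4 %*% g + W4 %*% h
      T11 <- T11 + crossprod(u4, O4 %*% u4)
      T12 <- T12 + crossprod(u4, O4 %*% v4)
      T22 <- T22 + crossprod(v4, O4 %*% v4)
      R1 <- R1 + crossprod(u4, O4 %*% y4)
      R2 <- R2 + crossprod(v4, O4 %*% y4)
    }
    T11 <- as.numeric(T11); T12 <- as.numeric(T12); T22 <- as.numeric(T22)
    R1 <- as.numeric(R1); R2 <- as.numeric(R2)
    if (fixI) {
      bI <- betaI_fix
      bA <- (R1 - T12 * bI) / T11 + stats::rnorm(1) / sqrt(T11)
    } else {
      Tm <- matrix(c(T11, T12, T12, T22), 2)
      U <- chol(Tm)
      mean <- backsolve(U, backsolve(U, c(R1, R2), transpose = TRUE))
      drw <- mean + backsolve(U, stats::rnorm(2))
      bA <- drw[1]; bI <- drw[2]
    }
    # variance components
    shape <- a0 + M / 2
    sig1 <- max((b0 + sum(g^2) / 2) / stats::rgamma(1, shape), 1e-12)
    sig2 <- max((b0 + sum(b^2) / 2) / stats::rgamma(1, shape), 1e-12)
    sig3 <- max((b0 + sum(h^2) / 2) / stats::rgamma(1, shape), 1e-12)
    if (it > n_burnin) draws[it - n_burnin, ] <- c(bA, bI, sig1, sig2, sig3)
  }
  draws
}

# split-Rhat (each chain halved) for one parameter across chains
split_rhat <- function(chains_param) {
  halves <- unlist(lapply(chains_param, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

summarize_chains <- function(chains, fixI) {
  pooled <- do.call(rbind, chains)
  qs <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  bA <- pooled[, "beta_A"]; bI <- pooled[, "beta_I"]
  out <- list(
    beta_A_mean = mean(bA), beta_A_sd = stats::sd(bA),
    beta_A_ci95 = qs(bA), beta_A_p = wald_p(mean(bA), stats::sd(bA)),
    beta_I_mean = mean(bI),
    beta_I_sd = if (fixI) 0 else stats::sd(bI),
    beta_I_ci95 = qs(bI),
    beta_I_p = if (fixI) NA_real_ else wald_p(mean(bI), stats::sd(bI)),
    beta_AI_cov = if (fixI) 0 else stats::cov(bA, bI),
    sigma2_means = colMeans(pooled[, 3:5, drop = FALSE]),
    rhat = c(beta_A = split_rhat(lapply(chains, function(x) x[, "beta_A"])),
             beta_I = if (fixI) NA_real_ else
               split_rhat(lapply(chains, function(x) x[, "beta_I"]))),
    chains = chains
  )
  out
}

#' @export
print.merlin_fit <- function(x, ...) {
  cat("MERLIN fit (", x$n_ivs, " instruments",
      if (x$experimental) ", no outcome GWIS — experimental" else "",
      ")\n", sep = "")
  est <- rbind(
    c(x$beta_A_mean, x$beta_A_sd, x$beta_A_ci95, x$beta_A_p),
    c(x$beta_I_mean, x$beta_I_sd, x$beta_I_ci95, x$beta_I_p)
  )
  dimnames(est) <- list(c("beta_A (average effect)",
                          "beta_I (interaction)"),
                        c("mean", "sd", "2.5%", "97.5%", "P"))
  print(signif(est, 4))
  invisible(x)
}

#' @export
summary.merlin_fit <- function(object, ...) {
  out <- object
  class(out) <- "summary.merlin_fit"
  out
}

#' @export
print.summary.merlin_fit <- function(x, ...) {
  print.merlin_fit(x)
  cat(sprintf("\nvariance components (posterior means): %s\n",
              paste(signif(x$sigma2_means, 3), collapse = ", ")))
  cat(sprintf("split-Rhat: beta_A %.3f, beta_I %s\n", x$rhat["beta_A"],
              ifelse(is.na(x$rhat["beta_I"]), "-",
                     sprintf("%.3f", x$rhat["beta_I"]))))
  cat(sprintf("chains: %d x %d iterations (%d burn-in)\n",
              length(x$chains), x$n_iter, x$n_burnin))
  invisible(x)
}

#' @export
coef.merlin_fit <- function(object, ...) {
  c(beta_A = object$beta_A_mean, beta_I = object$beta_I_mean)
}

#' @export
vcov.merlin_fit <- function(object, ...) {
  v <- matrix(c(object$beta_A_sd^2, object$beta_AI_cov,
                object$beta_AI_cov, object$beta_I_sd^2), 2,
              dimnames = list(c("beta_A", "beta_I"), c("beta_A", "beta_I")))
  v
}

#' @export
confint.merlin_fit <- function(object, parm = c("beta_A", "beta_I"),
                               level = 0.95, ...) {
  pooled <- do.call(rbind, object$chains)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  t(vapply(parm, function(p) stats::quantile(pooled[, p], probs),
           numeric(2)))
}

#' Write a MERLIN fit as JSON
#'
#' @param fit A `merlin_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    beta_A = list(mean = fit$beta_A_mean, sd = fit$beta_A_sd,
                  ci95 = fit$beta_A_ci95, p = fit$beta_A_p),
    beta_I = list(mean = fit$beta_I_mean, sd = fit$beta_I_sd,
                  ci95 = fit$beta_I_ci95, p = fit$beta_I_p),
    beta_AI_cov = fit$beta_AI_cov,
    sigma2_means = as.list(fit$sigma2_means),
    rhat = as.list(fit$rhat),
    n_ivs = fit$n_ivs,
    convergence_ok = fit$convergence_ok,
    experimental = fit$experimental
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
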
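#' Replicate a simulation scenario and benchmark estimators
#'
#' Runs `n_reps` independent replicates of a scenario; in each, simulates
#' the study, selects instruments, fits MERLIN and the requested
#' comparators, and records estimates, standard errors and P values. MERLIN
#' uses the dual-threshold instrument rule of [select_ivs()]; comparators
#' use the classical exposure-GWAS threshold `comparator_t_gwas`.
#'
#' @param scenario A [sim_scenario()] (its own `seed` is ignored here).
#' @param n_reps Number of replicates.
#' @param methods Subset of `c("merlin", "ivw", "egger", "stratified_ivw")`.
#' @param iv An [iv_config()] for MERLIN's instrument selection.
#' @param comparator_t_gwas Exposure-GWAS P threshold for comparators.
#' @param mcmc List of MCMC settings for the per-replicate fits
#'   (`n_iter`, `n_burnin`, `n_chains`).
#' @param seed Master seed governing all replicates.
#' @return Data frame with one row per replicate.
#' @export
merlin_replicates <- function(scenario, n_reps = 100,
                              methods = c("merlin", "ivw"),
                              iv = iv_config(),
                              comparator_t_gwas = 5e-8,
                              mcmc = list(n_iter = 2000, n_burnin = 500,
                                          n_chains = 1),
                              seed = NULL) {
  methods <- match.arg(methods, c("merlin", "ivw", "egger", "stratified_ivw"),
                       several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  sc$seed <- NULL
  rows <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    sim <- simulate_scenario(sc, stratified = "stratified_ivw" %in% methods)
    pan <- sim$panel
    row <- list(rep = rep)
    if ("merlin" %in% methods) {
      ivs <- select_ivs(pan, iv, ld = NULL)
      fit <- merlin(subset_panel(pan, ivs), modifier = sc$modifier,
                    n_iter = mcmc$n_iter, n_burnin = mcmc$n_burnin,
                    n_chains = mcmc$n_chains)
      row <- c(row, list(merlin_beta_A = fit$beta_A_mean,
                         merlin_beta_A_sd = fit$beta_A_sd,
                         merlin_beta_A_p = fit$beta_A_p,
                         merlin_beta_I = fit$beta_I_mean,
                         merlin_beta_I_sd = fit$beta_I_sd,
                         merlin_beta_I_p = fit$beta_I_p,
                         merlin_n_ivs = fit$n_ivs))
    }
    if ("ivw" %in% methods || "egger" %in% methods) {
      sel <- pan$p_gwas < comparator_t_gwas
      if ("ivw" %in% methods) {
        r <- if (sum(sel) >= 1) {
          mr_ivw(pan$gamma_G[sel], pan$s1[sel], pan$Gamma_G[sel], pan$s3[sel])
        } else NULL
        row <- c(row, list(ivw_est = r$estimate %||% NA_real_,
                           ivw_se = r$se %||% NA_real_,
                           ivw_p = r$p %||% NA_real_))
      }
      if ("egger" %in% methods) {
        r <- if (sum(sel) >= 3) {
          mr_egger(pan$gamma_G[sel], pan$s1[sel], pan$Gamma_G[sel], pan$s3[sel])
        } else NULL
        row <- c(row, list(egger_est = r$estimate %||% NA_real_,
                           egger_se = r$se %||% NA_real_,
                           egger_p = r$p %||% NA_real_))
      }
    }
    if ("stratified_ivw" %in% methods) {
      r <- tryCatch(
        mr_stratified(sim$tables$exp_gwas_m, sim$tables$out_gwas_m,
                      sim$tables$exp_gwas_f, sim$tables$out_gwas_f,
                      method = "ivw", t_gwas = comparator_t_gwas),
        error = function(e) NULL)
      row <- c(row, list(
        strat_beta_I = if (is.null(r)) NA_real_ else r$interaction$beta,
        strat_beta_I_p = if (is.null(r)) NA_real_ else r$interaction$p))
    }
    rows[[rep]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
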
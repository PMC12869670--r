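test_that("exposure block mean reduces correctly and matches hand expansion", {
  g <- c(0.1, -0.2, 0.3)
  s <- c(0.01, 0.02, 0.03)
  expect_equal(exposure_block_mean(g, s, NULL), g)
  expect_equal(exposure_block_mean(g, s, diag(3)), g)
  expect_equal(exposure_block_mean(rep(0, 3), s, diag(3)), rep(0, 3))
  # 2-SNP case, r = 0.5, unequal SEs: mean_i = s_i sum_j r_ij g_j / s_j
  g2 <- c(0.1, 0.3); s2 <- c(0.01, 0.05)
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  hand <- c(s2[1] * (g2[1] / s2[1] + 0.5 * g2[2] / s2[2]),
            s2[2] * (0.5 * g2[1] / s2[1] + g2[2] / s2[2]))
  expect_equal(exposure_block_mean(g2, s2, R), hand)
})

test_that("outcome means implement the interaction leakage terms", {
  M <- 4
  par <- list(beta_A = 0, beta_I = 0.3, gamma_G = rep(0, M),
              gamma_GI = rep(0.2, M), beta_G = rep(0, M))
  s <- rep(1, M)
  mod <- modifier_spec("binary", 0.5)
  expect_equal(outcome_gwas_mean(par, s, s, NULL, mod), rep(0.06, M))

  # beta_I = 0: the interaction-free limit is S3 R S3^-1 Gamma_G
  par0 <- list(beta_A = 0.4, beta_I = 0, gamma_G = stats::rnorm(M),
               gamma_GI = stats::rnorm(M), beta_G = stats::rnorm(M, 0, 0.1))
  s3 <- stats::runif(M, 0.01, 0.05); s4 <- stats::runif(M, 0.01, 0.05)
  R <- 0.4 + 0.6 * diag(M)
  Gamma_G <- par0$beta_A * par0$gamma_G + par0$beta_G
  expect_equal(outcome_gwas_mean(par0, s3, s4, R, mod),
               exposure_block_mean(Gamma_G, s3, R))
  expect_equal(outcome_gwas_mean(par0, s3, s4, R, modifier_spec("continuous")),
               exposure_block_mean(Gamma_G, s3, R))

  # the E[E^2] = 1 leakage is modifier-kind independent
  parI <- list(beta_A = 0.2, beta_I = 0.25, gamma_G = stats::rnorm(M),
               gamma_GI = stats::rnorm(M), beta_G = rep(0, M))
  expect_equal(outcome_gwas_mean(parI, s3, s4, NULL, mod),
               outcome_gwas_mean(parI, s3, s4, NULL, modifier_spec("continuous")))
})

test_that("outcome GWIS mean carries the mu3 skewness term only when unbalanced", {
  M <- 3
  par <- list(beta_A = 0.1, beta_I = 0.3, gamma_G = c(0.1, 0.2, -0.1),
              gamma_GI = c(0.05, -0.04, 0.08), beta_G = rep(0, M))
  s3 <- rep(0.02, M); s4 <- rep(0.03, M)
  balanced <- modifier_spec("binary", 0.5)
  cont <- modifier_spec("continuous")
  expect_equal(outcome_gwis_mean(par, s3, s4, NULL, balanced),
               outcome_gwis_mean(par, s3, s4, NULL, cont))
  unb <- modifier_spec("binary", 0.25)
  Gamma_GI <- par$beta_A * par$gamma_GI + par$beta_I * par$gamma_G
  expect_equal(outcome_gwis_mean(par, s3, s4, NULL, unb),
               Gamma_GI + unb$mu3 * par$beta_I * par$gamma_GI)
  # null model
  par0 <- list(beta_A = 0, beta_I = 0, gamma_G = rep(0, M),
               gamma_GI = par$gamma_GI, beta_G = rep(0, M))
  expect_equal(outcome_gwis_mean(par0, s3, s4, NULL, unb), rep(0, M))
})

test_that("log likelihood matches the closed form and an independent oracle", {
  M <- 5
  par <- list(beta_A = 0.2, beta_I = 0.1, gamma_G = stats::rnorm(M, 0, 0.1),
              gamma_GI = stats::rnorm(M, 0, 0.05),
              beta_G = stats::rnorm(M, 0, 0.02))
  mod <- modifier_spec("binary", 0.5)
  ones <- rep(1, M)
  at_mean <- make_panel(
    gamma_G = par$gamma_G, s1 = ones,
    gamma_GI = par$gamma_GI, s2 = ones,
    Gamma_G = outcome_gwas_mean(par, ones, ones, NULL, mod), s3 = ones,
    Gamma_GI = outcome_gwis_mean(par, ones, ones, NULL, mod), s4 = ones)
  expect_equal(merlin_loglik(par, at_mean, NULL, mod),
               -(4 * M / 2) * log(2 * pi))

  # any perturbation of an observed vector lowers the likelihood
  pert <- at_mean
  pert$Gamma_G <- pert$Gamma_G + 0.1
  expect_lt(merlin_loglik(par, pert, NULL, mod),
            merlin_loglik(par, at_mean, NULL, mod))

  # random LD instance against a generic multivariate-normal density
  set.seed(31)
  R <- estimate_ld(matrix(stats::rnorm(60 * M), 60, M), shrink = 0.1)
  s1 <- stats::runif(M, 0.01, 0.03); s2 <- stats::runif(M, 0.01, 0.03)
  s3 <- stats::runif(M, 0.01, 0.03); s4 <- stats::runif(M, 0.01, 0.03)
  pan <- make_panel(gamma_G = stats::rnorm(M, 0, 0.05), s1 = s1,
                    gamma_GI = stats::rnorm(M, 0, 0.05), s2 = s2,
                    Gamma_G = stats::rnorm(M, 0, 0.05), s3 = s3,
                    Gamma_GI = stats::rnorm(M, 0, 0.05), s4 = s4)
  SRS <- function(s) diag(s) %*% unname(R) %*% diag(s)
  ora <- dmvnorm_oracle(pan$gamma_G, exposure_block_mean(par$gamma_G, s1, R), SRS(s1)) +
    dmvnorm_oracle(pan$gamma_GI, exposure_block_mean(par$gamma_GI, s2, R), SRS(s2)) +
    dmvnorm_oracle(pan$Gamma_G, outcome_gwas_mean(par, s3, s4, R, mod), SRS(s3)) +
    dmvnorm_oracle(pan$Gamma_GI, outcome_gwis_mean(par, s3, s4, R, mod), SRS(s4))
  expect_equal(merlin_loglik(par, pan, R, mod), as.numeric(ora),
               tolerance = 1e-8)
  # block subsetting
  b13 <- dmvnorm_oracle(pan$gamma_G, exposure_block_mean(par$gamma_G, s1, R), SRS(s1)) +
    dmvnorm_oracle(pan$Gamma_G, outcome_gwas_mean(par, s3, s4, R, mod), SRS(s3))
  expect_equal(merlin_loglik(par, pan, R, mod, blocks = c(1, 3)),
               as.numeric(b13), tolerance = 1e-8)
})

test_that("moment oracle: per-SNP regression coefficients match the block means", {
  # central joint test of the likelihood mean structures and the simulation
  # engine: one large cohort per modifier preset, per-SNP GWAS/GWIS scans,
  # observed coefficients compared to the model means at the true parameters
  presets <- list(modifier_spec("binary", 0.5),
                  modifier_spec("binary", 0.25),
                  modifier_spec("continuous"))
  set.seed(202)
  for (mod in presets) {
    oc <- oracle_cohort(n = 150000, m = 8, mod = mod,
                        beta_A = 0.2, beta_I = 0.3)
    par <- list(beta_A = 0.2, beta_I = 0.3, gamma_G = oc$eff$gamma_G,
                gamma_GI = oc$eff$gamma_GI, beta_G = oc$eff$beta_G)
    checks <- list(
      list(obs = oc$exp_gwas, mean = exposure_block_mean(par$gamma_G,
                                                         oc$exp_gwas$se)),
      list(obs = oc$exp_gwis, mean = exposure_block_mean(par$gamma_GI,
                                                         oc$exp_gwis$se)),
      list(obs = oc$out_gwas, mean = outcome_gwas_mean(par, oc$out_gwas$se,
                                                       oc$out_gwis$se, NULL, mod)),
      list(obs = oc$out_gwis, mean = outcome_gwis_mean(par, oc$out_gwas$se,
                                                       oc$out_gwis$se, NULL, mod)))
    for (chk in checks) {
      z <- (chk$obs$beta - chk$mean) / chk$obs$se
      expect_lt(max(abs(z)), 3.9)
      expect_lt(mean(abs(z)), 1.6)
    }
  }
})

test_that("the unbalanced-modifier skewness term is required, not incidental", {
  # refitting the p = 0.25 cohort's GWIS block with mu3 forced to zero must
  # produce a systematic deviation where the correct mean does not
  set.seed(203)
  mod <- modifier_spec("binary", 0.25)
  oc <- oracle_cohort(n = 150000, m = 8, mod = mod, beta_A = 0, beta_I = 0.3,
                      rho_AI = 0, h2_pleio = 0)
  par <- list(beta_A = 0, beta_I = 0.3, gamma_G = oc$eff$gamma_G,
              gamma_GI = oc$eff$gamma_GI, beta_G = oc$eff$beta_G)
  right <- outcome_gwis_mean(par, oc$out_gwas$se, oc$out_gwis$se, NULL, mod)
  wrong <- outcome_gwis_mean(par, oc$out_gwas$se, oc$out_gwis$se, NULL,
                             modifier_spec("continuous"))
  z_right <- (oc$out_gwis$beta - right) / oc$out_gwis$se
  z_wrong <- (oc$out_gwis$beta - wrong) / oc$out_gwis$se
  expect_lt(max(abs(z_right)), 3.9)
  expect_gt(max(abs(z_wrong)), 5)
})
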
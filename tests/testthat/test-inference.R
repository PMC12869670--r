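test_that("MERLIN recovers the average effect on a seeded simulation", {
  sc <- sim_scenario(beta_A = 0.3, beta_I = 0, rho_AI = 0,
                     h2_gamma_G = 0.3, h2_gamma_GI = 0.15, seed = 301)
  sim <- simulate_scenario(sc)
  fit <- merlin(sim$panel, n_iter = 3000, n_burnin = 1000, n_chains = 2,
                seed = 302)
  expect_lt(abs(fit$beta_A_mean - 0.3), 3 * fit$beta_A_sd)
  expect_gt(fit$beta_I_ci95[2], 0)
  expect_lt(fit$beta_I_ci95[1], 0)
  expect_true(fit$convergence_ok)
  expect_equal(unname(coef(fit)),
               c(fit$beta_A_mean, fit$beta_I_mean))
  expect_equal(vcov(fit)[1, 2], fit$beta_AI_cov)
})

test_that("the illustrative opposite-sex scenario separates the two effects", {
  sc <- sim_scenario(beta_M = 0.3, beta_F = -0.3, rho_AI = 0.8,
                     h2_gamma_G = 0.3, h2_gamma_GI = 0.3, seed = 303)
  sim <- simulate_scenario(sc)
  fit <- merlin(subset_panel(sim$panel, select_ivs(sim$panel)),
                n_iter = 3000, n_burnin = 1000, n_chains = 1, seed = 304)
  expect_lt(abs(fit$beta_I_mean - 0.3), 4 * fit$beta_I_sd)
  expect_lt(abs(fit$beta_A_mean), 4 * fit$beta_A_sd)
  # sex-combined IVW on the same panel is pulled off the null
  sel <- sim$panel$p_gwas < 5e-8
  ivw <- mr_ivw(sim$panel$gamma_G[sel], sim$panel$s1[sel],
                sim$panel$Gamma_G[sel], sim$panel$s3[sel])
  expect_lt(ivw$p, 0.05)
  expect_gt(ivw$estimate, 0.1)
})

test_that("no-signal null pins the interaction at zero", {
  set.seed(305)
  M <- 50
  s <- rep(0.01, M)
  g <- stats::rnorm(M, 0, 0.05)
  pan <- make_panel(gamma_G = g + s * stats::rnorm(M), s1 = s,
                    gamma_GI = numeric(M), s2 = rep(100, M),
                    Gamma_G = s * stats::rnorm(M), s3 = s,
                    Gamma_GI = numeric(M), s4 = s)
  fit <- merlin(pan, n_iter = 2000, n_burnin = 500, n_chains = 1, seed = 306)
  expect_lt(abs(fit$beta_I_mean), 3 * fit$beta_I_sd)
  expect_lt(abs(fit$beta_A_mean), 3 * fit$beta_A_sd)
})

test_that("identical seed and configuration give bit-identical chains", {
  sc <- sim_scenario(n_exposure = 4000, n_outcome = 4000, m_snps = 50,
                     beta_A = 0.2, beta_I = 0.1, h2_gamma_G = 0.3,
                     h2_gamma_GI = 0.15, seed = 307)
  sim <- simulate_scenario(sc)
  f1 <- merlin(sim$panel, n_iter = 1500, n_burnin = 500, seed = 308)
  f2 <- merlin(sim$panel, n_iter = 1500, n_burnin = 500, seed = 308)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$beta_A_mean, f2$beta_A_mean)
})

test_that("with the interaction disabled MERLIN agrees with IVW", {
  sc <- sim_scenario(beta_A = 0.3, beta_I = 0, rho_AI = 0,
                     h2_gamma_G = 0.3, h2_gamma_GI = 0.05, h2_beta_G = 0,
                     seed = 309)
  sim <- simulate_scenario(sc)
  sel <- sim$panel$p_gwas < 5e-8
  pan <- subset_panel(sim$panel, sim$panel$snp[sel])
  # silence the GWIS channels and fix beta_I = 0: a classical two-sample MR
  M <- length(pan$snp)
  pan$gamma_GI <- numeric(M); pan$s2 <- rep(1e3, M)
  pan$Gamma_GI <- numeric(M); pan$s4 <- rep(1e3, M)
  fit <- merlin(pan, fix_beta_I = 0, n_iter = 3000, n_burnin = 1000,
                seed = 310)
  ivw <- mr_ivw(pan$gamma_G, pan$s1, pan$Gamma_G, pan$s3)
  expect_lt(abs(fit$beta_A_mean - ivw$estimate),
            2 * sqrt(fit$beta_A_sd^2 + ivw$se^2))
  expect_equal(fit$beta_I_mean, 0)
  expect_equal(fit$beta_I_sd, 0)
})

test_that("negating the modifier coding negates only the interaction", {
  sc <- sim_scenario(beta_A = 0.2, beta_I = 0.25, rho_AI = 0,
                     h2_gamma_G = 0.3, h2_gamma_GI = 0.2, seed = 311)
  sim <- simulate_scenario(sc)
  pan <- sim$panel
  flip <- pan
  flip$gamma_GI <- -flip$gamma_GI
  flip$Gamma_GI <- -flip$Gamma_GI
  f1 <- merlin(pan, n_iter = 2500, n_burnin = 1000, seed = 312)
  f2 <- merlin(flip, n_iter = 2500, n_burnin = 1000, seed = 312)
  expect_lt(abs(f2$beta_I_mean + f1$beta_I_mean),
            3 * sqrt(f1$beta_I_sd^2 + f2$beta_I_sd^2) / sqrt(100))
  expect_lt(abs(f2$beta_A_mean - f1$beta_A_mean),
            3 * sqrt(f1$beta_A_sd^2 + f2$beta_A_sd^2) / sqrt(100))
})

test_that("empirical power for the interaction rises with its true size", {
  power <- vapply(c(0, 0.1, 0.2), function(b) {
    sc <- sim_scenario(n_exposure = 8000, n_outcome = 8000, m_snps = 80,
                       beta_A = 0, beta_I = b, rho_AI = 0.4,
                       h2_gamma_G = 0.3, h2_gamma_GI = 0.15)
    res <- merlin_replicates(sc, n_reps = 20, methods = "merlin", seed = 313)
    mean(res$merlin_beta_I_p < 0.05)
  }, 0)
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.3)
  expect_gt(power[3], 0.7)
})

test_that("the no-outcome-GWIS strategy still identifies both effects", {
  sc <- sim_scenario(beta_A = 0.1, beta_I = 0.3, rho_AI = 0,
                     h2_gamma_G = 0.3, h2_gamma_GI = 0.3, seed = 314)
  sim <- simulate_scenario(sc)
  full <- merlin(sim$panel, n_iter = 3000, n_burnin = 1000, seed = 315)
  red <- fit_merlin_no_outcome_gwis(sim$panel, n_iter = 3000,
                                    n_burnin = 1000, seed = 315)
  expect_true(red$experimental)
  expect_false(full$experimental)
  expect_lt(abs(red$beta_I_mean - 0.3), 4 * red$beta_I_sd)
  expect_gt(red$beta_I_sd, full$beta_I_sd)   # less information, wider posterior
  expect_lt(abs(red$beta_A_mean - full$beta_A_mean),
            3 * sqrt(red$beta_A_sd^2 + full$beta_A_sd^2))
})

test_that("without exposure GWIS signal the reduced fit warns of weak identification", {
  set.seed(316)
  M <- 40
  s1 <- rep(0.012, M)
  s3 <- rep(0.05, M)              # noisy outcome GWAS
  g <- stats::rnorm(M, 0, 0.06)
  s2 <- rep(0.05, M)
  pan <- make_panel(gamma_G = g + s1 * stats::rnorm(M), s1 = s1,
                    gamma_GI = s2 * stats::rnorm(M), s2 = s2,   # gamma_GI = 0
                    Gamma_G = 0.2 * g + s3 * stats::rnorm(M), s3 = s3,
                    Gamma_GI = s3 * stats::rnorm(M), s4 = s3)
  expect_warning(
    red <- fit_merlin_no_outcome_gwis(pan, n_iter = 2000, n_burnin = 500,
                                      seed = 317),
    "weakly identified")
  expect_gt(red$beta_I_sd, 0.25)
})

test_that("fit summaries, JSON export and printing are coherent", {
  sc <- sim_scenario(n_exposure = 3000, n_outcome = 3000, m_snps = 40,
                     beta_A = 0.2, h2_gamma_G = 0.3, h2_gamma_GI = 0.1,
                     seed = 318)
  sim <- simulate_scenario(sc)
  fit <- merlin(sim$panel, n_iter = 1500, n_burnin = 500, seed = 319)
  expect_true(fit$beta_A_ci95[1] <= fit$beta_A_mean &&
                fit$beta_A_mean <= fit$beta_A_ci95[2])
  expect_gt(fit$beta_A_p, 0)
  ci <- confint(fit)
  expect_equal(unname(ci["beta_A", ]), unname(fit$beta_A_ci95))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$beta_A$mean, fit$beta_A_mean)
  expect_equal(js$n_ivs, fit$n_ivs)
  expect_output(print(fit), "MERLIN fit")
  expect_output(print(summary(fit)), "variance components")
  expect_error(merlin(make_panel(0.1, 0.01, 0, 0.01, 0, 0.01, 0, 0.01)),
               "at least 2")
})
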
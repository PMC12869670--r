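# Small builders and independent oracles used across the test files.

# a well-formed sumstats data.frame with m SNPs
toy_sumstats_df <- function(m = 5, beta = NULL, se = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    snp = sprintf("rs%03d", seq_len(m)),
    chr = "1",
    pos = seq_len(m) * 1e5,
    ea = rep(c("A", "C", "G", "T", "A"), length.out = m),
    oa = rep(c("G", "T", "A", "C", "C"), length.out = m),
    eaf = seq(0.1, 0.45, length.out = m),
    beta = if (is.null(beta)) round(stats::rnorm(m, 0, 0.05), 4) else beta,
    se = if (is.null(se)) rep(0.01, m) else se,
    n = 50000,
    p = NA_real_,
    stringsAsFactors = FALSE
  )
}

toy_tables <- function(m = 5, seed = 1) {
  set.seed(seed)
  list(
    exp_gwas = sumstats_table(toy_sumstats_df(m), "X", "GWAS"),
    exp_gwis = sumstats_table(toy_sumstats_df(m), "X", "GWIS"),
    out_gwas = sumstats_table(toy_sumstats_df(m), "Y", "GWAS"),
    out_gwis = sumstats_table(toy_sumstats_df(m), "Y", "GWIS")
  )
}

# hand-built harmonized panel from raw vectors (bypasses harmonize())
make_panel <- function(gamma_G, s1, gamma_GI, s2, Gamma_G, s3, Gamma_GI, s4,
                       pos = NULL) {
  M <- length(gamma_G)
  p <- list(snp = sprintf("rs%03d", seq_len(M)), chr = rep("1", M),
            pos = if (is.null(pos)) seq_len(M) * 2e6 else pos,
            ea = rep("A", M), oa = rep("G", M),
            gamma_G = gamma_G, s1 = s1, gamma_GI = gamma_GI, s2 = s2,
            Gamma_G = Gamma_G, s3 = s3, Gamma_GI = Gamma_GI, s4 = s4,
            p_gwas = wald_p(gamma_G, s1), p_gwis = wald_p(gamma_GI, s2),
            n_exp = rep(2e4, M))
  class(p) <- "harmonized_panel"
  p
}

# independent multivariate-normal log density (solve/determinant based,
# no shared code with the package internals)
dmvnorm_oracle <- function(x, mean, Sigma) {
  k <- length(x)
  d <- x - mean
  -0.5 * (k * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
            drop(t(d) %*% solve(Sigma) %*% d))
}

# independent clumping oracle: walk candidates in (priority P, id) order and
# keep each one not in LD (r^2 > r2_max within the window) with any kept SNP
brute_clump <- function(ids, p_gwas, p_gwis, pos, ld, cfg) {
  cand <- which(p_gwas < cfg$t_gwas | (cfg$t_gwis > 0 & p_gwis < cfg$t_gwis))
  prio <- pmin(p_gwas[cand], if (cfg$t_gwis > 0) p_gwis[cand] else Inf)
  ord <- cand[order(prio, ids[cand])]
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      if (abs(pos[i] - pos[k]) <= cfg$window_bp &&
          ld[ids[i], ids[k]]^2 > cfg$r2_max) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  ids[kept]
}

# closed-form weighted least squares oracle: coefficients of y ~ X with
# weights w, computed from the normal equations directly
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

# single simulated cohort with per-SNP scans at given truth; used by the
# moment-structure oracle
oracle_cohort <- function(n, m, mod, beta_A, beta_I, rho_AI = 0.4,
                          h2_G = 0.3, h2_GI = 0.2, h2_pleio = 0.05) {
  sc <- sim_scenario(n_exposure = n, n_outcome = n, m_snps = m,
                     h2_gamma_G = h2_G, h2_gamma_GI = h2_GI,
                     h2_beta_G = h2_pleio, rho_AI = rho_AI,
                     beta_A = beta_A, beta_I = beta_I, modifier = mod)
  G <- gen_genotypes(n, m)
  E <- merlinmr:::modifier_draw(mod, n)
  gv <- apply(G, 2, stats::var)
  eff <- gen_effects(m, h2_G, h2_GI, h2_pleio, rho_AI, gv)
  ph <- gen_phenotypes(G, E, eff, sc)
  list(G = G, E = E, eff = eff, ph = ph,
       exp_gwas = run_gwas(ph$X, G), exp_gwis = run_gwis(ph$X, G, E),
       out_gwas = run_gwas(ph$Y, G), out_gwis = run_gwis(ph$Y, G, E))
}
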
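#' Define a simulation scenario
#'
#' Generative configuration for the synthetic two-cohort study: an exposure
#' cohort and an outcome cohort (optionally overlapping), independent
#' binomial SNPs, per-SNP additive and SNP-by-modifier interaction effects
#' on the exposure with correlation `rho_AI`, horizontal pleiotropy on the
#' outcome, and composite residuals correlated across the two traits.
#' Variance shares are realized exactly by rescaling the drawn effects;
#' phenotypes are scaled to unit total variance.
#'
#' @param n_exposure,n_outcome Cohort sizes.
#' @param n_overlap Individuals shared between the two cohorts (shared
#'   genotypes, modifier and residual draws).
#' @param m_snps Number of candidate instruments M.
#' @param maf_range Range from which per-SNP minor-allele frequencies are
#'   drawn uniformly.
#' @param h2_gamma_G Variance share of the exposure explained by additive
#'   SNP effects.
#' @param h2_gamma_GI Variance share explained by SNP-by-modifier
#'   interaction effects.
#' @param h2_beta_G Variance share of the outcome explained by horizontal
#'   pleiotropy.
#' @param rho_AI Correlation between a SNP's additive and interaction
#'   effects on the exposure.
#' @param beta_A,beta_I True average causal effect and causal interaction.
#' @param beta_M,beta_F Alternative parameterization by stratum-specific
#'   causal effects (modifier coded +1/-1): converted to
#'   `beta_A = (beta_M + beta_F)/2`, `beta_I = (beta_M - beta_F)/2`.
#' @param gamma_E,beta_E Modifier main effects on exposure and outcome.
#' @param resid_corr Correlation of the composite residuals of the two
#'   traits (environment + confounder + noise), default 0.6.
#' @param modifier A [modifier_spec()].
#' @param seed Optional integer seed for [simulate_scenario()].
#' @return A list of class `merlin_scenario`.
#' @export
sim_scenario <- function(n_exposure = 20000, n_outcome = 20000,
                         n_overlap = 0, m_snps = 200,
                         maf_range = c(0.05, 0.5),
                         h2_gamma_G = 0.3, h2_gamma_GI = 0.15,
                         h2_beta_G = 0, rho_AI = 0,
                         beta_A = 0, beta_I = 0,
                         beta_M = NULL, beta_F = NULL,
                         gamma_E = 0.1, beta_E = 0.1, resid_corr = 0.6,
                         modifier = modifier_spec("binary", p = 0.5),
                         seed = NULL) {
  if (!is.null(beta_M) && !is.null(beta_F)) {
    beta_A <- (beta_M + beta_F) / 2
    beta_I <- (beta_M - beta_F) / 2
  }
  stopifnot(n_exposure > 10, n_outcome > 10,
            n_overlap >= 0, n_overlap <= min(n_exposure, n_outcome),
            m_snps >= 1, abs(rho_AI) <= 1,
            h2_gamma_G >= 0, h2_gamma_GI >= 0, h2_beta_G >= 0,
            h2_beta_G < 1, abs(resid_corr) <= 1)
  if (h2_gamma_G + h2_gamma_GI + gamma_E^2 >= 1) {
    stop("infeasible variance shares: h2_gamma_G + h2_gamma_GI + gamma_E^2 ",
         "must be < 1")
  }
  structure(list(n_exposure = n_exposure, n_outcome = n_outcome,
                 n_overlap = n_overlap, m_snps = m_snps,
                 maf_range = maf_range, h2_gamma_G = h2_gamma_G,
                 h2_gamma_GI = h2_gamma_GI, h2_beta_G = h2_beta_G,
                 rho_AI = rho_AI, beta_A = beta_A, beta_I = beta_I,
                 gamma_E = gamma_E, beta_E = beta_E,
                 resid_corr = resid_corr, modifier = modifier, seed = seed),
            class = "merlin_scenario")
}

#' Generate independent synthetic genotypes
#'
#' Column j is i.i.d. Binomial(2, maf_j) with `maf_j ~ Uniform(maf_range)`;
#' columns are mean-centered. MAFs are attached as the `"maf"` attribute.
#'
#' @param n,m Individuals and SNPs.
#' @inheritParams sim_scenario
#' @return Centered n x m dosage matrix.
#' @export
gen_genotypes <- function(n, m, maf_range = c(0.05, 0.5)) {
  stopifnot(n >= 2, m >= 1)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  G <- .gen_genotypes_cpp(as.integer(n), maf)
  colnames(G) <- sprintf("snp%04d", seq_len(m))
  attr(G, "maf") <- maf
  G
}

#' Draw per-SNP true effects with exact variance shares
#'
#' `(gamma_G_j, gamma_GI_j)` are bivariate normal with correlation
#' `rho_AI`, then each vector is rescaled so its realized contribution to
#' the exposure variance equals `h2_G` / `h2_GI` exactly; pleiotropic
#' effects `beta_G_j` are independent normal rescaled to `h2_pleio` of the
#' outcome variance.
#'
#' @param m Number of SNPs.
#' @param h2_G,h2_GI,h2_pleio Target variance shares.
#' @param rho_AI Effect correlation.
#' @param geno_var Per-SNP genotype variances.
#' @return List with `gamma_G`, `gamma_GI`, `beta_G`.
#' @export
gen_effects <- function(m, h2_G, h2_GI, h2_pleio, rho_AI, geno_var) {
  stopifnot(length(geno_var) == m, all(geno_var > 0))
  z1 <- stats::rnorm(m)
  z2 <- stats::rnorm(m)
  scale_to <- function(v, h2) {
    if (h2 == 0) return(numeric(m))
    v * sqrt(h2 / sum(v^2 * geno_var))
  }
  gamma_G <- scale_to(z1, h2_G)
  gamma_GI <- scale_to(rho_AI * z1 + sqrt(1 - rho_AI^2) * z2, h2_GI)
  beta_G <- scale_to(stats::rnorm(m), h2_pleio)
  list(gamma_G = gamma_G, gamma_GI = gamma_GI, beta_G = beta_G)
}

#' Simulate exposure and outcome phenotypes
#'
#' Builds `X = G gamma_G + E gamma_E + (G o E) gamma_GI + e_X` and
#' `Y = X beta_A + G beta_G + E beta_E + (X o E) beta_I + e_Y`. The
#' composite residuals (modifier main effect + confounder + noise) have
#' correlation `resid_corr` and are scaled — using realized sample moments —
#' so both phenotypes have unit variance.
#'
#' @param G Centered dosage matrix.
#' @param E Standardized modifier vector.
#' @param effects Output of [gen_effects()].
#' @param scenario A `merlin_scenario` (supplies the causal and nuisance
#'   parameters).
#' @return List with `X` and `Y`.
#' @export
gen_phenotypes <- function(G, E, effects, scenario) {
  n <- nrow(G)
  stopifnot(length(E) == n)
  sc <- scenario
  vX <- 1 - sc$h2_gamma_G - sc$h2_gamma_GI
  kap2 <- vX - sc$gamma_E^2
  if (kap2 <= 0) stop("infeasible exposure residual variance")
  kappa <- sqrt(kap2)
  uX0 <- stats::rnorm(n)
  X <- .matvec_cpp(G, effects$gamma_G) + E * .matvec_cpp(G, effects$gamma_GI) +
    sc$gamma_E * E + kappa * uX0
  S_Y <- sc$beta_A * X + .matvec_cpp(G, effects$beta_G) + sc$beta_E * E +
    sc$beta_I * X * E
  vS <- stats::var(S_Y)
  r <- stats::cov(S_Y, uX0)
  # residual loading a on the shared component and b on fresh noise:
  #   corr(e_X, e_Y) = resid_corr with e_X = gamma_E E + kappa uX0,
  #   e_Y = beta_E E + a uX0 + b eps, and realized var(Y) = 1.
  a <- 0
  for (i in 1:200) {
    q <- 1 - vS - 2 * a * r          # a^2 + b^2
    if (q <= 0) stop("infeasible outcome residual variance")
    vY <- sc$beta_E^2 + q
    a_new <- (sc$resid_corr * sqrt(vX * vY) - sc$gamma_E * sc$beta_E) / kappa
    if (abs(a_new - a) < 1e-12) break
    a <- a_new
  }
  q <- 1 - vS - 2 * a * r
  b2 <- q - a^2
  if (b2 < 0) stop("infeasible residual correlation for this scenario")
  Y <- S_Y + a * uX0 + sqrt(b2) * stats::rnorm(n)
  list(X = X, Y = Y)
}

# assemble a sumstats table from a scan result (m x 3: beta, se, p);
# a deterministic fit gives se = 0, floored to keep the record valid
scan_to_sumstats <- function(scan, snp_info, n, trait, kind) {
  sumstats_table(
    data.frame(snp = snp_info$snp, chr = snp_info$chr, pos = snp_info$pos,
               ea = snp_info$ea, oa = snp_info$oa, eaf = snp_info$eaf,
               beta = scan[, 1], se = pmax(scan[, 2], 1e-300), n = n,
               p = scan[, 3], stringsAsFactors = FALSE),
    trait = trait, kind = kind)
}

#' Per-SNP association scans
#'
#' `run_gwas()` fits `trait ~ intercept + G_j` for every SNP;
#' `run_gwis()` fits `trait ~ intercept + G_j + E + G_j:E` and reports the
#' interaction coefficient. Both return [sumstats_table()]s with `beta`,
#' `se`, `n` and two-sided `p`.
#'
#' @param trait Phenotype vector.
#' @param G Centered dosage matrix (columns named; `"maf"` attribute used
#'   for `eaf` when present).
#' @param E Standardized modifier vector (GWIS only).
#' @param trait_label Trait name recorded in the table.
#' @return A `sumstats` table with one row per SNP.
#' @export
run_gwas <- function(trait, G, trait_label = "trait") {
  n <- nrow(G)
  stopifnot(length(trait) == n, n > 10)
  scan <- .gwas_scan_cpp(G, trait, 1L, n)
  scan_to_sumstats(scan, default_snp_info(G), n, trait_label, "GWAS")
}

#' @rdname run_gwas
#' @export
run_gwis <- function(trait, G, E, trait_label = "trait") {
  n <- nrow(G)
  stopifnot(length(trait) == n, length(E) == n, n > 10)
  scan <- .gwis_scan_cpp(G, trait, E, 1L, n)
  scan_to_sumstats(scan, default_snp_info(G), n, trait_label, "GWIS")
}

default_snp_info <- function(G) {
  m <- ncol(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(m))
  maf <- attr(G, "maf")
  if (is.null(maf)) maf <- rep(NA_real_, m)
  list(snp = ids, chr = rep("1", m), pos = as.numeric(seq_len(m)) * 2e6,
       ea = rep("A", m), oa = rep("G", m), eaf = maf)
}

#' Simulate a full two-cohort summary-statistics study
#'
#' Draws one population (exposure cohort plus outcome cohort, sharing
#' `n_overlap` individuals — genotypes, modifier and residuals), simulates
#' the two phenotypes, runs the four per-SNP analyses (exposure GWAS+GWIS
#' on the exposure cohort, outcome GWAS+GWIS on the outcome cohort),
#' harmonizes, and returns the panel together with the generative truth.
#'
#' @param scenario A [sim_scenario()].
#' @param stratified Also return stratum-specific GWAS tables (binary
#'   modifier only), for the sex-stratified comparators.
#' @return List with `panel` (a `harmonized_panel`), `truth` (true
#'   parameter record), `tables` (the four `sumstats` tables, plus
#'   stratified ones when requested), and `scenario`.
#' @export
simulate_scenario <- function(scenario, stratified = FALSE) {
  sc <- scenario
  if (!is.null(sc$seed)) set.seed(sc$seed)
  n_union <- sc$n_exposure + sc$n_outcome - sc$n_overlap
  exp_rows <- c(1L, sc$n_exposure)
  out_rows <- c(sc$n_exposure - sc$n_overlap + 1L, n_union)
  n_out <- out_rows[2] - out_rows[1] + 1L

  G <- gen_genotypes(n_union, sc$m_snps, sc$maf_range)
  E <- modifier_draw(sc$modifier, n_union)
  geno_var <- .col_ss_cpp(G, 1L, n_union) / (n_union - 1)
  effects <- gen_effects(sc$m_snps, sc$h2_gamma_G, sc$h2_gamma_GI,
                         sc$h2_beta_G, sc$rho_AI, geno_var)
  ph <- gen_phenotypes(G, E, effects, sc)
  info <- default_snp_info(G)

  Xe <- ph$X[exp_rows[1]:exp_rows[2]]
  Ee <- E[exp_rows[1]:exp_rows[2]]
  Yo <- ph$Y[out_rows[1]:out_rows[2]]
  Eo <- E[out_rows[1]:out_rows[2]]
  tabs <- list(
    exp_gwas = scan_to_sumstats(.gwas_scan_cpp(G, Xe, exp_rows[1], exp_rows[2]),
                                info, sc$n_exposure, "exposure", "GWAS"),
    exp_gwis = scan_to_sumstats(.gwis_scan_cpp(G, Xe, Ee, exp_rows[1], exp_rows[2]),
                                info, sc$n_exposure, "exposure", "GWIS"),
    out_gwas = scan_to_sumstats(.gwas_scan_cpp(G, Yo, out_rows[1], out_rows[2]),
                                info, n_out, "outcome", "GWAS"),
    out_gwis = scan_to_sumstats(.gwis_scan_cpp(G, Yo, Eo, out_rows[1], out_rows[2]),
                                info, n_out, "outcome", "GWIS"))
  if (stratified) {
    if (sc$modifier$kind != "binary") {
      stop("stratified tables require a binary modifier")
    }
    m_rows <- function(rows, trait, lev, label) {
      loc <- which(E[rows[1]:rows[2]] == lev)
      Gs <- G[rows[1]:rows[2], , drop = FALSE][loc, , drop = FALSE]
      attr(Gs, "maf") <- attr(G, "maf")
      run_gwas(trait[loc], Gs, label)
    }
    e1 <- sc$modifier$levels[1]; e0 <- sc$modifier$levels[2]
    tabs$exp_gwas_m <- m_rows(exp_rows, Xe, e1, "exposure.M")
    tabs$exp_gwas_f <- m_rows(exp_rows, Xe, e0, "exposure.F")
    tabs$out_gwas_m <- m_rows(out_rows, Yo, e1, "outcome.M")
    tabs$out_gwas_f <- m_rows(out_rows, Yo, e0, "outcome.F")
  }
  panel <- suppressMessages(
    harmonize(tabs$exp_gwas, tabs$exp_gwis, tabs$out_gwas, tabs$out_gwis))
  truth <- list(beta_A = sc$beta_A, beta_I = sc$beta_I,
                gamma_G = effects$gamma_G, gamma_GI = effects$gamma_GI,
                beta_G = effects$beta_G, maf = attr(G, "maf"),
                geno_var = geno_var)
  list(panel = panel, truth = truth, tables = tabs, scenario = sc)
}
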
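#' Estimate an LD correlation matrix from a reference genotype panel
#'
#' Pairwise Pearson correlations of genotype dosages, shrunk toward the
#' identity, `R <- (1 - shrink) R + shrink I`, so that the result is
#' positive definite and safely invertible in the likelihood. Zero-variance
#' SNPs are excluded with a warning.
#'
#' @param genotypes n x M numeric dosage matrix (individuals x SNPs).
#' @param snp_ids SNP ids; defaults to the matrix column names.
#' @param shrink Shrinkage weight toward the identity (default 0.05).
#' @return A symmetric correlation matrix with unit diagonal and SNP ids as
#'   dimnames.
#' @export
estimate_ld <- function(genotypes, snp_ids = colnames(genotypes),
                        shrink = 0.05) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop("need at least 2 individuals")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance SNP(s) excluded from the LD matrix")
    genotypes <- genotypes[, v > 0, drop = FALSE]
    snp_ids <- snp_ids[v > 0]
  }
  r <- stats::cor(genotypes)
  r <- (1 - shrink) * r + shrink * diag(ncol(r))
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Instrument-selection configuration
#'
#' Defaults mirror the MERLIN settings: genome-wide exposure-GWAS threshold
#' `5e-8`, exposure-GWIS threshold `5e-6`, clumping `r^2 < 0.3` within a
#' 1 Mb window.
#'
#' @param t_gwas Exposure-GWAS P threshold.
#' @param t_gwis Exposure-GWIS P threshold (0 disables the GWIS channel).
#' @param r2_max Clumping r-squared threshold.
#' @param window_bp Clumping window in base pairs.
#' @return A list of class `iv_config`.
#' @export
iv_config <- function(t_gwas = 5e-8, t_gwis = 5e-6, r2_max = 0.3,
                      window_bp = 1e6) {
  stopifnot(t_gwas > 0, t_gwas <= 1, t_gwis >= 0, t_gwis <= 1,
            r2_max > 0, r2_max <= 1, window_bp > 0)
  structure(list(t_gwas = t_gwas, t_gwis = t_gwis, r2_max = r2_max,
                 window_bp = window_bp), class = "iv_config")
}

#' Dual-threshold instrument selection with min-P LD clumping
#'
#' Candidates are SNPs significant in the exposure GWAS (`P < t_gwas`) OR
#' the exposure GWIS (`P < t_gwis`); each candidate's priority P value is
#' the smaller of the two. Greedy clumping then repeatedly keeps the
#' unclaimed candidate with the smallest priority P (ties broken by SNP id)
#' and removes remaining candidates with `r^2 > r2_max` within `window_bp`
#' of it. With `ld = NULL` instruments are treated as independent and
#' clumping removes nothing.
#'
#' @param panel A `harmonized_panel` (exposure GWAS/GWIS P values and
#'   positions are taken from it).
#' @param cfg An [iv_config()].
#' @param ld LD correlation matrix covering the panel SNPs, or `NULL`.
#' @return Character vector of kept SNP ids, sorted by priority P.
#' @export
select_ivs <- function(panel, cfg = iv_config(), ld = NULL) {
  cand <- which(panel$p_gwas < cfg$t_gwas |
                  (cfg$t_gwis > 0 & panel$p_gwis < cfg$t_gwis))
  if (length(cand) == 0L) {
    stop("no SNP passes either significance threshold; ",
         "consider relaxing t_gwas/t_gwis")
  }
  prio <- pmin(panel$p_gwas[cand],
               if (cfg$t_gwis > 0) panel$p_gwis[cand] else Inf)
  ids <- panel$snp[cand]
  pos <- panel$pos[cand]
  chr <- panel$chr[cand]
  ord <- order(prio, ids)
  ids <- ids[ord]; prio <- prio[ord]; pos <- pos[ord]; chr <- chr[ord]
  if (is.null(ld)) return(ids)
  if (!all(ids %in% rownames(ld))) stop("LD matrix does not cover all candidates")
  claimed <- rep(FALSE, length(ids))
  kept <- character(0)
  for (i in seq_along(ids)) {
    if (claimed[i]) next
    kept <- c(kept, ids[i])
    claimed[i] <- TRUE
    later <- which(!claimed)
    if (length(later) == 0L) break
    same_win <- !is.na(pos[later]) & !is.na(pos[i]) &
      chr[later] == chr[i] & abs(pos[later] - pos[i]) <= cfg$window_bp
    same_win[is.na(same_win)] <- TRUE  # unknown positions: be conservative
    r2 <- ld[ids[i], ids[later]]^2
    claimed[later[same_win & r2 > cfg$r2_max]] <- TRUE
  }
  kept
}
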
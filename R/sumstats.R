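#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame with one row per SNP and the
#' canonical columns `snp`, `chr`, `pos`, `ea` (effect allele), `oa` (other
#' allele), `eaf` (effect-allele frequency), `beta`, `se`, `n`, `p`, plus
#' attributes `trait` and `kind` (`"GWAS"` or `"GWIS"`). Missing `p` values
#' are recomputed as two-sided normal from `beta / se`.
#'
#' @param data Data frame holding at least `snp`, `ea`, `oa`, `beta`, `se`.
#' @param trait Trait label.
#' @param kind `"GWAS"` or `"GWIS"`.
#' @return A `sumstats` data frame.
#' @export
sumstats_table <- function(data, trait = "trait", kind = c("GWAS", "GWIS")) {
  kind <- match.arg(kind)
  need <- c("snp", "ea", "oa", "beta", "se")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (opt in c("chr", "pos", "eaf", "n", "p")) {
    if (is.null(data[[opt]])) data[[opt]] <- NA
  }
  data <- data[c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "n", "p")]
  data$snp <- as.character(data$snp)
  data$ea <- toupper(as.character(data$ea))
  data$oa <- toupper(as.character(data$oa))
  if (anyDuplicated(data$snp)) {
    ndup <- sum(duplicated(data$snp))
    message(ndup, " duplicate snp id(s): keeping first occurrence")
    data <- data[!duplicated(data$snp), , drop = FALSE]
  }
  bad <- !is.finite(data$beta) | !is.finite(data$se) | data$se <= 0
  if (any(bad)) data <- data[!bad, , drop = FALSE]
  if (nrow(data) == 0L) stop("no valid records")
  if (any(data$ea == data$oa)) stop("effect and other allele must differ")
  fix_p <- !is.finite(data$p)
  data$p[fix_p] <- wald_p(data$beta[fix_p], data$se[fix_p])
  rownames(data) <- NULL
  structure(data, trait = trait, kind = kind, n_dropped = sum(bad),
            class = c("sumstats", "data.frame"))
}

# default GWAS-SSF-like header dialect
default_column_map <- c(snp = "snp", chr = "chr", pos = "pos", ea = "ea",
                        oa = "oa", eaf = "eaf", beta = "beta", se = "se",
                        n = "n", p = "p")

#' Read a summary-statistics table from a delimited text file
#'
#' Reads a tab-separated (optionally gzip-compressed) table, renames columns
#' according to `column_map`, drops rows with unparseable `beta`/`se`
#' (counted in the `n_dropped` attribute), and returns a [sumstats_table()].
#'
#' @param path File path.
#' @param kind `"GWAS"` or `"GWIS"`.
#' @param trait Trait label; defaults to the file name.
#' @param column_map Named character vector mapping canonical names
#'   (`snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `n`, `p`) to the
#'   file's header names. Unspecified entries fall back to the canonical
#'   name itself.
#' @return A `sumstats` data frame.
#' @export
read_sumstats <- function(path, kind = c("GWAS", "GWIS"), trait = NULL,
                          column_map = NULL) {
  kind <- match.arg(kind)
  if (is.null(trait)) trait <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  map <- default_column_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  mandatory <- c("snp", "ea", "oa", "beta", "se")
  for (cn in mandatory) {
    if (!map[[cn]] %in% names(raw)) {
      stop("column '", map[[cn]], "' (", cn, ") not found in ", path)
    }
  }
  out <- data.frame(snp = raw[[map[["snp"]]]], stringsAsFactors = FALSE)
  for (cn in c("chr", "pos", "ea", "oa", "eaf", "beta", "se", "n", "p")) {
    src <- map[[cn]]
    out[[cn]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  for (cn in c("pos", "eaf", "beta", "se", "n", "p")) {
    out[[cn]] <- suppressWarnings(as.numeric(out[[cn]]))
  }
  tab <- sumstats_table(out, trait = trait, kind = kind)
  if (attr(tab, "n_dropped") > 0) {
    message(attr(tab, "n_dropped"), " row(s) with unparseable beta/se dropped")
  }
  tab
}

#' Write a summary-statistics table as TSV
#'
#' @param x A `sumstats` data frame.
#' @param path Output path (`.gz` suffix writes gzip-compressed).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Keeps SNPs with `eaf`-derived MAF at or above `maf_min` and, when the
#' chi-square rule is enabled, squared z-scores below `max(80, n / 1000)`
#' (a guard against implausibly strong associations relative to the study
#' size). Order is preserved; drop counts are recorded in the `qc_log`
#' attribute.
#'
#' @param x A `sumstats` data frame.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param z2_rule Apply the `Z^2 < max(80, n/1000)` filter?
#' @return The filtered `sumstats` table.
#' @export
qc_filter <- function(x, maf_min = 0.05, z2_rule = TRUE) {
  keep <- rep(TRUE, nrow(x))
  log <- list(n_in = nrow(x))
  if (!is.null(maf_min) && maf_min > 0) {
    if (all(is.na(x$eaf))) stop("MAF filter enabled but `eaf` is absent")
    maf <- pmin(x$eaf, 1 - x$eaf)
    drop_maf <- !is.na(maf) & maf < maf_min
    log$n_maf_dropped <- sum(drop_maf)
    keep <- keep & !drop_maf
  }
  if (isTRUE(z2_rule)) {
    if (all(is.na(x$n))) stop("Z^2 filter enabled but `n` is absent")
    z2 <- (x$beta / x$se)^2
    thr <- pmax(80, x$n / 1000)
    drop_z2 <- !is.na(z2) & z2 >= thr
    log$n_z2_dropped <- sum(drop_z2)
    keep <- keep & !drop_z2
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait") <- attr(x, "trait")
  attr(out, "kind") <- attr(x, "kind")
  attr(out, "qc_log") <- c(log, n_out = nrow(out))
  class(out) <- class(x)
  out
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) {
  ea == complement_allele(oa)
}

# Orient `tab` (restricted to `snps`, in that order) to the reference
# effect/other alleles. Returns data.frame(beta, se, eaf, p, ok).
orient_to <- function(tab, snps, ref_ea, ref_oa) {
  idx <- match(snps, tab$snp)
  ea <- tab$ea[idx]; oa <- tab$oa[idx]
  beta <- tab$beta[idx]; eaf <- tab$eaf[idx]
  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  flip_same <- complement_allele(ea) == ref_ea & complement_allele(oa) == ref_oa
  flip_swap <- complement_allele(ea) == ref_oa & complement_allele(oa) == ref_ea
  sign <- ifelse(same | (flip_same & !same), 1,
                 ifelse(swap | flip_swap, -1, NA_real_))
  data.frame(beta = beta * sign,
             se = tab$se[idx],
             eaf = ifelse(sign == 1, eaf, 1 - eaf),
             p = tab$p[idx],
             n = tab$n[idx],
             ok = !is.na(sign),
             stringsAsFactors = FALSE)
}

#' Harmonize the four summary-statistics inputs into one panel
#'
#' Intersects the four tables on SNP id (order follows the exposure GWAS),
#' aligns each source to the exposure-GWAS effect allele (negating `beta`
#' and reflecting `eaf` under an allele swap, handling strand flips), and
#' assembles the per-SNP vectors used by the likelihood: exposure GWAS
#' `gamma_G` with SE diagonal `s1`, exposure GWIS `gamma_GI` / `s2`, outcome
#' GWAS `Gamma_G` / `s3`, outcome GWIS `Gamma_GI` / `s4`. Strand-ambiguous
#' (A/T, C/G) SNPs are dropped by default since their orientation cannot be
#' resolved from alleles alone; SNPs whose allele pairs cannot be reconciled
#' are dropped with a warning.
#'
#' @param exp_gwas,exp_gwis,out_gwas,out_gwis `sumstats` tables.
#' @param drop_palindromic Drop strand-ambiguous SNPs (default `TRUE`).
#' @return An object of class `harmonized_panel`: a list of aligned vectors
#'   (`snp`, `chr`, `pos`, `ea`, `oa`, `gamma_G`, `s1`, `gamma_GI`, `s2`,
#'   `Gamma_G`, `s3`, `Gamma_GI`, `s4`, `p_gwas`, `p_gwis`, `n_exp`).
#' @export
harmonize <- function(exp_gwas, exp_gwis, out_gwas, out_gwis,
                      drop_palindromic = TRUE) {
  snps <- Reduce(intersect, list(exp_gwas$snp, exp_gwis$snp,
                                 out_gwas$snp, out_gwis$snp))
  snps <- exp_gwas$snp[exp_gwas$snp %in% snps]
  if (length(snps) == 0L) stop("no SNPs shared by all four input tables")
  ridx <- match(snps, exp_gwas$snp)
  ref_ea <- exp_gwas$ea[ridx]
  ref_oa <- exp_gwas$oa[ridx]
  keep <- rep(TRUE, length(snps))
  if (drop_palindromic) {
    pal <- is_palindromic(ref_ea, ref_oa)
    if (any(pal)) {
      message(sum(pal), " strand-ambiguous SNP(s) dropped")
      keep <- keep & !pal
    }
  }
  o2 <- orient_to(exp_gwis, snps, ref_ea, ref_oa)
  o3 <- orient_to(out_gwas, snps, ref_ea, ref_oa)
  o4 <- orient_to(out_gwis, snps, ref_ea, ref_oa)
  unresolved <- !(o2$ok & o3$ok & o4$ok)
  if (any(unresolved & keep)) {
    warning(sum(unresolved & keep),
            " SNP(s) with irreconcilable allele pairs dropped")
    keep <- keep & !unresolved
  }
  if (!any(keep)) stop("no SNPs left after harmonization")
  panel <- list(
    snp = snps[keep],
    chr = exp_gwas$chr[ridx][keep],
    pos = exp_gwas$pos[ridx][keep],
    ea = ref_ea[keep],
    oa = ref_oa[keep],
    gamma_G = exp_gwas$beta[ridx][keep],
    s1 = exp_gwas$se[ridx][keep],
    gamma_GI = o2$beta[keep],
    s2 = o2$se[keep],
    Gamma_G = o3$beta[keep],
    s3 = o3$se[keep],
    Gamma_GI = o4$beta[keep],
    s4 = o4$se[keep],
    p_gwas = exp_gwas$p[ridx][keep],
    p_gwis = o2$p[keep],
    n_exp = exp_gwas$n[ridx][keep]
  )
  class(panel) <- "harmonized_panel"
  panel
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf("harmonized panel: %d SNPs\n", length(x$snp)))
  invisible(x)
}

#' Subset a harmonized panel by SNP id
#'
#' @param panel A `harmonized_panel`.
#' @param snps Character vector of SNP ids to keep (order respected).
#' @return The restricted `harmonized_panel`.
#' @export
subset_panel <- function(panel, snps) {
  idx <- match(snps, panel$snp)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snps[is.na(idx)], collapse = ", "))
  out <- lapply(unclass(panel), function(v) v[idx])
  class(out) <- "harmonized_panel"
  out
}

# number of SNPs in a panel
panel_size <- function(panel) length(panel$snp)

# align an exposure/outcome pair of GWAS tables on shared SNPs (used by the
# stratified comparators); orientation to the exposure's effect allele
align_pair <- function(expo, outc) {
  snps <- expo$snp[expo$snp %in% outc$snp]
  if (length(snps) == 0L) stop("no shared SNPs between exposure and outcome")
  ei <- match(snps, expo$snp)
  o <- orient_to(outc, snps, expo$ea[ei], expo$oa[ei])
  keep <- o$ok
  list(snp = snps[keep],
       beta_exp = expo$beta[ei][keep], se_exp = expo$se[ei][keep],
       p_exp = expo$p[ei][keep],
       beta_out = o$beta[keep], se_out = o$se[keep])
}
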
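#' Specify the effect modifier E
#'
#' The modifier enters the model as a standardized variable (mean 0,
#' variance 1). A binary modifier with stratum-1 proportion `p` is coded at
#' the two standardized Bernoulli levels returned by [standardized_levels()];
#' its skewness [modifier_mu3()] enters the outcome-GWIS likelihood mean. A
#' continuous modifier is assumed standardized by the caller (see
#' [standardize_modifier()]) and is treated as having zero skewness.
#'
#' @param kind `"binary"` or `"continuous"`.
#' @param p Stratum-1 proportion for a binary modifier, in (0, 1).
#' @param mu3 Third central moment of the standardized modifier. Computed
#'   from `p` for a binary modifier; defaults to 0 for a continuous one.
#' @return An object of class `modifier_spec`: a list with `kind`, `p`,
#'   `mu3`, and (binary only) `levels = c(e1, e0)`.
#' @examples
#' modifier_spec("binary", p = 0.5)   # sex coded +1 / -1
#' modifier_spec("continuous")        # e.g. standardized age
#' @export
modifier_spec <- function(kind = c("binary", "continuous"), p = 0.5,
                          mu3 = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    lev <- standardized_levels(p)
    spec <- list(kind = kind, p = p, mu3 = modifier_mu3(p), levels = lev)
  } else {
    spec <- list(kind = kind, p = NA_real_,
                 mu3 = if (is.null(mu3)) 0 else mu3, levels = NULL)
  }
  class(spec) <- "modifier_spec"
  spec
}

#' @export
print.modifier_spec <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf("binary modifier: p = %g, levels (%+.4f, %+.4f), mu3 = %.4f\n",
                x$p, x$levels[1], x$levels[2], x$mu3))
  } else {
    cat(sprintf("continuous modifier (standardized), mu3 = %g\n", x$mu3))
  }
  invisible(x)
}

#' Standardized two-point coding of a binary modifier
#'
#' A Bernoulli(p) variable standardized to mean 0 and variance 1 takes the
#' value `e1 = sqrt((1-p)/p)` in stratum 1 and `e0 = -sqrt(p/(1-p))` in
#' stratum 0. For `p = 0.5` this is the familiar +1/-1 coding.
#'
#' @param p Stratum-1 proportion, in (0, 1).
#' @return Numeric vector `c(e1, e0)`.
#' @export
standardized_levels <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!(p > 0 && p < 1)) stop("`p` must lie strictly between 0 and 1")
  c(sqrt((1 - p) / p), -sqrt(p / (1 - p)))
}

#' Skewness of a standardized binary modifier
#'
#' Third central moment of the standardized Bernoulli(p) variable:
#' `(1 - 2p) / sqrt(p (1 - p))`. Vanishes for a balanced modifier
#' (`p = 0.5`) and satisfies `mu3(p) = -mu3(1 - p)`.
#'
#' @inheritParams standardized_levels
#' @return The skewness, a scalar.
#' @export
modifier_mu3 <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!(p > 0 && p < 1)) stop("`p` must lie strictly between 0 and 1")
  (1 - 2 * p) / sqrt(p * (1 - p))
}

#' Standardize a continuous modifier
#'
#' Subtracts the mean and divides by the standard deviation.
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
standardize_modifier <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("modifier has zero variance")
  (x - mean(x)) / s
}

# Draw n modifier values according to a modifier_spec (standardized scale).
modifier_draw <- function(spec, n) {
  if (spec$kind == "binary") {
    ifelse(stats::runif(n) < spec$p, spec$levels[1], spec$levels[2])
  } else {
    stats::rnorm(n)
  }
}
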
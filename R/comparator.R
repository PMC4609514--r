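# Allele comparison: Z-statistic on two affinity estimates, its
# significance, and the excess/deficiency/norm decision for the minor
# allele.

.ALPHA_BUCKETS <- c(">0.05", "<0.05", "<0.01", "<0.001", "<1e-7")

#' Z-statistic comparing two affinity estimates
#'
#' Two-sample z on the \eqn{-\ln K_D} estimates with the perturbation
#' uncertainties as the standard errors:
#' \eqn{z = |m_a - m_b| / \sqrt{\delta_a^2 + \delta_b^2}}. Symmetric in its
#' arguments.
#'
#' @param a,b `affinity_estimate` objects (from [scan_promoter()])
#' @return z (nonnegative, dimensionless)
#' @export
fisher_z <- function(a, b) {
  stopifnot(inherits(a, "affinity_estimate"), inherits(b, "affinity_estimate"))
  if (!is.finite(a$delta) || !is.finite(b$delta)) {
    stop("both deltas must be finite", call. = FALSE)
  }
  num <- abs(a$minus_ln_kd - b$minus_ln_kd)
  den <- sqrt(a$delta^2 + b$delta^2)
  if (den == 0) {
    if (num == 0) return(0)
    stop("degenerate variance: both deltas are zero but the affinities differ",
         call. = FALSE)
  }
  num / den
}

#' Significance of a Z-statistic
#'
#' Two-sided standard-normal tail: \eqn{\alpha = 2(1 - \Phi(z))} and the
#' probability rate \eqn{p = 1 - \alpha}. The bucket reproduces the
#' conventional reporting vocabulary
#' \{>0.05, <0.05, <0.01, <0.001, <1e-7\}.
#'
#' @param z a nonnegative z value
#' @return a list with `p`, `alpha` and `alpha_bucket`
#' @export
z_significance <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 0) {
    stop("z must be a single nonnegative number", call. = FALSE)
  }
  alpha <- 2 * stats::pnorm(z, lower.tail = FALSE)
  bucket <- if (alpha < 1e-7) "<1e-7"
            else if (alpha < 1e-3) "<0.001"
            else if (alpha < 1e-2) "<0.01"
            else if (alpha < 0.05) "<0.05"
            else ">0.05"
  list(p = 1 - alpha, alpha = alpha, alpha_bucket = bucket)
}

#' Compare ancestral and minor allele affinity estimates
#'
#' Computes [fisher_z()] and its significance and decides, at the given
#' significance threshold, whether the minor allele predicts gene
#' overexpression (`"excess"`: significant affinity gain), lowered
#' expression (`"deficiency"`: significant affinity loss) or no change
#' (`"norm"`).
#'
#' @param ancestral,minor `affinity_estimate` objects computed with the
#'   same parameter set
#' @param alpha significance threshold on \eqn{\alpha} (default 0.05)
#' @return an object of class `tbp_comparison` with elements `ancestral`,
#'   `minor`, `z`, `p`, `alpha`, `alpha_bucket`, `decision` and
#'   `direction_arrow` (`"↑"`, `"↓"` or `"="`)
#' @export
compare_alleles <- function(ancestral, minor, alpha = 0.05) {
  z <- fisher_z(ancestral, minor)
  sig <- z_significance(z)
  significant <- sig$alpha < alpha
  if (!significant || minor$minus_ln_kd == ancestral$minus_ln_kd) {
    decision <- "norm"
    arrow <- "="
  } else if (minor$minus_ln_kd > ancestral$minus_ln_kd) {
    decision <- "excess"
    arrow <- "↑"
  } else {
    decision <- "deficiency"
    arrow <- "↓"
  }
  structure(list(ancestral = ancestral, minor = minor, z = z, p = sig$p,
                 alpha = sig$alpha, alpha_bucket = sig$alpha_bucket,
                 decision = decision, direction_arrow = arrow,
                 threshold = alpha),
            class = "tbp_comparison")
}

#' @export
print.tbp_comparison <- function(x, ...) {
  cat(sprintf(
    "tbp_comparison: ancestral -ln(KD) %.4f +/- %.4f vs minor %.4f +/- %.4f\n",
    x$ancestral$minus_ln_kd, x$ancestral$delta,
    x$minor$minus_ln_kd, x$minor$delta))
  cat(sprintf("  Z = %.2f, alpha %s (p = %.6g) -> %s (%s)\n",
              x$z, x$alpha_bucket, x$p, x$decision, x$direction_arrow))
  invisible(x)
}
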
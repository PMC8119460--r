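#' Likelihood ratio test for nested codon models
#'
#' Computes \code{2 * (lnL_alt - lnL_null)}, clamped at zero when the
#' optimizer returns an alternative marginally below the null, and refers it
#' to the upper tail of the chi-square distribution (plain chi-square with
#' the stated df; for the branch-site and intensity tests df = 1).
#'
#' @param logLikAlt,logLikNull Maximized log-likelihoods of the alternative
#'   and nested null models.
#' @param df Degrees of freedom (>= 1).
#' @param nTests Bonferroni multiplier for the adjusted p-value.
#' @return An [LRTResult-class].
#' @examples
#' lrtPvalue(-1000, -1037.36)          # stat 74.72, p ~ 5.4e-18
#' lrtPvalue(-500, -500)$p             # 1
#' @export
lrtPvalue <- function(logLikAlt, logLikNull, df = 1, nTests = 1) {
  if (df < 1) stop("df must be >= 1")
  if (!is.finite(logLikAlt) || !is.finite(logLikNull))
    stop("log-likelihoods must be finite")
  stat <- 2 * (logLikAlt - logLikNull)
  if (stat < -1e-6)
    warning("alternative log-likelihood below null by ", -stat / 2,
            "; 2*dlnL clamped to 0 (check convergence)")
  stat <- max(0, stat)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new("LRTResult", stat = stat, df = df, p = p,
      pAdjusted = min(1, p * nTests), nTests = nTests)
}

#' @describeIn lrtPvalue Bonferroni adjustment, \code{min(1, p * nTests)}.
#' @param p Unadjusted p-value in [0, 1].
#' @export
bonferroniAdjust <- function(p, nTests = 2) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(nTests < 1)) stop("nTests must be >= 1")
  pmin(1, p * nTests)
}

#' @rdname LRTResult-class
#' @param object An [LRTResult-class].
#' @export
setMethod("show", "LRTResult", function(object) {
  cat("LRT: 2dlnL = ", formatC(object@stat, format = "f", digits = 4),
      ", df = ", object@df,
      ", p = ", format(object@p, digits = 4),
      " (Bonferroni x", object@nTests, ": ",
      format(object@pAdjusted, digits = 4), ")\n", sep = "")
})

#' @rdname LRTResult-class
#' @export
as.data.frame.LRTResult <- function(x, ...)
  data.frame(stat = x@stat, df = x@df, p = x@p, p_bonferroni = x@pAdjusted,
             n_tests = x@nTests)
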
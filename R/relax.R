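#' Fit the selection-intensity (RELAX-style) model
#'
#' Models the omega distribution as a small number of categories shared by
#' all branches; on test branches every category omega is raised to the
#' selection-intensity exponent k, so k > 1 pushes categories away from
#' neutrality (intensified selection) and k < 1 pulls them toward omega = 1
#' (relaxed selection). Branches labeled \code{unclassified} keep the
#' reference distribution. The null pins k = 1, under which test and
#' reference distributions are identical.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree A [LabeledTree-class] with an intensity (test/reference)
#'   partition.
#' @param null Fit the null (k = 1).
#' @param nCategories Number of omega categories (default 3).
#' @param frequencies Frequency scheme tag or [CodonFrequencies-class].
#' @param warmStart Optional [CodonFit-class] seeding the starts.
#' @param control Optimizer control (\code{relTol}, \code{maxit},
#'   \code{kStarts}, default \code{c(1, 3, 0.3)} for the alternative).
#' @return A [CodonFit-class] with parameters \code{kappa}, \code{omegas},
#'   \code{weights}, \code{k}. The k bound is [0.02, 50]; boundary estimates
#'   are flagged in \code{capped}.
#' @export
fitRelax <- function(aln, tree, null = FALSE, nCategories = 3,
                     frequencies = "F3x4", warmStart = NULL, control = list()) {
  if (tree@kind != "intensity")
    stop("fitRelax requires a tree with a test/reference partition")
  if (!any(tree@edgeLabels == "test") || !any(tree@edgeLabels == "reference"))
    stop("both test and reference partitions must be non-empty")
  ctx <- .makeCtx(aln, tree, frequencies)
  modelTag <- if (null) "relax-null" else "relax-alt"
  if (ctx$nVariable == 0L)
    return(.uninformativeFit(modelTag, ctx,
      params = list(kappa = NA_real_, k = NA_real_)))
  nc <- as.integer(nCategories)
  if (nc < 2L) stop("need at least 2 omega categories")

  # Outer bounded quasi-Newton over (log kappa, log omega_1..omega_nc,
  # [log k]); the category weights enter only the mixing step and are
  # profiled out through a stick-breaking parameterization.
  classes <- function(omegas, k)
    lapply(seq_along(omegas), function(i) list(
      omega = c(reference = omegas[i], test = omegas[i]^k,
                unclassified = omegas[i])))
  wp <- .relaxWarm(warmStart, nc)
  # optionally re-estimate the test-branch length (as a multiplier) in both
  # the null and the alternative fit (control$freeFgLength)
  fgFree <- any(ctx$labels == "test" & ctx$lengths > 0) &&
    isTRUE(control$freeFgLength)
  # fixed inner start keeps the profiled objective smooth and deterministic
  profiled <- function(kappa, omegas, k, m)
    .profileMixture(.ctxCllGeneric(ctx, kappa, classes(omegas, k),
                                   lengths = if (fgFree)
                                     .fgScaled(ctx, m, "test")),
                    ctx$weights, type = "simplex", start = rep(1 / nc, nc))
  unpack <- function(par) {
    omegas <- exp(par[1 + seq_len(nc)])
    k <- if (null) 1 else exp(par[2 + nc])
    m <- if (fgFree) exp(par[length(par)]) else 1
    list(kappa = exp(par[1]), omegas = omegas, k = k, m = m)
  }
  obj <- function(par) {
    u <- unpack(par)
    -profiled(u$kappa, u$omegas, u$k, u$m)$logLik
  }
  omStart <- wp$omegas
  omStart[-nc] <- pmin(pmax(omStart[-nc], 2e-4), 1)
  omStart[nc] <- min(max(omStart[nc], 1), 49)
  baseStart <- c(log(min(max(wp$kappa, 0.02), 99)), log(omStart))
  # k = 1 is not a useful start: warm-started from the null fit it sits at a
  # stationary point of the profile; the two starts bracket both directions
  kStarts <- control$kStarts %||% c(3, 0.3)
  starts <- if (null) rbind(c(baseStart, if (fgFree) 0))
            else do.call(rbind, lapply(kStarts, function(k0)
              c(baseStart, log(k0), if (fgFree) 0)))
  lowOm <- c(rep(log(1e-4), nc - 1), log(1))     # last category allowed > 1
  uppOm <- c(rep(log(1), nc - 1), log(50))
  lower <- c(log(.KAPPA_BOUNDS[1]), lowOm)
  upper <- c(log(.KAPPA_BOUNDS[2]), uppOm)
  if (!null) { lower <- c(lower, log(0.02)); upper <- c(upper, log(50)) }
  if (fgFree) { lower <- c(lower, log(1e-3)); upper <- c(upper, log(1e3)) }
  res <- .mlDriver(obj, starts, lower, upper, control)
  if (!res$ok) return(.failedFit(modelTag, res$restarts))
  u <- unpack(res$par)
  prof <- profiled(u$kappa, u$omegas, u$k, u$m)
  est <- list(kappa = u$kappa, omegas = u$omegas,
              weights = prof$par, k = u$k,
              testLengthMult = if (fgFree) u$m else 1)
  capped <- character(0)
  if (!null && (u$k <= 0.02 * 1.001 || u$k >= 50 * 0.999)) capped <- "k"
  degenerate <- all(abs(u$omegas - 1) < 1e-3)
  .newFit(modelTag, res$logLik, est, np = length(res$par) + nc - 1L,
          res$converged,
          res$restarts, capped = capped,
          informative = !degenerate,
          details = list(freqs = ctx$freqObj,
                         note = if (degenerate)
                           "reference omega distribution degenerate at 1; k unidentifiable"))
}

.relaxWarm <- function(warmStart, nc) {
  if (!is.null(warmStart) && !is.null(warmStart@params$omegas) &&
      length(warmStart@params$omegas) == nc) {
    pp <- warmStart@params
    wts <- pmin(pmax(pp$weights, 1e-3), 1 - 1e-3)
    return(list(kappa = pp$kappa, omegas = pmax(pp$omegas, 1e-4),
                weights = wts / sum(wts)))
  }
  omegas <- exp(seq(log(0.1), log(1), length.out = nc))
  omegas[nc] <- 2
  list(kappa = 2, omegas = omegas, weights = rep(1 / nc, nc))
}

#' Selection-intensity test for one gene
#'
#' Fits the alternative (k free) and null (k = 1) intensity models and
#' classifies the gene as intensified (k > 1, LRT significant), relaxed
#' (k < 1, significant) or no-change.
#'
#' @inheritParams fitRelax
#' @param alpha Significance threshold for the classification (default 0.05).
#' @return A [RelaxResult-class].
#' @export
relaxTest <- function(aln, tree, nCategories = 3, frequencies = "F3x4",
                      alpha = 0.05, control = list()) {
  nullFit <- fitRelax(aln, tree, null = TRUE, nCategories = nCategories,
                      frequencies = frequencies, control = control)
  altFit <- fitRelax(aln, tree, null = FALSE, nCategories = nCategories,
                     frequencies = frequencies, warmStart = nullFit,
                     control = control)
  if (!nullFit@converged || !altFit@converged)
    return(new("RelaxResult", gene = aln@geneId, k = NA_real_,
               logLikAlt = altFit@logLik, logLikNull = nullFit@logLik,
               lrt = new("LRTResult", stat = 0, df = 1, p = 1, pAdjusted = 1,
                         nTests = 1),
               classification = "no-change", converged = FALSE,
               status = "optimizer did not converge"))
  lrt <- lrtPvalue(altFit@logLik, nullFit@logLik, df = 1)
  k <- altFit@params$k
  cls <- if (lrt@p < alpha && k > 1) "intensified"
         else if (lrt@p < alpha && k < 1) "relaxed"
         else "no-change"
  status <- if (!altFit@informative)
    altFit@details$note %||% "non-informative" else "ok"
  new("RelaxResult", gene = aln@geneId, k = k, logLikAlt = altFit@logLik,
      logLikNull = nullFit@logLik, lrt = lrt, classification = cls,
      converged = TRUE, status = status)
}

setMethod("show", "RelaxResult", function(object) {
  cat("RelaxResult ", object@gene, ": k = ",
      formatC(object@k, format = "f", digits = 3),
      ", p = ", format(object@lrt@p, digits = 4),
      " -> ", object@classification,
      if (object@status != "ok") paste0(" [", object@status, "]") else "",
      "\n", sep = "")
})

#' Selection-intensity scan over a gene panel
#'
#' @param alignments Named list of [CodonAlignment-class] objects.
#' @param tree A [LabeledTree-class] with the test/reference partition.
#' @inheritParams relaxTest
#' @return List of [RelaxResult-class], ordered by gene name.
#' @export
relaxPanel <- function(alignments, tree, nCategories = 3,
                       frequencies = "F3x4", alpha = 0.05, control = list()) {
  if (length(alignments) == 0L) stop("empty gene panel")
  genes <- vapply(alignments, geneId, character(1))
  alignments <- alignments[order(genes)]
  out <- lapply(alignments, function(a)
    tryCatch(relaxTest(a, tree, nCategories = nCategories,
                       frequencies = frequencies, alpha = alpha,
                       control = control),
             error = function(e)
               new("RelaxResult", gene = a@geneId, k = NA_real_,
                   logLikAlt = NA_real_, logLikNull = NA_real_,
                   lrt = new("LRTResult", stat = 0, df = 1, p = 1,
                             pAdjusted = 1, nTests = 1),
                   classification = "no-change", converged = FALSE,
                   status = conditionMessage(e))))
  names(out) <- vapply(out, function(r) r@gene, character(1))
  out
}

#' Tabulate a selection-intensity scan
#' @param results List of [RelaxResult-class] (from [relaxPanel()]).
#' @return data.frame with k, lnL values, LRT columns and classification.
#' @export
relaxTable <- function(results) {
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(gene = r@gene, k = r@k, logLik_alt = r@logLikAlt,
               logLik_null = r@logLikNull, stat = r@lrt@stat, p = r@lrt@p,
               classification = r@classification, status = r@status)))
  rownames(out) <- NULL
  out
}
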
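# ---- optimizer driver ------------------------------------------------------
# Bounded quasi-Newton (nlminb/PORT) over a deterministic start grid; the best
# start wins. Objective is the negative log-likelihood on a transformed scale
# (log for ratio parameters, natural for proportions) with box constraints.
.OMEGA_CAP <- 999
.KAPPA_BOUNDS <- c(0.01, 100)

.mlDriver <- function(obj, starts, lower, upper, control = list()) {
  relTol <- control$relTol %||% 1e-8
  maxit <- control$maxit %||% 200
  h <- control$gradStep %||% 1e-6
  # cached forward-difference gradient: profiled objectives are smooth but
  # carry ~1e-11 solver granularity, so tiny automatic steps are unusable
  memoPar <- NULL
  memoVal <- NULL
  fn <- function(par) {
    v <- obj(par)
    memoPar <<- par; memoVal <<- v
    v
  }
  gr <- function(par) {
    f0 <- if (!is.null(memoPar) && isTRUE(all.equal(par, memoPar,
                                                    tolerance = 0)))
      memoVal else obj(par)
    vapply(seq_along(par), function(j) {
      pj <- par
      pj[j] <- pj[j] + h
      (obj(pj) - f0) / h
    }, numeric(1))
  }
  # multistart schedule: the first start gets the full iteration budget;
  # later starts get a capped budget and are polished to full convergence
  # only when they beat the incumbent
  laterMaxit <- control$laterMaxit %||% 40
  factr <- relTol / .Machine$double.eps * 0.1
  runOne <- function(par0, iters) {
    fit <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = factr, maxit = iters)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value)) fit$ok <- fit$convergence == 0
    fit
  }
  best <- NULL
  nused <- 0L
  for (s in seq_len(nrow(starts))) {
    nused <- nused + 1L
    fit <- runOne(starts[s, ], if (s == 1L) maxit else laterMaxit)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (s > 1L && !is.null(best) && fit$value < best$value - 1e-6 &&
        !fit$ok) {
      polished <- runOne(fit$par, maxit)
      if (!is.null(polished) && is.finite(polished$value) &&
          polished$value <= fit$value) fit <- polished
    }
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) return(list(ok = FALSE, restarts = nused))
  list(ok = TRUE, par = best$par, logLik = -best$value,
       converged = best$ok, restarts = nused)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cappedParams <- function(est, bounds, tol = 1e-3) {
  names(which(vapply(names(est), function(nm) {
    b <- bounds[[nm]]
    !is.null(b) && (est[[nm]] <= b[1] * (1 + tol) + 1e-9 ||
                      est[[nm]] >= b[2] * (1 - tol))
  }, logical(1))))
}

.newFit <- function(model, logLik, params, np, converged, restarts, capped,
                    informative = TRUE, details = list())
  new("CodonFit", model = model, logLik = logLik, params = params,
      np = as.integer(np), converged = converged,
      restarts = as.integer(restarts), capped = capped,
      informative = informative, details = details)

setMethod("show", "CodonFit", function(object) {
  cat("CodonFit [", object@model, "] lnL = ",
      formatC(object@logLik, format = "f", digits = 4),
      " (np = ", object@np, ", ",
      if (object@converged) "converged" else "NOT converged",
      if (!object@informative) ", non-informative" else "",
      if (length(object@capped)) paste0(", capped: ",
                                        paste(object@capped, collapse = ",")) else "",
      ")\n", sep = "")
  est <- object@params
  flat <- unlist(est[!vapply(est, is.list, logical(1))])
  flat <- flat[!grepl("^branchLengths", names(flat))]
  cat("  ", paste(names(flat), signif(unlist(flat), 4), sep = " = ",
                  collapse = ", "), "\n", sep = "")
})

#' @rdname CodonFit-class
#' @param object A [CodonFit-class].
#' @export
setMethod("logLik", "CodonFit", function(object, ...) object@logLik)

# ---- one-ratio model -------------------------------------------------------

#' Fit the one-ratio branch model
#'
#' A single dN/dS ratio shared by all branches (the null of the two-ratio
#' branch test). Optionally optimizes branch lengths jointly; the estimated
#' lengths can then be reused by downstream fits.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree A [LabeledTree-class].
#' @param frequencies Frequency scheme tag or a [CodonFrequencies-class].
#' @param branchLengths \code{"fixed"} (use the tree's lengths) or
#'   \code{"optimize"} (estimate jointly under this model).
#' @param control Optimizer control: \code{relTol}, \code{maxit}.
#' @details With \code{control$freeFgLength = TRUE}, fits on labeled trees
#'   re-estimate the foreground branch length as a free multiplier
#'   (\code{fgLengthMult} in the parameter list) in every model of a
#'   comparison — an option for when the input branch lengths are
#'   distrusted. The default uses the input lengths as-is.
#' @return A [CodonFit-class] with parameters \code{kappa}, \code{omega} and
#'   (if optimized) \code{branchLengths}.
#' @export
fitOneRatio <- function(aln, tree, frequencies = "F3x4",
                        branchLengths = c("fixed", "optimize"),
                        control = list()) {
  branchLengths <- match.arg(branchLengths)
  ctx <- .makeCtx(aln, tree, frequencies)
  if (ctx$nVariable == 0L)
    return(.uninformativeFit("one-ratio", ctx,
                             params = list(kappa = NA_real_, omega = NA_real_)))
  nE <- length(ctx$lengths)
  # optionally re-estimate the foreground branch length as a multiplier
  # (control$freeFgLength), e.g. when the input lengths are distrusted
  fgFree <- branchLengths == "fixed" && tree@kind == "selection" &&
    any(ctx$labels == "foreground" & ctx$lengths > 0) &&
    isTRUE(control$freeFgLength)
  mix1 <- function(w) list(list(prop = 1,
                                omega = c(background = w, foreground = w)))
  obj <- if (branchLengths == "optimize") {
    function(par) -.ctxLogLik(ctx, exp(par[1]), mix1(exp(par[2])),
                              lengths = exp(par[2 + seq_len(nE)]))$logLik
  } else if (fgFree) {
    function(par) -.ctxLogLik(ctx, exp(par[1]), mix1(exp(par[2])),
                              lengths = .fgScaled(ctx, exp(par[3])))$logLik
  } else {
    function(par) -.ctxLogLik(ctx, exp(par[1]), mix1(exp(par[2])))$logLik
  }
  base <- c(log(2), log(0.4))
  lower <- c(log(.KAPPA_BOUNDS[1]), log(1e-4))
  upper <- c(log(.KAPPA_BOUNDS[2]), log(.OMEGA_CAP))
  if (branchLengths == "optimize") {
    bl0 <- log(pmax(ctx$lengths, 1e-4))
    base <- c(base, bl0)
    lower <- c(lower, rep(log(1e-8), nE))
    upper <- c(upper, rep(log(20), nE))
    starts <- rbind(base)
  } else if (fgFree) {
    starts <- rbind(c(base, 0), c(log(2), log(1.5), 0))
    lower <- c(lower, log(1e-3))
    upper <- c(upper, log(1e3))
  } else {
    starts <- rbind(base, c(log(2), log(1.5)))
  }
  res <- .mlDriver(obj, starts, lower, upper, control)
  if (!res$ok) return(.failedFit("one-ratio", res$restarts))
  est <- list(kappa = exp(res$par[1]), omega = exp(res$par[2]))
  details <- list(freqs = ctx$freqObj)
  if (fgFree) est$fgLengthMult <- exp(res$par[3])
  if (branchLengths == "optimize") {
    bl <- exp(res$par[2 + seq_len(nE)])
    est$branchLengths <- bl
    details$tree <- .withLengths(tree, ctx, bl)
  }
  .newFit("one-ratio", res$logLik, est,
          np = length(res$par), res$converged, res$restarts,
          .cappedParams(est[c("kappa", "omega")],
                        list(kappa = .KAPPA_BOUNDS, omega = c(1e-4, .OMEGA_CAP))),
          details = details)
}

# rebuild a LabeledTree whose (postorder-ordered) lengths were re-estimated
.withLengths <- function(tree, ctx, postLengths) {
  tr <- tree@tree
  keyOrig <- paste(tr$edge[, 1], tr$edge[, 2])
  keyPost <- paste(ctx$edge[, 1], ctx$edge[, 2])
  tr$edge.length <- postLengths[match(keyOrig, keyPost)]
  new("LabeledTree", tree = tr, edgeLabels = tree@edgeLabels, kind = tree@kind)
}

# branch lengths with the labeled (foreground/test) branches scaled by m
.fgScaled <- function(ctx, m, label = "foreground") {
  len <- ctx$lengths
  sel <- ctx$labels == label
  len[sel] <- len[sel] * m
  len
}

.makeCtx <- function(aln, tree, frequencies) {
  if (is(frequencies, "CodonFrequencies"))
    .likContext(aln, tree, freqs = frequencies)
  else .likContext(aln, tree, scheme = frequencies)
}

.uninformativeFit <- function(model, ctx, params) {
  ll <- tryCatch(.ctxLogLik(ctx, 2,
    list(list(prop = 1, omega = c(background = 1, foreground = 1,
                                  reference = 1, test = 1,
                                  unclassified = 1))))$logLik,
    error = function(e) NA_real_)
  .newFit(model, ll, params, np = 0L, converged = TRUE, restarts = 0L,
          capped = character(0), informative = FALSE,
          details = list(note = "no variable codon sites; omega unidentifiable"))
}

.failedFit <- function(model, restarts)
  .newFit(model, NA_real_, list(), np = 0L, converged = FALSE,
          restarts = restarts, capped = character(0),
          details = list(note = "optimizer failed on all starts"))

# ---- two-ratio branch model ------------------------------------------------

#' Fit the two-ratio branch model
#'
#' Separate dN/dS ratios for foreground and background branches. With
#' \code{constrainFg1 = TRUE} the foreground omega is pinned to 1 (the null
#' of the test that foreground omega exceeds 1).
#'
#' @inheritParams fitOneRatio
#' @param constrainFg1 Pin the foreground omega to 1.
#' @return A [CodonFit-class] with \code{kappa}, \code{omegaBg},
#'   \code{omegaFg}.
#' @export
fitTwoRatio <- function(aln, tree, constrainFg1 = FALSE, frequencies = "F3x4",
                        control = list()) {
  if (tree@kind != "selection")
    stop("the two-ratio model requires a tree with a foreground branch label")
  ctx <- .makeCtx(aln, tree, frequencies)
  fgZero <- all(ctx$lengths[ctx$labels == "foreground"] == 0)
  if (ctx$nVariable == 0L)
    return(.uninformativeFit("two-ratio", ctx,
      params = list(kappa = NA_real_, omegaBg = NA_real_, omegaFg = NA_real_)))
  mk <- function(wbg, wfg) list(list(prop = 1, omega = c(background = wbg,
                                                         foreground = wfg)))
  fgFree <- !fgZero && (control$freeFgLength %||% FALSE)
  if (constrainFg1) {
    obj <- if (fgFree)
      function(par) -.ctxLogLik(ctx, exp(par[1]), mk(exp(par[2]), 1),
                                lengths = .fgScaled(ctx, exp(par[3])))$logLik
    else function(par) -.ctxLogLik(ctx, exp(par[1]),
                                   mk(exp(par[2]), 1))$logLik
    starts <- rbind(c(log(2), log(0.4), if (fgFree) 0))
    lower <- c(log(.KAPPA_BOUNDS[1]), log(1e-4), if (fgFree) log(1e-3))
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.OMEGA_CAP), if (fgFree) log(1e3))
  } else {
    obj <- if (fgFree)
      function(par) -.ctxLogLik(ctx, exp(par[1]),
                                mk(exp(par[2]), exp(par[3])),
                                lengths = .fgScaled(ctx, exp(par[4])))$logLik
    else function(par) -.ctxLogLik(ctx, exp(par[1]),
                                   mk(exp(par[2]), exp(par[3])))$logLik
    starts <- rbind(c(log(2), log(0.4), log(0.4), if (fgFree) 0),
                    c(log(2), log(0.4), log(3), if (fgFree) 0))
    lower <- c(log(.KAPPA_BOUNDS[1]), log(1e-4), log(1e-4),
               if (fgFree) log(1e-3))
    upper <- c(log(.KAPPA_BOUNDS[2]), log(.OMEGA_CAP), log(.OMEGA_CAP),
               if (fgFree) log(1e3))
  }
  res <- .mlDriver(obj, starts, lower, upper, control)
  if (!res$ok) return(.failedFit("two-ratio", res$restarts))
  est <- list(kappa = exp(res$par[1]), omegaBg = exp(res$par[2]),
              omegaFg = if (constrainFg1) 1 else exp(res$par[3]))
  if (fgFree) est$fgLengthMult <- exp(res$par[length(res$par)])
  bounds <- list(kappa = .KAPPA_BOUNDS, omegaBg = c(1e-4, .OMEGA_CAP),
                 omegaFg = c(1e-4, .OMEGA_CAP))
  .newFit(if (constrainFg1) "two-ratio-fg1" else "two-ratio",
          res$logLik, est, np = length(res$par), res$converged, res$restarts,
          .cappedParams(est, if (constrainFg1) bounds[1:2] else bounds),
          informative = !fgZero,
          details = list(freqs = ctx$freqObj,
                         note = if (fgZero) "foreground branch has zero length; omegaFg unidentifiable"))
}

# ---- branch-site model (model A / test 2) ----------------------------------

#' Fit the branch-site model (alternative or null)
#'
#' The four-class branch-site model: conserved (0 < omega0 < 1) and neutral
#' (omega1 = 1) sites across all branches, plus classes 2a/2b in which the
#' foreground branches take a shared omega2. The alternative frees
#' omega2 >= 1; the null pins omega2 = 1. The likelihood ratio between the
#' two, referred to chi-square with 1 df, is the positive-selection test.
#'
#' @inheritParams fitOneRatio
#' @param null Fit the null (omega2 = 1) instead of the alternative.
#' @param warmStart Optional [CodonFit-class] from the null fit; its
#'   parameter estimates seed the optimizer starts.
#' @param control Optimizer control: \code{relTol}, \code{maxit},
#'   \code{omega2Starts} (default \code{c(1.5, 5, 50)}).
#' @return A [CodonFit-class] with \code{kappa}, \code{omega0}, \code{omega2},
#'   \code{p0}, \code{p1} (class proportions 2a/2b derived).
#' @export
fitBranchSite <- function(aln, tree, null = FALSE, frequencies = "F3x4",
                          warmStart = NULL, control = list()) {
  if (tree@kind != "selection")
    stop("the branch-site model requires a tree with a foreground branch label")
  ctx <- .makeCtx(aln, tree, frequencies)
  if (ctx$nVariable == 0L)
    return(.uninformativeFit(if (null) "branch-site-null" else "branch-site-alt",
      ctx, params = list(kappa = NA_real_, omega0 = NA_real_,
                         omega2 = NA_real_, p0 = NA_real_, p1 = NA_real_)))
  fgZero <- all(ctx$lengths[ctx$labels == "foreground"] == 0)

  # The class proportions only enter the cheap mixing step, so they are
  # profiled out: the outer bounded quasi-Newton search runs over
  # (log kappa, omega0[, log omega2]) and the inner profile maximizes over
  # (q = p0 + p1, r = p0 / (p0 + p1)) at every outer evaluation.
  bsClasses <- function(w0, w2)
    list(list(omega = c(background = w0, foreground = w0)),
         list(omega = c(background = 1, foreground = 1)),
         list(omega = c(background = w0, foreground = w2)),
         list(omega = c(background = 1, foreground = w2)))
  # Optionally (control$freeFgLength) the foreground branch length is
  # re-estimated as a multiplier in BOTH the null and the alternative fit,
  # for when the input length is distrusted; the default trusts the input
  # tree, which our calibrations show holds the nominal test size while
  # keeping full power.
  fgFree <- !fgZero && (control$freeFgLength %||% FALSE)
  cllFun <- if (!is.null(ctx$bs)) {
    function(kappa, w0, w2, m) .ctxCllBS(ctx, kappa, w0, w2,
                                         fgLen = ctx$bs$fgLen * m)
  } else {
    function(kappa, w0, w2, m) {
      len <- ctx$lengths
      len[ctx$labels == "foreground"] <- len[ctx$labels == "foreground"] * m
      .ctxCllGeneric(ctx, kappa, bsClasses(w0, w2), lengths = len)
    }
  }
  w <- .warmPars(warmStart)
  # the inner solve always starts from the same fixed point so the profiled
  # objective is a deterministic, smooth function of the outer parameters
  # (a data-dependent inner start injects noise into the outer search)
  profiled <- function(kappa, w0, w2, m)
    .profileMixture(cllFun(kappa, w0, w2, m), ctx$weights,
                    type = "branchsite", start = c(0.85, 0.7))
  mBounds <- log(c(1e-3, 1e3))
  mStart <- log(min(max(w$fgMult, 1.5e-3), 900))
  if (null) {
    obj <- if (fgFree)
      function(par) -profiled(exp(par[1]), par[2], 1, exp(par[3]))$logLik
    else function(par) -profiled(exp(par[1]), par[2], 1, 1)$logLik
    starts <- rbind(c(log(w$kappa), w$omega0, if (fgFree) mStart))
    lower <- c(log(.KAPPA_BOUNDS[1]), 1e-4, if (fgFree) mBounds[1])
    upper <- c(log(.KAPPA_BOUNDS[2]), 0.999, if (fgFree) mBounds[2])
  } else {
    om2Starts <- control$omega2Starts %||% c(1.5, 5, 50)
    obj <- if (fgFree)
      function(par) -profiled(exp(par[1]), par[2], exp(par[3]),
                              exp(par[4]))$logLik
    else function(par) -profiled(exp(par[1]), par[2], exp(par[3]), 1)$logLik
    starts <- do.call(rbind, lapply(om2Starts, function(w2)
      c(log(w$kappa), w$omega0, log(w2), if (fgFree) mStart)))
    lower <- c(log(.KAPPA_BOUNDS[1]), 1e-4, 0, if (fgFree) mBounds[1])
    upper <- c(log(.KAPPA_BOUNDS[2]), 0.999, log(.OMEGA_CAP),
               if (fgFree) mBounds[2])
  }
  res <- .mlDriver(obj, starts, lower, upper, control)
  if (!res$ok)
    return(.failedFit(if (null) "branch-site-null" else "branch-site-alt",
                      res$restarts))
  p <- res$par
  m <- if (fgFree) exp(p[length(p)]) else 1
  prof <- profiled(exp(p[1]), p[2], if (null) 1 else exp(p[3]), m)
  q <- prof$par[1]; r <- prof$par[2]
  est <- list(kappa = exp(p[1]), omega0 = p[2],
              omega2 = if (null) 1 else exp(p[3]),
              p0 = q * r, p1 = q * (1 - r),
              fgLengthMult = m,
              fgLength = if (!is.null(ctx$bs)) ctx$bs$fgLen * m else NA_real_)
  capped <- .cappedParams(list(kappa = est$kappa, omega2 = est$omega2),
                          list(kappa = .KAPPA_BOUNDS,
                               omega2 = c(if (null) 0 else 1, .OMEGA_CAP)))
  if (null) capped <- setdiff(capped, "omega2")
  boundary <- character(0)
  if (min(est$p0, est$p1, 1 - est$p0 - est$p1) < 2e-4)
    boundary <- "proportions"
  .newFit(if (null) "branch-site-null" else "branch-site-alt",
          res$logLik, est, np = length(p) + 2L, res$converged, res$restarts,
          capped = c(capped, boundary), informative = !fgZero,
          details = list(freqs = ctx$freqObj, ctx = ctx,
                         note = if (fgZero) "foreground branch has zero length"))
}

.warmPars <- function(warmStart) {
  if (is.null(warmStart) || !length(warmStart@params) ||
      is.na(warmStart@params$kappa %||% NA))
    return(list(kappa = 2, omega0 = 0.2, q = 0.85, r = 0.7, fgMult = 1))
  pp <- warmStart@params
  q <- min(max(pp$p0 + pp$p1, 1e-3), 1 - 1e-3)
  r <- min(max(pp$p0 / max(pp$p0 + pp$p1, 1e-8), 1e-3), 1 - 1e-3)
  list(kappa = min(max(pp$kappa, 0.02), 99),
       omega0 = min(max(pp$omega0, 1e-3), 0.99), q = q, r = r,
       fgMult = pp$fgLengthMult %||% 1)
}

#' Branch-site positive-selection test for one gene
#'
#' Fits the branch-site null and alternative models and returns both fits
#' plus the likelihood ratio test (df = 1) with Bonferroni adjustment.
#'
#' @inheritParams fitBranchSite
#' @param nTests Bonferroni multiplier (default 2: the number of foreground
#'   branches tested per gene in the intended workflow).
#' @return List with \code{null}, \code{alt} ([CodonFit-class]) and
#'   \code{lrt} ([LRTResult-class]).
#' @export
branchSiteTest <- function(aln, tree, frequencies = "F3x4", nTests = 2,
                           control = list()) {
  nullFit <- fitBranchSite(aln, tree, null = TRUE, frequencies = frequencies,
                           control = control)
  altFit <- fitBranchSite(aln, tree, null = FALSE, frequencies = frequencies,
                          warmStart = nullFit, control = control)
  list(null = nullFit, alt = altFit,
       lrt = lrtPvalue(altFit@logLik, nullFit@logLik, df = 1,
                       nTests = nTests))
}
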
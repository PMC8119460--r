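#' @useDynLib phylotroph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- site-class structures -------------------------------------------------
# A "class structure" is a list of site classes; each class has a mixture
# proportion and a named omega vector keyed by branch label. This is the one
# place where the model families are spelled out.
.classStructure <- function(model) {
  om <- model@omegas
  pr <- model@proportions
  switch(model@modelType,
    "one-ratio" = list(list(prop = 1,
      omega = c(background = unname(om["omega"]),
                foreground = unname(om["omega"])))),
    "two-ratio" = list(list(prop = 1,
      omega = c(background = unname(om["background"]),
                foreground = unname(om["foreground"])))),
    "branch-site" = {
      w0 <- unname(om["omega0"]); w2 <- unname(om["omega2"])
      list(
        list(prop = unname(pr["p0"]),  omega = c(background = w0, foreground = w0)),
        list(prop = unname(pr["p1"]),  omega = c(background = 1,  foreground = 1)),
        list(prop = unname(pr["p2a"]), omega = c(background = w0, foreground = w2)),
        list(prop = unname(pr["p2b"]), omega = c(background = 1,  foreground = w2)))
    },
    "relax" = {
      k <- model@k
      lapply(seq_along(om), function(i) list(prop = unname(pr[i]),
        omega = c(reference = unname(om[i]),
                  test = unname(om[i])^k,
                  unclassified = unname(om[i]))))
    },
    stop("unknown modelType"))
}

# ---- model constructors ----------------------------------------------------

#' Site-class model constructors
#'
#' Convenience constructors for the model families used in the selection
#' tests: a single-ratio model, a two-ratio (foreground/background) branch
#' model, the four-class branch-site model, and the RELAX-style intensity
#' model in which test-branch omegas equal reference omegas raised to k.
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega,omegaBg,omegaFg,omega0,omega2 dN/dS parameters.
#' @param p0,p1 Branch-site proportions of the conserved and neutral classes;
#'   classes 2a/2b take the remainder split in proportion p0:p1.
#' @param omegas,weights RELAX reference-category omegas and weights.
#' @param k RELAX selection-intensity exponent.
#' @param freqs A [CodonFrequencies-class] (default equal).
#' @return A [SiteClassModel-class].
#' @examples
#' m <- branchSiteModel(2, 0.2, 5, 0.6, 0.3)
#' sum(m@proportions)  # 1
#' @name siteClassModels
NULL

#' @rdname siteClassModels
#' @export
oneRatioModel <- function(kappa, omega, freqs = equalCodonFrequencies())
  new("SiteClassModel", modelType = "one-ratio", kappa = kappa,
      omegas = c(omega = omega), proportions = c(all = 1), k = 1,
      freqs = freqs)

#' @rdname siteClassModels
#' @export
twoRatioModel <- function(kappa, omegaBg, omegaFg,
                          freqs = equalCodonFrequencies())
  new("SiteClassModel", modelType = "two-ratio", kappa = kappa,
      omegas = c(background = omegaBg, foreground = omegaFg),
      proportions = c(all = 1), k = 1, freqs = freqs)

#' @rdname siteClassModels
#' @export
branchSiteModel <- function(kappa, omega0, omega2, p0, p1,
                            freqs = equalCodonFrequencies()) {
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1)
    stop("p0, p1 must be non-negative with p0 + p1 <= 1")
  p2 <- 1 - p0 - p1
  share <- if (p0 + p1 > 0) p0 / (p0 + p1) else 0.5
  new("SiteClassModel", modelType = "branch-site", kappa = kappa,
      omegas = c(omega0 = omega0, omega2 = omega2),
      proportions = c(p0 = p0, p1 = p1, p2a = p2 * share,
                      p2b = p2 * (1 - share)),
      k = 1, freqs = freqs)
}

#' @rdname siteClassModels
#' @export
relaxModel <- function(kappa, omegas, weights, k = 1,
                       freqs = equalCodonFrequencies()) {
  if (length(omegas) != length(weights)) stop("need one weight per omega category")
  names(omegas) <- paste0("omega", seq_along(omegas))
  names(weights) <- paste0("w", seq_along(weights))
  new("SiteClassModel", modelType = "relax", kappa = kappa, omegas = omegas,
      proportions = weights / sum(weights), k = k, freqs = freqs)
}

# ---- likelihood context ----------------------------------------------------
# Precomputed, parameter-independent structure reused across optimizer
# evaluations: site patterns, postorder edges, branch labels, frequencies.
.likContext <- function(aln, ltree, freqs = NULL, scheme = "F3x4") {
  tr <- ltree@tree
  if (!setequal(aln@taxa, tr$tip.label))
    stop("alignment '", aln@geneId, "' and tree have different taxon sets")
  aln <- .alignTo(aln, tr$tip.label)
  post <- ape::reorder.phylo(tr, "postorder")
  keyOrig <- paste(tr$edge[, 1], tr$edge[, 2])
  keyPost <- paste(post$edge[, 1], post$edge[, 2])
  labPost <- ltree@edgeLabels[match(keyPost, keyOrig)]
  key <- apply(aln@states, 2, paste, collapse = ",")
  pat <- match(key, unique(key))
  keep <- !duplicated(key)
  states <- aln@states[, keep, drop = FALSE]
  if (is.null(freqs)) freqs <- estimateCodonFrequencies(aln, scheme)
  ctx <- list(aln = aln, geneId = aln@geneId,
       edge = matrix(as.integer(post$edge), ncol = 2),
       lengths = post$edge.length, labels = labPost,
       nNode = tr$Nnode, states = states,
       weights = tabulate(pat),
       patIndex = pat, freqObj = freqs, pi = freqs@freqs,
       nVariable = sum(apply(aln@states, 2, function(s) {
         s <- s[s > 0L]; length(unique(s)) > 1L
       })))
  if (ltree@kind == "selection" && sum(ltree@edgeLabels == "foreground") == 1L)
    ctx$bs <- .bsFastContext(ltree)
  ctx
}

# Fast-path structure for the branch-site family with a single foreground
# branch: reroot at the foreground edge's parent so the four site classes can
# share two background pruning passes (the classes differ only in the
# transition matrix applied on the foreground branch).
.bsFastContext <- function(ltree) {
  phy <- ltree@tree
  fgE <- which(ltree@edgeLabels == "foreground")
  parent <- phy$edge[fgE, 1]
  child <- phy$edge[fgE, 2]
  nTip <- length(phy$tip.label)
  fgTips <- if (child <= nTip) phy$tip.label[child]
            else phy$tip.label[.cladeTips(phy, child)]
  root0 <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  tr2 <- if (parent == root0) phy
         else ape::root(phy, node = parent, resolve.root = FALSE)
  post <- ape::reorder.phylo(tr2, "postorder")
  tipsBelow <- lapply(seq_len(nrow(post$edge)), function(e) {
    ch <- post$edge[e, 2]
    if (ch <= nTip) post$tip.label[ch]
    else post$tip.label[.cladeTips(post, ch)]
  })
  fgIdx <- which(vapply(tipsBelow, function(tp) setequal(tp, fgTips),
                        logical(1)))
  if (length(fgIdx) != 1L) return(NULL)  # fall back to the generic path
  fgIdx <- fgIdx[1]
  nmax <- nTip + post$Nnode
  inSub <- logical(nmax)
  ch <- post$edge[fgIdx, 2]
  inSub[ch] <- TRUE
  if (ch > nTip) {
    stack <- ch
    while (length(stack)) {
      nd <- stack[1]; stack <- stack[-1]
      kids <- post$edge[post$edge[, 1] == nd, 2]
      inSub[kids] <- TRUE
      stack <- c(stack, kids[kids > nTip])
    }
  }
  list(edge = matrix(as.integer(post$edge), ncol = 2),
       lengths = post$edge.length, fgIdx = fgIdx, inSub = inSub,
       fgLen = post$edge.length[fgIdx], nNode = post$Nnode)
}

# Per-class per-pattern log-likelihoods of the four branch-site classes using
# the shared-regime fast path (requires ctx$bs). The whole computation
# (generator construction, eigendecomposition, both pruning passes) runs in
# compiled code; .ctxCllBSRef is the R reference used in tests.
.ctxCllBS <- function(ctx, kappa, w0, w2, fgLen = ctx$bs$fgLen) {
  bs <- ctx$bs
  cllBranchSite(geneticCode()$pairType, ctx$pi, kappa, w0, w2, bs$edge,
                bs$lengths, bs$fgIdx, bs$inSub, ctx$states, bs$nNode, fgLen)
}

.ctxCllBSRef <- function(ctx, kappa, w0, w2, fgLen = ctx$bs$fgLen) {
  uniq <- unique(c(w0, 1, w2))
  decs <- lapply(uniq, function(w)
    .decomposeQ(.neutralScaledQ(kappa, w, ctx$freqObj), ctx$pi))
  bs <- ctx$bs
  E <- nrow(bs$edge)
  regime <- function(w) {
    di <- decs[[match(w, uniq)]]
    Ps <- vector("list", E)
    for (e in seq_len(E))
      Ps[[e]] <- if (e == bs$fgIdx) matrix(0) else .Pfromdec(di, bs$lengths[e])
    prunePartsExclude(bs$edge, Ps, ctx$states, bs$nNode, bs$fgIdx, bs$inSub)
  }
  rA <- regime(w0)
  rB <- regime(1)
  Pfg <- lapply(uniq, function(w)
    .Pfromdec(decs[[match(w, uniq)]], fgLen))
  comb <- function(rr, w) {
    P <- Pfg[[match(w, uniq)]]
    v <- colSums(ctx$pi * rr$rest * (P %*% rr$sub))
    ifelse(v > 0, log(v), -Inf) + as.numeric(rr$logRest) + as.numeric(rr$logSub)
  }
  rbind(comb(rA, w0), comb(rB, 1), comb(rA, w2), comb(rB, w2))
}

# Per-class per-pattern log-likelihoods for arbitrary class structures via
# the generic kernel (proportions irrelevant).
.ctxCllGeneric <- function(ctx, kappa, classes, lengths = NULL) {
  if (is.null(lengths)) lengths <- ctx$lengths
  omegaByEdge <- do.call(rbind, lapply(classes, function(cl)
    unname(cl$omega[ctx$labels])))
  cllClasses(geneticCode()$pairType, ctx$pi, kappa, omegaByEdge, ctx$edge,
             lengths, ctx$states, ctx$nNode)
}

# R reference implementation of the generic per-class kernel (tests)
.ctxCllGenericRef <- function(ctx, kappa, classes, lengths = NULL) {
  dummy <- lapply(classes, function(cl) list(prop = 1 / length(classes),
                                             omega = cl$omega))
  .ctxLogLik(ctx, kappa, dummy, lengths = lengths,
             perClass = TRUE)$classPatternLogLik
}

# Maximize the mixture log-likelihood over the class proportions for fixed
# per-class pattern log-likelihoods. The proportions enter only the cheap
# mixing step, so they are profiled out of the expensive outer optimization
# by an EM iteration with a closed-form M-step (monotone and deterministic,
# so the profiled objective is smooth to machine precision for the outer
# quasi-Newton search).
#
# type "branchsite": proportions (q r, q(1-r), (1-q) r, (1-q)(1-r)) over the
# four classes, profiled over (q, r). type "simplex": free weights.
.profileMixture <- function(cll, siteWeights, type = c("branchsite", "simplex"),
                            start, tol = 1e-11, maxit = 2000) {
  type <- match.arg(type)
  if (type == "branchsite") {
    v <- profileBSMix(cll, siteWeights, start[1], start[2])
    return(list(logLik = v[1], par = v[2:3]))
  }
  v <- profileSimplexMix(cll, siteWeights, start)
  list(logLik = v[1], par = v[-1])
}

# R reference implementation of the proportion profiling (tests)
.profileMixtureRef <- function(cll, siteWeights,
                               type = c("branchsite", "simplex"),
                               start, tol = 1e-11, maxit = 2000) {
  type <- match.arg(type)
  base <- apply(cll, 2, max)
  base[!is.finite(base)] <- 0
  M <- exp(sweep(cll, 2, base))
  eps <- 1e-7
  nc <- nrow(cll)
  baseSum <- sum(siteWeights * base)
  toProps <- function(par) {
    if (type == "branchsite")
      c(par[1] * par[2], par[1] * (1 - par[2]),
        (1 - par[1]) * par[2], (1 - par[1]) * (1 - par[2]))
    else c(par, 1 - sum(par))
  }
  value <- function(par) {
    D <- colSums(toProps(par) * M)
    if (any(D <= 0)) return(-Inf)
    sum(siteWeights * log(D)) + baseSum
  }
  clampPar <- function(par) {
    if (type == "branchsite") return(pmin(pmax(par, eps), 1 - eps))
    par <- pmax(par, eps)
    tot <- sum(par)
    if (tot > 1 - eps) par <- par * (1 - eps) / tot
    par
  }
  # EM warmup (monotone, closed-form M-step) followed by damped Newton with
  # an adaptive Levenberg ridge; the deterministic solve from fixed starts
  # makes the profiled value a smooth function of the outer model parameters.
  solveFrom <- function(par) {
    par <- clampPar(par)
    for (it in 1:30) {
      props <- toProps(par)
      D <- colSums(props * M)
      if (any(D <= 0)) return(list(logLik = -Inf, par = par))
      Gam <- props * as.numeric(M %*% (siteWeights / D))
      tot <- sum(Gam)
      par <- clampPar(if (type == "branchsite")
        c((Gam[1] + Gam[2]) / tot, (Gam[1] + Gam[3]) / tot)
        else (Gam / tot)[-nc])
    }
    ll <- value(par)
    lam <- 1e-8
    stall <- 0L
    for (it in seq_len(200)) {
      props <- toProps(par)
      D <- colSums(props * M)
      g <- as.numeric(M %*% (siteWeights / D))     # d ll / d props
      U <- M * rep(sqrt(siteWeights) / D, each = nc)
      Hpp <- -tcrossprod(U)
      if (type == "branchsite") {
        q <- par[1]; r <- par[2]
        Jq <- c(r, 1 - r, -r, -(1 - r))
        Jr <- c(q, -q, 1 - q, -(1 - q))
        grad <- c(sum(g * Jq), sum(g * Jr))
        cross <- sum(g * c(1, -1, -1, 1))
        H <- matrix(c(Jq %*% Hpp %*% Jq, Jq %*% Hpp %*% Jr + cross,
                      Jq %*% Hpp %*% Jr + cross, Jr %*% Hpp %*% Jr), 2, 2)
      } else {
        grad <- g[-nc] - g[nc]
        H <- Hpp[-nc, -nc, drop = FALSE] -
          outer(Hpp[-nc, nc], rep(1, nc - 1)) -
          outer(rep(1, nc - 1), Hpp[nc, -nc]) + Hpp[nc, nc]
      }
      scale <- max(abs(diag(H)), 1)
      accepted <- FALSE
      for (tries in 1:12) {
        step <- tryCatch(solve(H - diag(lam * scale, length(par)), grad),
                         error = function(e) NULL)
        if (!is.null(step)) {
          if (sum(step * grad) > 0) step <- -step
          cand <- clampPar(par - step)
          llC <- value(cand)
          if (llC >= ll) {
            improved <- llC - ll
            par <- cand; ll <- llC
            lam <- max(lam / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lam <- lam * 10
      }
      if (!accepted || improved < tol) {
        stall <- stall + 1L
        if (stall >= 2L || !accepted) break
      } else stall <- 0L
    }
    list(logLik = ll, par = par)
  }
  best <- solveFrom(if (type == "branchsite") start
                    else (start / sum(start))[-nc])
  list(logLik = best$logLik,
       par = if (type == "branchsite") best$par
             else { p <- c(best$par, 1 - sum(best$par)); p / sum(p) })
}

# Per-class per-pattern log-likelihoods plus the mixture total.
# `kappa` and `classes` carry all parameter dependence; `lengths` may
# override the context's branch lengths (branch-length optimization).
.ctxLogLik <- function(ctx, kappa, classes, lengths = NULL, perClass = FALSE) {
  if (is.null(lengths)) lengths <- ctx$lengths
  omvals <- sort(unique(unlist(lapply(classes, function(cl) cl$omega))))
  decs <- lapply(omvals, function(w)
    .decomposeQ(.neutralScaledQ(kappa, w, ctx$freqObj), ctx$pi))
  E <- nrow(ctx$edge)
  Pcache <- lapply(seq_along(omvals), function(i) vector("list", E))
  npat <- ncol(ctx$states)
  nclass <- length(classes)
  cll <- matrix(-Inf, nclass, npat)
  for (ci in seq_len(nclass)) {
    cl <- classes[[ci]]
    omIdx <- match(unname(cl$omega[ctx$labels]), omvals)
    Ps <- vector("list", E)
    for (e in seq_len(E)) {
      i <- omIdx[e]
      if (is.null(Pcache[[i]][[e]]))
        Pcache[[i]][[e]] <- .Pfromdec(decs[[i]], lengths[e])
      Ps[[e]] <- Pcache[[i]][[e]]
    }
    cll[ci, ] <- prunePatterns(ctx$edge, Ps, ctx$states, ctx$pi, ctx$nNode)
  }
  props <- vapply(classes, function(cl) cl$prop, numeric(1))
  active <- props > 0
  lw <- log(props[active])
  M <- cll[active, , drop = FALSE] + lw
  m <- apply(M, 2, max)
  m0 <- ifelse(is.finite(m), m, 0)
  mix <- log(colSums(exp(sweep(M, 2, m0)))) + m0
  total <- sum(ctx$weights * mix)
  if (!perClass) return(list(logLik = total, patternLogLik = mix))
  list(logLik = total, patternLogLik = mix, classPatternLogLik = cll,
       props = props)
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Computes the phylogenetic log-likelihood of a codon alignment under a
#' site-class mixture model by Felsenstein pruning on the 61-state sense-codon
#' space. Each site's likelihood is a mixture over site classes weighted by
#' the class proportions, with the class determining the branch-specific
#' omega through the tree's partition labels. Gaps and ambiguous codons are
#' marginalized as missing data. Underflow is handled by log-space rescaling.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree A [LabeledTree-class] whose leaf set equals the alignment's
#'   taxa.
#' @param model A [SiteClassModel-class].
#' @return A list with \code{logLik} (total), \code{perSite} (per-codon-site
#'   log-likelihoods summing to the total) and, for site-class mixtures,
#'   \code{classPosterior} inputs are available via [sitePosteriors()].
#' @examples
#' tr <- labeledTree("((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
#' aln <- simulateAlignment(oneRatioModel(2, 0.3), tr, 30, seed = 1)$alignment
#' codonLogLik(aln, tr, oneRatioModel(2, 0.3))$logLik
#' @export
codonLogLik <- function(aln, tree, model) {
  .checkModelTree(model, tree)
  ctx <- .likContext(aln, tree, freqs = model@freqs)
  res <- .ctxLogLik(ctx, model@kappa, .classStructure(model))
  list(logLik = res$logLik, perSite = res$patternLogLik[ctx$patIndex])
}

.checkModelTree <- function(model, tree) {
  if (model@modelType %in% c("two-ratio", "branch-site")) {
    if (tree@kind != "selection" || !any(tree@edgeLabels == "foreground"))
      stop("a ", model@modelType,
           " analysis requires a tree with at least one foreground branch")
  }
  if (model@modelType == "relax") {
    if (tree@kind != "intensity" || !any(tree@edgeLabels == "test"))
      stop("a relax analysis requires a tree with a test/reference partition")
  }
  invisible(TRUE)
}
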
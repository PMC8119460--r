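#' Empirical-Bayes identification of positively selected sites
#'
#' Given a converged branch-site alternative fit, computes the posterior
#' probability that each codon site belongs to the positively selected
#' classes (2a + 2b) on the foreground, by Bayes' rule on the per-class site
#' likelihoods weighted by the estimated class proportions (naive empirical
#' Bayes with plug-in maximum-likelihood estimates). Sites with posterior
#' at or above the support threshold are flagged high-support.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree The [LabeledTree-class] used in the fit.
#' @param altFit A converged [CodonFit-class] from
#'   \code{fitBranchSite(..., null = FALSE)}.
#' @param referenceTaxon Taxon whose residue letters annotate the sites;
#'   default: the alphabetically first leaf descending from the (first)
#'   foreground branch.
#' @param threshold High-support threshold on the selected-class posterior
#'   (default 0.90).
#' @return data.frame with one row per codon site: \code{site} (1-based),
#'   \code{residue} (reference amino acid, \code{"-"} if missing),
#'   \code{posterior} (selected-class posterior), \code{highSupport}.
#'   Posteriors over the four classes sum to 1 at every site.
#' @export
sitePosteriors <- function(aln, tree, altFit, referenceTaxon = NULL,
                           threshold = 0.90) {
  if (!is(altFit, "CodonFit") || altFit@model != "branch-site-alt")
    stop("altFit must be a branch-site alternative fit")
  if (!altFit@converged) stop("refusing to compute posteriors from an unconverged fit")
  if (!altFit@informative)
    stop("refusing to compute posteriors from a non-informative fit")
  pp <- altFit@params
  model <- branchSiteModel(pp$kappa, pp$omega0, max(pp$omega2, 1),
                           pp$p0, pp$p1,
                           freqs = altFit@details$freqs %||% equalCodonFrequencies())
  ctx <- .likContext(aln, tree, freqs = model@freqs)
  res <- .ctxLogLik(ctx, model@kappa, .classStructure(model), perClass = TRUE)
  cll <- res$classPatternLogLik      # 4 x npatterns
  lw <- log(pmax(res$props, 0))
  M <- cll + lw
  m <- apply(M, 2, max)
  post <- exp(sweep(M, 2, m))
  post <- sweep(post, 2, colSums(post), "/")
  sel <- post[3, ] + post[4, ]       # classes 2a + 2b
  sel <- sel[ctx$patIndex]

  refTaxon <- referenceTaxon %||% .defaultReferenceTaxon(tree)
  if (!refTaxon %in% aln@taxa) stop("reference taxon '", refTaxon,
                                    "' not in alignment")
  gc <- geneticCode()
  st <- aln@states[match(refTaxon, aln@taxa), ]
  residue <- ifelse(st > 0L, unname(gc$aa[st]), "-")
  data.frame(site = seq_along(sel), residue = residue, posterior = sel,
             highSupport = sel >= threshold)
}

# alphabetically first leaf below the first foreground branch
.defaultReferenceTaxon <- function(tree) {
  fg <- foregroundEdges(tree)
  if (length(fg) == 0L) return(sort(tree@tree$tip.label)[1])
  child <- tree@tree$edge[fg[1], 2]
  nTip <- length(tree@tree$tip.label)
  tips <- if (child <= nTip) tree@tree$tip.label[child]
          else tree@tree$tip.label[.cladeTips(tree@tree, child)]
  sort(tips)[1]
}

.cladeTips <- function(tr, node) {
  nTip <- length(tr$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= nTip])
    stack <- c(stack, ch[ch > nTip])
  }
  out
}
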
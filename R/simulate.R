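#' Simulate a codon alignment along a labeled tree
#'
#' Generates a codon alignment under a site-class mixture model: each site is
#' assigned a class i.i.d. from the class proportions, the root codon is drawn
#' from the stationary frequencies, and evolution proceeds along each branch
#' by the class- and partition-specific transition probabilities. The true
#' per-site class assignment is returned alongside the data.
#'
#' @param model A [SiteClassModel-class].
#' @param tree A [LabeledTree-class] (its labels select the per-branch omega
#'   of each class).
#' @param nCodons Number of codon sites.
#' @param seed Optional integer seed; a fixed seed gives bit-identical output.
#' @param geneId Gene identifier for the alignment.
#' @return List with \code{alignment} ([CodonAlignment-class]), \code{truth}
#'   (data.frame \code{site}, \code{class}) and \code{model}.
#' @examples
#' tr <- labeledTree("((A:0.2,B:0.2):0.2,C:0.2,D:0.2);")
#' sim <- simulateAlignment(oneRatioModel(2, 0.3), tr, 50, seed = 7)
#' sim$alignment
#' @export
simulateAlignment <- function(model, tree, nCodons, seed = NULL,
                              geneId = "simgene") {
  if (nCodons < 1) stop("nCodons must be positive")
  if (!is.null(seed)) set.seed(seed)
  classes <- .classStructure(model)
  pi <- model@freqs@freqs
  tr <- tree@tree
  post <- ape::reorder.phylo(tr, "postorder")
  keyOrig <- paste(tr$edge[, 1], tr$edge[, 2])
  keyPost <- paste(post$edge[, 1], post$edge[, 2])
  labPost <- tree@edgeLabels[match(keyPost, keyOrig)]
  nTip <- length(tr$tip.label)
  nNode <- tr$Nnode
  props <- vapply(classes, function(cl) cl$prop, numeric(1))
  siteClass <- sample.int(length(classes), nCodons, replace = TRUE,
                          prob = props)
  states <- matrix(0L, nTip + nNode, nCodons)
  root <- post$edge[nrow(post$edge), 1]
  states[root, ] <- sample.int(61L, nCodons, replace = TRUE, prob = pi)
  # preorder = reversed postorder; parents are simulated before children
  omvals <- sort(unique(unlist(lapply(classes, function(cl) cl$omega))))
  decs <- lapply(omvals, function(w)
    .decomposeQ(.neutralScaledQ(model@kappa, w, model@freqs), pi))
  for (e in rev(seq_len(nrow(post$edge)))) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    t <- post$edge.length[e]
    for (ci in unique(siteClass)) {
      idx <- which(siteClass == ci)
      w <- unname(classes[[ci]]$omega[labPost[e]])
      P <- .Pfromdec(decs[[match(w, omvals)]], t)
      P[P < 1e-300] <- 0
      parStates <- states[parent, idx]
      for (s in unique(parStates)) {
        ii <- idx[parStates == s]
        states[child, ii] <- sample.int(61L, length(ii), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  gcc <- geneticCode()
  seqs <- apply(states[seq_len(nTip), , drop = FALSE], 1, function(row)
    paste0(gcc$codons[row], collapse = ""))
  names(seqs) <- tr$tip.label
  list(alignment = codonAlignment(seqs, geneId = geneId),
       truth = data.frame(site = seq_len(nCodons), class = siteClass),
       model = model)
}

#' Balanced or pectinate simulation tree with a labeled branch
#'
#' Builds the desk-scale simulation tree used throughout the package's
#' calibration and power studies: \code{nTaxa} tips, every branch of length
#' \code{branchLength}, unrooted (basal trifurcation), with one internal
#' branch labeled as foreground (selection kind) or test vs a reference
#' branch (intensity kind).
#'
#' @param nTaxa Number of tips (>= 4).
#' @param branchLength Length of every branch, in expected substitutions per
#'   codon.
#' @param shape \code{"balanced"} or \code{"pectinate"}.
#' @param kind \code{"selection"} (one foreground branch),
#'   \code{"intensity"} (one test and one reference branch) or \code{"none"}.
#' @return A [LabeledTree-class].
#' @export
simulationTree <- function(nTaxa = 8, branchLength = 0.2,
                           shape = c("balanced", "pectinate"),
                           kind = c("selection", "intensity", "none")) {
  shape <- match.arg(shape)
  kind <- match.arg(kind)
  if (nTaxa < 4) stop("need at least 4 taxa")
  tips <- paste0("t", seq_len(nTaxa))
  nest <- function(v) {
    if (length(v) == 1) return(v)
    h <- ceiling(length(v) / 2)
    paste0("(", nest(v[1:h]), ",", nest(v[(h + 1):length(v)]), ")")
  }
  # basal trifurcation makes the tree explicitly unrooted
  newick <- if (shape == "balanced") {
    a <- ceiling(nTaxa / 3); b <- ceiling(2 * nTaxa / 3)
    paste0("(", nest(tips[1:a]), ",", nest(tips[(a + 1):b]), ",",
           nest(tips[(b + 1):nTaxa]), ");")
  } else {
    inner <- tips[1]
    for (i in 2:(nTaxa - 2)) inner <- paste0("(", inner, ",", tips[i], ")")
    paste0("(", inner, ",", tips[nTaxa - 1], ",", tips[nTaxa], ");")
  }
  tr <- ape::read.tree(text = newick)
  tr$edge.length <- rep(branchLength, nrow(tr$edge))
  nTip <- length(tr$tip.label)
  internal <- which(tr$edge[, 2] > nTip)
  if (kind == "selection")
    labeledTree(tr, foreground = internal[1])
  else if (kind == "intensity") {
    ref <- if (length(internal) >= 2) internal[2]
           else which(tr$edge[, 2] <= nTip)[1]
    labeledTree(tr, test = internal[1], reference = ref)
  } else labeledTree(tr)
}
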
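#' Specify a synthetic gene-panel scenario
#'
#' A scenario describes a panel of genes evolving on a shared tree where a
#' chosen foreground branch has a subset of genes under positive selection,
#' with pathway membership structured to mimic an ancestral-diet signature:
#' a \code{"carnivore-ancestor"} places selected genes predominantly in the
#' protein and fat pathways (PDA/FDA), an \code{"herbivore-ancestor"} in the
#' carbohydrate and fat pathways (CDA/FDA), and \code{"null"} has no selected
#' genes.
#'
#' @param tag Scenario tag.
#' @param nGenes Panel size (default 30, the package's desk-scale panel).
#' @param pathwayProbs Membership distribution over CDA/PDA/FDA.
#' @param selectedFraction Named per-pathway probability that a gene is under
#'   foreground positive selection; defaults follow the tag (0.5 in the two
#'   favoured pathways, 0.08 in the disfavoured one, 0 for null).
#' @param omega2 Foreground dN/dS of selected sites in selected genes
#'   (default 8).
#' @param siteFraction Fraction of sites in the selected classes (2a + 2b)
#'   of selected genes (default 0.3).
#' @param nCodons,nTaxa,branchLength,kappa,omega0 Simulation conditions
#'   (defaults: 300 codons, 8 taxa, 0.2 substitutions/codon per branch,
#'   kappa 2, omega0 0.2).
#' @return A list of class \code{"ScenarioSpec"}.
#' @export
scenarioSpec <- function(tag = c("herbivore-ancestor", "carnivore-ancestor",
                                 "null"),
                         nGenes = 30, pathwayProbs = c(CDA = 1/3, PDA = 1/3,
                                                       FDA = 1/3),
                         selectedFraction = NULL, omega2 = 8,
                         siteFraction = 0.3, nCodons = 300, nTaxa = 8,
                         branchLength = 0.2, kappa = 2, omega0 = 0.2) {
  tag <- match.arg(tag)
  if (nGenes < 1) stop("panel size must be positive")
  if (siteFraction < 0 || siteFraction > 1) stop("siteFraction must lie in [0, 1]")
  if (is.null(selectedFraction))
    selectedFraction <- switch(tag,
      "herbivore-ancestor" = c(CDA = 0.5, PDA = 0.08, FDA = 0.5),
      "carnivore-ancestor" = c(CDA = 0.08, PDA = 0.5, FDA = 0.5),
      "null" = c(CDA = 0, PDA = 0, FDA = 0))
  if (any(selectedFraction < 0 | selectedFraction > 1))
    stop("selected fractions must lie in [0, 1]")
  structure(list(tag = tag, nGenes = as.integer(nGenes),
                 pathwayProbs = pathwayProbs / sum(pathwayProbs),
                 selectedFraction = selectedFraction, omega2 = omega2,
                 siteFraction = siteFraction, nCodons = nCodons,
                 nTaxa = nTaxa, branchLength = branchLength, kappa = kappa,
                 omega0 = omega0),
            class = "ScenarioSpec")
}

#' Simulate a gene panel under a scenario
#'
#' One codon alignment per gene, a shared labeled tree, a truth table
#' recording which genes and pathways carry selection, and the matching
#' pathway catalog.
#'
#' @param spec A [scenarioSpec()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param tree Optional [LabeledTree-class]; default [simulationTree()] at
#'   the scenario's conditions.
#' @return List with \code{alignments}, \code{tree}, \code{truth}
#'   (data.frame gene/pathway/selected/omega2), \code{catalog}.
#' @export
simulatePanel <- function(spec, seed = 1, tree = NULL) {
  if (!inherits(spec, "ScenarioSpec")) stop("spec must come from scenarioSpec()")
  set.seed(seed)
  if (is.null(tree))
    tree <- simulationTree(spec$nTaxa, spec$branchLength, kind = "selection")
  genes <- sprintf("gene%03d", seq_len(spec$nGenes))
  # stratified allocation: pathway membership and per-pathway selected
  # fractions are honored exactly (up to rounding), so every panel's truth
  # matches the scenario's stated profile; only which genes carry the
  # selection is random
  pws <- names(spec$pathwayProbs)
  nPer <- floor(spec$pathwayProbs * spec$nGenes)
  rem <- spec$nGenes - sum(nPer)
  if (rem > 0) {
    extra <- order(spec$pathwayProbs * spec$nGenes - nPer,
                   decreasing = TRUE)[seq_len(rem)]
    nPer[extra] <- nPer[extra] + 1L
  }
  pw <- sample(rep(pws, times = nPer))
  selected <- logical(spec$nGenes)
  for (p in pws) {
    idx <- which(pw == p)
    nSel <- round(spec$selectedFraction[[p]] * length(idx))
    if (nSel > 0) selected[sample(idx, nSel)] <- TRUE
  }
  f <- spec$siteFraction
  p0 <- (1 - f) * 0.7; p1 <- (1 - f) * 0.3
  alignments <- vector("list", spec$nGenes)
  for (i in seq_len(spec$nGenes)) {
    w2 <- if (selected[i]) spec$omega2 else 1
    model <- branchSiteModel(spec$kappa, spec$omega0, w2, p0, p1)
    alignments[[i]] <- simulateAlignment(model, tree, spec$nCodons,
                                         geneId = genes[i])$alignment
  }
  names(alignments) <- genes
  truth <- data.frame(gene = genes, pathway = pw, selected = selected,
                      omega2 = ifelse(selected, spec$omega2, 1))
  catalog <- new("PathwayCatalog",
                 mapping = stats::setNames(as.list(pw), genes),
                 accessions = c(CDA = "map04973", PDA = "map04974",
                                FDA = "map04975"))
  list(alignments = alignments, tree = tree, truth = truth, catalog = catalog)
}

#' Run a scenario end to end
#'
#' Simulates a panel, scans it with the branch-site test, aggregates the PSGs
#' into a pathway profile and emits the diet call.
#'
#' @inheritParams simulatePanel
#' @param branchName Branch identifier for the profile.
#' @param alpha PSG inclusion threshold.
#' @param control Optimizer control passed to [runGenePanel()].
#' @return List with \code{records}, \code{profile} ([PathwayProfile-class]),
#'   \code{diet} ([DietCall-class]), \code{truth}.
#' @export
runScenario <- function(spec, seed = 1, branchName = spec$tag, alpha = 0.05,
                        control = list()) {
  panel <- simulatePanel(spec, seed = seed)
  records <- runGenePanel(panel$alignments, panel$tree,
                          branchName = branchName, alpha = alpha,
                          control = control)
  profile <- aggregateProfile(records, panel$catalog, branch = branchName)
  diet <- callDiet(profile)
  list(records = records, profile = profile, diet = diet,
       truth = panel$truth)
}
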
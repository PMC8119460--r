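#' @import methods
NULL

setOldClass("phylo")

#' Codon alignment container
#'
#' Stores an in-frame coding-sequence alignment as a taxa x codon-site matrix
#' over the sense-codon alphabet. Codons containing a gap (\code{-}) or an
#' ambiguity (\code{N}) are treated as missing data and encoded as 0; sense
#' codons are encoded as their index (1..61) in \code{geneticCode()$codons}.
#' In-frame stop codons are rejected at construction.
#'
#' @slot geneId Single gene identifier.
#' @slot taxa Ordered taxon names (unique).
#' @slot states Integer matrix (taxa x codon sites) of codon state indices,
#'   0 = missing.
#' @seealso [codonAlignment()], [readCodonFasta()]
#' @exportClass CodonAlignment
setClass("CodonAlignment",
         representation(geneId = "character", taxa = "character",
                        states = "matrix"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be a single string")
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicate taxon names")
  if (!is.integer(object@states)) msg <- c(msg, "states must be an integer matrix")
  if (nrow(object@states) != length(object@taxa))
    msg <- c(msg, "states must have one row per taxon")
  if (length(object@states) && (min(object@states) < 0L || max(object@states) > 61L))
    msg <- c(msg, "codon state indices must lie in 0..61")
  if (length(msg)) msg else TRUE
})

#' Phylogeny with a branch partition
#'
#' An unrooted species tree (an \pkg{ape} \code{phylo} with branch lengths in
#' expected substitutions per codon) whose branches carry a partition label:
#' \code{"background"}/\code{"foreground"} for selection tests, or
#' \code{"reference"}/\code{"test"}/\code{"unclassified"} for
#' selection-intensity tests. Labels are per edge of \code{tree$edge}.
#'
#' @slot tree An \code{ape::phylo} object.
#' @slot edgeLabels Character vector, one label per edge.
#' @slot kind Labeling dialect: \code{"selection"}, \code{"intensity"} or
#'   \code{"none"}.
#' @seealso [labeledTree()], [readLabeledNewick()], [labelBranch()]
#' @exportClass LabeledTree
setClass("LabeledTree",
         representation(tree = "phylo", edgeLabels = "character",
                        kind = "character"))

setValidity("LabeledTree", function(object) {
  msg <- character()
  tr <- object@tree
  if (is.null(tr$edge.length)) msg <- c(msg, "tree must have branch lengths")
  else if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    msg <- c(msg, "branch lengths must be finite and non-negative")
  if (anyDuplicated(tr$tip.label)) msg <- c(msg, "duplicate leaf names")
  if (length(object@edgeLabels) != nrow(tr$edge))
    msg <- c(msg, "edgeLabels must have one entry per edge")
  ok <- switch(object@kind,
               selection = c("background", "foreground"),
               intensity = c("reference", "test", "unclassified"),
               none = "background",
               NULL)
  if (is.null(ok)) msg <- c(msg, "kind must be selection/intensity/none")
  else if (!all(object@edgeLabels %in% ok))
    msg <- c(msg, paste0("edge labels must be in {", paste(ok, collapse = ", "), "}"))
  if (length(msg)) msg else TRUE
})

#' Stationary codon frequencies
#'
#' @slot freqs Numeric vector of 61 stationary probabilities (sense codons).
#' @slot scheme Estimation scheme tag: \code{"equal"}, \code{"F1x4"},
#'   \code{"F3x4"} or \code{"empirical"}.
#' @seealso [estimateCodonFrequencies()]
#' @exportClass CodonFrequencies
setClass("CodonFrequencies",
         representation(freqs = "numeric", scheme = "character"))

setValidity("CodonFrequencies", function(object) {
  msg <- character()
  if (length(object@freqs) != 61L) msg <- c(msg, "need 61 sense-codon frequencies")
  if (any(object@freqs < 0)) msg <- c(msg, "frequencies must be non-negative")
  if (abs(sum(object@freqs) - 1) > 1e-12) msg <- c(msg, "frequencies must sum to 1")
  if (!object@scheme %in% c("equal", "F1x4", "F3x4", "empirical"))
    msg <- c(msg, "unknown frequency scheme")
  if (length(msg)) msg else TRUE
})

#' Site-class mixture model for codon evolution
#'
#' Describes the mixture of site classes used by the branch-site model and its
#' relatives: class proportions, per-class per-partition dN/dS values, the
#' transition/transversion ratio kappa, and stationary frequencies. For the
#' branch-site model the four classes are 0 (conserved everywhere), 1 (neutral
#' everywhere), 2a (conserved on background, omega2 on foreground) and 2b
#' (neutral on background, omega2 on foreground); proportions of 2a and 2b are
#' derived from p0, p1 in proportion p0:p1. For RELAX-style models, class
#' omegas on test branches are the reference omegas raised to the exponent k.
#'
#' @slot modelType One of \code{"one-ratio"}, \code{"two-ratio"},
#'   \code{"branch-site"}, \code{"relax"}.
#' @slot kappa Transition/transversion rate ratio (> 0).
#' @slot omegas Named numeric vector of dN/dS parameters (interpretation
#'   depends on modelType; see Details).
#' @slot proportions Named numeric vector of site-class proportions summing
#'   to 1.
#' @slot k RELAX selection-intensity exponent (1 outside relax models).
#' @slot freqs A [CodonFrequencies-class] object.
#' @exportClass SiteClassModel
setClass("SiteClassModel",
         representation(modelType = "character", kappa = "numeric",
                        omegas = "numeric", proportions = "numeric",
                        k = "numeric", freqs = "CodonFrequencies"))

setValidity("SiteClassModel", function(object) {
  msg <- character()
  if (!object@modelType %in% c("one-ratio", "two-ratio", "branch-site", "relax"))
    msg <- c(msg, "unknown modelType")
  if (!is.finite(object@kappa) || object@kappa <= 0)
    msg <- c(msg, "kappa must be positive and finite")
  if (any(!is.finite(object@omegas)) || any(object@omegas < 0))
    msg <- c(msg, "omegas must be finite and non-negative")
  if (any(object@proportions < 0) ||
      abs(sum(object@proportions) - 1) > 1e-8)
    msg <- c(msg, "class proportions must be non-negative and sum to 1")
  if (!is.finite(object@k) || object@k < 0) msg <- c(msg, "k must be >= 0")
  if (object@modelType == "branch-site") {
    if (!all(c("omega0", "omega2") %in% names(object@omegas)))
      msg <- c(msg, "branch-site model needs omega0 and omega2")
    else {
      if (object@omegas[["omega0"]] >= 1) msg <- c(msg, "omega0 must be < 1")
      if (object@omegas[["omega2"]] < 1) msg <- c(msg, "omega2 must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of a codon model
#'
#' @slot model Model tag (e.g. \code{"branch-site-alt"}).
#' @slot logLik Maximized log-likelihood.
#' @slot params Named list of parameter estimates (kappa, omegas, proportions,
#'   optionally branch lengths).
#' @slot np Number of free parameters.
#' @slot converged Convergence flag.
#' @slot restarts Number of optimizer starts used.
#' @slot capped Names of parameters estimated at a configured bound
#'   (e.g. omega2 at the 999 reporting cap).
#' @slot informative FALSE when the data carry no signal for the parameter of
#'   interest (e.g. identical sequences, zero-length foreground branch).
#' @slot details List of internals (site log-likelihood matrices, class
#'   proportions, frequency object, tree) used by downstream operations.
#' @exportClass CodonFit
setClass("CodonFit",
         representation(model = "character", logLik = "numeric",
                        params = "list", np = "integer", converged = "logical",
                        restarts = "integer", capped = "character",
                        informative = "logical", details = "list"))

setValidity("CodonFit", function(object) {
  msg <- character()
  if (length(object@logLik) != 1L || (object@converged && !is.finite(object@logLik)))
    msg <- c(msg, "logLik must be a single finite value on success")
  if (object@np < 0L) msg <- c(msg, "np must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Likelihood-ratio test result
#'
#' @slot stat 2*(lnL_alt - lnL_null), clamped at 0.
#' @slot df Degrees of freedom.
#' @slot p Upper-tail chi-square p-value.
#' @slot pAdjusted Bonferroni-adjusted p-value, min(1, p * nTests).
#' @slot nTests Number of tests used for the adjustment.
#' @exportClass LRTResult
setClass("LRTResult",
         representation(stat = "numeric", df = "numeric", p = "numeric",
                        pAdjusted = "numeric", nTests = "numeric"))

setValidity("LRTResult", function(object) {
  msg <- character()
  if (object@stat < 0) msg <- c(msg, "stat must be >= 0 after clamping")
  if (object@df < 1) msg <- c(msg, "df must be >= 1")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (abs(object@pAdjusted - min(1, object@p * object@nTests)) > 1e-12)
    msg <- c(msg, "pAdjusted must equal min(1, p * nTests)")
  if (length(msg)) msg else TRUE
})

#' Per-gene positive-selection record
#'
#' One gene's branch-site test on one foreground branch: the LRT, the
#' foreground omega2 estimate, and empirical-Bayes site posteriors. A gene is
#' flagged as a PSG when the (uncorrected) LRT p-value passes the configured
#' threshold and the foreground omega exceeds 1.
#'
#' @slot gene Gene identifier.
#' @slot branch Foreground-branch identifier.
#' @slot nTaxa Number of species in the gene's alignment.
#' @slot lrt An [LRTResult-class].
#' @slot omegaFg Foreground omega2 estimate (shared by classes 2a/2b).
#' @slot omegaCapped TRUE when omega2 sits at the reporting cap.
#' @slot sites data.frame of candidate selected sites (site, residue,
#'   posterior, highSupport) with posterior of the selected class > 0.5.
#' @slot isPSG Inclusion flag.
#' @slot status \code{"ok"} or a failure/uninformative note.
#' @exportClass PSGRecord
setClass("PSGRecord",
         representation(gene = "character", branch = "character",
                        nTaxa = "integer", lrt = "LRTResult",
                        omegaFg = "numeric", omegaCapped = "logical",
                        sites = "data.frame", isPSG = "logical",
                        status = "character"))

#' RELAX-style selection-intensity result
#'
#' @slot gene Gene identifier.
#' @slot k Selection-intensity exponent estimate.
#' @slot logLikAlt,logLikNull Maximized log-likelihoods of the alternative
#'   (k free) and null (k = 1) models.
#' @slot lrt An [LRTResult-class] with df = 1.
#' @slot classification \code{"intensified"} (k > 1, significant),
#'   \code{"relaxed"} (k < 1, significant) or \code{"no-change"}.
#' @slot converged Convergence flag.
#' @slot status \code{"ok"} or a failure note.
#' @exportClass RelaxResult
setClass("RelaxResult",
         representation(gene = "character", k = "numeric",
                        logLikAlt = "numeric", logLikNull = "numeric",
                        lrt = "LRTResult", classification = "character",
                        converged = "logical", status = "character"))

setValidity("RelaxResult", function(object) {
  msg <- character()
  cls <- object@classification
  if (!cls %in% c("intensified", "relaxed", "no-change"))
    msg <- c(msg, "unknown classification")
  if (length(msg)) msg else TRUE
})

#' Gene-to-pathway catalog
#'
#' Maps genes to one or more digestion-and-absorption pathways: CDA
#' (carbohydrate, map04973), PDA (protein, map04974), FDA (fat, map04975).
#'
#' @slot mapping Named list: gene -> character vector of pathway tags.
#' @slot accessions Named character vector of pathway accessions.
#' @seealso [readPathwayCatalog()], [defaultPathwayCatalog()]
#' @exportClass PathwayCatalog
setClass("PathwayCatalog",
         representation(mapping = "list", accessions = "character"))

setValidity("PathwayCatalog", function(object) {
  msg <- character()
  tags <- unique(unlist(object@mapping))
  if (!all(tags %in% c("CDA", "PDA", "FDA")))
    msg <- c(msg, "pathway tags must be drawn from {CDA, PDA, FDA}")
  if (any(lengths(object@mapping) == 0L))
    msg <- c(msg, "every gene must belong to at least one pathway")
  if (length(msg)) msg else TRUE
})

#' Per-branch pathway profile of positively selected genes
#'
#' @slot branch Branch identifier.
#' @slot counts Named integer vector of PSG counts per pathway
#'   (multi-membership genes counted in every pathway they belong to).
#' @slot minP Named numeric vector: smallest uncorrected p among the pathway's
#'   PSGs (NA when the pathway has none).
#' @slot genes Named list of PSG gene vectors per pathway.
#' @slot ranking Pathways ordered by descending count, ties broken by smaller
#'   minimum p; zero-length when all counts are zero.
#' @exportClass PathwayProfile
setClass("PathwayProfile",
         representation(branch = "character", counts = "integer",
                        minP = "numeric", genes = "list",
                        ranking = "character"))

setValidity("PathwayProfile", function(object) {
  msg <- character()
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (!identical(sort(names(object@counts)), sort(names(object@minP))))
    msg <- c(msg, "counts and minP must cover the same pathways")
  if (length(msg)) msg else TRUE
})

#' Rule-based ancestral-diet call
#'
#' @slot branch Branch identifier.
#' @slot category One of \code{"carnivore"}, \code{"herbivore"},
#'   \code{"omnivore-ambiguous"}, \code{"indeterminate"}.
#' @slot subtype For herbivore calls, the marker-refined subtype
#'   (\code{"fruit"}, \code{"seed/nut"}, \code{"fruit/seed/nut"} or
#'   \code{"unrefined"}); \code{NA} otherwise.
#' @slot nutrientEmphasis Human-readable summary of the inferred
#'   carbohydrate/protein/fat emphasis.
#' @slot markers data.frame of marker-gene annotations that fired.
#' @slot evidence Character vector: the rules fired, in order.
#' @exportClass DietCall
setClass("DietCall",
         representation(branch = "character", category = "character",
                        subtype = "character", nutrientEmphasis = "character",
                        markers = "data.frame", evidence = "character"))

setValidity("DietCall", function(object) {
  msg <- character()
  if (!object@category %in% c("carnivore", "herbivore", "omnivore-ambiguous",
                              "indeterminate"))
    msg <- c(msg, "unknown diet category")
  if (object@category != "indeterminate" && length(object@evidence) == 0L)
    msg <- c(msg, "evidence trail must be non-empty for a determinate call")
  if (length(msg)) msg else TRUE
})
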
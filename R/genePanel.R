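#' Branch-site selection scan over a gene panel
#'
#' Runs the branch-site positive-selection test for every gene in a panel and
#' assembles per-gene [PSGRecord-class]s. A gene is flagged as a positively
#' selected gene (PSG) when its uncorrected LRT p-value is below \code{alpha}
#' and the foreground omega2 estimate exceeds 1 (Bonferroni-adjusted p-values
#' are reported alongside but do not gate inclusion). Per-gene failures are
#' recorded in the record's \code{status} and do not abort the scan.
#'
#' @param alignments Named list of [CodonAlignment-class] objects (or a list
#'   of tasks, each \code{list(aln = , tree = )} for per-gene trees).
#' @param tree A [LabeledTree-class] with a foreground branch, shared by all
#'   genes (ignored for task lists carrying their own trees).
#' @param branchName Label stored in each record (e.g. \code{"ancestral_bird"}).
#' @param alpha Uncorrected p-value threshold for PSG inclusion (default 0.05).
#' @param nTests Bonferroni multiplier (default 2).
#' @param frequencies Frequency scheme tag.
#' @param referenceTaxon Passed to [sitePosteriors()].
#' @param posteriorCutoff Sites with selected-class posterior above this value
#'   are listed in the record (default 0.5).
#' @param control Optimizer control passed to [fitBranchSite()].
#' @return List of [PSGRecord-class], ordered by gene name.
#' @seealso [psgTable()], [aggregateProfile()]
#' @export
runGenePanel <- function(alignments, tree = NULL, branchName = "foreground",
                         alpha = 0.05, nTests = 2, frequencies = "F3x4",
                         referenceTaxon = NULL, posteriorCutoff = 0.5,
                         control = list()) {
  if (length(alignments) == 0L) stop("empty gene panel")
  tasks <- lapply(alignments, function(a) {
    if (is(a, "CodonAlignment")) list(aln = a, tree = tree)
    else if (is.list(a) && is(a$aln, "CodonAlignment")) {
      if (is.null(a$tree)) a$tree <- tree
      a
    } else stop("panel entries must be CodonAlignment objects or list(aln=, tree=)")
  })
  genes <- vapply(tasks, function(t) t$aln@geneId, character(1))
  ord <- order(genes)
  tasks <- tasks[ord]; genes <- genes[ord]
  records <- lapply(seq_along(tasks), function(i) {
    t <- tasks[[i]]
    tryCatch(
      .geneRecord(t$aln, t$tree, branchName, alpha, nTests, frequencies,
                  referenceTaxon, posteriorCutoff, control),
      error = function(e) .failedRecord(genes[i], branchName,
                                        conditionMessage(e)))
  })
  names(records) <- genes
  records
}

.geneRecord <- function(aln, tree, branchName, alpha, nTests, frequencies,
                        referenceTaxon, posteriorCutoff, control) {
  if (is.null(tree)) stop("no tree supplied for gene ", aln@geneId)
  bst <- branchSiteTest(aln, tree, frequencies = frequencies, nTests = nTests,
                        control = control)
  if (!bst$alt@converged || !bst$null@converged)
    return(.failedRecord(aln@geneId, branchName, "optimizer did not converge"))
  if (!bst$alt@informative)
    return(.failedRecord(aln@geneId, branchName,
                         bst$alt@details$note %||% "non-informative data",
                         lrt = bst$lrt))
  omegaFg <- bst$alt@params$omega2
  isPSG <- bst$lrt@p < alpha && omegaFg > 1
  sites <- data.frame(site = integer(0), residue = character(0),
                      posterior = numeric(0), highSupport = logical(0))
  if (isPSG) {
    sp <- sitePosteriors(aln, tree, bst$alt, referenceTaxon = referenceTaxon)
    sites <- sp[sp$posterior > posteriorCutoff, , drop = FALSE]
    rownames(sites) <- NULL
  }
  new("PSGRecord", gene = aln@geneId, branch = branchName,
      nTaxa = length(aln@taxa), lrt = bst$lrt, omegaFg = omegaFg,
      omegaCapped = "omega2" %in% bst$alt@capped, sites = sites,
      isPSG = isPSG, status = "ok")
}

.failedRecord <- function(gene, branch, msg, lrt = NULL) {
  new("PSGRecord", gene = gene, branch = branch, nTaxa = NA_integer_,
      lrt = lrt %||% new("LRTResult", stat = 0, df = 1, p = 1, pAdjusted = 1,
                         nTests = 1),
      omegaFg = NA_real_, omegaCapped = FALSE,
      sites = data.frame(), isPSG = FALSE, status = msg)
}

setMethod("show", "PSGRecord", function(object) {
  cat("PSGRecord ", object@gene, " [", object@branch, "] ",
      if (object@isPSG) "PSG" else "not selected",
      ": 2dlnL = ", formatC(object@lrt@stat, format = "f", digits = 2),
      ", p = ", format(object@lrt@p, digits = 4),
      ", omega_fg = ", formatC(object@omegaFg, format = "f", digits = 2),
      if (object@omegaCapped) " (capped)" else "",
      ", ", nrow(object@sites), " candidate sites",
      if (object@status != "ok") paste0(" [", object@status, "]") else "",
      "\n", sep = "")
})

#' Tabulate a panel scan
#'
#' Flattens a list of [PSGRecord-class]s into a tidy data.frame mirroring the
#' columns of a published selection-scan table: gene, N, 2dlnL, df, p,
#' Bonferroni p, foreground omega, and the candidate selected sites (sites
#' with >= 90 percent posterior support marked with \code{^}).
#'
#' @param records List of [PSGRecord-class] (from [runGenePanel()]).
#' @return data.frame, one row per gene.
#' @export
psgTable <- function(records) {
  rows <- lapply(records, function(r) {
    sites <- if (nrow(r@sites)) paste0(r@sites$site, r@sites$residue,
                                       ifelse(r@sites$highSupport, "^", ""),
                                       collapse = ", ") else ""
    data.frame(gene = r@gene, branch = r@branch, n_taxa = r@nTaxa,
               stat = r@lrt@stat, df = r@lrt@df, p = r@lrt@p,
               p_bonferroni = r@lrt@pAdjusted, omega_fg = r@omegaFg,
               omega_capped = r@omegaCapped, n_sites = nrow(r@sites),
               sites = sites, is_psg = r@isPSG, status = r@status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
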
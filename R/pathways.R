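#' Read a gene-to-pathway catalog
#'
#' Two-column delimited text: gene identifier and a semicolon-separated list
#' of pathway tags (CDA, PDA, FDA). Multi-membership is allowed (a gene may
#' sit in several pathways and is then counted in each).
#'
#' @param path Path to the catalog file (TSV with header
#'   \code{gene<TAB>pathways}).
#' @return A [PathwayCatalog-class].
#' @export
readPathwayCatalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathways") %in% names(df)))
    stop("catalog must have columns 'gene' and 'pathways'")
  mapping <- stats::setNames(strsplit(df$pathways, ";\\s*"), df$gene)
  new("PathwayCatalog", mapping = mapping,
      accessions = c(CDA = "map04973", PDA = "map04974", FDA = "map04975"))
}

#' Bundled digestion-and-absorption pathway catalog
#'
#' The catalog of digestive system-related genes assigned to the KEGG
#' carbohydrate (CDA, map04973), protein (PDA, map04974) and fat (FDA,
#' map04975) digestion-and-absorption pathways used by the ancestral-diet
#' analyses.
#'
#' @return A [PathwayCatalog-class].
#' @export
defaultPathwayCatalog <- function()
  readPathwayCatalog(system.file("extdata", "pathway_catalog.tsv",
                                 package = "phylotroph", mustWork = TRUE))

#' Bundled dietary marker-gene table
#'
#' Two marker genes with diet-indicative substrate specificity: SLC2A5
#' (GLUT5, the fructose transporter, a fruit-sugar signal) and ABCG5
#' (sterolin-1, plant-sterol elimination, a seed/nut signal). Extensible by
#' passing a data.frame of the same shape to [callDiet()].
#'
#' @return data.frame with columns \code{gene}, \code{signal}
#'   (\code{"fruit-sugar"} or \code{"plant-sterol"}), \code{evidence}.
#' @export
defaultMarkerTable <- function()
  utils::read.delim(system.file("extdata", "marker_table.tsv",
                                package = "phylotroph", mustWork = TRUE),
                    stringsAsFactors = FALSE)

# normalize PSG input: list of PSGRecord (filtered on isPSG) or a data.frame
# with columns gene, p (optionally is_psg)
.psgFrame <- function(psgs) {
  if (is.data.frame(psgs)) {
    if (!all(c("gene", "p") %in% names(psgs)))
      stop("PSG data.frame needs columns 'gene' and 'p'")
    if ("is_psg" %in% names(psgs)) psgs <- psgs[psgs$is_psg, , drop = FALSE]
    return(psgs[, c("gene", "p")])
  }
  recs <- Filter(function(r) is(r, "PSGRecord") && r@isPSG, psgs)
  data.frame(gene = vapply(recs, function(r) r@gene, character(1)),
             p = vapply(recs, function(r) r@lrt@p, numeric(1)))
}

#' Aggregate positively selected genes into a pathway profile
#'
#' Counts PSGs per pathway (multi-membership genes counted in every pathway
#' they belong to), records the smallest uncorrected p per pathway, and ranks
#' pathways by count with ties broken by smaller minimum p.
#'
#' @param psgs List of [PSGRecord-class] (only records with \code{isPSG} are
#'   used) or a data.frame with columns \code{gene}, \code{p} (and optionally
#'   \code{is_psg}).
#' @param catalog A [PathwayCatalog-class] covering every PSG gene.
#' @param branch Branch identifier stored in the profile.
#' @return A [PathwayProfile-class].
#' @export
aggregateProfile <- function(psgs, catalog, branch = "branch") {
  df <- .psgFrame(psgs)
  missing <- setdiff(df$gene, names(catalog@mapping))
  if (length(missing))
    stop("PSG gene(s) missing from pathway catalog: ",
         paste(missing, collapse = ", "))
  pathways <- names(catalog@accessions)
  counts <- stats::setNames(integer(length(pathways)), pathways)
  minP <- stats::setNames(rep(NA_real_, length(pathways)), pathways)
  genes <- stats::setNames(vector("list", length(pathways)), pathways)
  for (pw in pathways) {
    inPw <- vapply(df$gene, function(g) pw %in% catalog@mapping[[g]],
                   logical(1))
    genes[[pw]] <- sort(unique(df$gene[inPw]))
    counts[pw] <- length(genes[[pw]])
    if (any(inPw)) minP[pw] <- min(df$p[inPw])
  }
  ranking <- if (all(counts == 0L)) character(0)
             else pathways[order(-counts, ifelse(is.na(minP), Inf, minP),
                                 pathways)]
  new("PathwayProfile", branch = branch, counts = counts, minP = minP,
      genes = genes, ranking = ranking)
}

#' @rdname PathwayProfile-class
#' @export
setMethod("pathwayCounts", "PathwayProfile", function(x) x@counts)

setMethod("show", "PathwayProfile", function(object) {
  cat("PathwayProfile [", object@branch, "]\n", sep = "")
  for (pw in names(object@counts))
    cat(sprintf("  %s: %d PSG%s%s\n", pw, object@counts[pw],
                if (object@counts[pw] == 1) "" else "s",
                if (is.na(object@minP[pw])) ""
                else sprintf(" (min p = %.3g)", object@minP[pw])))
  if (length(object@ranking))
    cat("  ranking:", paste(object@ranking, collapse = " > "), "\n")
  else cat("  ranking: undefined (no PSGs)\n")
})

#' Rule-based ancestral-diet call from a pathway profile
#'
#' Freezes the narrative mapping from nutrient-pathway selection profiles to
#' diet into an explicit rule set: a strictly top-ranked protein pathway
#' (PDA) calls a carnivore; carbohydrate and fat pathways (CDA, FDA) jointly
#' dominant with PDA last call an herbivore, refined to fruit and/or seed/nut
#' eating when the fructose-transporter or plant-sterol marker PSGs are
#' present; an all-zero profile is indeterminate; anything else is
#' omnivore-ambiguous. Every rule fired is recorded in the evidence trail.
#'
#' @param profile A [PathwayProfile-class].
#' @param markers Marker table (default [defaultMarkerTable()]).
#' @return A [DietCall-class].
#' @export
callDiet <- function(profile, markers = defaultMarkerTable()) {
  counts <- profile@counts
  psgGenes <- sort(unique(unlist(profile@genes)))
  hit <- markers[markers$gene %in% psgGenes, , drop = FALSE]
  evid <- character(0)
  note <- function(x) evid <<- c(evid, x)

  if (all(counts == 0L))
    return(new("DietCall", branch = profile@branch,
               category = "indeterminate", subtype = NA_character_,
               nutrientEmphasis = "no positively selected genes",
               markers = hit, evidence = character(0)))

  others <- function(pw) counts[setdiff(names(counts), pw)]
  cat <- NULL; subtype <- NA_character_; emphasis <- ""
  if (counts["PDA"] > max(others("PDA"))) {
    note(sprintf("PDA strictly top-ranked (%d vs %s): protein-dominated profile",
                 counts["PDA"],
                 paste(names(others("PDA")), others("PDA"), sep = "=",
                       collapse = ", ")))
    cat <- "carnivore"
    emphasis <- "high protein, then fat, minimal carbohydrate"
  } else if (counts["PDA"] < counts["CDA"] && counts["PDA"] < counts["FDA"]) {
    note(sprintf("CDA and FDA jointly dominant with PDA last (CDA=%d, FDA=%d, PDA=%d): carbohydrate/fat profile",
                 counts["CDA"], counts["FDA"], counts["PDA"]))
    cat <- "herbivore"
    emphasis <- "high carbohydrate and fat, minimal protein"
    fruit <- any(hit$signal == "fruit-sugar")
    seednut <- any(hit$signal == "plant-sterol")
    if (fruit) note(paste0("fructose-transporter marker PSG present (",
                           paste(hit$gene[hit$signal == "fruit-sugar"],
                                 collapse = ", "), "): fruit signal"))
    if (seednut) note(paste0("plant-sterol marker PSG present (",
                             paste(hit$gene[hit$signal == "plant-sterol"],
                                   collapse = ", "), "): seed/nut signal"))
    subtype <- if (fruit && seednut) "fruit/seed/nut"
               else if (fruit) "fruit"
               else if (seednut) "seed/nut"
               else "unrefined"
  } else {
    note(sprintf("no dominance pattern (CDA=%d, PDA=%d, FDA=%d)",
                 counts["CDA"], counts["PDA"], counts["FDA"]))
    cat <- "omnivore-ambiguous"
    emphasis <- "mixed nutrient emphasis"
  }
  new("DietCall", branch = profile@branch, category = cat, subtype = subtype,
      nutrientEmphasis = emphasis, markers = hit, evidence = evid)
}

#' @rdname DietCall-class
#' @export
setMethod("dietCategory", "DietCall", function(x) x@category)

#' @rdname DietCall-class
#' @export
setMethod("evidenceTrail", "DietCall", function(x) x@evidence)

setMethod("show", "DietCall", function(object) {
  cat("DietCall [", object@branch, "]: ", object@category,
      if (!is.na(object@subtype)) paste0(" (", object@subtype, ")") else "",
      "\n  nutrient profile: ", object@nutrientEmphasis, "\n", sep = "")
  for (e in object@evidence) cat("  - ", e, "\n", sep = "")
})

#' Contrast the pathway profiles of two branches
#'
#' @param profileA,profileB [PathwayProfile-class] objects on the same
#'   catalog (same pathway set).
#' @param relaxResults Optional list of [RelaxResult-class]; per-pathway
#'   tallies of intensified and relaxed genes are added.
#' @param catalog [PathwayCatalog-class] used to map relax results to
#'   pathways (required when \code{relaxResults} is given).
#' @return List with \code{deltas} (counts A - B), \code{sharedPSGs},
#'   \code{profiles}, and optionally \code{intensityTally} (data.frame
#'   pathway, intensified, relaxed).
#' @export
compareBranches <- function(profileA, profileB, relaxResults = NULL,
                            catalog = NULL) {
  if (!identical(sort(names(profileA@counts)), sort(names(profileB@counts))))
    stop("profiles were built on different pathway catalogs")
  pws <- names(profileA@counts)
  deltas <- profileA@counts - profileB@counts[pws]
  shared <- sort(intersect(unlist(profileA@genes), unlist(profileB@genes)))
  out <- list(deltas = deltas, sharedPSGs = shared,
              profiles = list(profileA, profileB))
  if (!is.null(relaxResults)) {
    if (is.null(catalog))
      stop("a catalog is required to tally relax results by pathway")
    tab <- relaxTable(relaxResults)
    missing <- setdiff(tab$gene, names(catalog@mapping))
    if (length(missing))
      stop("relax gene(s) missing from pathway catalog: ",
           paste(missing, collapse = ", "))
    tally <- do.call(rbind, lapply(pws, function(pw) {
      inPw <- vapply(tab$gene, function(g) pw %in% catalog@mapping[[g]],
                     logical(1))
      data.frame(pathway = pw,
                 intensified = sum(tab$classification[inPw] == "intensified"),
                 relaxed = sum(tab$classification[inPw] == "relaxed"))
    }))
    out$intensityTally <- tally
  }
  out
}
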
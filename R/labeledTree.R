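#' Construct a labeled phylogeny
#'
#' Wraps an \pkg{ape} \code{phylo} tree with a branch partition. For selection
#' tests the partition is background/foreground; for selection-intensity tests
#' it is reference/test/unclassified.
#'
#' @param tree An \code{ape::phylo} with branch lengths (expected substitutions
#'   per codon), or a Newick string.
#' @param foreground Branches to mark as foreground: either integer edge
#'   indices into \code{tree$edge}, or a character vector of tip labels whose
#'   most recent common ancestor's stem branch is marked (a single tip marks
#'   its terminal branch).
#' @param test,reference As \code{foreground}, for the intensity partition.
#'   Branches in neither set are \code{"unclassified"} and keep the reference
#'   omega distribution untransformed.
#' @return A [LabeledTree-class].
#' @examples
#' tr <- labeledTree("((A:1,B:1):1,C:1,D:1);", foreground = c("A", "B"))
#' sum(edgeLabels(tr) == "foreground")  # 1
#' @export
labeledTree <- function(tree, foreground = NULL, test = NULL, reference = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick string")
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  nE <- nrow(tree$edge)
  if (!is.null(foreground) && (!is.null(test) || !is.null(reference)))
    stop("specify either a foreground set or a test/reference partition, not both")
  if (!is.null(foreground)) {
    labels <- rep("background", nE)
    labels[.resolveEdges(tree, foreground)] <- "foreground"
    kind <- "selection"
  } else if (!is.null(test)) {
    labels <- rep("unclassified", nE)
    labels[.resolveEdges(tree, test)] <- "test"
    if (!is.null(reference)) labels[.resolveEdges(tree, reference)] <- "reference"
    if (!any(labels == "reference"))
      stop("intensity partition needs a non-empty reference set")
    kind <- "intensity"
  } else {
    labels <- rep("background", nE)
    kind <- "none"
  }
  new("LabeledTree", tree = tree, edgeLabels = labels, kind = kind)
}

.resolveEdges <- function(tree, spec) {
  if (is.numeric(spec)) {
    if (any(spec < 1 | spec > nrow(tree$edge))) stop("edge index out of range")
    return(as.integer(spec))
  }
  miss <- setdiff(spec, tree$tip.label)
  if (length(miss)) stop("unknown tip label(s): ", paste(miss, collapse = ", "))
  node <- if (length(spec) == 1L) match(spec, tree$tip.label)
          else ape::getMRCA(tree, spec)
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) == 0L)
    stop("the MRCA of the given tips is the root; its stem branch does not exist")
  edge
}

#' @rdname LabeledTree-class
#' @export
setMethod("edgeLabels", "LabeledTree", function(x) x@edgeLabels)

#' @rdname LabeledTree-class
#' @export
setMethod("foregroundEdges", "LabeledTree", function(x)
  which(x@edgeLabels %in% c("foreground", "test")))

#' @rdname LabeledTree-class
#' @export
setMethod("taxa", "LabeledTree", function(x) x@tree$tip.label)

setMethod("show", "LabeledTree", function(object) {
  tab <- table(object@edgeLabels)
  cat("LabeledTree (", object@kind, "): ", length(object@tree$tip.label),
      " tips, ", nrow(object@tree$edge), " branches [",
      paste(names(tab), tab, sep = ":", collapse = ", "), "]\n", sep = "")
})

#' Read a Newick tree with branch labels
#'
#' Accepts the branch-label dialects of the codon-model tools this package
#' mirrors: \code{#1} after a tip or closing parenthesis marks that branch as
#' foreground; \code{{test}} / \code{{reference}} tags mark the intensity
#' partition. Labels apply to the branch subtending the tagged node.
#'
#' @param path Path to a Newick file, or a Newick string via \code{text}.
#' @param text Newick string (alternative to \code{path}).
#' @param require Optional: \code{"selection"} or \code{"intensity"} to demand
#'   that the corresponding labels are present (error otherwise).
#' @return A [LabeledTree-class].
#' @examples
#' tr <- readLabeledNewick(text = "((A:1,B:1)#1:0.5,C:1,D:1);")
#' edgeLabels(tr)[foregroundEdges(tr)]
#' @export
readLabeledNewick <- function(path = NULL, text = NULL, require = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (grepl("#\\s*[2-9]", text))
    stop("only one foreground label class (#1) is supported")
  marked <- gsub("\\{\\s*test\\s*\\}", "__TEST__",
                 gsub("\\{\\s*reference\\s*\\}", "__REF__",
                      gsub("#\\s*1", "__FG__", text)))
  tr <- tryCatch(ape::read.tree(text = marked),
                 error = function(e) stop("failed to parse Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse Newick input")
  if (anyDuplicated(gsub("__(FG|TEST|REF)__", "", tr$tip.label)))
    stop("duplicate leaf names in tree")
  nTip <- length(tr$tip.label)
  allLabs <- c(tr$tip.label, if (is.null(tr$node.label)) rep("", tr$Nnode)
               else tr$node.label)
  findMark <- function(mark) {
    nodes <- grep(mark, allLabs, fixed = TRUE)
    unlist(lapply(nodes, function(nd) {
      e <- which(tr$edge[, 2] == nd)
      if (length(e) == 0L)
        stop("a branch label sits at the root; label a non-root node instead")
      e
    }))
  }
  fg <- findMark("__FG__")
  te <- findMark("__TEST__")
  re <- findMark("__REF__")
  # strip markers
  strip <- function(x) gsub("__(FG|TEST|REF)__", "", x)
  tr$tip.label <- strip(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- strip(tr$node.label)
  if (length(fg) && (length(te) || length(re)))
    stop("cannot mix #1 foreground labels with {test}/{reference} tags")
  out <- if (length(fg)) labeledTree(tr, foreground = fg)
         else if (length(te) || length(re)) {
           if (!length(te)) stop("tree has {reference} tags but no {test} branch")
           if (!length(re)) stop("tree has {test} tags but no {reference} branch")
           labeledTree(tr, test = te, reference = re)
         } else labeledTree(tr)
  if (!is.null(require)) {
    if (require == "selection" && out@kind != "selection")
      stop("a labeled analysis was requested but the tree carries no #1 foreground label")
    if (require == "intensity" && out@kind != "intensity")
      stop("an intensity analysis was requested but the tree carries no {test}/{reference} labels")
  }
  out
}

#' Mark the stem branch of a clade as foreground
#'
#' @param ltree A [LabeledTree-class] (existing labels are replaced).
#' @param tips Tip labels whose MRCA's stem branch is marked.
#' @return A [LabeledTree-class] with kind \code{"selection"}.
#' @export
labelBranch <- function(ltree, tips) {
  labeledTree(ltree@tree, foreground = tips)
}
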
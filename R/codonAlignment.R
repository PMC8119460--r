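#' Construct a codon alignment
#'
#' Builds a [CodonAlignment-class] from nucleotide sequences. Sequences must be
#' codon-aligned (equal lengths, divisible by 3). Codons containing a gap or an
#' ambiguity character are treated as missing data; in-frame stop codons raise
#' an error naming the sequence and codon position.
#'
#' @param sequences Named character vector of aligned nucleotide sequences, or
#'   a character matrix (taxa x codon sites) of codon strings.
#' @param geneId Gene identifier (default \code{"gene"}).
#' @return A [CodonAlignment-class] object.
#' @examples
#' aln <- codonAlignment(c(a = "ATGAAA", b = "ATGAAG"), geneId = "toy")
#' nsites(aln)  # 2
#' @export
codonAlignment <- function(sequences, geneId = "gene") {
  gc <- geneticCode()
  if (is.matrix(sequences)) {
    codmat <- toupper(sequences)
    taxa <- rownames(codmat)
    if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(codmat)))
  } else {
    seqs <- toupper(gsub("\\s", "", sequences))
    taxa <- names(seqs)
    if (is.null(taxa)) taxa <- paste0("t", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
    if (lens[1] %% 3L != 0L)
      stop("alignment length ", lens[1], " is not divisible by 3")
    nsite <- lens[1] %/% 3L
    codmat <- matrix("", length(seqs), nsite)
    for (i in seq_along(seqs))
      codmat[i, ] <- substring(seqs[i], 3L * seq_len(nsite) - 2L, 3L * seq_len(nsite))
  }
  states <- matrix(0L, nrow(codmat), ncol(codmat))
  idx <- match(codmat, gc$codons)
  states[] <- ifelse(is.na(idx), 0L, idx)
  # distinguish missing (gap/ambiguity) from stops/garbage
  bad <- which(is.na(idx) & !grepl("[-N?]", codmat))
  if (length(bad)) {
    pos <- arrayInd(bad[1], dim(codmat))
    cod <- codmat[bad[1]]
    if (cod %in% gc$stops)
      stop("in-frame stop codon ", cod, " in sequence '", taxa[pos[1]],
           "' at codon position ", pos[2])
    stop("unrecognized codon '", cod, "' in sequence '", taxa[pos[1]],
         "' at codon position ", pos[2])
  }
  new("CodonAlignment", geneId = as.character(geneId),
      taxa = as.character(taxa), states = states)
}

#' @rdname CodonAlignment-class
#' @export
setMethod("geneId", "CodonAlignment", function(x) x@geneId)

#' @rdname CodonAlignment-class
#' @export
setMethod("taxa", "CodonAlignment", function(x) x@taxa)

#' @rdname CodonAlignment-class
#' @export
setMethod("nsites", "CodonAlignment", function(x) ncol(x@states))

#' @describeIn CodonAlignment-class Codon-string matrix (taxa x sites);
#'   missing codons shown as \code{"---"}.
#' @export
setMethod("as.matrix", "CodonAlignment", function(x, ...) {
  gc <- geneticCode()
  out <- matrix("---", nrow(x@states), ncol(x@states),
                dimnames = list(x@taxa, NULL))
  nz <- x@states > 0L
  out[nz] <- gc$codons[x@states[nz]]
  out
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment '", object@geneId, "': ", length(object@taxa),
      " taxa x ", ncol(object@states), " codon sites (",
      sum(object@states == 0L), " missing codons)\n", sep = "")
})

#' Read a codon alignment from FASTA
#'
#' @param path Path to an aligned FASTA file of in-frame coding sequences.
#' @param geneId Gene identifier; defaults to the file name without extension.
#' @return A [CodonAlignment-class].
#' @export
readCodonFasta <- function(path, geneId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(geneId)) geneId <- sub("\\.[^.]*$", "", basename(path))
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stop("no records in ", path)
  seqs <- stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  aln <- codonAlignment(seqs, geneId = geneId)
  if (all(aln@states == 0L)) stop("alignment in ", path, " contains only gaps")
  aln
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [CodonAlignment-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCodonFasta <- function(aln, path) {
  mat <- as.matrix(aln)
  seqs <- apply(mat, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a codon alignment from sequential PHYLIP
#'
#' Only the sequential layout is supported (the whole sequence follows each
#' name); interleaved files are rejected.
#'
#' @inheritParams readCodonFasta
#' @return A [CodonAlignment-class].
#' @export
readCodonPhylip <- function(path, geneId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(geneId)) geneId <- sub("\\.[^.]*$", "", basename(path))
  dna <- tryCatch(ape::read.dna(path, format = "sequential", as.character = TRUE),
                  error = function(e)
                    stop("failed to parse ", path, " as sequential PHYLIP ",
                         "(interleaved files are not supported): ",
                         conditionMessage(e)))
  seqs <- apply(dna, 1, paste0, collapse = "")
  codonAlignment(stats::setNames(toupper(seqs), rownames(dna)), geneId = geneId)
}

# Restrict an alignment to the taxa present in a tree (order of the tree).
.alignTo <- function(aln, taxaOrder) {
  miss <- setdiff(taxaOrder, aln@taxa)
  if (length(miss))
    stop("alignment '", aln@geneId, "' lacks taxa: ", paste(miss, collapse = ", "))
  new("CodonAlignment", geneId = aln@geneId, taxa = taxaOrder,
      states = aln@states[match(taxaOrder, aln@taxa), , drop = FALSE])
}
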
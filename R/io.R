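#' Read a selection-table fixture
#'
#' Reads the bundled transcription of the published selection-scan table
#' (per-branch rows of gene, species number N, 2dlnL, df, printed p-value,
#' printed Bonferroni p-value, foreground omega estimates, and the selected
#' sites with \code{^} marking sites at >= 90 percent posterior support).
#' p-values are kept as printed strings so their precision is preserved, with
#' parsed numeric columns alongside.
#'
#' @param path Path to the fixture TSV; default: the bundled file.
#' @return data.frame with columns \code{branch}, \code{gene}, \code{n_taxa},
#'   \code{stat}, \code{df}, \code{p_printed}, \code{p_bonferroni_printed},
#'   \code{omega2a}, \code{omega2b}, \code{sites}, \code{p}, and
#'   \code{p_bonferroni}.
#' @export
readTable1Fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_fixture.tsv",
                        package = "phylotroph", mustWork = TRUE)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("branch", "gene", "n_taxa", "stat", "df", "p_printed",
            "p_bonferroni_printed", "omega2a", "omega2b", "sites")
  if (!all(need %in% names(df)))
    stop("fixture is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cl in c("n_taxa", "df")) df[[cl]] <- as.integer(df[[cl]])
  for (cl in c("stat", "omega2a", "omega2b")) df[[cl]] <- as.numeric(df[[cl]])
  df$p <- as.numeric(df$p_printed)
  df$p_bonferroni <- as.numeric(df$p_bonferroni_printed)
  if (any(df$df != 1L)) stop("every fixture row must have df = 1")
  df
}

# Does `value` reproduce the printed string at its printed precision?
# Agreement within one unit in the last printed digit, which accepts both
# rounding and truncation conventions.
.matchesPrinted <- function(value, printed) {
  printed <- trimws(printed)
  num <- as.numeric(printed)
  mant <- sub("[eE].*$", "", printed)
  d <- if (grepl("\\.", mant)) nchar(sub("^[^.]*\\.", "", mant)) else 0L
  expo <- if (grepl("[eE]", printed))
    as.integer(sub("^.*[eE]", "", printed)) else 0L
  ulp <- 10^(expo - d)
  abs(value - num) < ulp * (1 + 1e-9)
}

#' Verify the arithmetic of the published selection table
#'
#' For every fixture row, recomputes the chi-square (df = 1) upper-tail
#' p-value from the printed 2dlnL and the Bonferroni value as twice the
#' printed p, and checks both against the printed values at their printed
#' precision. Two known exceptions are annotated: the CELA3B and SLC36A1
#' rows (both with 15 species) print a corrected p equal to the raw p
#' instead of twice it (possibly tested on a single branch).
#'
#' @param fixture data.frame from [readTable1Fixture()].
#' @param nTests Bonferroni multiplier (default 2).
#' @return data.frame with per-row computed values, \code{p_match} and
#'   \code{bonferroni_match} flags, and a \code{note} column.
#' @export
checkTable1 <- function(fixture = readTable1Fixture(), nTests = 2) {
  pComp <- stats::pchisq(fixture$stat, df = fixture$df, lower.tail = FALSE)
  bonfComp <- bonferroniAdjust(fixture$p, nTests = nTests)
  pMatch <- mapply(.matchesPrinted, pComp, fixture$p_printed)
  bonfMatch <- mapply(.matchesPrinted, bonfComp,
                      fixture$p_bonferroni_printed)
  note <- ifelse(!bonfMatch & .matchesPrinted2(fixture$p,
                                               fixture$p_bonferroni_printed),
                 "printed corrected p equals raw p (not x2); single-branch test?",
                 "")
  data.frame(branch = fixture$branch, gene = fixture$gene,
             stat = fixture$stat, p_printed = fixture$p_printed,
             p_computed = pComp, p_match = pMatch,
             p_bonferroni_printed = fixture$p_bonferroni_printed,
             p_bonferroni_computed = bonfComp,
             bonferroni_match = bonfMatch, note = note)
}

.matchesPrinted2 <- function(values, printed)
  mapply(.matchesPrinted, values, printed)

#' Write a results table as delimited text
#'
#' @param df data.frame (e.g. from [psgTable()] or [relaxTable()]).
#' @param path Output path (tab-separated, with header).
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a diet call (with its evidence trail) as structured text
#'
#' @param diet A [DietCall-class].
#' @param path Output path (JSON).
#' @return Invisibly, \code{path}.
#' @export
writeDietCall <- function(diet, path) {
  obj <- list(branch = diet@branch, category = diet@category,
              subtype = diet@subtype,
              nutrient_emphasis = diet@nutrientEmphasis,
              markers = diet@markers, evidence = diet@evidence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
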
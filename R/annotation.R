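#' Load a cis-regulatory element table
#'
#' Reads a TSV of known plant cis-regulatory elements with columns
#' `pattern` (IUPAC nucleotide codes), `element_name`, `description` and
#' `source`. The package bundles a curated snapshot of well-characterized
#' plant elements (G-box, ABRE, ACGT/desiccation elements, W-box, GT-1,
#' Mem1/CACT module, rolD, site II, CuRE GTAC core, A-box, cytokinin POR
#' element, legA CAAT consensus, among others); pass a path to substitute
#' your own table. Patterns are validated at load time.
#'
#' @param path Path to an element TSV; `NULL` (default) loads the bundled
#'   snapshot.
#' @return A data.frame with the four columns above.
#' @seealso [matchCisElements()], [annotateMotifs()]
#' @export
readCisElements <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cis_elements.tsv",
                        package = "promoscan", mustWork = TRUE)
  tab <- read.delim(path, colClasses = "character")
  need <- c("pattern", "element_name", "description", "source")
  if (!all(need %in% colnames(tab)))
    stop("element table must have columns: ", paste(need, collapse = ", "))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", tab$pattern)
  if (any(bad))
    stop("invalid IUPAC pattern(s) in element table: ",
         paste(tab$pattern[bad], collapse = ", "))
  tab
}

#' Match a motif against a cis-element table
#'
#' A table row matches when the element's IUPAC pattern occurs as a
#' substring of the motif under IUPAC degeneracy, or — for patterns
#' longer than the motif — when the motif occurs within the pattern.
#' Matching is on the given strand only by default, consistent with
#' strand-specific motif counting; set `revcomp = TRUE` to also match
#' the motif's reverse complement.
#'
#' @param motif A k-mer over {A,C,G,T}.
#' @param elements Element table from [readCisElements()].
#' @param revcomp Also try the reverse complement of `motif`
#'   (default `FALSE`).
#' @return The matching rows of `elements` (possibly zero rows), in
#'   table order.
#' @export
#' @examples
#' tab <- readCisElements()
#' matchCisElements("CACGTG", tab)$element_name
matchCisElements <- function(motif, elements, revcomp = FALSE) {
  if (!grepl("^[ACGT]+$", motif))
    stop("'motif' must be a string over A, C, G, T")
  queries <- Biostrings::DNAString(motif)
  if (revcomp)
    queries <- list(queries, Biostrings::reverseComplement(queries))
  else
    queries <- list(queries)
  hit <- vapply(elements$pattern, function(pat) {
    p <- Biostrings::DNAString(pat)
    any(vapply(queries, function(q) {
      if (length(p) <= length(q))
        ## degenerate pattern inside the literal motif
        Biostrings::countPattern(p, q, fixed = "subject") > 0
      else
        ## literal motif inside the (possibly degenerate) longer pattern
        Biostrings::countPattern(q, p, fixed = "pattern") > 0
    }, logical(1)))
  }, logical(1))
  elements[hit, , drop = FALSE]
}

#' Annotate enrichment records with known cis-elements
#'
#' Attaches, to every motif record, the names and descriptions of all
#' matching elements (joined with `"; "` in table order). By default,
#' records whose motif matches no known element are dropped — only
#' positively matching motifs are reported; set `keepUnmatched = TRUE`
#' to retain them with empty annotation. Statistical fields are never
#' altered.
#'
#' @param records Enrichment records (typically the output of
#'   [filterEnriched()]) with a `motif` column.
#' @param elements Element table from [readCisElements()].
#' @param keepUnmatched Keep records without a match (default `FALSE`).
#' @param revcomp Passed to [matchCisElements()].
#' @return `records` with `element_name` and `annotation` columns
#'   appended, possibly with unmatched rows removed.
#' @export
annotateMotifs <- function(records, elements = readCisElements(),
                           keepUnmatched = FALSE, revcomp = FALSE) {
  if (!"motif" %in% colnames(records))
    stop("'records' must have a 'motif' column")
  n <- nrow(records)
  nameCol <- character(n)
  descCol <- character(n)
  matched <- logical(n)
  for (i in seq_len(n)) {
    hits <- matchCisElements(records$motif[i], elements, revcomp = revcomp)
    matched[i] <- nrow(hits) > 0
    nameCol[i] <- paste(hits$element_name, collapse = "; ")
    descCol[i] <- paste(hits$description, collapse = "; ")
  }
  records$element_name <- nameCol
  records$annotation <- descCol
  if (!keepUnmatched)
    records <- records[matched, , drop = FALSE]
  records
}
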
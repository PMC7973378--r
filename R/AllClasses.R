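#' PromoterSet: fixed-length upstream promoter windows
#'
#' A `PromoterSet` is a [Biostrings::DNAStringSet] of promoter sequences,
#' one per gene, named by gene ID, together with the target window length
#' and the genomic provenance of every window (contig, start, end, strand)
#' in its metadata columns. Sequences are stored 5'->3' relative to the
#' gene: minus-strand promoters are reverse-complemented at extraction
#' time. A sequence is shorter than `targetLength` only when the window
#' was truncated at a contig edge.
#'
#' @slot targetLength Integer, the requested window length L in bases.
#' @seealso [extractPromoters()], [readPromoters()], [writePromoters()]
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importMethodsFrom Biostrings width
#' @importMethodsFrom S4Vectors mcols "mcols<-" metadata "metadata<-"
#' @export
setClass("PromoterSet",
  contains = "DNAStringSet",
  representation(targetLength = "integer")
)

setValidity("PromoterSet", function(object) {
  msg <- character()
  if (length(object@targetLength) != 1L || is.na(object@targetLength) ||
      object@targetLength < 1L)
    msg <- c(msg, "targetLength must be a single positive integer")
  if (length(object) > 0) {
    if (is.null(names(object)) || anyNA(names(object)) ||
        any(names(object) == ""))
      msg <- c(msg, "all promoters must be named by gene ID")
    else if (anyDuplicated(names(object)))
      msg <- c(msg, "gene IDs must be unique")
    if (length(object@targetLength) == 1L && !is.na(object@targetLength) &&
        any(Biostrings::width(object) > object@targetLength))
      msg <- c(msg, "promoter widths must not exceed targetLength")
  }
  if (length(msg)) msg else TRUE
})

PromoterSet <- function(sequences, targetLength,
                        contig = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_) {
  sequences <- Biostrings::DNAStringSet(sequences)
  mc <- S4Vectors::DataFrame(
    contig = rep_len(contig, length(sequences)),
    start  = rep_len(as.integer(start), length(sequences)),
    end    = rep_len(as.integer(end), length(sequences)),
    strand = rep_len(strand, length(sequences))
  )
  S4Vectors::mcols(sequences) <- mc
  new("PromoterSet", sequences, targetLength = as.integer(targetLength))
}

#' @describeIn PromoterSet-class Target promoter window length in bases.
#' @param x A `PromoterSet`.
#' @export
targetLength <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  x@targetLength
}

#' @describeIn PromoterSet-class Named integer vector of realized promoter
#'   lengths (shorter than `targetLength(x)` only at contig edges).
#' @export
promoterLengths <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  stats::setNames(Biostrings::width(x), names(x))
}

setMethod("show", "PromoterSet", function(object) {
  cat(sprintf("PromoterSet of %d promoters (target length %d bp)\n",
              length(object), object@targetLength))
  if (length(object)) {
    trunc <- sum(Biostrings::width(object) < object@targetLength)
    if (trunc)
      cat(sprintf("  %d window(s) truncated at a contig edge\n", trunc))
    callNextMethod()
  }
})

#' MotifCountTable: k-mer counts in foreground vs background promoters
#'
#' Holds, for every k-mer over {A,C,G,T}, its count in a foreground set of
#' promoters and in all (background) promoters, together with the two
#' denominators the enrichment fraction divides by. Two counting modes are
#' supported: `"presence"` counts promoters containing at least one
#' occurrence (denominators are promoter counts), `"occurrence"` counts
#' every sliding window (denominators are valid-window totals). Windows
#' containing a non-ACGT base are skipped in both modes.
#'
#' @slot counts A [S4Vectors::DataFrame] with columns `motif`, `k_fg`
#'   (foreground count) and `n_bg` (background count), one row per k-mer.
#' @slot k Integer motif length.
#' @slot mode `"presence"` or `"occurrence"`.
#' @slot K_fg Foreground denominator (promoters or windows).
#' @slot N_bg Background denominator (promoters or windows).
#' @seealso [countMotifs()], [motifEnrichment()]
#' @export
setClass("MotifCountTable",
  representation(counts = "DataFrame", k = "integer", mode = "character",
                 K_fg = "numeric", N_bg = "numeric")
)

setValidity("MotifCountTable", function(object) {
  msg <- character()
  if (!all(c("motif", "k_fg", "n_bg") %in% colnames(object@counts)))
    msg <- c(msg, "counts must have columns motif, k_fg, n_bg")
  if (!object@mode %in% c("presence", "occurrence"))
    msg <- c(msg, "mode must be 'presence' or 'occurrence'")
  else if (nrow(object@counts)) {
    if (any(object@counts$k_fg > object@counts$n_bg))
      msg <- c(msg, "foreground counts cannot exceed background counts")
    if (object@mode == "presence" &&
        (any(object@counts$k_fg > object@K_fg) ||
         any(object@counts$n_bg > object@N_bg)))
      msg <- c(msg, "presence counts cannot exceed promoter totals")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifCountTable-class Per-motif count table as a `DataFrame`.
#' @param x A `MotifCountTable`.
#' @export
motifCounts <- function(x) {
  stopifnot(is(x, "MotifCountTable"))
  x@counts
}

#' @describeIn MotifCountTable-class Counting mode, `"presence"` or
#'   `"occurrence"`.
#' @export
countingMode <- function(x) {
  stopifnot(is(x, "MotifCountTable"))
  x@mode
}

#' @describeIn MotifCountTable-class Foreground (`K_fg`) and background
#'   (`N_bg`) denominators as a named numeric vector.
#' @export
countDenominators <- function(x) {
  stopifnot(is(x, "MotifCountTable"))
  c(K_fg = x@K_fg, N_bg = x@N_bg)
}

setMethod("show", "MotifCountTable", function(object) {
  cat(sprintf("MotifCountTable: %d %d-mers, %s mode\n",
              nrow(object@counts), object@k, object@mode))
  unit <- if (object@mode == "presence") "promoters" else "windows"
  cat(sprintf("  foreground: %g %s; background: %g %s\n",
              object@K_fg, unit, object@N_bg, unit))
})

#' TrendClusterSet: hierarchical trend clusters of an expression matrix
#'
#' The result of complete-linkage hierarchical clustering of per-gene
#' expression profiles, optionally labeled by treatment-response trend.
#' Labels are `"up_enhanced"` (flooding-induced, stronger in the reference
#' genotype), `"down_enhanced"` (flooding-repressed, stronger in the
#' reference genotype) or `"other"`; unlabeled sets carry `NA` labels.
#'
#' @slot assignments Named integer vector mapping gene ID to cluster index.
#' @slot labels Character vector of per-cluster labels (or `NA` before
#'   [labelTrends()] is applied), named by cluster index.
#' @slot log2fc Numeric matrix (cluster x genotype) of cluster-level
#'   pseudocounted log2 flooded/control fold changes; empty until labeled.
#' @slot tree The [stats::hclust] merge tree that produced the clusters.
#' @slot params List of clustering/labeling parameters (distance, linkage,
#'   n_clusters, pseudocount, reference genotype, treatment levels).
#' @seealso [clusterTrends()], [labelTrends()], [trendGeneLists()]
#' @export
setClass("TrendClusterSet",
  representation(assignments = "integer", labels = "character",
                 log2fc = "matrix", tree = "ANY", params = "list")
)

setValidity("TrendClusterSet", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by gene ID")
  k <- length(unique(object@assignments))
  if (length(object@labels) && length(object@labels) < k)
    msg <- c(msg, "one label per cluster required")
  ok <- c("up_enhanced", "down_enhanced", "other")
  if (length(object@labels) && !all(is.na(object@labels) |
                                    object@labels %in% ok))
    msg <- c(msg, sprintf("labels must be NA or one of: %s",
                          paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn TrendClusterSet-class Named integer vector of cluster
#'   memberships.
#' @param x A `TrendClusterSet`.
#' @export
clusterAssignments <- function(x) {
  stopifnot(is(x, "TrendClusterSet"))
  x@assignments
}

#' @describeIn TrendClusterSet-class Per-cluster trend labels (named by
#'   cluster index; `NA` if [labelTrends()] has not been run).
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "TrendClusterSet"))
  x@labels
}

setMethod("show", "TrendClusterSet", function(object) {
  k <- length(unique(object@assignments))
  cat(sprintf("TrendClusterSet: %d genes in %d clusters (%s, %s linkage)\n",
              length(object@assignments), k,
              object@params$distance %||% "euclidean",
              object@params$linkage %||% "complete"))
  if (length(object@labels) && !all(is.na(object@labels))) {
    tab <- table(object@labels[as.character(object@assignments)])
    for (lab in names(tab))
      cat(sprintf("  %s: %d genes\n", lab, tab[[lab]]))
  } else {
    cat("  (unlabeled; run labelTrends())\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
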
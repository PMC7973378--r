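#' Hierarchical trend clustering of an expression matrix
#'
#' Clusters genes by their treatment-response profile: for every gene the
#' replicate-mean FPKM is computed per (genotype, treatment) cell (four
#' values in a 2x2 design), the profile is row z-scored so that clustering
#' follows trend shape rather than expression magnitude, and genes are
#' joined by complete-linkage agglomeration on Euclidean distances.
#' Constant profiles (zero variance) z-score to all zeros. The result is
#' deterministic given the input gene order.
#'
#' @param se [SummarizedExperiment::SummarizedExperiment] with assay
#'   `fpkm` and `colData` columns `genotype` and `treatment` (every
#'   genotype x treatment cell must have at least one replicate; values
#'   must be non-negative and complete).
#' @param nClusters Number of clusters to cut the tree into (1..nGenes).
#' @return An unlabeled [TrendClusterSet].
#' @seealso [labelTrends()], [trendGeneLists()]
#' @export
clusterTrends <- function(se, nClusters = 8L) {
  mat <- .validateFpkm(se)
  nClusters <- checkCount(nClusters, "nClusters")
  if (nClusters > nrow(mat))
    stop("'nClusters' cannot exceed the number of genes (", nrow(mat), ")")

  prof <- .cellMeans(se)                      # genes x cells
  z <- t(apply(prof, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  tree <- hclust(dist(z), method = "complete")
  assignments <- cutree(tree, k = nClusters)
  new("TrendClusterSet",
      assignments = stats::setNames(as.integer(assignments), rownames(mat)),
      labels = rep(NA_character_, nClusters),
      log2fc = matrix(numeric(0), 0, 0),
      tree = tree,
      params = list(distance = "euclidean", linkage = "complete",
                    n_clusters = nClusters, standardized = TRUE))
}

#' Label trend clusters by genotype-contrasted flooding response
#'
#' For every cluster, the mean FPKM over the cluster's genes and
#' replicates is formed per (genotype, treatment) cell, and the
#' pseudocounted log2 flooded/control fold change is computed per
#' genotype. A cluster is `"up_enhanced"` when the reference genotype's
#' fold change is positive and strictly larger than the other genotype's;
#' `"down_enhanced"` when it is negative and strictly smaller; `"other"`
#' otherwise (including exact ties).
#'
#' @param clusters A [TrendClusterSet] from [clusterTrends()] on the same
#'   matrix.
#' @param se The expression matrix the clusters were derived from.
#' @param pseudocount Added to both numerator and denominator FPKM before
#'   the log ratio (default 1 FPKM; guards against zeros).
#' @param refGenotype Genotype treated as the reference (wild-type
#'   analog); defaults to the first genotype level in `colData`.
#' @param controlLevel,floodedLevel Treatment levels; default to the
#'   first and second level observed.
#' @return The input [TrendClusterSet] with `labels` and per-cluster
#'   `log2fc` filled in.
#' @export
labelTrends <- function(clusters, se, pseudocount = 1,
                        refGenotype = NULL, controlLevel = NULL,
                        floodedLevel = NULL) {
  stopifnot(is(clusters, "TrendClusterSet"), pseudocount > 0)
  mat <- .validateFpkm(se)
  if (!identical(sort(names(clusterAssignments(clusters))),
                 sort(rownames(mat))))
    stop("'clusters' was not derived from this expression matrix ",
         "(gene sets differ)")

  cd <- SummarizedExperiment::colData(se)
  genotypes <- unique(as.character(cd$genotype))
  treatments <- unique(as.character(cd$treatment))
  refGenotype <- refGenotype %||% genotypes[1]
  controlLevel <- controlLevel %||% treatments[1]
  floodedLevel <- floodedLevel %||% setdiff(treatments, controlLevel)[1]
  stopifnot(refGenotype %in% genotypes,
            all(c(controlLevel, floodedLevel) %in% treatments))
  otherGenotype <- setdiff(genotypes, refGenotype)[1]

  asg <- clusterAssignments(clusters)
  idx <- sort(unique(asg))
  fc <- matrix(NA_real_, nrow = length(idx), ncol = 2,
               dimnames = list(as.character(idx),
                               c(refGenotype, otherGenotype)))
  cellMean <- function(genes, g, t) {
    cols <- cd$genotype == g & cd$treatment == t
    mean(mat[genes, cols, drop = FALSE])
  }
  labels <- stats::setNames(rep("other", length(idx)), as.character(idx))
  for (ci in seq_along(idx)) {
    genes <- names(asg)[asg == idx[ci]]
    for (g in c(refGenotype, otherGenotype)) {
      fc[ci, g] <- log2((cellMean(genes, g, floodedLevel) + pseudocount) /
                        (cellMean(genes, g, controlLevel) + pseudocount))
    }
    a <- fc[ci, refGenotype]; b <- fc[ci, otherGenotype]
    if (a > 0 && a > b) labels[ci] <- "up_enhanced"
    else if (a < 0 && a < b) labels[ci] <- "down_enhanced"
  }
  out <- clusters
  out@labels <- labels
  out@log2fc <- fc
  out@params <- c(out@params,
                  list(pseudocount = pseudocount,
                       ref_genotype = refGenotype,
                       control_level = controlLevel,
                       flooded_level = floodedLevel))
  validObject(out)
  out
}

#' Gene lists of labeled trend clusters
#'
#' Collects gene IDs of all clusters labeled `"up_enhanced"` and
#' `"down_enhanced"`; genes in `"other"` clusters are excluded.
#'
#' @param clusters A labeled [TrendClusterSet].
#' @return Named list with character vectors `up_enhanced` and
#'   `down_enhanced` (either may be empty).
#' @export
trendGeneLists <- function(clusters) {
  stopifnot(is(clusters, "TrendClusterSet"))
  labels <- clusterLabels(clusters)
  if (all(is.na(labels)))
    stop("clusters are unlabeled; run labelTrends() first")
  asg <- clusterAssignments(clusters)
  pick <- function(lab) {
    keep <- names(labels)[!is.na(labels) & labels == lab]
    names(asg)[as.character(asg) %in% keep]
  }
  list(up_enhanced = pick("up_enhanced"),
       down_enhanced = pick("down_enhanced"))
}

## shared validation: fpkm assay, complete design, non-negative values
.validateFpkm <- function(se) {
  if (!is(se, "SummarizedExperiment"))
    stop("'se' must be a SummarizedExperiment")
  if (!"fpkm" %in% SummarizedExperiment::assayNames(se))
    stop("'se' must carry an assay named 'fpkm'")
  mat <- SummarizedExperiment::assay(se, "fpkm")
  if (anyNA(mat) || any(mat < 0))
    stop("FPKM values must be non-negative and complete")
  cd <- SummarizedExperiment::colData(se)
  if (!all(c("genotype", "treatment") %in% colnames(cd)))
    stop("colData must have 'genotype' and 'treatment' columns")
  cells <- table(cd$genotype, cd$treatment)
  if (any(cells == 0))
    stop("every genotype x treatment cell needs at least one replicate")
  mat
}

## genes x (genotype:treatment) replicate-mean matrix, fixed column order
.cellMeans <- function(se) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  cd <- SummarizedExperiment::colData(se)
  grp <- interaction(cd$genotype, cd$treatment, drop = TRUE, lex.order = TRUE)
  out <- sapply(levels(grp), function(g)
    rowMeans(mat[, grp == g, drop = FALSE]))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), levels(grp)))
  out
}
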
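#' Generate an FPKM-scale expression matrix with planted trends
#'
#' Simulates a two-genotype (reference/wild-type analog vs deficient
#' analog) by two-treatment (control vs flooded) design with replicate
#' columns, on the FPKM scale with multiplicative log-normal noise. Genes
#' assigned trend `"up_enhanced"` respond to flooding with
#' `+log2fcRef` (reference genotype) and `+log2fcOther` (other genotype);
#' `"down_enhanced"` genes respond with the mirrored negative fold
#' changes; `"null"` genes have no treatment effect. Because the analysis
#' consumes FPKM, noise is log-normal on the expression value rather than
#' count-level negative-binomial.
#'
#' @param nGenes Number of genes.
#' @param geneIds Optional character vector of `nGenes` gene IDs
#'   (defaults to `Gene0001`, ...); lets the matrix share IDs with a
#'   synthetic genome.
#' @param trendAssignments Named character vector (gene ID ->
#'   `"up_enhanced"`, `"down_enhanced"` or `"null"`). Genes not named are
#'   `"null"`. `NULL` means all-null.
#' @param genotypes Length-2 character vector; the first is the reference
#'   (wild-type analog) with the stronger response.
#' @param treatments Length-2 character vector, control level first.
#' @param nReplicates Replicates per (genotype, treatment) cell.
#' @param baseExpression Mean control-level FPKM.
#' @param log2fcRef,log2fcOther Magnitudes of the flooding log2 fold
#'   change in the reference and other genotype; the reference response
#'   must be strictly stronger (`|log2fcOther| < |log2fcRef|`).
#' @param noiseSdLog Standard deviation of the natural-log-scale noise
#'   (0 gives a noise-free matrix).
#' @param seed Integer seed; identical arguments give an identical matrix.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"fpkm"`, `colData` columns `genotype`, `treatment`, `replicate`, and
#'   `rowData` column `trend` holding the planted assignment.
#' @export
#' @examples
#' se <- syntheticExpression(nGenes = 6,
#'   trendAssignments = c(Gene0001 = "up_enhanced"), noiseSdLog = 0,
#'   seed = 1)
#' SummarizedExperiment::assay(se)[1, ]
syntheticExpression <- function(nGenes = 300L, trendAssignments = NULL,
                                geneIds = NULL,
                                genotypes = c("A", "B"),
                                treatments = c("control", "flooded"),
                                nReplicates = 3L, baseExpression = 50,
                                log2fcRef = 2, log2fcOther = 1,
                                noiseSdLog = 0.1, seed = 1L) {
  nGenes <- checkCount(nGenes, "nGenes", min = 0L)
  nReplicates <- checkCount(nReplicates, "nReplicates")
  stopifnot(length(genotypes) == 2L, length(treatments) == 2L,
            baseExpression > 0, noiseSdLog >= 0)
  if (abs(log2fcOther) >= abs(log2fcRef))
    stop("the reference-genotype response must be strictly stronger: ",
         "|log2fcOther| < |log2fcRef|")

  if (is.null(geneIds))
    geneIds <- sprintf("Gene%04d", seq_len(nGenes))
  stopifnot(length(geneIds) == nGenes, !anyDuplicated(geneIds))
  if (!is.null(trendAssignments)) {
    if (is.null(names(trendAssignments)))
      stop("'trendAssignments' must be named by gene ID")
    bad <- setdiff(names(trendAssignments), geneIds)
    if (length(bad))
      stop("trendAssignments names outside the gene set: ",
           paste(utils::head(bad, 5), collapse = ", "))
    ok <- c("up_enhanced", "down_enhanced", "null")
    if (!all(trendAssignments %in% ok))
      stop("trend values must be one of: ", paste(ok, collapse = ", "))
  }
  trend <- stats::setNames(rep("null", nGenes), geneIds)
  if (!is.null(trendAssignments))
    trend[names(trendAssignments)] <- trendAssignments

  design <- expand.grid(replicate = seq_len(nReplicates),
                        treatment = treatments, genotype = genotypes,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)[, 3:1]
  sampleIds <- sprintf("%s_%s_r%d", design$genotype, design$treatment,
                       design$replicate)

  ## per-gene per-genotype flooding log2 fold change
  fc <- matrix(0, nrow = nGenes, ncol = 2,
               dimnames = list(geneIds, genotypes))
  fc[trend == "up_enhanced", ] <- rep(c(abs(log2fcRef), abs(log2fcOther)),
                                      each = sum(trend == "up_enhanced"))
  fc[trend == "down_enhanced", ] <- rep(-c(abs(log2fcRef), abs(log2fcOther)),
                                        each = sum(trend == "down_enhanced"))

  flooded <- design$treatment == treatments[2]
  mu <- matrix(baseExpression, nrow = nGenes, ncol = nrow(design),
               dimnames = list(geneIds, sampleIds))
  for (j in which(flooded))
    mu[, j] <- baseExpression * 2^fc[, design$genotype[j]]

  vals <- withSeed(seed, {
    noise <- matrix(rnorm(length(mu), mean = 0, sd = noiseSdLog),
                    nrow = nrow(mu))
    mu * exp(noise)
  })

  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = vals),
    colData = S4Vectors::DataFrame(design, row.names = sampleIds),
    rowData = S4Vectors::DataFrame(trend = unname(trend),
                                   row.names = geneIds)
  )
}
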
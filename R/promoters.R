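#' Extract fixed-length upstream promoter windows
#'
#' For every gene passing the biotype filter, takes the `upstream` bases
#' immediately 5' of the transcription start site (TSS), excluding the
#' TSS base itself. On the `+` strand with TSS at 1-based position t the
#' window is `[max(1, t-upstream), t-1]` on the forward strand; on the
#' `-` strand it is the reverse complement of
#' `[t+1, min(contig_end, t+upstream)]`, so every promoter reads 5'->3'
#' relative to its gene. Windows truncated at a contig edge are retained
#' with their realized length; a gene whose window is empty (TSS at the
#' very contig edge) is skipped with a warning. One promoter is extracted
#' per gene, anchored at the gene-level TSS (the 5'-most annotated base).
#'
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param genes [GenomicRanges::GRanges] of gene bodies with metadata
#'   columns `gene_id` and `biotype` (as returned by [readGeneModels()]
#'   or [syntheticGenome()]).
#' @param upstream Window length L in bases (default 1000).
#' @param biotype Biotype retained (default `"protein_coding"`); `NULL`
#'   keeps all genes.
#' @return A [PromoterSet] named by gene ID with source coordinates
#'   (1-based inclusive, promoter interval on the forward strand) in its
#'   metadata columns.
#' @seealso [countMotifs()] for downstream k-mer counting.
#' @export
#' @examples
#' g <- syntheticGenome(nContigs = 1, genesPerContig = 3,
#'                      intergenicLen = 1200, geneLen = 500, seed = 2)
#' extractPromoters(g$genome, g$genes, upstream = 1000)
extractPromoters <- function(genome, genes, upstream = 1000L,
                             biotype = "protein_coding") {
  upstream <- checkCount(upstream, "upstream")
  if (!is.null(biotype))
    genes <- genes[genes$biotype %in% biotype]
  if (length(genes) == 0L)
    return(PromoterSet(Biostrings::DNAStringSet(), upstream))

  contigs <- as.character(GenomicRanges::seqnames(genes))
  unknown <- !(contigs %in% names(genome))
  if (any(unknown))
    stop(sprintf("gene '%s' refers to unknown contig '%s'",
                 genes$gene_id[which(unknown)[1]],
                 contigs[which(unknown)[1]]))

  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*"))
    stop("genes must be stranded (+/-): ",
         paste(genes$gene_id[str == "*"], collapse = ", "))
  tss <- ifelse(str == "-", GenomicRanges::end(genes),
                GenomicRanges::start(genes))

  ws <- ifelse(str == "-", tss + 1L, pmax(1L, tss - upstream))
  we <- ifelse(str == "-", pmin(lens[contigs], tss + upstream), tss - 1L)
  empty <- we < ws
  if (any(empty)) {
    warning("skipping gene(s) with empty promoter window at contig edge: ",
            paste(genes$gene_id[empty], collapse = ", "))
    genes <- genes[!empty]; contigs <- contigs[!empty]; str <- str[!empty]
    ws <- ws[!empty]; we <- we[!empty]
  }
  if (length(genes) == 0L)
    return(PromoterSet(Biostrings::DNAStringSet(), upstream))

  seqs <- Biostrings::DNAStringSet(vapply(seq_along(genes), function(i) {
    as.character(Biostrings::subseq(genome[[contigs[i]]], ws[i], we[i]))
  }, character(1)))
  minus <- str == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- genes$gene_id
  PromoterSet(seqs, targetLength = upstream, contig = contigs,
              start = as.integer(ws), end = as.integer(we), strand = str)
}
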
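#' Generate a toy annotated genome
#'
#' Builds a multi-contig random genome with protein-coding genes laid out
#' on a regular grid: each contig is an alternation of intergenic spacers
#' and gene bodies, with a trailing spacer, so that every gene has at least
#' `intergenicLen` bases of gene-free sequence upstream of its TSS on
#' either strand. Strands are drawn from the seeded stream; the TSS is the
#' gene's 5'-most base (start on `+`, end on `-`). With
#' `intergenicLen` larger than the promoter window, upstream windows never
#' overlap a neighboring gene, which keeps promoter-extraction tests free
#' of overlap policy.
#'
#' Identical arguments (including `seed`) give byte-identical output.
#'
#' @param nContigs Number of contigs (0 gives an empty genome).
#' @param genesPerContig Genes per contig.
#' @param intergenicLen Spacer length in bases between/around gene bodies.
#' @param geneLen Gene body length in bases.
#' @param gcFraction Genome GC content in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `genome`, a named [Biostrings::DNAStringSet] of
#'   contigs (with `seqlengths`-compatible names `ctg01`, ...), and
#'   `genes`, a [GenomicRanges::GRanges] of gene bodies with metadata
#'   columns `gene_id`, `biotype` (`"protein_coding"`) and `tss`.
#' @seealso [writeGenome()], [extractPromoters()]
#' @export
#' @examples
#' g <- syntheticGenome(nContigs = 2, genesPerContig = 3,
#'                      intergenicLen = 1200, geneLen = 500, seed = 7)
#' g$genes
syntheticGenome <- function(nContigs = 2L, genesPerContig = 10L,
                            intergenicLen = 1500L, geneLen = 1000L,
                            gcFraction = 0.36, seed = 1L) {
  nContigs <- checkCount(nContigs, "nContigs", min = 0L)
  if (nContigs == 0L) {
    genes <- GenomicRanges::GRanges(
      gene_id = character(), biotype = character(), tss = integer())
    return(list(genome = Biostrings::DNAStringSet(), genes = genes))
  }
  genesPerContig <- checkCount(genesPerContig, "genesPerContig")
  intergenicLen <- checkCount(intergenicLen, "intergenicLen")
  geneLen <- checkCount(geneLen, "geneLen")
  gcFraction <- checkFraction(gcFraction, "gcFraction")

  contigLen <- genesPerContig * (intergenicLen + geneLen) + intergenicLen
  contigNames <- sprintf("ctg%02d", seq_len(nContigs))
  nGenes <- nContigs * genesPerContig

  ## one seeded stream drives bases then strands, in a fixed order
  out <- withSeed(seed, {
    prob <- c((1 - gcFraction) / 2, gcFraction / 2,
              gcFraction / 2, (1 - gcFraction) / 2)
    seqs <- vapply(seq_len(nContigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE,
                   prob = prob), collapse = "")
    }, character(1))
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)
    list(seqs = seqs, strands = strands)
  })

  genome <- Biostrings::DNAStringSet(out$seqs)
  names(genome) <- contigNames

  starts <- rep(intergenicLen + (seq_len(genesPerContig) - 1L) *
                  (intergenicLen + geneLen) + 1L, nContigs)
  genes <- GenomicRanges::GRanges(
    seqnames = rep(contigNames, each = genesPerContig),
    ranges = IRanges::IRanges(start = starts, width = geneLen),
    strand = out$strands,
    seqlengths = stats::setNames(rep(contigLen, nContigs), contigNames)
  )
  genes$gene_id <- sprintf("Gene%04d", seq_len(nGenes))
  genes$biotype <- "protein_coding"
  genes$tss <- ifelse(out$strands == "+", GenomicRanges::start(genes),
                      GenomicRanges::end(genes))
  names(genes) <- genes$gene_id
  list(genome = genome, genes = genes)
}

#' Plant a motif into promoter (or any) sequences
#'
#' Each foreground sequence independently receives one planted copy of
#' `motif` with probability `foregroundRate`; every other sequence with
#' probability `backgroundRate`. A planted copy overwrites exactly
#' `nchar(motif)` bases at a uniformly drawn offset, so sequence lengths
#' (and any genomic coordinates) are unchanged. The returned log records
#' planted copies only; chance occurrences of the motif elsewhere are
#' possible and intentional, which is why downstream tests use presence
#' (at least one occurrence), monotone under extra copies.
#'
#' @param sequences A named [Biostrings::DNAStringSet] (a [PromoterSet]
#'   works and keeps its class and metadata).
#' @param motif Motif string over {A,C,G,T}, no longer than the shortest
#'   sequence.
#' @param foreground Character vector of sequence names forming the
#'   foreground set; must all exist in `sequences`.
#' @param foregroundRate,backgroundRate Per-sequence planting
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `sequences` (modified copy, same class) and
#'   `plantings`, a data.frame with columns `gene_id` and `offset`
#'   (1-based start of the planted copy).
#' @export
plantMotifs <- function(sequences, motif, foreground,
                        foregroundRate = 0.5, backgroundRate = 0.1,
                        seed = 1L) {
  if (!grepl("^[ACGT]+$", motif))
    stop("'motif' must be a non-empty string over A, C, G, T")
  k <- nchar(motif)
  nms <- names(sequences)
  if (length(sequences) && is.null(nms))
    stop("'sequences' must be named")
  missing <- setdiff(foreground, nms)
  if (length(missing))
    stop("foreground gene(s) not in sequences: ",
         paste(missing, collapse = ", "))
  foregroundRate <- checkFraction(foregroundRate, "foregroundRate")
  backgroundRate <- checkFraction(backgroundRate, "backgroundRate")
  w <- Biostrings::width(sequences)
  if (length(sequences) && k > min(w))
    stop("'motif' is longer than the shortest sequence")

  is_fg <- nms %in% foreground
  rate <- ifelse(is_fg, foregroundRate, backgroundRate)
  draw <- withSeed(seed, {
    plant <- runif(length(sequences)) < rate
    ## offsets drawn for all sequences to keep the stream layout simple
    offset <- floor(runif(length(sequences)) * (w - k + 1)) + 1L
    list(plant = plant, offset = as.integer(offset))
  })

  idx <- which(draw$plant)
  plain <- plainDNAStringSet(sequences)
  if (length(idx)) {
    at <- replicate(length(sequences), IRanges::IRanges(), simplify = FALSE)
    val <- rep(list(character(0)), length(sequences))
    for (j in idx) {
      at[[j]] <- IRanges::IRanges(start = draw$offset[j], width = k)
      val[[j]] <- motif
    }
    plain <- Biostrings::replaceAt(plain, at = as(at, "IRangesList"),
                                   value = as(val, "CharacterList"))
  }
  out <- sequences
  if (is(sequences, "PromoterSet")) {
    out <- new("PromoterSet", plain, targetLength = targetLength(sequences))
    S4Vectors::mcols(out) <- S4Vectors::mcols(sequences)
    names(out) <- nms
  } else {
    out <- plain
    names(out) <- nms
  }
  log <- data.frame(gene_id = nms[idx],
                    offset = draw$offset[idx],
                    stringsAsFactors = FALSE)
  list(sequences = out, plantings = log)
}
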
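#' Read and write the pipeline's standard file formats
#'
#' @description
#' Thin wrappers around Biostrings and rtracklayer that fix the on-disk
#' conventions used throughout the pipeline:
#' \itemize{
#'   \item genome FASTA wrapped at 60 columns; sequences are uppercased on
#'     read (soft-masking is dropped), `N`s are preserved;
#'   \item GFF3 (1-based inclusive, strand `+`/`-`) with `gene` features
#'     carrying `ID` and `biotype` attributes;
#'   \item promoter FASTA with headers `gene_id|contig:start-end(strand)`
#'     plus a sidecar TSV of per-gene realized lengths;
#'   \item expression matrix TSV (genes x samples, one header line) with a
#'     separate design TSV (`sample`, `genotype`, `treatment`,
#'     `replicate`);
#'   \item plain-text gene lists, one ID per line.
#' }
#'
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param genes [GenomicRanges::GRanges] with `gene_id` and `biotype`
#'   metadata columns.
#' @param fastaPath,gffPath,path,matrixPath,designPath File paths.
#' @return Readers return the corresponding in-memory object; writers
#'   return the path invisibly.
#' @name promoscan-io
NULL

#' @rdname promoscan-io
#' @export
writeGenome <- function(genome, genes, fastaPath, gffPath) {
  Biostrings::writeXStringSet(genome, fastaPath, width = 60L)
  gr <- genes
  gr$ID <- gr$gene_id
  gr$type <- "gene"
  rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}

#' @rdname promoscan-io
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ## drop description after first whitespace, as genome FASTA headers carry
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname promoscan-io
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (is.null(gr$ID) || anyNA(gr$ID))
    stop("GFF3 gene features must carry an ID attribute: ", path)
  gr$gene_id <- gr$ID
  if (is.null(gr$biotype))
    gr$biotype <- "protein_coding"
  gr$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                   GenomicRanges::end(gr), GenomicRanges::start(gr))
  names(gr) <- gr$gene_id
  gr
}

#' @rdname promoscan-io
#' @param promoters A [PromoterSet].
#' @param lengthsPath Optional path for the sidecar per-gene length TSV.
#' @export
writePromoters <- function(promoters, path, lengthsPath = NULL) {
  stopifnot(is(promoters, "PromoterSet"))
  mc <- S4Vectors::mcols(promoters)
  out <- plainDNAStringSet(promoters)
  names(out) <- sprintf("%s|%s:%d-%d(%s)", names(promoters),
                        mc$contig, mc$start, mc$end, mc$strand)
  Biostrings::writeXStringSet(out, path, width = 60L)
  if (!is.null(lengthsPath)) {
    df <- data.frame(gene_id = names(promoters),
                     length = Biostrings::width(promoters))
    write.table(df, lengthsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname promoscan-io
#' @param targetLength Target window length recorded in the returned
#'   [PromoterSet]; defaults to the longest sequence in the file.
#' @export
readPromoters <- function(path, targetLength = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  m <- regmatches(hdr, regexec(
    "^([^|]+)\\|([^:]+):(\\d+)-(\\d+)\\(([+-])\\)", hdr))
  parsed <- lengths(m) == 6L
  gene <- ifelse(parsed, vapply(m, function(p) p[2], character(1)),
                 sub("\\s.*$", "", hdr))
  if (is.null(targetLength))
    targetLength <- max(Biostrings::width(x), 1L)
  PromoterSet(
    stats::setNames(x, gene),
    targetLength = targetLength,
    contig = ifelse(parsed, vapply(m, `[`, character(1), 3), NA),
    start = ifelse(parsed, as.integer(vapply(m, `[`, character(1), 4)), NA),
    end = ifelse(parsed, as.integer(vapply(m, `[`, character(1), 5)), NA),
    strand = ifelse(parsed, vapply(m, `[`, character(1), 6), NA)
  )
}

#' @rdname promoscan-io
#' @param se A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `fpkm` and design columns in `colData`.
#' @export
writeExpression <- function(se, matrixPath, designPath) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(se)
  design <- data.frame(sample = rownames(cd),
                       genotype = cd$genotype, treatment = cd$treatment,
                       replicate = cd$replicate)
  write.table(design, designPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrixPath, designPath))
}

#' @rdname promoscan-io
#' @export
readExpression <- function(matrixPath, designPath) {
  mat <- read.delim(matrixPath, check.names = FALSE)
  rownames(mat) <- mat$gene_id
  mat <- as.matrix(mat[, -1, drop = FALSE])
  design <- read.delim(designPath, colClasses = "character")
  design$replicate <- as.integer(design$replicate)
  need <- c("sample", "genotype", "treatment", "replicate")
  if (!all(need %in% colnames(design)))
    stop("design TSV must have columns: ", paste(need, collapse = ", "))
  if (!setequal(design$sample, colnames(mat)))
    stop("design samples do not match expression matrix columns")
  mat <- mat[, design$sample, drop = FALSE]
  if (anyNA(mat) || any(mat < 0))
    stop("expression values must be non-negative and complete")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(design[, -1], row.names = design$sample)
  )
}

#' @rdname promoscan-io
#' @param lists Named list of character vectors of gene IDs.
#' @param dir Output directory.
#' @export
writeGeneLists <- function(lists, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0("genes_", names(lists), ".txt"))
  for (i in seq_along(lists))
    writeLines(lists[[i]], paths[i])
  invisible(stats::setNames(paths, names(lists)))
}

#' @rdname promoscan-io
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
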
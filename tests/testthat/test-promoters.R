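## explicit two-gene toy contig: coordinates checked by hand slicing
handGenome <- function() {
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  DNAStringSet(c(chrT = s))
}

test_that("a plus-strand promoter is the L bases ending just before the TSS", {
  set.seed(101)
  genome <- handGenome()
  genes <- GRanges("chrT", IRanges(1001, 1600), strand = "+",
                   gene_id = "gP", biotype = "protein_coding",
                   seqlengths = c(chrT = 2000))
  p <- extractPromoters(genome, genes, upstream = 1000)
  expect_identical(as.character(p[["gP"]]),
                   as.character(subseq(genome[[1]], 1, 1000)))
  expect_identical(unname(promoterLengths(p)), 1000L)
})

test_that("a minus-strand promoter is the reverse complement downstream", {
  set.seed(102)
  genome <- handGenome()
  genes <- GRanges("chrT", IRanges(400, 1000), strand = "-",
                   gene_id = "gM", biotype = "protein_coding",
                   seqlengths = c(chrT = 2000))
  p <- extractPromoters(genome, genes, upstream = 1000)
  expect_identical(
    as.character(p[["gM"]]),
    as.character(reverseComplement(subseq(genome[[1]], 1001, 2000))))
})

test_that("contig-edge windows are truncated, empty ones skipped", {
  set.seed(103)
  genome <- handGenome()
  genes <- GRanges("chrT", IRanges(c(500, 1, 1500), c(600, 80, 2000)),
                   strand = c("+", "+", "-"),
                   gene_id = c("gTrunc", "gEdge", "gEdgeM"),
                   biotype = "protein_coding",
                   seqlengths = c(chrT = 2000))
  expect_warning(p <- extractPromoters(genome, genes, upstream = 1000),
                 "gEdge")
  ## truncated plus-strand promoter: bases 1..499
  expect_identical(as.character(p[["gTrunc"]]),
                   as.character(subseq(genome[[1]], 1, 499)))
  expect_identical(unname(promoterLengths(p)["gTrunc"]), 499L)
  ## TSS at base 1 (plus) and at the last base (minus) yield no window
  expect_false("gEdge" %in% names(p))
  expect_false("gEdgeM" %in% names(p))
})

test_that("biotype filtering and unknown contigs behave as specified", {
  set.seed(104)
  genome <- handGenome()
  genes <- GRanges(c("chrT", "chrT"), IRanges(c(1001, 1201), width = 100),
                   strand = "+", gene_id = c("gPC", "gNC"),
                   biotype = c("protein_coding", "lncRNA"),
                   seqlengths = c(chrT = 2000))
  p <- extractPromoters(genome, genes)
  expect_identical(names(p), "gPC")
  bad <- GRanges("chrX", IRanges(1001, 1100), strand = "+",
                 gene_id = "gBad", biotype = "protein_coding")
  expect_error(extractPromoters(genome, bad), "gBad")
})

test_that("extracted promoters equal the generator's known upstream slice", {
  g <- smallGenome()
  p <- extractPromoters(g$genome, g$genes, upstream = 1000)
  expect_identical(sort(names(p)), sort(g$genes$gene_id))
  for (i in seq_along(g$genes)) {
    gene <- g$genes[i]
    contig <- g$genome[[as.character(seqnames(gene))]]
    expected <- if (as.character(strand(gene)) == "+") {
      subseq(contig, start(gene) - 1000, start(gene) - 1)
    } else {
      reverseComplement(subseq(contig, end(gene) + 1, end(gene) + 1000))
    }
    expect_identical(as.character(p[[gene$gene_id]]),
                     as.character(expected))
  }
})

test_that("extraction is invariant under full genome reverse complement", {
  g <- smallGenome()
  p <- extractPromoters(g$genome, g$genes)
  lens <- setNames(width(g$genome), names(g$genome))
  rcGenome <- reverseComplement(g$genome)
  rcGenes <- g$genes
  newStart <- lens[as.character(seqnames(g$genes))] - end(g$genes) + 1
  newEnd <- lens[as.character(seqnames(g$genes))] - start(g$genes) + 1
  rcGenes <- GRanges(seqnames(g$genes), IRanges(newStart, newEnd),
                     strand = ifelse(strand(g$genes) == "+", "-", "+"),
                     gene_id = g$genes$gene_id,
                     biotype = g$genes$biotype,
                     seqlengths = lens)
  p2 <- extractPromoters(rcGenome, rcGenes)
  expect_identical(as.character(p2[names(p)]), as.character(p))
})

test_that("promoter FASTA round trip is exact, including coordinates", {
  g <- smallGenome()
  p <- extractPromoters(g$genome, g$genes)
  fa <- tempfile(fileext = ".fa")
  writePromoters(p, fa)
  p2 <- readPromoters(fa, targetLength = targetLength(p))
  expect_identical(as.character(p2), as.character(p))
  expect_identical(names(p2), names(p))
  expect_equal(as.data.frame(S4Vectors::mcols(p2)),
               as.data.frame(S4Vectors::mcols(p)))
  expect_identical(targetLength(p2), targetLength(p))
})

test_that("lowercase genome FASTA is uppercased on read, Ns preserved", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgtnACGTN"), fa)
  x <- readGenomeFasta(fa)
  expect_identical(as.character(x[[1]]), "ACGTNACGTN")
})
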
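suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

## tiny annotated genome used across promoter tests
smallGenome <- function(seed = 11L) {
  syntheticGenome(nContigs = 2L, genesPerContig = 5L,
                  intergenicLen = 1200L, geneLen = 400L,
                  gcFraction = 0.4, seed = seed)
}

## a PromoterSet built directly from explicit sequences
promoterSetFrom <- function(seqs, targetLength = max(nchar(seqs))) {
  promoscan:::PromoterSet(Biostrings::DNAStringSet(seqs),
                          targetLength = targetLength)
}

## 300-gene planted-trend matrix at the benchmark noise level
plantedExpression <- function(seed = 5L, noiseSdLog = 0.1) {
  trend <- setNames(
    rep(c("up_enhanced", "down_enhanced", "null"), each = 100),
    sprintf("Gene%04d", 1:300))
  syntheticExpression(nGenes = 300L, trendAssignments = trend,
                      nReplicates = 3L, baseExpression = 50,
                      log2fcRef = 2, log2fcOther = 1,
                      noiseSdLog = noiseSdLog, seed = seed)
}

## independent brute-force window scan: counts of every k-mer in one string
bruteForceKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(table(factor(character(), levels = character())))
  wins <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  wins <- wins[grepl("^[ACGT]+$", wins)]
  table(wins)
}

## independent hypergeometric upper tail by direct choose() summation
bruteForceHyper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- max(k, max(0, K + n - N)):hi
  sum(choose(n, i) * choose(N - n, K - i)) / choose(N, K)
}

## independent BH step-up evaluated from the definition
bruteForceBH <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## expand an IUPAC pattern into its explicit set of concrete sequences
iupacExpand <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  opts <- strsplit(map[strsplit(pattern, "")[[1]]], "")
  do.call(paste0, do.call(expand.grid, opts))
}
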
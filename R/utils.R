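#' @importFrom methods new is validObject setClass setGeneric setMethod show
#' @importFrom stats dist hclust cutree phyper p.adjust rnorm runif
#' @importFrom utils read.delim write.table packageVersion
NULL

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. All generators route their randomness through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Seeded random DNA sequences
#'
#' Draws independent sequences over {A,C,G,T} with a target GC fraction.
#' Used by the synthetic-genome generator and directly in benchmarks that
#' need promoter-sized random sequence without a full genome.
#'
#' @param n Number of sequences.
#' @param width Length of each sequence in bases (scalar or vector of
#'   length `n`).
#' @param gcFraction Probability that a base is G or C, in `[0, 1]`.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A [Biostrings::DNAStringSet] of `n` sequences.
#' @export
#' @examples
#' randomDNA(3, 20, gcFraction = 0.4, seed = 1)
randomDNA <- function(n, width, gcFraction = 0.5, seed = 1L) {
  stopifnot(length(n) == 1L, n >= 0)
  if (!is.numeric(gcFraction) || gcFraction < 0 || gcFraction > 1)
    stop("'gcFraction' must be in [0, 1]")
  width <- rep_len(as.integer(width), n)
  if (n > 0 && any(width < 0)) stop("'width' must be non-negative")
  prob <- c((1 - gcFraction) / 2, gcFraction / 2,
            gcFraction / 2, (1 - gcFraction) / 2)
  seqs <- withSeed(seed, {
    vapply(width, function(w) {
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
  })
  Biostrings::DNAStringSet(seqs)
}

## downgrade a PromoterSet (or any XStringSet) to a bare DNAStringSet
## without the mcols-drop warning
plainDNAStringSet <- function(x) {
  if (is(x, "XStringSet"))
    S4Vectors::mcols(x) <- NULL
  Biostrings::DNAStringSet(x)
}

## single positive-integer check with a domain-specific message
checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

checkFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a fraction in [0, 1]", name))
  as.numeric(x)
}
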
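#' Count k-mer motifs in foreground vs all promoters
#'
#' Tabulates every k-mer over {A,C,G,T} in a foreground subset of
#' promoters and in the full promoter set (the background), on the
#' promoter strand as extracted (no reverse-complement collapsing).
#' Sliding windows containing any non-ACGT character are skipped.
#'
#' In `"presence"` mode a promoter contributes at most 1 to a motif's
#' count (the motif is present or not) and the denominators are promoter
#' counts. In `"occurrence"` mode every window is counted and the
#' denominators are the total number of valid windows
#' (`sum(length - k + 1)` minus windows containing `N`).
#'
#' @param promoters A [PromoterSet] (or named [Biostrings::DNAStringSet])
#'   of all genome promoters, the background.
#' @param foreground Character vector of gene IDs forming the foreground;
#'   every ID must be present in `promoters`.
#' @param k Motif length (default 6, hexamers).
#' @param mode `"presence"` (default) or `"occurrence"`.
#' @return A [MotifCountTable] with one row per k-mer (all `4^k`,
#'   including zero counts, so the multiple-testing family is stable).
#' @seealso [motifEnrichment()] for scoring the table.
#' @export
#' @examples
#' p <- PromoterSet(Biostrings::DNAStringSet(c(g1 = "ACGTACGT")), 8)
#' motifCounts(countMotifs(p, "g1", k = 6, mode = "occurrence"))[1:3, ]
countMotifs <- function(promoters, foreground, k = 6L,
                        mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  k <- checkCount(k, "k")
  x <- plainDNAStringSet(promoters)
  if (length(x) == 0L)
    stop("'promoters' is empty")
  if (is.null(names(x)))
    stop("'promoters' must be named by gene ID")
  missing <- setdiff(foreground, names(x))
  if (length(missing))
    stop("foreground gene(s) without a promoter: ",
         paste(missing, collapse = ", "))
  if (k > min(Biostrings::width(x)))
    stop("'k' exceeds the shortest promoter length")

  ## per-promoter occurrence counts of all 4^k words; windows containing
  ## non-ACGT letters are dropped by oligonucleotideFrequency
  occ <- Biostrings::oligonucleotideFrequency(x, width = k)
  fg <- names(x) %in% foreground

  if (mode == "presence") {
    k_fg <- colSums(occ[fg, , drop = FALSE] > 0)
    n_bg <- colSums(occ > 0)
    K_fg <- sum(fg)
    N_bg <- length(x)
  } else {
    k_fg <- colSums(occ[fg, , drop = FALSE])
    n_bg <- colSums(occ)
    K_fg <- sum(occ[fg, , drop = FALSE])
    N_bg <- sum(occ)
  }
  counts <- S4Vectors::DataFrame(motif = colnames(occ),
                                 k_fg = as.numeric(k_fg),
                                 n_bg = as.numeric(n_bg))
  rownames(counts) <- NULL
  new("MotifCountTable", counts = counts, k = k, mode = mode,
      K_fg = as.numeric(K_fg), N_bg = as.numeric(N_bg))
}

#' Motif enrichment fraction
#'
#' The ratio of a motif's relative frequency among foreground promoters
#' to its relative frequency among all genome promoters:
#' `(k_fg / K_fg) / (n_bg / N_bg)`. A value of 1 means the motif is
#' exactly as frequent in the foreground as genome-wide; the pipeline's
#' default retention threshold is 1.1. Vectorized over all arguments;
#' full floating precision is retained.
#'
#' @param k_fg Motif count in foreground promoters.
#' @param K_fg Foreground denominator (number of foreground promoters, or
#'   total foreground windows in occurrence mode).
#' @param n_bg Motif count in all genome promoters; must be positive (a
#'   motif absent from the background cannot be scored).
#' @param N_bg Background denominator.
#' @return Numeric vector of enrichment fractions.
#' @export
#' @examples
#' enrichmentFraction(128, 849, 3824, 34417)  # 1.35692989
enrichmentFraction <- function(k_fg, K_fg, n_bg, N_bg) {
  if (any(K_fg <= 0)) stop("'K_fg' must be positive")
  if (any(N_bg <= 0)) stop("'N_bg' must be positive")
  if (any(n_bg <= 0))
    stop("'n_bg' must be positive: a motif absent from the background ",
         "promoters cannot be scored")
  if (any(k_fg < 0)) stop("'k_fg' must be non-negative")
  (k_fg / K_fg) / (n_bg / N_bg)
}

#' Upper-tail hypergeometric p-value for motif enrichment
#'
#' Probability of observing at least `k_fg` promoters containing the
#' motif when `K_fg` promoters are drawn without replacement from a
#' population of `N_bg` promoters of which `n_bg` contain it:
#' `P(X >= k_fg)` with `X ~ Hypergeometric(N_bg, n_bg, K_fg)`. Computed
#' via [stats::phyper], whose log-space internals are numerically safe in
#' the extreme tails. Vectorized.
#'
#' @inheritParams enrichmentFraction
#' @return p-values in `(0, 1]`; `k_fg = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeomPvalue(2, 2, 2, 4)  # 1/6
hypergeomPvalue <- function(k_fg, K_fg, n_bg, N_bg) {
  n <- max(length(k_fg), length(K_fg), length(n_bg), length(N_bg))
  k_fg <- rep_len(k_fg, n); K_fg <- rep_len(K_fg, n)
  n_bg <- rep_len(n_bg, n); N_bg <- rep_len(N_bg, n)
  if (any(k_fg < 0) || any(n_bg < 0) || any(K_fg < 0) || any(N_bg < 1))
    stop("counts must be non-negative (N_bg >= 1)")
  if (any(n_bg > N_bg) || any(K_fg > N_bg))
    stop("'n_bg' and 'K_fg' cannot exceed 'N_bg'")
  if (any(k_fg > pmin(K_fg, n_bg)))
    stop("inconsistent counts: k_fg exceeds min(K_fg, n_bg)")
  phyper(k_fg - 1, m = n_bg, n = N_bg - n_bg, k = K_fg,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment
#' `q_(i) = min_(j>=i) (p_(j) * m / j)` clipped at 1, returned in the
#' input order (delegates to [stats::p.adjust]). The family size `m` is
#' the full input length: callers pass p-values for all motifs in the
#' count table, not only those above the enrichment threshold, so the
#' FDR is not misstated by an effect-size pre-filter.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Score a motif count table
#'
#' Computes, for every motif in the table, the enrichment fraction, the
#' upper-tail hypergeometric p-value, the BH-adjusted q-value (family =
#' all `4^k` motifs) and a pass flag (`enrichment >= minEnrichment` and
#' `q <= alpha`). Motifs absent from the foreground get enrichment 0 and
#' p = 1 rather than being dropped, keeping the BH family stable; motifs
#' absent from the background as well are retained the same way.
#'
#' @param countTable A [MotifCountTable] from [countMotifs()].
#' @param minEnrichment Retention threshold on the enrichment fraction
#'   (default 1.1).
#' @param alpha FDR level for the BH criterion (default 0.05).
#' @return A [S4Vectors::DataFrame] with columns `motif`, `k_fg`, `K_fg`,
#'   `n_bg`, `N_bg`, `enrichment`, `p_raw`, `q_bh`, `passes`, one row per
#'   motif in table order.
#' @seealso [filterEnriched()], [annotateMotifs()]
#' @export
motifEnrichment <- function(countTable, minEnrichment = 1.1, alpha = 0.05) {
  stopifnot(is(countTable, "MotifCountTable"))
  cts <- motifCounts(countTable)
  K <- countTable@K_fg
  N <- countTable@N_bg
  scorable <- cts$k_fg > 0 & cts$n_bg > 0
  enr <- numeric(nrow(cts))
  enr[scorable] <- enrichmentFraction(cts$k_fg[scorable], K,
                                      cts$n_bg[scorable], N)
  p <- rep(1, nrow(cts))
  p[scorable] <- hypergeomPvalue(cts$k_fg[scorable], K,
                                 cts$n_bg[scorable], N)
  q <- bhAdjust(p)
  res <- S4Vectors::DataFrame(
    motif = cts$motif, k_fg = cts$k_fg, K_fg = K,
    n_bg = cts$n_bg, N_bg = N,
    enrichment = enr, p_raw = p, q_bh = q,
    passes = enr >= minEnrichment & q <= alpha)
  S4Vectors::metadata(res) <- list(mode = countingMode(countTable),
                                   k = countTable@k,
                                   min_enrichment = minEnrichment,
                                   alpha = alpha)
  res
}

#' Filter and rank enriched motifs
#'
#' Retains motifs with `enrichment >= minEnrichment` and `q_bh <= alpha`
#' and sorts them by enrichment descending, ties broken by raw p-value
#' ascending. The `passes` flag is (re)set on all records before
#' filtering.
#'
#' @param records A `DataFrame`/data.frame of enrichment records as
#'   produced by [motifEnrichment()].
#' @param minEnrichment,alpha Thresholds (defaults 1.1 and 0.05).
#' @return The retained records, sorted.
#' @export
filterEnriched <- function(records, minEnrichment = 1.1, alpha = 0.05) {
  need <- c("motif", "enrichment", "p_raw", "q_bh")
  if (!all(need %in% colnames(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$passes <- records$enrichment >= minEnrichment &
    records$q_bh <= alpha
  out <- records[records$passes, , drop = FALSE]
  out[order(-out$enrichment, out$p_raw), , drop = FALSE]
}
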
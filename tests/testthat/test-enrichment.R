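test_that("occurrence counting enumerates sliding windows by hand", {
  p <- promoterSetFrom(c(g1 = "ACGTACGT"))
  mct <- countMotifs(p, "g1", k = 6, mode = "occurrence")
  cts <- motifCounts(mct)
  nz <- cts[cts$n_bg > 0, ]
  expect_setequal(nz$motif, c("ACGTAC", "CGTACG", "GTACGT"))
  expect_true(all(nz$n_bg == 1))
  expect_equal(unname(countDenominators(mct)),
               c(3, 3))  # 8 - 6 + 1 windows, foreground == background
})

test_that("presence counting records promoters, not occurrences", {
  p <- promoterSetFrom(c(g1 = "ACGTACGT"))
  mct <- countMotifs(p, "g1", k = 6, mode = "presence")
  cts <- motifCounts(mct)
  nz <- cts[cts$n_bg > 0, ]
  expect_true(all(nz$k_fg == 1))
  expect_equal(unname(countDenominators(mct)), c(1, 1))
  ## a repeated motif still counts once per promoter
  p2 <- promoterSetFrom(c(g1 = "CACGTGCACGTG", g2 = "AAAAAAAAAAAA"))
  mct2 <- countMotifs(p2, "g1", k = 6, mode = "presence")
  cts2 <- motifCounts(mct2)
  expect_equal(cts2$n_bg[cts2$motif == "CACGTG"], 1)
  occ2 <- countMotifs(p2, "g1", k = 6, mode = "occurrence")
  expect_equal(motifCounts(occ2)$n_bg[cts2$motif == "CACGTG"], 2)
})

test_that("window totals match an independent brute-force scan", {
  p <- randomDNA(20, 1000, seed = 13)
  names(p) <- sprintf("g%02d", 1:20)
  ps <- promoterSetFrom(as.character(p))
  mct <- countMotifs(ps, names(p)[1:5], k = 6, mode = "occurrence")
  cts <- motifCounts(mct)
  expect_equal(sum(cts$n_bg), 20 * 995)
  ## per-motif counts equal the brute-force scan summed over promoters
  wins <- unlist(lapply(as.character(p), function(s)
    substring(s, 1:995, 6:1000)))
  brute <- table(wins)
  got <- setNames(cts$n_bg, cts$motif)
  expect_equal(unname(got[names(brute)]), unname(as.numeric(brute)))
  expect_equal(sum(got), sum(brute))
})

test_that("windows containing N are skipped in both modes", {
  p <- promoterSetFrom(c(g1 = "ACGNTACGTA"))
  occ <- countMotifs(p, "g1", k = 6, mode = "occurrence")
  ## only windows 5..10 avoid the N: TACGTA
  cts <- motifCounts(occ)
  expect_equal(sum(cts$n_bg), 1)
  expect_equal(cts$n_bg[cts$motif == "TACGTA"], 1)
})

test_that("enrichment fraction reproduces published table values", {
  expect_equal(enrichmentFraction(128, 849, 3824, 34417), 1.35692989,
               tolerance = 5e-7)
  expect_equal(enrichmentFraction(110, 631, 3947, 34417), 1.52008968,
               tolerance = 5e-7)
  expect_identical(enrichmentFraction(10, 100, 100, 1000), 1)
})

test_that("enrichment fraction is scale free and validates inputs", {
  base <- enrichmentFraction(7, 50, 300, 2000)
  for (c in c(2, 10, 0.5))
    expect_equal(enrichmentFraction(7 * c, 50 * c, 300 * c, 2000 * c),
                 base, tolerance = 1e-12)
  expect_error(enrichmentFraction(1, 0, 10, 100), "K_fg")
  expect_error(enrichmentFraction(1, 10, 0, 100), "n_bg")
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  ## N=4, n=2, K=2: C(4,2)=6 equally likely samples, one has both
  expect_equal(hypergeomPvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-14)
  ## N=20, n=6, K=8, k=4 against direct summation
  expect_equal(hypergeomPvalue(4, 8, 6, 20), bruteForceHyper(4, 8, 6, 20),
               tolerance = 1e-14)
  expect_identical(hypergeomPvalue(0, 8, 6, 20), 1)
  expect_error(hypergeomPvalue(7, 8, 6, 20), "inconsistent")
  expect_error(hypergeomPvalue(9, 8, 10, 20), "inconsistent")
})

test_that("hypergeometric tail is strictly decreasing in the count", {
  for (spec in list(c(K = 10, n = 12, N = 25), c(K = 5, n = 5, N = 8))) {
    lo <- max(0, spec[["K"]] + spec[["n"]] - spec[["N"]])
    ks <- lo:min(spec[["K"]], spec[["n"]])
    ps <- hypergeomPvalue(ks, spec[["K"]], spec[["n"]], spec[["N"]])
    expect_true(all(diff(ps) < 0))
  }
})

test_that("BH adjustment matches the hand step-up evaluation", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  p <- c(0.003, 0.04, 0.2, 0.6, 0.008)
  expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-15)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("motif scoring keeps the full family and flags passers", {
  p <- randomDNA(60, 400, seed = 17)
  names(p) <- sprintf("g%02d", 1:60)
  planted <- plantMotifs(promoterSetFrom(as.character(p)), "CACGTG",
                         names(p)[1:20], foregroundRate = 1,
                         backgroundRate = 0, seed = 18)
  mct <- countMotifs(planted$sequences, names(p)[1:20], k = 6)
  res <- motifEnrichment(mct)
  expect_equal(nrow(res), 4^6)
  expect_true(all(res$q_bh >= res$p_raw))
  ## absent-from-foreground motifs keep enrichment 0 and p 1
  zero <- res[res$k_fg == 0, ]
  expect_true(all(zero$enrichment == 0) && all(zero$p_raw == 1))
  row <- res[res$motif == "CACGTG", ]
  expect_true(row$passes)
  expect_gt(row$enrichment, 1.1)
})

test_that("filtering applies both thresholds and the sort order", {
  rec <- S4Vectors::DataFrame(
    motif = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
    enrichment = c(1.36, 1.09, 1.5, 1.36),
    p_raw = c(0.002, 1e-9, 0.001, 0.001),
    q_bh = c(0.000215, 1e-9, 0.2, 0.0004))
  out <- filterEnriched(rec, minEnrichment = 1.1, alpha = 0.05)
  ## 1.09 fails the threshold even at tiny q; q=0.2 fails significance;
  ## ties on enrichment break by raw p ascending
  expect_identical(out$motif, c("TTTTTT", "AAAAAA"))
  expect_true(all(out$passes))
})

test_that("counting validates the foreground and promoter lengths", {
  p <- promoterSetFrom(c(g1 = "ACGTACGT"))
  expect_error(countMotifs(p, "gX"), "gX")
  expect_error(countMotifs(p, "g1", k = 9), "shortest")
})
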
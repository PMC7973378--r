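## build a SummarizedExperiment directly from a cell-mean specification:
## one replicate per cell keeps hand-computed profiles exact
seFromCells <- function(cells) {
  ## cells: genes x 4 matrix, columns A.control, A.flooded, B.control,
  ## B.flooded
  design <- data.frame(
    genotype = rep(c("A", "B"), each = 2),
    treatment = rep(c("control", "flooded"), 2),
    replicate = 1L)
  colnames(cells) <- sprintf("%s_%s_r1", design$genotype, design$treatment)
  SummarizedExperiment(
    assays = list(fpkm = cells),
    colData = DataFrame(design, row.names = colnames(cells)))
}

test_that("identical profiles merge at height zero into one cluster", {
  cells <- rbind(g1 = c(10, 40, 10, 20), g2 = c(10, 40, 10, 20))
  se <- seFromCells(cells)
  cl <- clusterTrends(se, nClusters = 1)
  expect_equal(unname(clusterAssignments(cl)), c(1L, 1L))
  expect_equal(cl@tree$height, 0)
})

test_that("complete linkage merges the closest pair first", {
  ## 1-D profiles at mutual distances 1, 2, 3 after raw clustering; use
  ## profiles whose z-scores preserve the ordering of pair distances
  cells <- rbind(gA = c(0, 1, 0, 1), gB = c(0, 1, 0, 1) * 1.0001,
                 gC = c(1, 0, 1, 0))
  se <- seFromCells(cells + 10)
  cl <- clusterTrends(se, nClusters = 2)
  asg <- clusterAssignments(cl)
  expect_identical(asg[["gA"]], asg[["gB"]])
  expect_false(asg[["gC"]] == asg[["gA"]])
})

test_that("well-separated planted groups are recovered exactly", {
  ## noise-free: same-group profiles are identical points after row
  ## standardization (flat null genes standardize to exact zeros)
  se <- plantedExpression(seed = 21, noiseSdLog = 0)
  cl <- clusterTrends(se, nClusters = 3)
  asg <- clusterAssignments(cl)
  trend <- setNames(rowData(se)$trend, rownames(se))
  ## each planted group maps to exactly one cluster
  tab <- table(trend[names(asg)], asg)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0) == 1)))
  expect_true(all(apply(tab, 2, function(c) sum(c > 0) == 1)))
})

test_that("trend labeling follows the genotype-contrasted fold changes", {
  cells <- rbind(up = c(10, 40, 10, 20),
                 down = c(10, 2.5, 10, 5),
                 flat = c(10, 10, 10, 10))
  se <- seFromCells(cells)
  cl <- clusterTrends(se, nClusters = 3)
  cl <- labelTrends(cl, se, pseudocount = 1)
  asg <- clusterAssignments(cl)
  labs <- clusterLabels(cl)
  expect_identical(unname(labs[as.character(asg[["up"]])]), "up_enhanced")
  expect_identical(unname(labs[as.character(asg[["down"]])]),
                   "down_enhanced")
  expect_identical(unname(labs[as.character(asg[["flat"]])]), "other")
  ## the cluster fold changes are the pseudocounted hand values
  fc <- cl@log2fc[as.character(asg[["up"]]), ]
  expect_equal(unname(fc["A"]), log2(41 / 11), tolerance = 1e-12)
  expect_equal(unname(fc["B"]), log2(21 / 11), tolerance = 1e-12)
})

test_that("an exact tie between genotype fold changes labels other", {
  cells <- rbind(tie = c(10, 40, 10, 40), ref = c(10, 10, 10, 10))
  se <- seFromCells(cells)
  cl <- clusterTrends(se, nClusters = 2)
  cl <- labelTrends(cl, se)
  labs <- clusterLabels(cl)
  asg <- clusterAssignments(cl)
  expect_identical(unname(labs[as.character(asg[["tie"]])]), "other")
})

test_that("gene lists collect labeled clusters and exclude other", {
  cells <- rbind(u1 = c(10, 40, 10, 20), u2 = c(10, 38, 10, 19),
                 f1 = c(10, 10, 10, 10), f2 = c(12, 12, 12, 12))
  se <- seFromCells(cells)
  cl <- labelTrends(clusterTrends(se, nClusters = 2), se)
  lists <- trendGeneLists(cl)
  expect_setequal(lists$up_enhanced, c("u1", "u2"))
  expect_length(lists$down_enhanced, 0)
})

test_that("planted trend groups are recovered with >= 95% sensitivity", {
  se <- plantedExpression(seed = 31, noiseSdLog = 0.1)
  cl <- labelTrends(clusterTrends(se, nClusters = 3), se)
  lists <- trendGeneLists(cl)
  trend <- setNames(rowData(se)$trend, rownames(se))
  up <- names(trend)[trend == "up_enhanced"]
  down <- names(trend)[trend == "down_enhanced"]
  expect_gte(length(intersect(lists$up_enhanced, up)) / length(up), 0.95)
  expect_gte(length(intersect(lists$down_enhanced, down)) / length(down),
             0.95)
})

test_that("memberships are invariant to gene order on tie-free data", {
  se <- plantedExpression(seed = 41, noiseSdLog = 0.1)
  cl1 <- clusterTrends(se, nClusters = 3)
  set.seed(99); ord <- sample(nrow(se))
  cl2 <- clusterTrends(se[ord, ], nClusters = 3)
  a1 <- clusterAssignments(cl1)
  a2 <- clusterAssignments(cl2)[names(a1)]
  ## same partition up to cluster relabeling
  expect_equal(length(unique(paste(a1, a2))), length(unique(a1)))
})

test_that("labels are scale invariant on noise-free planted data", {
  se <- plantedExpression(seed = 51, noiseSdLog = 0)
  cl <- labelTrends(clusterTrends(se, nClusters = 3), se)
  se10 <- se
  assay(se10) <- assay(se) * 10
  cl10 <- labelTrends(clusterTrends(se10, nClusters = 3), se10)
  l1 <- clusterLabels(cl)[as.character(clusterAssignments(cl))]
  l2 <- clusterLabels(cl10)[as.character(clusterAssignments(cl10))]
  expect_identical(unname(l1), unname(l2))
})

test_that("invalid clustering inputs are rejected", {
  se <- plantedExpression(seed = 1)
  expect_error(clusterTrends(se, nClusters = 0), "nClusters")
  expect_error(clusterTrends(se, nClusters = 1000), "cannot exceed")
  cl <- clusterTrends(se, nClusters = 3)
  expect_error(trendGeneLists(cl), "unlabeled")
  se2 <- plantedExpression(seed = 2)
  rownames(se2) <- paste0("X", rownames(se2))
  expect_error(labelTrends(cl, se2), "gene sets differ")
})
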
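#' Run the promoter motif enrichment pipeline end-to-end
#'
#' Orchestrates all stages: acquire a genome + annotation + expression
#' matrix (either from files or from the seeded synthetic generator),
#' extract promoters, cluster expression trends and label them, derive
#' the up/down foreground gene lists, count hexamers and score
#' enrichment per list, annotate passing motifs against the cis-element
#' table, and write every intermediate artifact plus a machine-readable
#' manifest into `outDir`. Rerunning with an identical config gives
#' byte-identical outputs.
#'
#' @param config A named list. Exactly one of:
#'   \describe{
#'     \item{`inputs`}{list with paths `genome` (FASTA), `gff` (GFF3),
#'       `expression` and `design` (TSVs as read by [readExpression()]).}
#'     \item{`synthetic`}{list of generator overrides: sublists `genome`
#'       (arguments of [syntheticGenome()]), `planting` (`motif`,
#'       `foregroundRate`, `backgroundRate`), and `expression`
#'       (`baseExpression`, `log2fcRef`, `log2fcOther`, `noiseSdLog`,
#'       `nReplicates`, `nUp`, `nDown`).}
#'   }
#'   plus optional analysis parameters `promoterLength` (1000), `k` (6),
#'   `mode` ("presence"), `minEnrichment` (1.1), `alpha` (0.05),
#'   `nClusters` (8), `pseudocount` (1), `elements` (path to a
#'   cis-element TSV; bundled snapshot by default) and `seed` (1).
#' @param outDir Output directory, created if needed.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`); `manifest$enrichment` holds the per-list annotated
#'   record counts and, for synthetic runs, whether the planted motif
#'   passed.
#' @export
runPipeline <- function(config, outDir = config$out_dir %||% "promoscan_run") {
  config <- .normalizeConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package = "promoscan",
                   version = as.character(packageVersion("promoscan")),
                   seed = seed, config = config, stages = list())

  ## stage 1: genome + annotation -------------------------------------
  if (!is.null(config$synthetic)) {
    gspec <- config$synthetic$genome
    gen <- do.call(syntheticGenome, c(gspec, list(seed = seed)))
    genome <- gen$genome
    genes <- gen$genes
  } else {
    genome <- readGenomeFasta(config$inputs$genome)
    genes <- readGeneModels(config$inputs$gff)
  }
  manifest$stages$genome <- list(n_contigs = length(genome),
                                 n_genes = length(genes))

  ## stage 2: promoters ------------------------------------------------
  promoters <- extractPromoters(genome, genes,
                                upstream = config$promoterLength)
  manifest$stages$promoters <- list(n_promoters = length(promoters),
                                    target_length = targetLength(promoters))

  ## stage 3 (synthetic only): plant trends + motif --------------------
  planted <- NULL
  if (!is.null(config$synthetic)) {
    espec <- config$synthetic$expression
    ids <- names(promoters)
    nUp <- min(espec$nUp, length(ids))
    nDown <- min(espec$nDown, max(0L, length(ids) - nUp))
    trend <- stats::setNames(
      rep(c("up_enhanced", "down_enhanced", "null"),
          c(nUp, nDown, length(ids) - nUp - nDown)), ids)
    pspec <- config$synthetic$planting
    plantRes <- plantMotifs(promoters, pspec$motif,
                            foreground = ids[trend == "up_enhanced"],
                            foregroundRate = pspec$foregroundRate,
                            backgroundRate = pspec$backgroundRate,
                            seed = seed + 1L)
    promoters <- plantRes$sequences
    planted <- pspec$motif
    write.table(plantRes$plantings, file.path(outDir, "plantings.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    se <- syntheticExpression(
      nGenes = length(ids), geneIds = ids,
      trendAssignments = trend,
      nReplicates = espec$nReplicates,
      baseExpression = espec$baseExpression,
      log2fcRef = espec$log2fcRef, log2fcOther = espec$log2fcOther,
      noiseSdLog = espec$noiseSdLog, seed = seed + 2L)
    writeGenome(genome, genes, file.path(outDir, "genome.fa"),
                file.path(outDir, "genes.gff3"))
  } else {
    se <- readExpression(config$inputs$expression, config$inputs$design)
  }
  writePromoters(promoters, file.path(outDir, "promoters.fa"),
                 file.path(outDir, "promoter_lengths.tsv"))
  writeExpression(se, file.path(outDir, "fpkm.tsv"),
                  file.path(outDir, "design.tsv"))

  ## stage 4: trend clustering -----------------------------------------
  clusters <- clusterTrends(se, nClusters = config$nClusters)
  clusters <- labelTrends(clusters, se, pseudocount = config$pseudocount)
  asg <- clusterAssignments(clusters)
  labs <- clusterLabels(clusters)
  write.table(
    data.frame(gene_id = names(asg), cluster = asg,
               label = labs[as.character(asg)]),
    file.path(outDir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  lists <- trendGeneLists(clusters)
  ## enrichment needs genes that actually have promoters
  lists <- lapply(lists, intersect, names(promoters))
  writeGeneLists(lists, outDir)
  manifest$stages$trends <- list(n_clusters = config$nClusters,
                                 n_up = length(lists$up_enhanced),
                                 n_down = length(lists$down_enhanced))

  ## stage 5: enrichment + annotation ----------------------------------
  elements <- readCisElements(config$elements)
  manifest$enrichment <- list()
  for (lab in names(lists)) {
    fg <- lists[[lab]]
    if (length(fg) == 0L) {
      manifest$enrichment[[lab]] <- list(n_foreground = 0L,
                                         n_passing = 0L)
      next
    }
    mct <- countMotifs(promoters, fg, k = config$k, mode = config$mode)
    res <- motifEnrichment(mct, minEnrichment = config$minEnrichment,
                           alpha = config$alpha)
    writeEnrichmentTsv(res, file.path(outDir,
                                      sprintf("enrichment_%s.tsv", lab)))
    kept <- filterEnriched(res, config$minEnrichment, config$alpha)
    ann <- annotateMotifs(kept, elements)
    writeEnrichmentTsv(ann, file.path(outDir,
                                      sprintf("annotated_%s.tsv", lab)))
    info <- list(n_foreground = length(fg),
                 n_passing = nrow(kept),
                 n_annotated = nrow(ann))
    if (!is.null(planted)) {
      info$planted_motif <- planted
      info$planted_motif_passes <- planted %in% kept$motif
      info$planted_motif_rank <-
        if (planted %in% kept$motif) match(planted, kept$motif)
        else NA_integer_
    }
    manifest$enrichment[[lab]] <- info
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' @rdname promoscan-io
#' @param records Enrichment records from [motifEnrichment()],
#'   [filterEnriched()] or [annotateMotifs()].
#' @export
writeEnrichmentTsv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## fill defaults + validate the exactly-one-input-source invariant
.normalizeConfig <- function(config) {
  stopifnot(is.list(config))
  hasReal <- !is.null(config$inputs)
  hasSynth <- !is.null(config$synthetic)
  if (hasReal == hasSynth)
    stop("config must provide exactly one of 'inputs' (file paths) ",
         "or 'synthetic' (generator spec)")
  defaults <- list(promoterLength = 1000L, k = 6L, mode = "presence",
                   minEnrichment = 1.1, alpha = 0.05, nClusters = 8L,
                   pseudocount = 1, seed = 1L, elements = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (hasSynth) {
    sdef <- list(
      genome = list(nContigs = 2L, genesPerContig = 100L,
                    intergenicLen = 1500L, geneLen = 1000L,
                    gcFraction = 0.36),
      planting = list(motif = "CACGTG", foregroundRate = 0.5,
                      backgroundRate = 0.1),
      expression = list(nReplicates = 3L, baseExpression = 50,
                        log2fcRef = 2, log2fcOther = 1, noiseSdLog = 0.1,
                        nUp = 50L, nDown = 50L))
    for (blk in names(sdef)) {
      given <- config$synthetic[[blk]] %||% list()
      bad <- setdiff(names(given), names(sdef[[blk]]))
      if (length(bad))
        stop("unknown synthetic ", blk, " field(s): ",
             paste(bad, collapse = ", "))
      config$synthetic[[blk]] <- utils::modifyList(sdef[[blk]], given)
    }
  }
  if (hasReal) {
    need <- c("genome", "gff", "expression", "design")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop("config$inputs is missing: ", paste(missing, collapse = ", "))
  }
  config$seed <- checkCount(config$seed, "seed", min = 0L)
  config
}

#' Read a flat key=value pipeline configuration file
#'
#' Parses a plain-text configuration with one `key = value` pair per
#' line (`#` comments allowed). Dots group keys into the nested blocks
#' [runPipeline()] expects, e.g. `synthetic.planting.motif = CACGTG` or
#' `inputs.genome = genome.fa`. Numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return A nested config list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  config <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    config <- .assignNested(config, keys, val)
  }
  config
}

.assignNested <- function(lst, keys, val) {
  if (length(keys) == 1L) {
    lst[[keys]] <- val
  } else {
    sub <- lst[[keys[1]]]
    if (is.null(sub)) sub <- list()
    lst[[keys[1]]] <- .assignNested(sub, keys[-1], val)
  }
  lst
}

#' Verify a transcribed enrichment count table
#'
#' Recomputes the enrichment fraction for every row of a TSV with columns
#' `motif`, `k_fg`, `K_fg`, `n_bg`, `N_bg`, `expected_enrichment` and
#' reports the largest absolute difference from the expected column. The
#' package bundles such a table for the published tomato soil-flooding
#' promoter clusters (34,417 genome promoters; 849 upregulated and 631
#' downregulated foreground promoters), used as a regression harness for
#' the enrichment arithmetic.
#'
#' @param path Path to the count TSV; `NULL` (default) uses the bundled
#'   table.
#' @param tolerance Maximum tolerated absolute difference (default 5e-7,
#'   matching tables printed to 7-8 decimals).
#' @return A list with `table` (per-row computed values, differences and
#'   `ok` flags), `maxAbsDiff`, `nFailing` and `ok`.
#' @export
#' @examples
#' verifyTables()$ok
verifyTables <- function(path = NULL, tolerance = 5e-7) {
  if (is.null(path))
    path <- system.file("extdata", "flooding_trend_hexamer_counts.tsv",
                        package = "promoscan", mustWork = TRUE)
  tab <- read.delim(path)
  need <- c("motif", "k_fg", "K_fg", "n_bg", "N_bg",
            "expected_enrichment")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("count table is missing column(s): ",
         paste(missing, collapse = ", "))
  num <- c("k_fg", "K_fg", "n_bg", "N_bg", "expected_enrichment")
  for (col in num)
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' at line %d", col,
                   bad + 1L))
    }
  tab$computed <- enrichmentFraction(tab$k_fg, tab$K_fg, tab$n_bg,
                                     tab$N_bg)
  tab$abs_diff <- abs(tab$computed - tab$expected_enrichment)
  tab$ok <- tab$abs_diff <= tolerance
  list(table = tab,
       maxAbsDiff = max(tab$abs_diff),
       nFailing = sum(!tab$ok),
       ok = all(tab$ok))
}
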
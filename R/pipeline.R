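#' @importFrom tools md5sum
NULL

.writeJson <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

#' Run the full analysis pipeline
#'
#' Orchestrates import (or simulation) -> probe summarization -> robust
#' control-probe normalization -> contamination filtering -> z-scoring ->
#' autoantigen calling -> association, longitudinal and enrichment
#' analyses, and persists results plus a run manifest when \code{outDir}
#' is given. Every stochastic stage draws from \code{seed}, so a rerun
#' with the same inputs and seed reproduces all result files.
#'
#' @param input Either the result of \code{\link{simulateExperiment}} /
#'   \code{\link{makeFixture}}, or a fixture directory written by
#'   \code{\link{writeFixture}}.
#' @param templates Known-antigen template gene ids for the
#'   template-correlation filter (default: none).
#' @param zThreshold,minPatients Calling parameters (defaults 3 and 3).
#' @param corThreshold Contamination correlation threshold (default 0.6).
#' @param topK Top reactivities for PCA/clustering (default 50).
#' @param resampleR Resampling-null draws (default 10000).
#' @param seed Seed for the resampling stage (default 1).
#' @param outDir Optional output directory for result files and the
#'   manifest.
#' @return List with all stage outputs (\code{raw}, \code{fit},
#'   \code{normalized}, \code{contamination}, \code{zscore},
#'   \code{callset}, \code{hits}, \code{association},
#'   \code{longitudinal}, \code{enrichment}, \code{manifest}).
#' @export
runPipeline <- function(input, templates = character(0), zThreshold = 3,
                        minPatients = 3L, corThreshold = 0.6, topK = 50L,
                        resampleR = 10000L, seed = 1L, outDir = NULL) {
  warningsLog <- character(0)
  logWarn <- function(w) {
    warningsLog <<- c(warningsLog, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- "import"
  res <- withCallingHandlers(tryCatch({
    if (is.character(input)) {
      paths <- list.files(file.path(input, "scans"), pattern = "\\.gpr$",
                          full.names = TRUE)
      scans <- readScans(paths)
      meta <- readSampleMeta(file.path(input, "meta.tsv"))
      categories <- readGeneCategories(file.path(input, "categories.tsv"))
      properties <- readGeneProperties(file.path(input, "properties.tsv"))
      om <- file.path(input, "ortholog_map.tsv")
      orthologMap <- if (file.exists(om))
        read.delim(om, stringsAsFactors = FALSE) else NULL
      deFiles <- list.files(input, pattern = "^de_.*\\.txt$",
                            full.names = TRUE)
      deLists <- lapply(deFiles, readLines)
      names(deLists) <- sub("^de_(.*)\\.txt$", "\\1", basename(deFiles))
    } else {
      scans <- input$scans; meta <- input$meta
      categories <- input$categories; properties <- input$properties
      orthologMap <- input$orthologMap; deLists <- input$deLists
    }

    stage <- "summarize"
    raw <- attachSampleMeta(summarizeProbes(scans), meta)

    stage <- "normalize"
    fit <- fitControlModel(raw)
    norm <- applyNormalization(raw, fit)

    stage <- "decontaminate"
    dec <- decontaminate(norm, templates = templates,
                         layout = scanLayout(scans),
                         threshold = corThreshold)

    stage <- "call"
    z <- zscoreMatrix(dec$matrix)
    callset <- callAutoantigens(z, zThreshold = zThreshold,
                                minPatients = minPatients)
    hits <- hitCounts(callset)
    repHits <- hitCounts(callset, representativesOnly = TRUE)

    stage <- "associate"
    assoc <- list(
      variance = varianceContrast(dec$matrix),
      pca = repertoirePCA(z, topK = topK, zThreshold = zThreshold),
      clustering = clusterRepertoire(z, topK = topK,
                                     zThreshold = zThreshold),
      regression = manifestationRegression(repHits, meta),
      mutation = tryCatch(mutationGroupTest(repHits, meta),
                          error = function(e) NULL))
    manifAll <- sort(unique(unlist(
      meta$manifestations[meta$group == "patient"])))
    reps <- representativeSamples(callset)
    modT <- list()
    for (mn in manifAll) {
      has <- vapply(meta$manifestations[match(reps, meta$sample_id)],
                    function(x) mn %in% x, TRUE)
      if (!any(has) || all(has)) next
      xm <- assay(dec$matrix, "exprs")[
        setdiff(rownames(dec$matrix),
                rownames(dec$matrix)[rowData(dec$matrix)$is_control]),
        reps, drop = FALSE]
      modT[[mn]] <- moderatedT(xm, has, manifestation = mn)
    }
    assoc$moderatedT <- modT

    stage <- "longitudinal"
    longi <- if (any(duplicated(meta$patient_id[meta$group == "patient"]))) {
      pairs <- formPairs(callset, meta)
      list(pairs = pairs, byCategory = aggregatePairs(pairs),
           trend = repertoireTrend(callset, meta))
    } else NULL

    stage <- "enrich"
    universe <- setdiff(rownames(dec$matrix),
                        rownames(dec$matrix)[rowData(dec$matrix)$is_control])
    aag <- autoantigens(callset)
    enr <- list()
    if (length(aag)) {
      enr$terms <- hypergeomEnrich(aag, categories, universe)
      dens <- snpDensity(properties)
      enr$snp_gene <- resamplingNull(
        aag, setNames(dens$d_gene, dens$gene_id), universe,
        R = resampleR, direction = "less", seed = seed)
      enr$evo_all <- resamplingNull(
        aag, setNames(properties$evo_rate_all, properties$gene_id),
        universe, R = resampleR, direction = "less", seed = seed + 1L)
      enr$tr_split <- splitTrNtr(aag, properties)
      if (length(deLists) && !is.null(orthologMap))
        enr$de_overlap <- lapply(deLists, function(dl)
          listOverlap(enr$tr_split$TR, dl, universe, orthologMap))
    }

    list(raw = raw, fit = fit, normalized = norm, contamination = dec$report,
         zscore = z, callset = callset, hits = hits, repHits = repHits,
         association = assoc, longitudinal = longi, enrichment = enr,
         meta = meta)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)), warning = logWarn)

  res$warnings <- warningsLog
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLines(autoantigens(res$callset),
               file.path(outDir, "autoantigens.txt"))
    calls <- data.frame(gene_id = rownames(callMatrix(res$callset)),
                        callMatrix(res$callset), check.names = FALSE)
    write.table(calls, file.path(outDir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeMatrixTsv(res$zscore, file.path(outDir, "zscore.tsv"))
    .writeJson(list(
      variance_p = res$association$variance$p,
      pca_explained = res$association$pca$explained[1:2],
      regression = res$association$regression[c("slope", "r", "p")],
      mutation = res$association$mutation,
      n_significant_moderated_t = sum(vapply(
        res$association$moderatedT,
        function(d) sum(d$p_adj < 0.05), 1L))),
      file.path(outDir, "association.json"))
    if (!is.null(res$longitudinal))
      .writeJson(res$longitudinal[c("byCategory")],
                 file.path(outDir, "longitudinal.json"))
    if (length(res$enrichment)) {
      write.table(res$enrichment$terms, file.path(outDir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      .writeJson(list(
        snp_gene_p = res$enrichment$snp_gene$p_emp,
        evo_all_p = res$enrichment$evo_all$p_emp),
        file.path(outDir, "resampling.json"))
    }
    files <- setdiff(list.files(outDir, full.names = TRUE),
                     file.path(outDir, "manifest.json"))
    checksums <- md5sum(files)
    names(checksums) <- basename(files)
    manifest <- list(
      parameters = list(zThreshold = zThreshold,
                        minPatients = minPatients,
                        corThreshold = corThreshold, topK = topK,
                        resampleR = resampleR),
      seed = seed,
      n_samples = ncol(res$raw), n_genes = length(
        setdiff(rownames(res$raw),
                rownames(res$raw)[rowData(res$raw)$is_control])),
      checksums = as.list(checksums),
      warnings = warningsLog,
      timestamp = format(Sys.time(), tz = "UTC"))
    .writeJson(manifest, file.path(outDir, "manifest.json"))
    res$manifest <- manifest
  }
  res
}

#' Render a markdown summary report
#'
#' @param res Result list from \code{\link{runPipeline}}.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly when written to a file.
#' @export
renderReport <- function(res, path = NULL) {
  aag <- autoantigens(res$callset)
  lines <- c(
    "# Autoantibody repertoire report", "",
    sprintf("Samples analysed: %d; genes after contamination filtering: %d.",
            ncol(res$zscore), nrow(res$zscore)),
    sprintf("Contamination flags: %d.", nrow(res$contamination@flagged)), "",
    "## Autoantigen calling", "",
    sprintf("%d autoantigens (z > %g in >= %d patients).",
            length(aag), res$callset@zThreshold, res$callset@minPatients),
    if (length(aag)) paste("Top calls:",
                           paste(utils::head(aag, 10L), collapse = ", "))
    else "No gene met the calling criteria.", "",
    "## Association", "",
    sprintf("Patient vs control per-sample SD rank-sum p = %.3g.",
            res$association$variance$p),
    sprintf("PCA: first two components explain %.1f%% and %.1f%% of variance.",
            100 * res$association$pca$explained[1L],
            100 * res$association$pca$explained[2L]),
    sprintf("Manifestations ~ log2 hits: slope %.3f, r = %.3f.",
            res$association$regression$slope, res$association$regression$r))
  if (!is.null(res$longitudinal)) {
    bc <- res$longitudinal$byCategory
    lines <- c(lines, "", "## Longitudinal", "",
               apply(bc, 1L, function(r) sprintf(
                 "%s (%s pairs): early-only %.2f, shared %.2f, late-only %.2f",
                 r[["category"]], r[["n_pairs"]],
                 as.numeric(r[["p_early_only"]]),
                 as.numeric(r[["p_shared"]]),
                 as.numeric(r[["p_late_only"]]))))
  }
  if (length(res$enrichment)) {
    sig <- res$enrichment$terms[res$enrichment$terms$p_adj < 0.05, ]
    lines <- c(lines, "", "## Enrichment", "",
               sprintf("%d term(s) enriched at adjusted p < 0.05.", nrow(sig)),
               sprintf("SNP gene-span density resampling p = %.4g; evolutionary rate p = %.4g.",
                       res$enrichment$snp_gene$p_emp,
                       res$enrichment$evo_all$p_emp))
  }
  lines <- as.character(lines)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
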
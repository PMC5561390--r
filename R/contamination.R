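#' @importFrom stats cor sd
NULL

.geneExprs <- function(norm) {
  x <- assay(norm, "exprs")
  rd <- rowData(norm)
  if ("is_control" %in% colnames(rd)) x[!rd$is_control, , drop = FALSE]
  else x[!grepl("^ctl:", rownames(x)), , drop = FALSE]
}

.emptyFlags <- function() DataFrame(
  gene_id = character(0), reason = character(0),
  partner_id = character(0), r = numeric(0))

#' Flag probes correlated with known-antigen templates
#'
#' Print contamination during array manufacture can smear protein from a
#' strongly reactive well into others, producing spurious probes whose
#' cross-sample profile tracks a known autoantigen. Every non-template gene
#' whose Pearson correlation (across all samples, on normalized log2 values)
#' with any template exceeds the threshold is flagged; the correlation rule
#' is signed, so anti-correlated profiles are not flagged.
#'
#' @param norm \code{SummarizedExperiment} at stage \code{normalized}.
#' @param templates Character vector of template gene ids (known antigens);
#'   must all be present in the matrix.
#' @param threshold Flag when \code{r > threshold} (default 0.6).
#' @return A \linkS4class{ContaminationReport}.
#' @export
flagTemplateCorrelated <- function(norm, templates, threshold = 0.6) {
  .assertStage(norm, "normalized")
  x <- .geneExprs(norm)
  if (ncol(x) < 3L) stop("need >= 3 samples for correlations", call. = FALSE)
  miss <- setdiff(templates, rownames(x))
  if (length(miss))
    stop("template(s) absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sds <- apply(x, 1L, sd)
  degenerate <- rownames(x)[sds == 0]
  if (length(degenerate))
    warning("zero-variance profile(s) skipped: ",
            paste(degenerate, collapse = ", "))
  usable <- setdiff(rownames(x), degenerate)
  tpl <- intersect(templates, usable)
  cand <- setdiff(usable, templates)
  flags <- .emptyFlags()
  if (length(tpl) && length(cand)) {
    rmat <- cor(t(x[cand, , drop = FALSE]), t(x[tpl, , drop = FALSE]))
    best <- apply(rmat, 1L, which.max)
    rbest <- rmat[cbind(seq_along(cand), best)]
    hit <- rbest > threshold
    flags <- DataFrame(gene_id = cand[hit],
                       reason = rep("template_correlation", sum(hit)),
                       partner_id = tpl[best][hit],
                       r = unname(rbest[hit]))
  }
  new("ContaminationReport", flagged = flags, threshold = threshold)
}

# adjacency of two spot coordinate sets within the same block
.anyAdjacent <- function(p1, p2, adjacency) {
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    if (p1$block[i] != p2$block[j]) next
    dr <- abs(p1$row[i] - p2$row[j]); dc <- abs(p1$col[i] - p2$col[j])
    ok <- if (adjacency == "rook") dr + dc == 1L else max(dr, dc) == 1L
    if (ok) return(TRUE)
  }
  FALSE
}

#' Flag probes correlated with a physically neighboring well
#'
#' For each pair of genes printed in adjacent wells of the same block, if
#' their normalized profiles correlate above the threshold the member with
#' the smaller dynamic range (max minus min across samples) is flagged as
#' the contaminated copy; the stronger partner — presumed the true
#' reactivity — is retained.
#'
#' @param norm \code{SummarizedExperiment} at stage \code{normalized}.
#' @param layout Spot layout: the \code{scanLayout} of a
#'   \linkS4class{ScanSet}, or any data.frame with columns \code{gene_id},
#'   \code{block}, \code{row}, \code{col}. Defaults to the matrix rowData.
#' @param threshold Flag when \code{r > threshold} (default 0.6).
#' @param adjacency \code{"queen"} (8-neighborhood, default — print pins
#'   deposit to diagonal wells too) or \code{"rook"} (4-neighborhood).
#' @return A \linkS4class{ContaminationReport}.
#' @export
flagNeighborCorrelated <- function(norm, layout = rowData(norm),
                                   threshold = 0.6,
                                   adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  .assertStage(norm, "normalized")
  x <- .geneExprs(norm)
  lay <- as.data.frame(layout)
  lay <- lay[!is.na(lay$gene_id) & lay$gene_id %in% rownames(x), , drop = FALSE]
  noLayout <- setdiff(rownames(x), lay$gene_id)
  if (length(noLayout))
    warning("gene(s) without layout skipped: ",
            paste(noLayout, collapse = ", "))
  # candidate pairs: genes with spots in the same or adjacent (row, col)
  # bins of one block, found through a position index
  pos <- split(lay[, c("block", "row", "col")], lay$gene_id)
  key <- paste(lay$block, lay$row, lay$col)
  at <- split(lay$gene_id, key)
  pairs <- new.env()
  for (i in seq_len(nrow(lay))) {
    b <- lay$block[i]; r <- lay$row[i]; cc <- lay$col[i]; g <- lay$gene_id[i]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      if (adjacency == "rook" && abs(dr) + abs(dc) != 1L) next
      nb <- at[[paste(b, r + dr, cc + dc)]]
      for (h in nb) if (h != g) {
        k <- paste(sort(c(g, h)), collapse = "\r")
        assign(k, TRUE, envir = pairs)
      }
    }
  }
  cand <- ls(pairs)
  flags <- .emptyFlags()
  # robust reactivity amplitude: mean of the 3 largest deviations from the
  # median, so single outlier spots cannot decide which copy is weaker
  rng <- apply(x, 1L, function(v) {
    d <- sort(v - stats::median(v), decreasing = TRUE)
    mean(d[seq_len(min(3L, length(d)))])
  })
  sds <- apply(x, 1L, sd)
  for (k in cand) {
    gh <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    if (sds[gh[1L]] == 0 || sds[gh[2L]] == 0) next
    r <- cor(x[gh[1L], ], x[gh[2L], ])
    if (is.na(r) || r <= threshold) next
    weak <- gh[order(rng[gh])][1L]
    strong <- setdiff(gh, weak)[1L]
    flags <- rbind(flags, DataFrame(gene_id = weak,
                                    reason = "neighbor_correlation",
                                    partner_id = strong, r = r))
  }
  if (nrow(flags)) {
    o <- order(flags$gene_id, flags$partner_id)
    flags <- flags[o, ]
  }
  new("ContaminationReport", flagged = flags, threshold = threshold)
}

#' Run both contamination filters and remove flagged genes
#'
#' Applies the template-correlation and neighbor-correlation filters on the
#' normalized matrix (after normalization, before z-scoring) and drops all
#' flagged genes. The report plus the retained matrix always partition the
#' input gene set.
#'
#' @inheritParams flagNeighborCorrelated
#' @param templates Known-antigen template gene ids (may be empty).
#' @return List with elements \code{matrix} (the cleaned
#'   \code{SummarizedExperiment}) and \code{report}
#'   (\linkS4class{ContaminationReport}).
#' @export
decontaminate <- function(norm, templates = character(0),
                          layout = rowData(norm), threshold = 0.6,
                          adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  repT <- if (length(templates))
    flagTemplateCorrelated(norm, templates, threshold)
  else new("ContaminationReport", flagged = .emptyFlags(),
           threshold = threshold)
  repN <- flagNeighborCorrelated(norm, layout, threshold, adjacency)
  flags <- rbind(repT@flagged, repN@flagged)
  report <- new("ContaminationReport", flagged = flags,
                threshold = threshold)
  drop <- flaggedGenes(report)
  list(matrix = norm[!rownames(norm) %in% drop, ], report = report)
}
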
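.metaOf <- function(se, meta = NULL) {
  if (is.null(meta)) meta <- as.data.frame(colData(se))
  miss <- setdiff(c("sample_id", "patient_id", "group"), colnames(meta))
  if (length(miss))
    stop("sample metadata lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta[match(colnames(se), meta$sample_id), , drop = FALSE]
}

#' Standardize normalized signals against the healthy-control cohort
#'
#' Per gene, the z-score is the number of control-cohort standard deviations
#' a sample lies from the control mean: \eqn{z_{ij} = (x_{ij} - m_i) / s_i},
#' where \eqn{m_i, s_i} are the mean and sample SD (n-1 denominator) over
#' the healthy samples — unrelated controls plus healthy relatives. Genes
#' that are constant across controls have no defined z and are dropped with
#' a warning. Control probes are excluded from the result.
#'
#' @param norm \code{SummarizedExperiment} at stage \code{normalized}.
#' @param meta Sample metadata (data.frame with \code{sample_id},
#'   \code{patient_id}, \code{group}); defaults to the matrix colData.
#' @return \code{SummarizedExperiment} at stage \code{zscore};
#'   \code{metadata()$control_ids} records the standardization cohort.
#' @export
zscoreMatrix <- function(norm, meta = NULL) {
  .assertStage(norm, "normalized")
  meta <- .metaOf(norm, meta)
  ctl <- meta$sample_id[meta$group %in% c("control", "relative")]
  if (length(ctl) < 2L)
    stop("need >= 2 control-group samples (controls + relatives)",
         call. = FALSE)
  x <- .geneExprs(norm)
  m <- rowMeans(x[, ctl, drop = FALSE])
  s <- apply(x[, ctl, drop = FALSE], 1L, sd)
  degenerate <- s == 0
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) constant across controls dropped: ",
            paste(utils::head(rownames(x)[degenerate], 5L), collapse = ", "))
  z <- (x[!degenerate, , drop = FALSE] - m[!degenerate]) / s[!degenerate]
  se <- SummarizedExperiment(assays = list(exprs = z))
  if (!is.null(colnames(norm)))
    colData(se) <- colData(norm)[colnames(z), , drop = FALSE]
  metadata(se)$stage <- "zscore"
  metadata(se)$control_ids <- ctl
  se
}

.pickRepresentatives <- function(hits, meta, rule) {
  pts <- unique(meta$patient_id[meta$group == "patient"])
  reps <- character(length(pts)); names(reps) <- pts
  for (p in pts) {
    cand <- meta[meta$patient_id == p & meta$group == "patient", , drop = FALSE]
    if (rule == "latest" && "age_at_sampling" %in% colnames(cand)) {
      o <- order(-cand$age_at_sampling, cand$sample_id)
    } else {
      age <- if ("age_at_sampling" %in% colnames(cand))
        cand$age_at_sampling else rep(0, nrow(cand))
      o <- order(-hits[cand$sample_id], -age, cand$sample_id)
    }
    reps[p] <- cand$sample_id[o[1L]]
  }
  reps
}

#' Call autoantigens from the z-score matrix
#'
#' A gene/sample pair is a positive call when its z-score strictly exceeds
#' \code{zThreshold}. One representative serum sample per patient is then
#' selected — by default the sample with the maximal number of positive
#' hits (ties broken towards the later sampling age) — and a gene is an
#' autoantigen when it is positive in at least \code{minPatients} distinct
#' patients' representative samples.
#'
#' @param z \code{SummarizedExperiment} at stage \code{zscore}.
#' @param meta Sample metadata; defaults to colData.
#' @param zThreshold Calling threshold (default 3; strict \code{>}).
#' @param minPatients Minimum distinct positive patients (default 3).
#' @param oneSamplePerPatient Representative-sample rule,
#'   \code{"max_hits"} (default) or \code{"latest"}.
#' @return A \linkS4class{CallSet}; \code{callMatrix()} keeps calls for all
#'   patient samples so longitudinal analyses can use every time point.
#' @export
callAutoantigens <- function(z, meta = NULL, zThreshold = 3,
                             minPatients = 3L,
                             oneSamplePerPatient = c("max_hits", "latest")) {
  rule <- match.arg(oneSamplePerPatient)
  .assertStage(z, "zscore")
  meta <- .metaOf(z, meta)
  pat <- meta$sample_id[meta$group == "patient"]
  if (!length(pat)) stop("no patient samples", call. = FALSE)
  zm <- assay(z, "exprs")[, pat, drop = FALSE]
  calls <- (zm > zThreshold) + 0
  hits <- colSums(calls)
  reps <- .pickRepresentatives(hits, meta, rule)
  nPos <- rowSums(calls[, reps, drop = FALSE])
  aag <- as.character(rownames(calls)[nPos >= minPatients])
  new("CallSet", calls = calls, representatives = reps,
      autoantigens = aag, zThreshold = zThreshold,
      minPatients = as.integer(minPatients))
}

#' Per-sample positive-call counts
#'
#' @param x A \linkS4class{CallSet} or a binary gene x sample call matrix.
#' @param representativesOnly Restrict to the one-sample-per-patient
#'   representative samples (default FALSE).
#' @return Data.frame with \code{sample_id}, \code{n_hits} and the
#'   companion \code{log2_hits = log2(n_hits + 1)}.
#' @export
hitCounts <- function(x, representativesOnly = FALSE) {
  m <- if (is(x, "CallSet")) callMatrix(x) else x
  if (representativesOnly && is(x, "CallSet"))
    m <- m[, representativeSamples(x), drop = FALSE]
  n <- colSums(m)
  data.frame(sample_id = colnames(m), n_hits = unname(n),
             log2_hits = log2(unname(n) + 1))
}
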
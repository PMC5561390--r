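#' Within-patient sample pairs and repertoire overlap
#'
#' For every patient with repeat sera, forms all ordered (earlier, later)
#' sample pairs and partitions each pair's positive calls into
#' early-specific, shared and late-specific sets. Pairs are binned into two
#' sampling-gap categories — less than versus at least 10 years apart (a
#' gap of exactly 10.0 years falls in \code{ge10}).
#'
#' This analysis deliberately uses the calls of ALL samples; the
#' one-sample-per-patient collapsing used for autoantigen calling does not
#' apply here.
#'
#' @param calls A \linkS4class{CallSet} or binary gene x sample matrix
#'   covering every sample.
#' @param meta Sample metadata with \code{patient_id} and
#'   \code{age_at_sampling}.
#' @param gapBoundary Category boundary in years (default 10).
#' @return Data.frame with one row per pair: patient, samples, gap (years),
#'   category, the three counts and the three proportions (summing to 1
#'   when any call is present in either sample).
#' @export
formPairs <- function(calls, meta, gapBoundary = 10) {
  m <- if (is(calls, "CallSet")) callMatrix(calls) else calls
  meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  multi <- names(which(table(meta$patient_id) >= 2L))
  if (!length(multi)) {
    warning("no patient with >= 2 samples; empty pair list")
    return(data.frame(patient_id = character(0), early_sample = character(0),
                      late_sample = character(0), gap = numeric(0),
                      category = character(0), n_early_only = integer(0),
                      n_shared = integer(0), n_late_only = integer(0),
                      p_early_only = numeric(0), p_shared = numeric(0),
                      p_late_only = numeric(0)))
  }
  rows <- list()
  for (p in multi) {
    sm <- meta[meta$patient_id == p, , drop = FALSE]
    sm <- sm[order(sm$age_at_sampling, sm$sample_id), , drop = FALSE]
    ns <- nrow(sm)
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      early <- rownames(m)[m[, sm$sample_id[i]] == 1]
      late <- rownames(m)[m[, sm$sample_id[j]] == 1]
      cnt <- c(length(setdiff(early, late)),
               length(intersect(early, late)),
               length(setdiff(late, early)))
      tot <- sum(cnt)
      prop <- if (tot > 0) cnt / tot else c(NA_real_, NA_real_, NA_real_)
      gap <- sm$age_at_sampling[j] - sm$age_at_sampling[i]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, early_sample = sm$sample_id[i],
        late_sample = sm$sample_id[j], gap = gap,
        category = if (gap >= gapBoundary) "ge10" else "lt10",
        n_early_only = cnt[1L], n_shared = cnt[2L], n_late_only = cnt[3L],
        p_early_only = prop[1L], p_shared = prop[2L], p_late_only = prop[3L])
    }
  }
  do.call(rbind, rows)
}

#' Aggregate pair overlaps per gap category
#'
#' Unweighted mean of the per-pair proportions within each gap category.
#'
#' @param pairs Data.frame from \code{\link{formPairs}}.
#' @return Data.frame with one row per category and mean proportions.
#' @export
aggregatePairs <- function(pairs) {
  ok <- !is.na(pairs$p_shared)
  pairs <- pairs[ok, , drop = FALSE]
  out <- lapply(split(pairs, pairs$category), function(d) data.frame(
    category = d$category[1L], n_pairs = nrow(d),
    p_early_only = mean(d$p_early_only),
    p_shared = mean(d$p_shared),
    p_late_only = mean(d$p_late_only)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Direction of repertoire size change per patient
#'
#' Compares the first and the last sample of every multi-sample patient and
#' classifies the patient as having an increased, or decreased-or-unchanged,
#' number of positive autoantigens over time.
#'
#' @inheritParams formPairs
#' @return List with \code{perPatient} (data.frame: patient, first/last
#'   hit counts, age gap, class) and \code{counts} (table of the two
#'   classes).
#' @export
repertoireTrend <- function(calls, meta) {
  m <- if (is(calls, "CallSet")) callMatrix(calls) else calls
  meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  multi <- names(which(table(meta$patient_id) >= 2L))
  rows <- lapply(multi, function(p) {
    sm <- meta[meta$patient_id == p, , drop = FALSE]
    sm <- sm[order(sm$age_at_sampling, sm$sample_id), , drop = FALSE]
    h1 <- sum(m[, sm$sample_id[1L]])
    h2 <- sum(m[, sm$sample_id[nrow(sm)]])
    data.frame(patient_id = p, first_hits = h1, last_hits = h2,
               delta_hits = h2 - h1,
               delta_age = sm$age_at_sampling[nrow(sm)] -
                 sm$age_at_sampling[1L],
               class = if (h2 > h1) "increased" else "decreased_or_unchanged")
  })
  perPatient <- do.call(rbind, rows)
  counts <- c(increased = sum(perPatient$class == "increased"),
              decreased_or_unchanged =
                sum(perPatient$class == "decreased_or_unchanged"))
  list(perPatient = perPatient, counts = counts)
}
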
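#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ScanSet: probe-level scans sharing one array layout
#'
#' Container for a set of GenePix-style scans that share an identical probe
#' layout. Foreground and background intensities are stored as spot-by-sample
#' matrices; the layout describes each spot's grid position and control status.
#'
#' @slot layout A \code{DataFrame} with one row per spot and columns
#'   \code{probe_id}, \code{gene_id} (NA for controls), \code{block},
#'   \code{row}, \code{col}, \code{is_control}, \code{control_series}
#'   (\code{"hIgG"}, \code{"V5"} or NA) and \code{control_level}
#'   (ordinal concentration level, NA for non-controls).
#' @slot fg,bg Numeric matrices (spots x samples) of foreground and
#'   background intensities in arbitrary fluorescence units.
#'
#' @details Validity enforces: unique \code{(block, row, col)} triples,
#'   non-negative intensities, control probes without a \code{gene_id},
#'   non-control probes without a control series, and matching dimensions.
#' @export
setClass("ScanSet", representation(
  layout = "DataFrame",
  fg = "matrix",
  bg = "matrix"
))

setValidity("ScanSet", function(object) {
  lay <- object@layout
  msgs <- character()
  need <- c("probe_id", "gene_id", "block", "row", "col",
            "is_control", "control_series", "control_level")
  miss <- setdiff(need, colnames(lay))
  if (length(miss))
    return(paste("layout lacks columns:", paste(miss, collapse = ", ")))
  key <- paste(lay$block, lay$row, lay$col)
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicated (block,row,col) positions in layout")
  if (any(lay$block < 1L) || any(lay$row < 1L) || any(lay$col < 1L))
    msgs <- c(msgs, "grid coordinates must be >= 1")
  if (nrow(object@fg) != nrow(lay) || nrow(object@bg) != nrow(lay))
    msgs <- c(msgs, "fg/bg row count must equal layout row count")
  if (!identical(dim(object@fg), dim(object@bg)))
    msgs <- c(msgs, "fg and bg dimensions differ")
  if (any(object@fg < 0, na.rm = TRUE) || any(object@bg < 0, na.rm = TRUE))
    msgs <- c(msgs, "intensities must be non-negative")
  ctl <- lay$is_control
  if (any(ctl & !is.na(lay$gene_id)))
    msgs <- c(msgs, "control probes must have gene_id = NA")
  if (any(!ctl & !is.na(lay$control_series)))
    msgs <- c(msgs, "non-control probes must have control_series = NA")
  if (any(ctl & !(lay$control_series %in% c("hIgG", "V5"))))
    msgs <- c(msgs, "control_series must be 'hIgG' or 'V5' for control probes")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' RlmFit: robust two-way additive fit on control probes
#'
#' Result of iteratively reweighted least squares on the model
#' \eqn{y_{ij} = b_i + a_j + e_{ij}} over control classes i and arrays j,
#' with a robust (Huber or Tukey) loss and the identifiability constraint
#' \eqn{\sum_j a_j = 0}.
#'
#' @slot arrayEffects Named numeric, per-array effect \eqn{a_j} (log2 units),
#'   centered to zero sum.
#' @slot probeEffects Named numeric, per control class effect \eqn{b_i}.
#' @slot scale Robust residual scale (MAD-based).
#' @slot nIter Iterations used.
#' @slot converged Logical; TRUE when the maximum parameter change fell
#'   below the tolerance.
#' @slot loss Character, \code{"huber"} or \code{"tukey"}.
#' @export
setClass("RlmFit", representation(
  arrayEffects = "numeric",
  probeEffects = "numeric",
  scale = "numeric",
  nIter = "integer",
  converged = "logical",
  loss = "character"
))

setValidity("RlmFit", function(object) {
  if (length(object@arrayEffects) &&
      abs(sum(object@arrayEffects)) > 1e-6 * max(1, max(abs(object@arrayEffects))))
    return("array effects must sum to zero")
  TRUE
})

#' ContaminationReport: print-contamination flags
#'
#' @slot flagged \code{DataFrame} with columns \code{gene_id},
#'   \code{reason} (\code{"template_correlation"} or
#'   \code{"neighbor_correlation"}), \code{partner_id} and \code{r}
#'   (Pearson correlation with the partner profile).
#' @slot threshold Correlation threshold applied (flags satisfy
#'   \code{r > threshold}).
#' @export
setClass("ContaminationReport", representation(
  flagged = "DataFrame",
  threshold = "numeric"
))

setValidity("ContaminationReport", function(object) {
  fl <- object@flagged
  if (nrow(fl) && any(fl$r <= object@threshold))
    return("every flagged entry must have r > threshold")
  if (nrow(fl) && !all(fl$reason %in% c("template_correlation",
                                        "neighbor_correlation")))
    return("unknown flag reason")
  TRUE
})

#' CallSet: binary positive-call matrix and derived autoantigen list
#'
#' @slot calls Binary (0/1) gene x sample matrix of positive calls for all
#'   patient samples (z above the threshold).
#' @slot representatives Named character; for each patient the sample chosen
#'   to represent them (one sample per patient).
#' @slot autoantigens Character vector of genes positive in at least
#'   \code{minPatients} distinct patients (counted over representative
#'   samples).
#' @slot zThreshold,minPatients Calling parameters.
#' @export
setClass("CallSet", representation(
  calls = "matrix",
  representatives = "character",
  autoantigens = "character",
  zThreshold = "numeric",
  minPatients = "integer"
))

setValidity("CallSet", function(object) {
  if (nrow(object@calls) && !all(object@calls %in% c(0, 1)))
    return("calls must be binary")
  if (!all(object@representatives %in% colnames(object@calls)))
    return("representative samples must be call columns")
  TRUE
})
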
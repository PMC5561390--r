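#' @rdname ScanSet-class
#' @param object,x A \code{ScanSet}.
#' @export
setGeneric("scanLayout", function(x) standardGeneric("scanLayout"))

#' @rdname ScanSet-class
#' @export
setMethod("scanLayout", "ScanSet", function(x) x@layout)

#' @rdname ScanSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ScanSet-class
#' @export
setMethod("sampleIds", "ScanSet", function(x) colnames(x@fg))

#' @rdname ScanSet-class
#' @export
setMethod("show", "ScanSet", function(object) {
  lay <- object@layout
  cat("ScanSet with", ncol(object@fg), "samples,", nrow(lay), "spots (",
      sum(lay$is_control), "control )\n")
  cat("  blocks:", length(unique(lay$block)),
      " genes:", length(unique(lay$gene_id[!lay$is_control])), "\n")
})

#' @rdname RlmFit-class
#' @param object,x An \code{RlmFit}.
#' @export
setGeneric("arrayEffects", function(x) standardGeneric("arrayEffects"))

#' @rdname RlmFit-class
#' @export
setMethod("arrayEffects", "RlmFit", function(x) x@arrayEffects)

#' @rdname RlmFit-class
#' @export
setGeneric("probeEffects", function(x) standardGeneric("probeEffects"))

#' @rdname RlmFit-class
#' @export
setMethod("probeEffects", "RlmFit", function(x) x@probeEffects)

#' @rdname RlmFit-class
#' @export
setMethod("show", "RlmFit", function(object) {
  cat("RlmFit (", object@loss, " loss): ", length(object@arrayEffects),
      " arrays, ", length(object@probeEffects), " control classes\n", sep = "")
  cat("  robust scale:", signif(object@scale, 4),
      " iterations:", object@nIter,
      " converged:", object@converged, "\n")
})

#' @rdname ContaminationReport-class
#' @param object,x A \code{ContaminationReport}.
#' @export
setGeneric("flaggedGenes", function(x) standardGeneric("flaggedGenes"))

#' @rdname ContaminationReport-class
#' @export
setMethod("flaggedGenes", "ContaminationReport",
          function(x) unique(as.character(x@flagged$gene_id)))

#' @rdname ContaminationReport-class
#' @export
setMethod("show", "ContaminationReport", function(object) {
  cat("ContaminationReport:", nrow(object@flagged), "flags (threshold r >",
      object@threshold, ")\n")
  if (nrow(object@flagged))
    print(table(object@flagged$reason))
})

#' @rdname CallSet-class
#' @param object,x A \code{CallSet}.
#' @export
setGeneric("autoantigens", function(x) standardGeneric("autoantigens"))

#' @rdname CallSet-class
#' @export
setMethod("autoantigens", "CallSet", function(x) x@autoantigens)

#' @rdname CallSet-class
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))

#' @rdname CallSet-class
#' @export
setMethod("callMatrix", "CallSet", function(x) x@calls)

#' @rdname CallSet-class
#' @export
setGeneric("representativeSamples",
           function(x) standardGeneric("representativeSamples"))

#' @rdname CallSet-class
#' @export
setMethod("representativeSamples", "CallSet", function(x) x@representatives)

#' @rdname CallSet-class
#' @export
setMethod("show", "CallSet", function(object) {
  cat("CallSet: ", length(object@autoantigens), " autoantigens (z > ",
      object@zThreshold, " in >= ", object@minPatients, " patients) across ",
      ncol(object@calls), " samples\n", sep = "")
})
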
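#' @importFrom stats mad
NULL

.controlRows <- function(se) {
  rd <- rowData(se)
  if ("is_control" %in% colnames(rd)) which(rd$is_control)
  else grep("^ctl:", rownames(se))
}

.huberWeights <- function(r, k) {
  w <- rep(1, length(r))
  big <- abs(r) > k
  w[big] <- k / abs(r[big])
  w
}

.tukeyWeights <- function(r, c) {
  w <- (1 - (r / c)^2)^2
  w[abs(r) >= c] <- 0
  w
}

#' Fit the robust control-probe normalization model
#'
#' Fits the two-way additive model \eqn{y_{ij} = b_i + a_j + e_{ij}} on the
#' control-probe classes (series x concentration level), which are assumed to
#' carry constant positive signal across arrays, by iteratively reweighted
#' least squares with a robust loss. The per-array effects \eqn{a_j} capture
#' technical intensity shifts and are constrained to sum to zero.
#'
#' The residual scale is re-estimated every iteration as the
#' median-absolute-deviation about zero; the Huber tuning constant is
#' \code{1.345 * scale} (95\% Gaussian efficiency), Tukey's bisquare uses
#' \code{4.685 * scale}. With all residuals inside the Huber threshold the
#' fit coincides with ordinary least squares.
#'
#' @param rawLog \code{SummarizedExperiment} at stage \code{raw_log} (only
#'   its control rows are used) or a plain control-class x array matrix.
#' @param loss \code{"huber"} (default) or \code{"tukey"}.
#' @param tol Convergence tolerance on the maximum parameter change
#'   (default 1e-8 log2 units).
#' @param maxIter Maximum IRLS iterations (default 50).
#' @return An \linkS4class{RlmFit}.
#' @export
fitControlModel <- function(rawLog, loss = c("huber", "tukey"),
                            tol = 1e-8, maxIter = 50L) {
  loss <- match.arg(loss)
  y <- if (is(rawLog, "SummarizedExperiment")) {
    idx <- .controlRows(rawLog)
    assay(rawLog, "exprs")[idx, , drop = FALSE]
  } else as.matrix(rawLog)
  if (ncol(y) < 2L)
    stop("need >= 2 arrays to fit array effects", call. = FALSE)
  if (nrow(y) < 2L)
    stop("need >= 2 control classes", call. = FALSE)
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
    stop("control class '", rownames(y)[bad[1L]],
         "' missing on array '", colnames(y)[bad[2L]], "'", call. = FALSE)
  }
  I <- nrow(y); J <- ncol(y)
  # parameters: b (I), a (J) with sum(a) = 0; IRLS via weighted row/column
  # sweeps of the additive model (weighted normal equations solved exactly
  # each iteration through lm.wfit on the full design)
  probe <- factor(rep(seq_len(I), times = J))
  array <- factor(rep(seq_len(J), each = I))
  X <- cbind(stats::model.matrix(~ probe - 1),
             stats::model.matrix(~ array)[, -1L, drop = FALSE])
  yv <- as.vector(y)
  w <- rep(1, length(yv))
  b <- rep(0, I); a <- rep(0, J)
  converged <- FALSE; iter <- 0L; scale <- NA_real_
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.wfit(X, yv, w)
    co <- fit$coefficients
    bNew <- co[seq_len(I)]
    aNew <- c(0, co[I + seq_len(J - 1L)])
    # re-centre to zero-sum array effects
    shift <- mean(aNew)
    aNew <- aNew - shift
    bNew <- bNew + shift
    delta <- max(abs(c(bNew - b, aNew - a)))
    b <- bNew; a <- aNew
    r <- yv - X %*% co
    scale <- mad(r, center = 0)
    if (scale <= .Machine$double.eps^0.5) { converged <- TRUE; break }
    w <- switch(loss,
                huber = .huberWeights(r / scale, 1.345),
                tukey = .tukeyWeights(r / scale, 4.685))
    # keep the design full-rank when the bisquare zeroes whole cells
    w <- pmax(as.vector(w), 1e-8)
    if (delta < tol && iter > 1L) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  if (!converged)
    warning("robust fit did not converge in ", maxIter, " iterations")
  names(a) <- colnames(y)
  names(b) <- rownames(y)
  new("RlmFit", arrayEffects = a, probeEffects = b, scale = scale,
      nIter = iter, converged = converged, loss = loss)
}

#' Subtract fitted array effects from an expression matrix
#'
#' Applies \eqn{y'_{ij} = y_{ij} - a_j} to every probe (control rows are
#' retained for diagnostics) and advances the stage to \code{normalized}.
#'
#' @param rawLog \code{SummarizedExperiment} at stage \code{raw_log}.
#' @param fit An \linkS4class{RlmFit} covering all samples of the matrix.
#' @return The normalized \code{SummarizedExperiment}.
#' @export
applyNormalization <- function(rawLog, fit) {
  .assertStage(rawLog, "raw_log")
  a <- arrayEffects(fit)
  miss <- setdiff(colnames(rawLog), names(a))
  if (length(miss))
    stop("no fitted array effect for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- rawLog
  assays(out)$exprs <- sweep(assay(rawLog, "exprs"), 2L,
                             a[colnames(rawLog)], "-")
  metadata(out)$stage <- "normalized"
  metadata(out)$array_effects <- a[colnames(rawLog)]
  out
}
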
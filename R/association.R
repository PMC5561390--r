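#' @importFrom stats pt p.adjust var cor cor.test wilcox.test prcomp hclust
#'   dist as.dist ptukey lm
NULL

# Invert the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; used by the empirical-Bayes moment fit.
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Moderated two-group t-tests with empirical-Bayes variance shrinkage
#'
#' Per gene, a two-group comparison with the gene's residual variance
#' \eqn{s_g^2} (df \eqn{d_g = n - 2}) shrunk towards a common prior:
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}. The prior
#' degrees of freedom \eqn{d_0} and variance \eqn{s_0^2} are estimated by
#' moment matching on \eqn{\log s_g^2} (closed form via trigamma
#' inversion). The moderated statistic
#' \eqn{t = \Delta / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})} is referred to a t
#' distribution with \eqn{d_0 + d_g} df, and p-values are
#' Benjamini-Hochberg adjusted over the requested test set, so the
#' adjustment universe (for example the most reactive proteins only, or the
#' whole platform) is under the caller's control.
#'
#' @param x \code{SummarizedExperiment} (its non-control rows are used) or a
#'   gene x sample numeric matrix of normalized log2 values.
#' @param groups Logical (or 0/1) vector, one entry per sample; TRUE marks
#'   the group whose mean enters with positive sign.
#' @param testSet Genes to test and to adjust over (default: all genes).
#' @param manifestation Optional label copied into the result.
#' @param priorDf Override for \eqn{d_0}: \code{0} gives the ordinary
#'   two-sample t, \code{Inf} the fully pooled t; \code{NULL} (default)
#'   estimates it from the data.
#' @return Data.frame with \code{gene_id}, \code{manifestation},
#'   \code{effect}, \code{t_mod}, \code{df_total}, \code{p}, \code{p_adj};
#'   the fitted hyperparameters are attached as attributes \code{d0} and
#'   \code{s0sq}.
#' @export
moderatedT <- function(x, groups, testSet = NULL, manifestation = NA_character_,
                       priorDf = NULL) {
  m <- if (is(x, "SummarizedExperiment")) .geneExprs(x) else as.matrix(x)
  groups <- as.logical(groups)
  stopifnot(length(groups) == ncol(m))
  if (!any(groups) || !any(!groups))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- sum(!groups); n2 <- sum(groups); n <- n1 + n2
  if (n < 3L) stop("need at least 3 samples in total", call. = FALSE)
  if (is.null(testSet)) testSet <- rownames(m)
  miss <- setdiff(testSet, rownames(m))
  if (length(miss))
    stop("test set gene(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- m[testSet, , drop = FALSE]
  m1 <- rowMeans(m[, !groups, drop = FALSE])
  m2 <- rowMeans(m[, groups, drop = FALSE])
  effect <- m2 - m1
  rss <- rowSums((m[, !groups, drop = FALSE] - m1)^2) +
    rowSums((m[, groups, drop = FALSE] - m2)^2)
  dg <- n - 2
  s2 <- rss / dg
  v <- 1 / n1 + 1 / n2

  if (is.null(priorDf)) {
    ok <- s2 > 0
    if (!any(ok)) {
      warning("all residual variances are zero; pooling completely (d0 = Inf)")
      d0 <- Inf; s0sq <- 0
    } else {
      e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
      emean <- mean(e)
      nOk <- length(e)
      rhs <- mean((e - emean)^2 * nOk / (nOk - 1) - trigamma(dg / 2))
      if (!is.finite(rhs) || rhs <= 0) {
        d0 <- Inf
        s0sq <- exp(emean)
      } else {
        d0 <- 2 * trigammaInverse(rhs)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    d0 <- priorDf
    s0sq <- if (d0 == 0) 0 else mean(s2)
  }
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + dg * s2) / (d0 + dg)
  tmod <- effect / sqrt(s2post * v)
  dfTotal <- d0 + dg
  p <- 2 * pt(abs(tmod), df = dfTotal, lower.tail = FALSE)
  out <- data.frame(gene_id = testSet, manifestation = manifestation,
                    effect = effect, t_mod = tmod,
                    df_total = rep(dfTotal, length(tmod)),
                    p = p, p_adj = p.adjust(p, method = "BH"),
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  out
}

#' Pairwise Pearson correlations between antigen reactivities
#'
#' @param z \code{SummarizedExperiment} at stage \code{zscore}.
#' @param genes Genes to correlate.
#' @param patientsOnly Restrict to patient samples when metadata is
#'   attached (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
antigenCorrelations <- function(z, genes, patientsOnly = TRUE) {
  .assertStage(z, "zscore")
  m <- assay(z, "exprs")
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stop("gene(s) absent: ", paste(miss, collapse = ", "), call. = FALSE)
  cd <- colData(z)
  if (patientsOnly && "group" %in% colnames(cd))
    m <- m[, cd$group == "patient", drop = FALSE]
  r <- cor(t(m[genes, , drop = FALSE]))
  diag(r) <- 1
  r
}

#' Per-sample signal dispersion and patient/control contrast
#'
#' Each sample is summarized by the SD of its values over all (non-control)
#' probes; a broader autoantibody repertoire inflates this dispersion. The
#' patient and control cohorts are compared with a Wilcoxon rank-sum test.
#'
#' @param norm \code{SummarizedExperiment} at stage \code{normalized}.
#' @param meta Sample metadata; defaults to colData.
#' @param alternative Passed to \code{wilcox.test} (default
#'   \code{"two.sided"}).
#' @return List with \code{sampleSd} (data.frame sample_id, group, sd) and
#'   \code{p} from the rank-sum test.
#' @export
varianceContrast <- function(norm, meta = NULL,
                             alternative = "two.sided") {
  .assertStage(norm, "normalized")
  meta <- .metaOf(norm, meta)
  x <- .geneExprs(norm)
  sds <- apply(x, 2L, sd)
  grp <- ifelse(meta$group == "patient", "patient", "control")
  if (min(table(grp)) < 2L || length(unique(grp)) < 2L)
    stop("need >= 2 samples in each of the patient and control groups",
         call. = FALSE)
  w <- wilcox.test(sds[grp == "patient"], sds[grp == "control"],
                   alternative = alternative, exact = FALSE)
  list(sampleSd = data.frame(sample_id = colnames(x), group = grp,
                             sd = unname(sds)),
       p = w$p.value)
}

.topReactiveGenes <- function(z, topK, zThreshold = 3, exclude = character(0)) {
  m <- assay(z, "exprs")
  cd <- colData(z)
  pat <- if ("group" %in% colnames(cd)) which(cd$group == "patient")
  else seq_len(ncol(m))
  npos <- rowSums(m[, pat, drop = FALSE] > zThreshold)
  npos <- npos[setdiff(names(npos), exclude)]
  names(sort(npos, decreasing = TRUE))[seq_len(min(topK, length(npos)))]
}

#' PCA of samples over the most common reactivities
#'
#' Genes are ranked by the number of patient samples in which they are
#' positive (z above \code{zThreshold}); the top \code{topK} genes feed a
#' centered principal component analysis of the samples.
#'
#' @param z \code{SummarizedExperiment} at stage \code{zscore}.
#' @param topK Number of top reactivities (default 50).
#' @param zThreshold Positivity threshold for ranking genes (default 3).
#' @return List with \code{scores} (samples x PCs), \code{explained}
#'   (per-PC explained-variance ratios, summing to at most 1) and
#'   \code{genes} used.
#' @export
repertoirePCA <- function(z, topK = 50L, zThreshold = 3) {
  .assertStage(z, "zscore")
  genes <- .topReactiveGenes(z, topK, zThreshold)
  m <- t(assay(z, "exprs")[genes, , drop = FALSE])
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2), genes = genes)
}

#' Hierarchical clustering of patients and top autoantigens
#'
#' Agglomerative clustering of both the sample columns and the top
#' reactivities (genes in \code{exclude}, e.g. type I interferons, removed
#' before ranking). Deterministic given its inputs.
#'
#' @param z \code{SummarizedExperiment} at stage \code{zscore}.
#' @param topK Number of top genes (default 50).
#' @param exclude Genes excluded before ranking.
#' @param linkage \code{"complete"} (default) or \code{"average"}.
#' @param metric \code{"euclidean"} (default) or \code{"correlation"}
#'   (distance \code{1 - r}).
#' @param zThreshold Positivity threshold for ranking (default 3).
#' @param patientsOnly Cluster patient samples only (default TRUE).
#' @return List with \code{rowClust}, \code{colClust} (\code{hclust}
#'   objects) and \code{matrix} (the clustered submatrix in dendrogram
#'   order).
#' @export
clusterRepertoire <- function(z, topK = 50L, exclude = character(0),
                              linkage = c("complete", "average"),
                              metric = c("euclidean", "correlation"),
                              zThreshold = 3, patientsOnly = TRUE) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  .assertStage(z, "zscore")
  genes <- .topReactiveGenes(z, topK, zThreshold, exclude)
  m <- assay(z, "exprs")[genes, , drop = FALSE]
  cd <- colData(z)
  if (patientsOnly && "group" %in% colnames(cd))
    m <- m[, cd$group == "patient", drop = FALSE]
  dfun <- function(a) if (metric == "euclidean") dist(a) else
    as.dist(1 - cor(t(a)))
  rowClust <- hclust(dfun(m), method = linkage)
  colClust <- hclust(dfun(t(m)), method = linkage)
  list(rowClust = rowClust, colClust = colClust,
       matrix = m[rowClust$order, colClust$order, drop = FALSE])
}

#' Regression of manifestation counts on repertoire size
#'
#' Ordinary least squares of the number of clinical manifestations on the
#' logarithmized number of positive autoantigen hits, over the per-patient
#' representative samples.
#'
#' @param hits Data.frame from \code{\link{hitCounts}} (needs
#'   \code{sample_id} and \code{log2_hits}).
#' @param meta Sample metadata with a \code{manifestations} list column.
#' @return List with \code{slope}, \code{intercept}, \code{r} (Pearson),
#'   \code{p} and a \code{degenerate} flag (TRUE when either variable is
#'   constant, in which case r is reported as 0).
#' @export
manifestationRegression <- function(hits, meta) {
  idx <- match(hits$sample_id, meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples", call. = FALSE)
  nman <- vapply(meta$manifestations[idx], length, 1L)
  x <- hits$log2_hits
  y <- nman
  if (var(y) == 0 || var(x) == 0) {
    slope <- if (var(x) == 0) NA_real_ else 0
    return(list(slope = 0, intercept = mean(y), r = 0, p = NA_real_,
                degenerate = TRUE))
  }
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Pairwise Nemenyi (Tukey-Kramer rank) comparison of mutation groups
#'
#' Patients' log2 hit counts are rank-transformed jointly (midranks for
#' ties); for each pair of mutation groups the statistic
#' \deqn{q = (\bar{R}_i - \bar{R}_j) / \sqrt{N(N+1)/12 (1/n_i + 1/n_j)}}
#' is referred to the studentized-range distribution with \code{k} groups
#' and infinite df (the \eqn{q\sqrt{2}} convention).
#'
#' @param hits Data.frame from \code{\link{hitCounts}}.
#' @param meta Sample metadata with \code{mutation_group}.
#' @return Data.frame with \code{group1}, \code{group2}, mean-rank
#'   difference, \code{q} and \code{p}.
#' @export
mutationGroupTest <- function(hits, meta) {
  idx <- match(hits$sample_id, meta$sample_id)
  g <- meta$mutation_group[idx]
  keep <- !is.na(g)
  g <- g[keep]
  y <- hits$log2_hits[keep]
  tab <- table(g)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("mutation group(s) with n < 2 excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !(g %in% small)
    g <- g[keep2]; y <- y[keep2]
  }
  groups <- sort(unique(g))
  k <- length(groups)
  if (k < 2L) stop("need >= 2 mutation groups with n >= 2", call. = FALSE)
  N <- length(y)
  R <- rank(y)  # midranks
  rbar <- tapply(R, g, mean)
  nn <- tapply(R, g, length)
  out <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    gi <- groups[i]; gj <- groups[j]
    q <- (rbar[[gi]] - rbar[[gj]]) /
      sqrt(N * (N + 1) / 12 * (1 / nn[[gi]] + 1 / nn[[gj]]))
    p <- ptukey(abs(q) * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = gi, group2 = gj,
                                 mean_rank_diff = rbar[[gi]] - rbar[[gj]],
                                 q = q, p = p))
  }
  rownames(out) <- NULL
  out
}
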
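#' @importFrom stats phyper
NULL

#' Hypergeometric over-representation of annotation terms
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term more than expected under random draws from the universe (the
#' platform content), using the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} for \eqn{X \sim HG(N, K, n)}; p-values are
#' Benjamini-Hochberg adjusted across all terms tested together.
#'
#' @param query Character vector of gene ids; must be a subset of the
#'   universe and non-empty.
#' @param categories Data.frame with columns \code{gene_id},
#'   \code{namespace}, \code{term}.
#' @param universe Background gene set (platform genes).
#' @return Data.frame with \code{namespace}, \code{term}, \code{N}
#'   (universe size), \code{K} (term size in universe), \code{n} (query
#'   size), \code{k} (overlap), \code{p_hyper} and \code{p_adj}; terms
#'   empty in the universe are skipped.
#' @export
hypergeomEnrich <- function(query, categories, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("empty query set", call. = FALSE)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
  categories <- categories[categories$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(query)
  keyTerms <- unique(categories[, c("namespace", "term")])
  rows <- lapply(seq_len(nrow(keyTerms)), function(i) {
    ns <- keyTerms$namespace[i]; tm <- keyTerms$term[i]
    members <- unique(categories$gene_id[categories$namespace == ns &
                                           categories$term == tm])
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    data.frame(namespace = ns, term = tm, N = N, K = K, n = n, k = k,
               p_hyper = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$p_adj <- p.adjust(res$p_hyper, method = "BH")
  res[order(res$p_hyper), ]
}

#' Resampling null for a continuous gene property
#'
#' Compares the mean of a per-gene property (SNP density, evolutionary
#' rate, ...) over the query set with the means of \code{R} random gene
#' groups of the same size drawn without replacement from the universe.
#' The empirical p-value carries the add-one correction
#' \eqn{p = (\#\{\mathrm{as\ or\ more\ extreme}\} + 1) / (R + 1)}, so the
#' minimal attainable value is \eqn{1/(R+1)}; ties count as extreme.
#'
#' @param query Gene ids (genes without a recorded property are dropped).
#' @param property Named numeric vector of per-gene values (names = gene
#'   ids); NA entries are dropped.
#' @param universe Background gene set; restricted to genes with a
#'   property value.
#' @param R Number of resampled groups (default 10000; fewer than 100
#'   triggers an instability warning).
#' @param direction \code{"less"} (default), \code{"greater"} or
#'   \code{"two_sided"}.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with \code{property} values used, \code{observed_mean},
#'   \code{null_means}, \code{R}, \code{p_emp}, \code{direction} and the
#'   effective query size \code{n}.
#' @export
resamplingNull <- function(query, property, universe, R = 10000L,
                           direction = c("less", "greater", "two_sided"),
                           seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  if (R < 100L) warning("R < 100 gives unstable empirical p-values")
  property <- property[!is.na(property)]
  universe <- intersect(unique(universe), names(property))
  query <- intersect(unique(query), universe)
  if (!length(query)) stop("no query gene with a property value",
                           call. = FALSE)
  n <- length(query)
  if (length(universe) < n)
    stop("universe smaller than query", call. = FALSE)
  obs <- mean(property[query])
  nullMeans <- vapply(seq_len(R), function(i)
    mean(property[sample(universe, n)]), numeric(1))
  extreme <- switch(direction,
                    less = sum(nullMeans <= obs),
                    greater = sum(nullMeans >= obs),
                    two_sided = sum(abs(nullMeans - mean(nullMeans)) >=
                                      abs(obs - mean(nullMeans))))
  list(observed_mean = obs, null_means = nullMeans, R = R,
       p_emp = (extreme + 1) / (R + 1), direction = direction, n = n)
}

#' Length-normalized SNP densities per gene
#'
#' \code{d_gene = snp_gene_count / gene_span_length} and
#' \code{d_exon = snp_exon_count / exon_total_length}; genes with a missing
#' or non-positive length are excluded and reported in the
#' \code{excluded} attribute.
#'
#' @param properties Data.frame with columns \code{gene_id},
#'   \code{snp_gene_count}, \code{snp_exon_count}, \code{gene_span_length},
#'   \code{exon_total_length}.
#' @return Data.frame with \code{gene_id}, \code{d_gene} (SNPs/bp over the
#'   gene span) and \code{d_exon} (SNPs/bp over exons).
#' @export
snpDensity <- function(properties) {
  need <- c("gene_id", "snp_gene_count", "snp_exon_count",
            "gene_span_length", "exon_total_length")
  miss <- setdiff(need, colnames(properties))
  if (length(miss))
    stop("property table lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(properties$gene_span_length) &
    properties$gene_span_length > 0 &
    !is.na(properties$exon_total_length) & properties$exon_total_length > 0
  excluded <- properties$gene_id[!ok]
  if (length(excluded))
    message(length(excluded), " gene(s) excluded for missing lengths")
  d <- data.frame(
    gene_id = properties$gene_id[ok],
    d_gene = properties$snp_gene_count[ok] / properties$gene_span_length[ok],
    d_exon = properties$snp_exon_count[ok] / properties$exon_total_length[ok])
  attr(d, "excluded") <- excluded
  d
}

#' Split an autoantigen set by tissue-restriction flag
#'
#' @param genes Gene ids to partition.
#' @param properties Data.frame with \code{gene_id} and \code{tr_flag}
#'   (\code{"TR"}, \code{"NTR"} or \code{"unknown"}).
#' @return List with \code{TR}, \code{NTR} and \code{excluded} (unknown or
#'   unannotated genes); the three parts reconstitute the input exactly.
#' @export
splitTrNtr <- function(genes, properties) {
  flag <- properties$tr_flag[match(genes, properties$gene_id)]
  flag[is.na(flag)] <- "unknown"
  list(TR = genes[flag == "TR"], NTR = genes[flag == "NTR"],
       excluded = genes[!flag %in% c("TR", "NTR")])
}

#' Overlap of the autoantigen set with an external gene list
#'
#' Hypergeometric overlap test between the (optionally ortholog-mapped)
#' query and a differential-expression gene list, with the mappable
#' platform content as universe. One-to-many ortholog mappings keep a
#' target gene when any query ortholog maps to it; duplicates are
#' collapsed before counting.
#'
#' @param query Gene ids (e.g. human autoantigen genes).
#' @param deList Differential-expression gene set in the target namespace.
#' @param universe Platform gene set (mapped alongside the query when a
#'   map is given).
#' @param orthologMap Optional data.frame with columns \code{from},
#'   \code{to} mapping query/universe ids to the deList namespace.
#' @return One-row data.frame in the \code{\link{hypergeomEnrich}} layout.
#' @export
listOverlap <- function(query, deList, universe, orthologMap = NULL) {
  mapIds <- function(ids) {
    if (is.null(orthologMap)) return(unique(ids))
    unique(orthologMap$to[orthologMap$from %in% ids])
  }
  q <- mapIds(query)
  u <- mapIds(universe)
  q <- intersect(q, u)
  d <- intersect(unique(deList), u)
  N <- length(u); K <- length(d); n <- length(q)
  k <- length(intersect(q, d))
  data.frame(namespace = "de_list", term = "overlap", N = N, K = K,
             n = n, k = k,
             p_hyper = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
             p_adj = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
}
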
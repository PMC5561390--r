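#' @importFrom utils read.delim write.table
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData colData<- rowData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Default GPR column mapping
#'
#' Maps the fields of the internal probe model to column names of a
#' GenePix-style (ATF header + tab-separated table) scan export. Override
#' entries to load exports from other scanners.
#'
#' @return Named character vector of column names.
#' @export
gprColumns <- function() {
  c(block = "Block", row = "Row", col = "Column",
    probe_id = "ID", gene_id = "Name",
    fg = "F635 Median", bg = "B635 Median",
    control_series = "ControlSeries", control_level = "ControlLevel")
}

# Parse one ATF-style file: "ATF\t1.0", "<nHeader>\t<nCols>", nHeader quoted
# key=value lines, then the tab table.
.readGpr <- function(path, columns) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^ATF", lines[1L]))
    stop("not an ATF/GPR file: ", path, call. = FALSE)
  nhead <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]][1L]))
  if (is.na(nhead)) stop("malformed ATF header in ", path, call. = FALSE)
  header <- readLines(path, n = 2L + nhead)[-(1:2)]
  tab <- read.delim(path, skip = 2L + nhead, check.names = FALSE,
                    stringsAsFactors = FALSE)
  sample_id <- sub("\\.gpr$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(header, regexec("SampleID=([^\"]+)", header))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) sample_id <- m[[which(hit)[1L]]][2L]

  required <- c("block", "row", "col", "probe_id", "fg", "bg")
  miss <- columns[required][!columns[required] %in% colnames(tab)]
  if (length(miss))
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)

  get <- function(field, default = NA) {
    cn <- columns[[field]]
    if (!is.null(cn) && cn %in% colnames(tab)) tab[[cn]] else
      rep(default, nrow(tab))
  }
  series <- as.character(get("control_series", NA_character_))
  series[!is.na(series) & series == ""] <- NA_character_
  gene <- as.character(get("gene_id", NA_character_))
  gene[!is.na(gene) & gene == ""] <- NA_character_
  lvl <- suppressWarnings(as.integer(get("control_level", NA_integer_)))
  lay <- DataFrame(
    probe_id = as.character(tab[[columns[["probe_id"]]]]),
    gene_id = gene,
    block = as.integer(tab[[columns[["block"]]]]),
    row = as.integer(tab[[columns[["row"]]]]),
    col = as.integer(tab[[columns[["col"]]]]),
    is_control = !is.na(series),
    control_series = series,
    control_level = lvl)
  list(sample_id = sample_id, layout = lay,
       fg = as.numeric(tab[[columns[["fg"]]]]),
       bg = as.numeric(tab[[columns[["bg"]]]]))
}

.layoutKey <- function(lay)
  paste(lay$probe_id, lay$block, lay$row, lay$col, sep = "\r")

#' Read GenePix-style scan files into a ScanSet
#'
#' Reads one or more tab-separated scan exports with an ATF-style header and
#' assembles them into a \linkS4class{ScanSet}. All scans in one experiment
#' must share the identical probe layout (the same set of
#' \code{(probe_id, block, row, col)}); with \code{layoutCheck = TRUE} a
#' mismatch is an error naming the offending probe.
#'
#' @param paths Character vector of file paths.
#' @param layoutCheck Enforce layout identity across files (default TRUE).
#' @param columns Column name mapping, see \code{\link{gprColumns}}.
#' @return A \linkS4class{ScanSet}.
#' @export
readScans <- function(paths, layoutCheck = TRUE, columns = gprColumns()) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("file(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  parsed <- lapply(paths, .readGpr, columns = columns)
  ref <- parsed[[1L]]$layout
  refKey <- .layoutKey(ref)
  ord <- order(ref$block, ref$row, ref$col)
  ref <- ref[ord, ]
  refKey <- refKey[ord]
  fg <- bg <- matrix(NA_real_, nrow(ref), length(parsed))
  ids <- character(length(parsed))
  for (j in seq_along(parsed)) {
    p <- parsed[[j]]
    key <- .layoutKey(p$layout)
    if (layoutCheck && !setequal(key, refKey)) {
      bad <- c(setdiff(refKey, key), setdiff(key, refKey))[1L]
      stop("layout error: probe '", strsplit(bad, "\r")[[1L]][1L],
           "' differs between ", basename(paths[1L]), " and ",
           basename(paths[j]), call. = FALSE)
    }
    idx <- match(refKey, key)
    fg[, j] <- p$fg[idx]
    bg[, j] <- p$bg[idx]
    ids[j] <- p$sample_id
  }
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  colnames(fg) <- colnames(bg) <- ids
  rownames(fg) <- rownames(bg) <- ref$probe_id
  new("ScanSet", layout = ref, fg = fg, bg = bg)
}

#' Write a ScanSet back to GPR files
#'
#' Writes one ATF-header tab-separated file per sample, using the same
#' column names \code{\link{readScans}} reads, so a read/write round trip
#' preserves all probe fields.
#'
#' @param scans A \linkS4class{ScanSet}.
#' @param dir Output directory (created if needed).
#' @param columns Column mapping as in \code{\link{readScans}}.
#' @return Invisibly, the paths written.
#' @export
writeScans <- function(scans, dir, columns = gprColumns()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- scans@layout
  paths <- character(0)
  for (id in sampleIds(scans)) {
    tab <- data.frame(
      b = lay$block, r = lay$row, cc = lay$col,
      id = lay$probe_id,
      name = ifelse(is.na(lay$gene_id), "", lay$gene_id),
      fg = format(scans@fg[, id], digits = 15, trim = TRUE, scientific = FALSE),
      bg = format(scans@bg[, id], digits = 15, trim = TRUE, scientific = FALSE),
      cs = ifelse(is.na(lay$control_series), "", lay$control_series),
      cl = ifelse(is.na(lay$control_level), "", lay$control_level),
      stringsAsFactors = FALSE, check.names = FALSE)
    colnames(tab) <- columns[c("block", "row", "col", "probe_id", "gene_id",
                               "fg", "bg", "control_series", "control_level")]
    path <- file.path(dir, paste0(id, ".gpr"))
    con <- file(path, "w")
    writeLines(c("ATF\t1.0",
                 paste0(2L, "\t", ncol(tab)),
                 "\"Type=GenePix Results 3\"",
                 paste0("\"SampleID=", id, "\"")), con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Summarize probe spots to gene-level log2 expression
#'
#' Per spot, the background is subtracted from the foreground and the result
#' floored at \code{floor} (in the scanner's arbitrary units) before taking
#' log2; replicate spots of a gene are then combined by the mean or median of
#' the log2 values. Control probes are summarized per control class
#' (series x concentration level) under ids \code{ctl:<series>:<level>}.
#'
#' @param scans A \linkS4class{ScanSet}.
#' @param method Replicate-spot aggregation, \code{"mean"} (default) or
#'   \code{"median"}.
#' @param floor Intensity floor applied before log2 (default 1 a.u.).
#' @return A \code{SummarizedExperiment} at stage \code{"raw_log"} with
#'   assays \code{exprs} (log2 a.u.) and \code{floored} (fraction of a
#'   gene's spots floored in that sample); \code{rowData} carries control
#'   status and the grid position of each gene's first spot.
#' @export
summarizeProbes <- function(scans, method = c("mean", "median"), floor = 1) {
  method <- match.arg(method)
  lay <- scans@layout
  net <- scans@fg - scans@bg
  floored <- net < floor
  lognet <- log2(pmax(net, floor))
  unit <- ifelse(lay$is_control,
                 paste0("ctl:", lay$control_series, ":", lay$control_level),
                 lay$gene_id)
  keep <- !is.na(unit)
  if (any(!keep))
    warning(sum(!keep), " spot(s) without gene or control annotation dropped")
  unit <- unit[keep]
  lognet <- lognet[keep, , drop = FALSE]
  floored <- floored[keep, , drop = FALSE]
  lay <- lay[keep, ]
  agg <- if (method == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  units <- unique(unit)
  exprs <- matrix(NA_real_, length(units), ncol(lognet),
                  dimnames = list(units, colnames(lognet)))
  flr <- exprs
  for (u in units) {
    rows <- which(unit == u)
    exprs[u, ] <- agg(lognet[rows, , drop = FALSE])
    flr[u, ] <- colMeans(floored[rows, , drop = FALSE])
  }
  first <- match(units, unit)
  rd <- DataFrame(
    gene_id = units,
    is_control = lay$is_control[first],
    control_series = lay$control_series[first],
    control_level = lay$control_level[first],
    block = lay$block[first], row = lay$row[first], col = lay$col[first],
    row.names = units)
  se <- SummarizedExperiment(assays = list(exprs = exprs, floored = flr),
                             rowData = rd)
  metadata(se)$stage <- "raw_log"
  metadata(se)$log_base <- 2
  metadata(se)$floor <- floor
  metadata(se)$summarize_method <- method
  se
}

#' @rdname summarizeProbes
#' @param se A \code{SummarizedExperiment} produced by this package.
#' @export
matrixStage <- function(se) metadata(se)$stage

.assertStage <- function(se, stage) {
  if (!identical(matrixStage(se), stage))
    stop("expected a matrix at stage '", stage, "', got '",
         matrixStage(se), "'", call. = FALSE)
  invisible(se)
}

#' Read a sample metadata table
#'
#' Tab-separated with header; required columns \code{sample_id},
#' \code{patient_id}, \code{group} (patient/control/relative); optional
#' \code{age_at_sampling}, \code{sex}, \code{country}, \code{mutation_group}
#' (1..3, empty for controls/relatives), \code{onset_age} and
#' \code{manifestations} (semicolon-separated set).
#'
#' @param path File path.
#' @return A data.frame, \code{manifestations} parsed into a list column.
#' @export
readSampleMeta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "patient_id", "group")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(meta$group %in% c("patient", "control", "relative")))
    stop("group must be patient/control/relative", call. = FALSE)
  if ("manifestations" %in% colnames(meta)) {
    meta$manifestations <- lapply(strsplit(
      ifelse(is.na(meta$manifestations), "", meta$manifestations), ";",
      fixed = TRUE), function(x) x[nzchar(x)])
  }
  if ("mutation_group" %in% colnames(meta)) {
    bad <- meta$group != "patient" & !is.na(meta$mutation_group)
    if (any(bad))
      stop("mutation_group must be empty for controls/relatives",
           call. = FALSE)
  }
  meta
}

#' Write a sample metadata table
#' @param meta Data.frame as returned by \code{\link{readSampleMeta}}.
#' @param path Output path.
#' @export
writeSampleMeta <- function(meta, path) {
  out <- meta
  if (is.list(out$manifestations))
    out$manifestations <- vapply(out$manifestations, paste, "", collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach sample metadata to an expression matrix
#' @param se A \code{SummarizedExperiment}.
#' @param meta Metadata data.frame with a \code{sample_id} column covering
#'   all matrix samples.
#' @return \code{se} with \code{colData} filled in.
#' @export
attachSampleMeta <- function(se, meta) {
  idx <- match(colnames(se), meta$sample_id)
  if (anyNA(idx))
    stop("metadata missing for sample(s): ",
         paste(colnames(se)[is.na(idx)], collapse = ", "), call. = FALSE)
  colData(se) <- DataFrame(meta[idx, , drop = FALSE],
                           row.names = colnames(se))
  se
}

#' Read or write an expression matrix as TSV
#'
#' Genes in rows, samples in columns, first column \code{gene_id}; the
#' processing stage is recorded in a \code{# stage=} comment line.
#'
#' @param se Matrix to write.
#' @param path File path.
#' @export
writeMatrixTsv <- function(se, path) {
  con <- file(path, "w")
  writeLines(paste0("# stage=", matrixStage(se)), con)
  df <- data.frame(gene_id = rownames(se), assay(se, "exprs"),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- if (grepl("^# stage=", first)) sub("^# stage=", "", first) else NULL
  tab <- read.delim(path, skip = if (is.null(stage)) 0L else 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  se <- SummarizedExperiment(assays = list(exprs = m))
  metadata(se)$stage <- stage
  se
}

#' Read per-gene annotation tables
#'
#' \code{readGeneCategories} reads categorical memberships (columns
#' \code{gene_id}, \code{namespace}, \code{term}); \code{readGeneProperties}
#' reads per-gene continuous properties (SNP counts, span lengths,
#' evolutionary rates, TR/NTR flag) with one row per gene.
#'
#' @param path File path (TSV with header).
#' @return A data.frame.
#' @export
readGeneCategories <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("gene_id", "namespace", "term"), colnames(tab))
  if (length(miss))
    stop("annotation table lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname readGeneCategories
#' @export
readGeneProperties <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% colnames(tab))
    stop("property table lacks gene_id", call. = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene_id in property table", call. = FALSE)
  tab
}
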
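suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# a SummarizedExperiment at a given stage, with optional sample metadata
makeSe <- function(values, stage = "normalized", meta = NULL,
                   isControl = rep(FALSE, nrow(values))) {
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(gene_id = rownames(values), is_control = isControl,
                        row.names = rownames(values)))
  metadata(se)$stage <- stage
  if (!is.null(meta)) se <- attachSampleMeta(se, meta)
  se
}

# minimal metadata for a set of patient/control samples
makeMeta <- function(patients, controls, relatives = character(0),
                     ages = NULL) {
  ids <- c(patients, controls, relatives)
  data.frame(
    sample_id = ids,
    patient_id = c(sub("_t[0-9]+$", "", patients),
                   paste0("HC_", c(controls, relatives))),
    group = rep(c("patient", "control", "relative"),
                c(length(patients), length(controls), length(relatives))),
    age_at_sampling = if (is.null(ages)) seq_along(ids) else ages,
    stringsAsFactors = FALSE)
}

# write a small two-block GPR file; probes = data.frame(probe_id, gene_id,
# block, row, col, fg, bg, control_series, control_level)
writeTestGpr <- function(path, sampleId, probes) {
  tab <- data.frame(
    Block = probes$block, Row = probes$row, Column = probes$col,
    ID = probes$probe_id,
    Name = ifelse(is.na(probes$gene_id), "", probes$gene_id),
    `F635 Median` = probes$fg, `B635 Median` = probes$bg,
    ControlSeries = ifelse(is.na(probes$control_series), "",
                           probes$control_series),
    ControlLevel = ifelse(is.na(probes$control_level), "",
                          probes$control_level),
    check.names = FALSE)
  con <- file(path, "w")
  writeLines(c("ATF\t1.0", paste0("2\t", ncol(tab)),
               "\"Type=GenePix Results 3\"",
               paste0("\"SampleID=", sampleId, "\"")), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

testProbes <- function() {
  data.frame(
    probe_id = c("p1", "p2", "p3", "c1", "c2"),
    gene_id = c("GA", "GB", "GB", NA, NA),
    block = c(1L, 1L, 1L, 2L, 2L),
    row = c(1L, 1L, 2L, 1L, 1L),
    col = c(1L, 2L, 1L, 1L, 2L),
    fg = c(1024, 54, 66, 500, 900),
    bg = c(0, 50, 50, 50, 50),
    control_series = c(NA, NA, NA, "hIgG", "V5"),
    control_level = c(NA, NA, NA, 1L, 2L),
    stringsAsFactors = FALSE)
}

# exhaustive upper-tail hypergeometric oracle by enumerating all draws
enumHyperP <- function(N, K, n, k) {
  hits <- 0L; total <- 0L
  for (draw in utils::combn(N, n, simplify = FALSE)) {
    total <- total + 1L
    if (sum(draw <= K) >= k) hits <- hits + 1L
  }
  hits / total
}

# additive two-way data with planted effects
additiveMatrix <- function(b, a) outer(b, a, "+")
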
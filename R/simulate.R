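#' @importFrom stats rnorm runif rpois rbinom plogis setNames
NULL

#' Configuration for the synthetic serology experiment
#'
#' Builds the parameter set for \code{\link{simulateExperiment}}. Defaults
#' emulate a ProtoArray-style screen of an APECED-like cohort: 50 patients
#' plus 20 healthy samples (12 unrelated controls and 8 heterozygous
#' relatives), 1000 probed genes, two control-probe series (hIgG, V5) of 10
#' concentration levels each, per-array technical effects of SD 0.5 log2
#' and contaminated-normal spot noise (5\% outliers at 5x SD) that
#' motivates the robust normalization.
#'
#' @param nPatients,nControls,nRelatives Cohort sizes (samples are added on
#'   top for longitudinal patients).
#' @param nGenes Number of non-control probes.
#' @param nControlLevels Concentration levels per control series (two
#'   series are always printed, so the number of control classes is twice
#'   this).
#' @param grid List with \code{blocks}, \code{rows}, \code{cols},
#'   \code{replicates}; \code{NULL} (default) sizes a 4-block grid
#'   automatically.
#' @param arrayEffectSd SD of the per-array technical effect (log2).
#' @param noiseSd Spot noise SD (log2); this is also the control-cohort SD
#'   scale in which reactivity effects are expressed.
#' @param outlierFrac,outlierK Contaminated-normal mixture: fraction of
#'   outlier spots and their SD multiplier.
#' @param nShared,sharedPrevalence Shared autoantigens planted across the
#'   cohort and the range their per-patient prevalence is drawn from.
#' @param sharedPatientsEach When set, overrides the prevalence draw: every
#'   shared antigen is planted in exactly this many randomly chosen
#'   patients, fixing the total number of planted reactivities.
#' @param delta Reactivity effect size in control-SD units (log2 shift is
#'   \code{delta * noiseSd}).
#' @param privateRate Poisson mean of additional patient-private
#'   reactivities.
#' @param nContaminated,carryCoef Number of planted print-contamination
#'   wells and their carryover coefficient.
#' @param nMultiPatients,acquisitionRate Longitudinal design: patients with
#'   a second serum sample, and the per-year Poisson rate at which new
#'   reactivities are acquired (repertoires only grow).
#' @param mutationRateMult Per mutation group (1..3), multiplier on the
#'   private reactivity rate.
#' @param manifBaseline,manifSlope,nManifestations Logistic link from log2
#'   hit counts to the probability of each candidate manifestation.
#' @param trFraction Fraction of genes flagged tissue-restricted.
#' @param snpShift,evoShift Multiplicative SNP-density and additive
#'   (log-scale) evolutionary-rate shift planted on reactive genes
#'   (both < 1 resp. < 0: reactive genes carry fewer SNPs and are more
#'   conserved).
#' @param seed RNG seed; the whole experiment is reproducible from it.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(nPatients = 50L, nControls = 12L, nRelatives = 8L,
                      nGenes = 1000L, nControlLevels = 10L, grid = NULL,
                      arrayEffectSd = 0.5, noiseSd = 0.35,
                      outlierFrac = 0.05, outlierK = 5,
                      nShared = 10L, sharedPrevalence = c(0.1, 0.6),
                      sharedPatientsEach = NULL,
                      delta = 6, privateRate = 5,
                      nContaminated = 5L, carryCoef = 0.7,
                      nMultiPatients = 10L, acquisitionRate = 0.5,
                      mutationRateMult = c(1.6, 1.4, 0.6),
                      manifBaseline = -3, manifSlope = 0.6,
                      nManifestations = 8L,
                      trFraction = 0.35, snpShift = 0.7, evoShift = -0.4,
                      seed = 1L) {
  nCtlClasses <- 2L * nControlLevels
  if (is.null(grid)) {
    total <- nGenes + nCtlClasses
    blocks <- 4L
    percap <- ceiling(total / blocks)
    cols <- ceiling(sqrt(percap))
    rows <- ceiling(percap / cols)
    grid <- list(blocks = blocks, rows = rows, cols = cols, replicates = 1L)
  }
  cap <- grid$blocks * grid$rows * grid$cols
  if (cap < (nGenes + nCtlClasses) * grid$replicates)
    stop("grid capacity ", cap, " < ", (nGenes + nCtlClasses) *
           grid$replicates, " spots required", call. = FALSE)
  cfg <- list(nPatients = nPatients, nControls = nControls,
              nRelatives = nRelatives, nGenes = nGenes,
              nControlLevels = nControlLevels, grid = grid,
              arrayEffectSd = arrayEffectSd, noiseSd = noiseSd,
              outlierFrac = outlierFrac, outlierK = outlierK,
              nShared = nShared, sharedPrevalence = sharedPrevalence,
              sharedPatientsEach = sharedPatientsEach,
              delta = delta, privateRate = privateRate,
              nContaminated = nContaminated, carryCoef = carryCoef,
              nMultiPatients = nMultiPatients,
              acquisitionRate = acquisitionRate,
              mutationRateMult = mutationRateMult,
              manifBaseline = manifBaseline, manifSlope = manifSlope,
              nManifestations = nManifestations,
              trFraction = trFraction, snpShift = snpShift,
              evoShift = evoShift, seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

# sequential block-filling layout for gene and control spots
.simLayout <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  ctl <- expand.grid(series = c("hIgG", "V5"),
                     level = seq_len(cfg$nControlLevels),
                     stringsAsFactors = FALSE)
  units <- data.frame(
    unit = c(genes, paste0("ctl-", ctl$series, "-", ctl$level)),
    gene_id = c(genes, rep(NA_character_, nrow(ctl))),
    is_control = c(rep(FALSE, length(genes)), rep(TRUE, nrow(ctl))),
    control_series = c(rep(NA_character_, length(genes)), ctl$series),
    control_level = c(rep(NA_integer_, length(genes)), ctl$level))
  reps <- cfg$grid$replicates
  spots <- units[rep(seq_len(nrow(units)), each = reps), , drop = FALSE]
  ns <- nrow(spots)
  idx <- seq_len(ns) - 1L
  perBlock <- cfg$grid$rows * cfg$grid$cols
  spots$block <- idx %/% perBlock + 1L
  within <- idx %% perBlock
  spots$row <- within %/% cfg$grid$cols + 1L
  spots$col <- within %% cfg$grid$cols + 1L
  spots$probe_id <- paste0(spots$unit, "_s",
                           sequence(rep(reps, nrow(units))))
  rownames(spots) <- NULL
  spots
}

# pick contamination (source, target) gene pairs from horizontally
# adjacent spots; sources are shared antigens, targets clean genes
.pickContamination <- function(cfg, spots, sharedGenes) {
  pairs <- NULL
  byPos <- setNames(spots$gene_id,
                    paste(spots$block, spots$row, spots$col))
  for (src in sharedGenes) {
    hit <- which(spots$gene_id %in% src)[1L]
    nb <- unname(byPos[paste(spots$block[hit], spots$row[hit],
                             spots$col[hit] + 1L)])
    if (is.na(nb) || nb %in% sharedGenes) next
    pairs <- rbind(pairs, data.frame(source = src, target = nb,
                                     coefficient = cfg$carryCoef))
    if (!is.null(pairs) && nrow(pairs) >= cfg$nContaminated) break
  }
  pairs
}

#' Simulate a complete protein-microarray serology experiment
#'
#' Generates scans, sample metadata, gene annotations and
#' differential-expression lists with the statistical structure the
#' analysis pipeline assumes, together with the ground truth needed to
#' verify every stage. The log2 net signal of gene i on array j is
#' \deqn{y_{ij} = \mu_i + a_j + \delta \sigma 1[\mathrm{reactive}] +
#'   \mathrm{carryover} + \epsilon_{ij}}
#' with gene baselines \eqn{\mu_i}, zero-mean array effects \eqn{a_j},
#' contaminated-normal noise \eqn{\epsilon}, and control classes following
#' a concentration ladder that is exactly constant across arrays before
#' array effects are applied.
#'
#' @param cfg A \code{\link{simConfig}} object.
#' @return List with \code{scans} (\linkS4class{ScanSet}), \code{meta},
#'   \code{categories}, \code{properties}, \code{deLists},
#'   \code{orthologMap} and \code{truth} (planted reactivities, array
#'   effects, contamination pairs, longitudinal acquisitions, annotation
#'   shifts).
#' @export
simulateExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  spots <- .simLayout(cfg)

  ## ---- cohort & samples ------------------------------------------------
  patients <- sprintf("P%03d", seq_len(cfg$nPatients))
  mutGroup <- sample(1:3, cfg$nPatients, replace = TRUE,
                     prob = c(0.25, 0.45, 0.30))
  patientAge <- round(runif(cfg$nPatients, 10, 55), 1)
  multi <- patients[seq_len(min(cfg$nMultiPatients, cfg$nPatients))]
  gaps <- setNames(numeric(length(multi)), multi)
  if (length(multi)) {
    half <- seq_along(multi) <= ceiling(length(multi) / 2)
    gaps[half] <- round(runif(sum(half), 1, 8), 1)
    gaps[!half] <- round(runif(sum(!half), 12, 30), 1)
  }
  meta <- data.frame(
    sample_id = paste0(patients, "_t1"), patient_id = patients,
    group = "patient", age_at_sampling = patientAge,
    sex = sample(c("F", "M"), cfg$nPatients, replace = TRUE),
    country = sample(c("FI", "IT", "NO", "SI", "EE"), cfg$nPatients,
                     replace = TRUE),
    mutation_group = mutGroup, onset_age = pmax(1, patientAge -
      round(runif(cfg$nPatients, 5, 30), 1)),
    stringsAsFactors = FALSE)
  if (length(multi)) {
    i <- match(multi, meta$patient_id)
    second <- meta[i, , drop = FALSE]
    second$sample_id <- paste0(multi, "_t2")
    second$age_at_sampling <- second$age_at_sampling + gaps[multi]
    meta <- rbind(meta, second)
  }
  nHealthy <- cfg$nControls + cfg$nRelatives
  healthy <- data.frame(
    sample_id = sprintf("C%03d", seq_len(nHealthy)),
    patient_id = sprintf("HC%03d", seq_len(nHealthy)),
    group = rep(c("control", "relative"),
                c(cfg$nControls, cfg$nRelatives)),
    age_at_sampling = round(runif(nHealthy, 10, 55), 1),
    sex = sample(c("F", "M"), nHealthy, replace = TRUE),
    country = sample(c("FI", "IT"), nHealthy, replace = TRUE),
    mutation_group = NA_integer_, onset_age = NA_real_,
    stringsAsFactors = FALSE)
  meta <- rbind(meta, healthy)

  ## ---- planted reactivities -------------------------------------------
  # spread shared antigens across the grid so none are printed adjacently
  shared <- genes[unique(round(seq(1, cfg$nGenes - 1,
                                   length.out = cfg$nShared)))]
  prev <- runif(cfg$nShared, cfg$sharedPrevalence[1], cfg$sharedPrevalence[2])
  baseSets <- vector("list", cfg$nPatients)
  names(baseSets) <- patients
  sharedOf <- if (is.null(cfg$sharedPatientsEach)) {
    lapply(seq_len(cfg$nPatients),
           function(p) shared[runif(cfg$nShared) < prev])
  } else {
    carriers <- lapply(shared, function(g)
      sample(patients, cfg$sharedPatientsEach))
    lapply(patients, function(p)
      shared[vapply(carriers, function(cc) p %in% cc, TRUE)])
  }
  for (p in seq_len(cfg$nPatients)) {
    rate <- cfg$privateRate * cfg$mutationRateMult[mutGroup[p]]
    nPriv <- rpois(1L, rate)
    priv <- sample(setdiff(genes, shared), min(nPriv, cfg$nGenes -
                                                 cfg$nShared))
    baseSets[[p]] <- union(sharedOf[[p]], priv)
  }
  acquisitions <- list()
  sampleSets <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    if (meta$group[i] != "patient") { sampleSets[[sid]] <- character(0); next }
    p <- meta$patient_id[i]
    if (grepl("_t2$", sid)) {
      nNew <- rpois(1L, cfg$acquisitionRate * gaps[p])
      new <- sample(setdiff(genes, baseSets[[p]]),
                    min(nNew, cfg$nGenes - length(baseSets[[p]])))
      acquisitions[[p]] <- new
      sampleSets[[sid]] <- union(baseSets[[p]], new)  # growth only, no loss
    } else sampleSets[[sid]] <- baseSets[[p]]
  }

  ## ---- signals ---------------------------------------------------------
  nS <- nrow(meta)
  baseline <- setNames(rnorm(cfg$nGenes, 8, 1), genes)
  a <- rnorm(nS, 0, cfg$arrayEffectSd)
  a <- a - mean(a)
  names(a) <- meta$sample_id
  # reactivity effects are in control-SD units; the control cohort's SD is
  # the full contaminated-normal mixture SD, which z-scoring divides by
  sigmaMix <- cfg$noiseSd *
    sqrt(1 - cfg$outlierFrac + cfg$outlierFrac * cfg$outlierK^2)
  deltaLog2 <- cfg$delta * sigmaMix
  net <- matrix(rep(baseline, nS), cfg$nGenes, nS,
                dimnames = list(genes, meta$sample_id))
  net <- sweep(net, 2L, a, "+")
  for (sid in meta$sample_id)
    net[sampleSets[[sid]], sid] <- net[sampleSets[[sid]], sid] + deltaLog2
  noise <- function(n) {
    out <- rnorm(n, 0, cfg$noiseSd)
    big <- runif(n) < cfg$outlierFrac
    out[big] <- rnorm(sum(big), 0, cfg$outlierK * cfg$noiseSd)
    out
  }
  geneNoise <- matrix(noise(cfg$nGenes * nS), cfg$nGenes, nS)
  net <- net + geneNoise
  contam <- .pickContamination(cfg, spots, shared)
  if (!is.null(contam)) for (r in seq_len(nrow(contam))) {
    src <- contam$source[r]; tgt <- contam$target[r]
    dev <- net[src, ] - baseline[src] - a  # reactivity + source noise
    net[tgt, ] <- baseline[tgt] + a + contam$coefficient[r] * dev +
      noise(nS)
  }
  ## control ladder: constant across arrays before array effects
  ctlRows <- spots[spots$is_control & !duplicated(spots$unit), ]
  ctlBase <- setNames(6 + 0.4 * ctlRows$control_level +
                        0.2 * (ctlRows$control_series == "V5"),
                      ctlRows$unit)
  ctlNet <- outer(ctlBase, a, "+") +
    matrix(noise(length(ctlBase) * nS), length(ctlBase), nS)
  colnames(ctlNet) <- meta$sample_id

  ## spot-level fg/bg (replicates share the gene value plus spot noise)
  unitNet <- rbind(net, ctlNet)
  spotNet <- unitNet[spots$unit, , drop = FALSE]
  if (cfg$grid$replicates > 1L)
    spotNet <- spotNet + matrix(rnorm(length(spotNet), 0, 0.05),
                                nrow(spotNet))
  bgVal <- 50
  fg <- round(2^spotNet + bgVal, 2)
  bg <- matrix(bgVal, nrow(fg), ncol(fg))
  dimnames(fg) <- dimnames(bg) <- list(spots$probe_id, meta$sample_id)
  lay <- DataFrame(probe_id = spots$probe_id, gene_id = spots$gene_id,
                   block = spots$block, row = spots$row, col = spots$col,
                   is_control = spots$is_control,
                   control_series = spots$control_series,
                   control_level = spots$control_level)
  scans <- new("ScanSet", layout = lay, fg = fg, bg = bg)

  ## ---- manifestations --------------------------------------------------
  manifNames <- paste0("manif", seq_len(cfg$nManifestations))
  meta$manifestations <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (meta$group[i] != "patient") { meta$manifestations[[i]] <- character(0); next }
    h <- length(sampleSets[[meta$sample_id[i]]])
    pr <- plogis(cfg$manifBaseline + cfg$manifSlope * log2(h + 1))
    meta$manifestations[[i]] <- manifNames[runif(cfg$nManifestations) < pr]
  }

  ## ---- annotations -----------------------------------------------------
  reactive <- unique(unlist(sampleSets))
  trFlag <- ifelse(runif(cfg$nGenes) < cfg$trFraction, "TR", "NTR")
  trFlag[sample(cfg$nGenes, round(0.05 * cfg$nGenes))] <- "unknown"
  names(trFlag) <- genes
  ## categorical memberships; "ptm:phospho" planted enriched in reactives
  pPhospho <- ifelse(genes %in% reactive, 0.45, 0.15)
  cats <- rbind(
    data.frame(gene_id = genes[runif(cfg$nGenes) < pPhospho],
               namespace = "ptm", term = "phospho"),
    data.frame(gene_id = genes[runif(cfg$nGenes) < 0.3],
               namespace = "compartment", term = "nucleus"),
    data.frame(gene_id = genes[runif(cfg$nGenes) < 0.25],
               namespace = "compartment", term = "membrane"),
    data.frame(gene_id = genes[runif(cfg$nGenes) < 0.2],
               namespace = "tissue", term = "lymphoid"))
  ## continuous properties; reactive genes get fewer SNPs, lower evo rate
  span <- round(runif(cfg$nGenes, 5e3, 2e5))
  exonLen <- round(span * runif(cfg$nGenes, 0.03, 0.1))
  snpRate <- 1e-3 * ifelse(genes %in% reactive, cfg$snpShift, 1)
  properties <- data.frame(
    gene_id = genes,
    tr_flag = unname(trFlag),
    snp_gene_count = rpois(cfg$nGenes, snpRate * span),
    snp_exon_count = rpois(cfg$nGenes, 0.5 * snpRate * exonLen),
    gene_span_length = span,
    exon_total_length = exonLen,
    evo_rate_all = exp(rnorm(cfg$nGenes, ifelse(genes %in% reactive,
                                                cfg$evoShift, 0), 0.5)),
    evo_rate_metazoa = exp(rnorm(cfg$nGenes, ifelse(genes %in% reactive,
                                                    cfg$evoShift, 0), 0.5)),
    stringsAsFactors = FALSE)

  ## ---- DE lists + ortholog map ----------------------------------------
  mappable <- genes[runif(cfg$nGenes) < 0.9]
  orthologMap <- data.frame(from = mappable, to = paste0("m", mappable))
  trReactive <- intersect(reactive, genes[trFlag == "TR"])
  inList <- union(intersect(trReactive, mappable)[
    runif(length(intersect(trReactive, mappable))) < 0.6],
    mappable[runif(length(mappable)) < 0.05])
  deLists <- list(mtec_mature_up = paste0("m", inList))

  truth <- list(
    baseSets = baseSets, sampleSets = sampleSets,
    reactiveGenes = reactive, sharedAntigens = shared,
    arrayEffects = a, contamination = contam,
    acquisitions = acquisitions, gaps = gaps,
    deltaLog2 = deltaLog2, trFlag = trFlag,
    plantedAutoantigens = {
      rep1 <- meta$sample_id[meta$group == "patient" &
                               !grepl("_t2$", meta$sample_id)]
      counts <- table(unlist(lapply(rep1, function(s) sampleSets[[s]])))
      names(counts)[counts >= 3]
    })
  list(scans = scans, meta = meta, categories = cats,
       properties = properties, deLists = deLists,
       orthologMap = orthologMap, truth = truth, config = cfg)
}

#' Build a ready-made simulated fixture
#'
#' \code{"tiny"} (6 samples x 40 genes, sub-second) serves unit tests;
#' \code{"default"} (50 patients + 20 healthy samples x 1000 genes) is the
#' scale used for end-to-end verification.
#'
#' @param size \code{"tiny"} or \code{"default"}.
#' @param seed RNG seed.
#' @param dir Optional directory: when given, scans are written as GPR
#'   files and tables as TSV/JSON via \code{\link{writeFixture}}.
#' @return The \code{\link{simulateExperiment}} result list.
#' @export
makeFixture <- function(size = c("tiny", "default"), seed = 1L, dir = NULL) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = simConfig(nPatients = 3L, nControls = 2L, nRelatives = 1L,
                     nGenes = 40L, nControlLevels = 4L, nShared = 3L,
                     sharedPrevalence = c(0.5, 0.9), privateRate = 2,
                     nContaminated = 1L, nMultiPatients = 0L,
                     nManifestations = 4L, seed = seed),
    default = simConfig(seed = seed))
  sim <- simulateExperiment(cfg)
  if (!is.null(dir)) writeFixture(sim, dir)
  sim
}

#' Write a simulated experiment to disk
#'
#' Emits the same formats \code{\link{readScans}} and the table readers
#' consume: one GPR file per sample under \code{scans/}, \code{meta.tsv},
#' \code{categories.tsv}, \code{properties.tsv}, \code{ortholog_map.tsv},
#' one \code{de_<name>.txt} per DE list, and \code{ground_truth.json}.
#'
#' @param sim Result of \code{\link{simulateExperiment}}.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeFixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeScans(sim$scans, file.path(dir, "scans"))
  writeSampleMeta(sim$meta, file.path(dir, "meta.tsv"))
  write.table(sim$categories, file.path(dir, "categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$properties, file.path(dir, "properties.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$orthologMap, file.path(dir, "ortholog_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$deLists))
    writeLines(sim$deLists[[nm]], file.path(dir, paste0("de_", nm, ".txt")))
  truth <- sim$truth
  truth$contamination <- if (is.null(truth$contamination)) list() else
    truth$contamination
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
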
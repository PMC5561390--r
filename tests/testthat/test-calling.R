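zFixture <- function() {
  # 4 patients (one with two samples), 3 controls
  meta <- makeMeta(c("p1_t1", "p1_t2", "p2_t1", "p3_t1", "p4_t1"),
                   c("c1", "c2", "c3"),
                   ages = c(20, 30, 25, 40, 35, 50, 50, 50))
  x <- matrix(0, 3, 8,
              dimnames = list(c("g1", "g2", "g3"), meta$sample_id))
  x["g1", ] <- c(10, 10, 10, 10, 0, 1, 2, 3)  # controls {1,2,3}
  x["g2", ] <- c(9, 9, 0, 0, 0, 1, 2, 3)
  x["g3", ] <- c(2, 2, 2, 2, 2, 2, 2, 2)      # constant in controls
  list(se = makeSe(x, meta = meta), meta = meta)
}

test_that("z-scores are standardized on the control cohort", {
  f <- zFixture()
  expect_warning(zscoreMatrix(f$se), "constant across controls")
  z <- suppressWarnings(zscoreMatrix(f$se))
  zm <- assay(z, "exprs")
  expect_false("g3" %in% rownames(zm))  # degenerate gene dropped
  # control values {1,2,3}: mean 2, sample SD 1; a value of 4 gives z = 2
  expect_equal(unname(zm["g1", "c2"]), 0)  # own value at control mean
  expect_equal(unname((10 - 2) / 1), unname(zm["g1", "p1_t1"]))
  expect_equal(unname(zm["g1", "c3"]), 1)

  few <- makeMeta("p1_t1", "c1")
  xs <- matrix(rnorm(4), 2, 2,
               dimnames = list(c("g1", "g2"), few$sample_id))
  expect_error(zscoreMatrix(makeSe(xs, meta = few)), ">= 2 control")
})

test_that("z-scoring is invariant to per-gene additive shifts", {
  f <- zFixture()
  z1 <- suppressWarnings(zscoreMatrix(f$se))
  shifted <- assay(f$se, "exprs")
  shifted["g1", ] <- shifted["g1", ] + 7
  z2 <- suppressWarnings(zscoreMatrix(makeSe(shifted, meta = f$meta)))
  expect_equal(assay(z1, "exprs"), assay(z2, "exprs"))
})

test_that("autoantigen calling applies the patient-count rule strictly", {
  meta <- makeMeta(paste0("p", 1:4, "_t1"), c("c1", "c2"))
  z <- matrix(0, 3, 6,
              dimnames = list(c("gA", "gB", "gC"), meta$sample_id))
  z["gA", 1:3] <- 5    # three positive patients -> autoantigen
  z["gB", 1:2] <- 5    # two -> not
  z["gC", 1:3] <- 3    # exactly at threshold -> strict > excludes
  se <- makeSe(z, stage = "zscore", meta = meta)
  cs <- callAutoantigens(se)
  expect_identical(autoantigens(cs), "gA")
  expect_equal(unname(callMatrix(cs)["gC", ]), rep(0, 4))
  # monotone: raising the threshold never adds autoantigens
  for (thr in c(1, 2, 4, 5.01)) {
    lower <- autoantigens(callAutoantigens(se, zThreshold = thr))
    expect_true(all(autoantigens(callAutoantigens(
      se, zThreshold = thr + 1)) %in% lower))
  }
})

test_that("the representative sample carries the maximal hit count", {
  meta <- makeMeta(c("p1_t1", "p1_t2", "p2_t1", "p3_t1"), c("c1", "c2"),
                   ages = c(10, 20, 30, 30, 50, 50))
  z <- matrix(0, 10, 6,
              dimnames = list(paste0("g", 1:10), meta$sample_id))
  z[1:5, "p1_t1"] <- 9   # 5 hits
  z[1:9, "p1_t2"] <- 9   # 9 hits -> representative
  z[1, c("p2_t1", "p3_t1")] <- 9
  se <- makeSe(z, stage = "zscore", meta = meta)
  cs <- callAutoantigens(se)
  expect_identical(unname(representativeSamples(cs)["p1"]), "p1_t2")
  # g1 is positive in p1 (via its representative), p2 and p3
  expect_identical(autoantigens(cs), "g1")
  latest <- callAutoantigens(se, oneSamplePerPatient = "latest")
  expect_identical(unname(representativeSamples(latest)["p1"]), "p1_t2")
})

test_that("hit counts match planted repertoires", {
  meta <- makeMeta(c("p1_t1", "p2_t1"), c("c1", "c2"))
  z <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), meta$sample_id))
  z[1:3, "p1_t1"] <- 5
  se <- makeSe(z, stage = "zscore", meta = meta)
  hits <- hitCounts(callAutoantigens(se, minPatients = 1L))
  expect_equal(hits$n_hits[hits$sample_id == "p1_t1"], 3)
  expect_equal(hits$n_hits[hits$sample_id == "p2_t1"], 0)
  expect_equal(hits$log2_hits, log2(hits$n_hits + 1))
})

test_that("planted autoantigens are recovered from simulated scans", {
  cfg <- simConfig(nPatients = 30L, nControls = 12L, nRelatives = 8L,
                   nGenes = 300L, nControlLevels = 5L, nShared = 8L,
                   sharedPrevalence = c(0.3, 0.5), privateRate = 2,
                   nContaminated = 0L, nMultiPatients = 0L, seed = 71L)
  sim <- simulateExperiment(cfg)
  raw <- attachSampleMeta(summarizeProbes(sim$scans), sim$meta)
  norm <- applyNormalization(raw, fitControlModel(raw))
  z <- suppressWarnings(zscoreMatrix(norm))
  cs <- callAutoantigens(z)
  # genes planted in >= 4 patients sit clear of the calling boundary
  repSets <- sim$truth$sampleSets[representativeSamples(cs)]
  perGene <- table(unlist(repSets))
  deep <- names(perGene)[perGene >= 4]
  expect_gte(mean(deep %in% autoantigens(cs)), 0.9)
  # per-sample counts over planted genes track the repertoires within
  # per-cell calling noise
  planted <- names(perGene)
  truthN <- vapply(colnames(callMatrix(cs)),
                   function(s) length(sim$truth$sampleSets[[s]]), 1L)
  plantedHits <- colSums(callMatrix(cs)[planted, , drop = FALSE])
  expect_gt(cor(plantedHits, truthN), 0.8)
  expect_lt(mean(abs(plantedHits - truthN)), 2)
})
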
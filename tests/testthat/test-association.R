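test_that("moderated t reduces to the classical t when the prior df is 0", {
  set.seed(31)
  x <- matrix(rnorm(20 * 12, 8), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  grp <- rep(c(FALSE, TRUE), each = 6)
  res <- moderatedT(x, grp, priorDf = 0)
  for (g in rownames(x)) {
    tt <- t.test(x[g, grp], x[g, !grp], var.equal = TRUE)
    expect_equal(res$t_mod[res$gene_id == g], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$p[res$gene_id == g], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(unique(res$df_total), 10)
})

test_that("infinite prior df pools variances completely", {
  set.seed(32)
  x <- matrix(rnorm(50 * 10, 8), 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  grp <- rep(c(FALSE, TRUE), each = 5)
  res <- moderatedT(x, grp, priorDf = Inf)
  # pooled-variance oracle computed directly
  m1 <- rowMeans(x[, !grp]); m2 <- rowMeans(x[, grp])
  s2 <- (rowSums((x[, !grp] - m1)^2) + rowSums((x[, grp] - m2)^2)) / 8
  tPool <- (m2 - m1) / sqrt(mean(s2) * (1 / 5 + 1 / 5))
  expect_equal(res$t_mod, unname(tPool), tolerance = 1e-10)
})

test_that("estimated hyperparameters match the independent limma fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  ng <- 200L
  x <- matrix(rnorm(ng * 16, sd = rep(sqrt(1 / rgamma(ng, 4, 4)), 16)),
              ng, 16, dimnames = list(paste0("g", seq_len(ng)),
                                      paste0("s", 1:16)))
  x <- x + 8
  grp <- rep(c(FALSE, TRUE), each = 8)
  x[, grp] <- x[, grp] + rep(rnorm(ng, 0, 0.3), sum(grp))
  res <- moderatedT(x, grp)
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, grp)))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up formula and is monotone", {
  set.seed(34)
  x <- matrix(rnorm(30 * 10, 8), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  res <- moderatedT(x, rep(c(FALSE, TRUE), each = 5))
  p <- res$p
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  expected <- pmin(1, cummin(m / (m:1) * p[o]))[order(o)]  # hand step-up
  expect_equal(res$p_adj, expected)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-12))
})

test_that("antigen correlations have unit diagonal and find latent factors", {
  set.seed(35)
  n <- 40L
  meta <- makeMeta(paste0("p", seq_len(n), "_t1"), c("c1", "c2"))
  f <- rnorm(n, 0, 3)
  z <- rbind(A = c(f + rnorm(n, 0, 0.1), 0, 0),
             B = c(f + rnorm(n, 0, 0.1), 0, 0),
             C = c(rnorm(n, 0, 3), 0, 0))
  colnames(z) <- meta$sample_id
  se <- makeSe(z, stage = "zscore", meta = meta)
  r <- antigenCorrelations(se, c("A", "B", "C"))
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))
  expect_gt(r["A", "B"], 0.99)
  expect_lt(abs(r["A", "C"]), 0.5)
  expect_equal(r, t(r))
  expect_error(antigenCorrelations(se, c("A", "nope")), "nope")
})

test_that("patient samples show larger within-sample dispersion", {
  set.seed(36)
  meta <- makeMeta(paste0("p", 1:15, "_t1"), paste0("c", 1:10))
  x <- matrix(rnorm(200 * 25, 8, 0.5), 200, 25,
              dimnames = list(paste0("g", 1:200), meta$sample_id))
  # plant extra reactivities in patients only
  for (j in 1:15) x[sample(200, 10), j] <- x[sample(200, 10), j] + 3
  se <- makeSe(x, meta = meta)
  vc <- varianceContrast(se, alternative = "greater")
  expect_lt(vc$p, 0.05)
  expect_gt(mean(vc$sampleSd$sd[vc$sampleSd$group == "patient"]),
            mean(vc$sampleSd$sd[vc$sampleSd$group == "control"]))

  one <- makeMeta("p1_t1", "c1")
  xs <- matrix(rnorm(20, 8), 10, 2,
               dimnames = list(paste0("g", 1:10), one$sample_id))
  expect_error(varianceContrast(makeSe(xs, meta = one)), ">= 2 samples")
})

test_that("PCA explained-variance ratios are proper and find rank-1 structure", {
  set.seed(37)
  meta <- makeMeta(paste0("p", 1:12, "_t1"), c("c1", "c2"))
  gene <- abs(rnorm(20, 4, 1))
  sampleLoad <- c(rnorm(12, 4, 2), 0, 0)
  z <- outer(gene, sampleLoad) + matrix(rnorm(20 * 14, 0, 0.01), 20, 14)
  dimnames(z) <- list(paste0("g", 1:20), meta$sample_id)
  se <- makeSe(z, stage = "zscore", meta = meta)
  pc <- repertoirePCA(se, topK = 10L)
  expect_lte(sum(pc$explained), 1 + 1e-12)
  expect_true(all(pc$explained >= 0))
  expect_identical(rownames(pc$scores), meta$sample_id)
  # planted rank-1 structure dominates the first component
  expect_gt(pc$explained[1L], 0.95)
})

test_that("clustering is deterministic and merges duplicates first", {
  set.seed(38)
  meta <- makeMeta(paste0("p", 1:6, "_t1"), c("c1", "c2"))
  z <- matrix(rnorm(12 * 8, 0, 2), 12, 8,
              dimnames = list(paste0("g", 1:12), meta$sample_id))
  z[, "p2_t1"] <- z[, "p1_t1"]  # exact duplicate samples
  z[1:6, 1:3] <- z[1:6, 1:3] + 6
  se <- makeSe(z, stage = "zscore", meta = meta)
  cl <- clusterRepertoire(se, topK = 12L)
  first <- cl$colClust$merge[1L, ]
  expect_setequal(cl$colClust$labels[-first],
                  c("p1_t1", "p2_t1"))
  # permuting input order leaves merge heights unchanged
  perm <- se[sample(nrow(se)), sample(ncol(se))]
  cl2 <- clusterRepertoire(perm, topK = 12L)
  expect_equal(sort(cl2$colClust$height), sort(cl$colClust$height))
  # excluded genes never enter the clustered matrix
  cl3 <- clusterRepertoire(se, topK = 12L, exclude = c("g1", "g2"))
  expect_false(any(c("g1", "g2") %in% rownames(cl3$matrix)))
})

test_that("manifestation regression recovers exact linear relations", {
  meta <- makeMeta(paste0("p", 1:6, "_t1"), "c1")
  meta$manifestations <- c(lapply(2 * log2(c(1, 3, 7, 15, 31, 63) + 1),
                                  function(k) paste0("m", seq_len(k))),
                           list(character(0)))
  hits <- data.frame(sample_id = paste0("p", 1:6, "_t1"),
                     n_hits = c(1, 3, 7, 15, 31, 63),
                     log2_hits = log2(c(1, 3, 7, 15, 31, 63) + 1))
  fit <- manifestationRegression(hits, meta)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_false(fit$degenerate)

  meta$manifestations <- rep(list(c("m1", "m2")), 7)
  flat <- manifestationRegression(hits, meta)
  expect_true(flat$degenerate)
  expect_equal(flat$r, 0)
  expect_equal(flat$slope, 0)
})

test_that("Nemenyi pairwise rank test behaves at the extremes", {
  meta <- makeMeta(paste0("p", 1:30, "_t1"), "c1")
  meta$mutation_group <- c(rep(1:3, each = 10), NA)
  # identical groups: all pairwise p near 1
  hitsEq <- data.frame(sample_id = paste0("p", 1:30, "_t1"),
                       n_hits = rep(c(4, 5, 6, 8, 10, 12, 16, 20, 30, 40), 3))
  hitsEq$log2_hits <- log2(hitsEq$n_hits + 1)
  resEq <- mutationGroupTest(hitsEq, meta)
  expect_true(all(resEq$p > 0.95))

  # two groups fully separated in rank
  hitsSep <- hitsEq
  hitsSep$n_hits <- c(1:10, 101:110, 11:20)
  hitsSep$log2_hits <- log2(hitsSep$n_hits + 1)
  resSep <- mutationGroupTest(hitsSep, meta)
  expect_lt(resSep$p[resSep$group1 == 1 & resSep$group2 == 2], 0.01)

  # permutation oracle for the separated pair: the observed mean-rank gap
  # should be extreme under random relabelling
  set.seed(39)
  y <- hitsSep$log2_hits[1:30]
  g <- rep(1:3, each = 10)
  obs <- abs(mean(rank(y)[g == 1]) - mean(rank(y)[g == 2]))
  perm <- replicate(2000, {
    gp <- sample(g)
    abs(mean(rank(y)[gp == 1]) - mean(rank(y)[gp == 2]))
  })
  expect_lt((sum(perm >= obs) + 1) / 2001, 0.01)

  # midranks: doubling every observation leaves ranks and p unchanged
  hitsDup <- hitsSep
  hitsDup$log2_hits <- 2 * hitsSep$log2_hits
  expect_equal(mutationGroupTest(hitsDup, meta)$p, resSep$p)

  # a group with n < 2 is excluded with a warning
  meta2 <- meta
  meta2$mutation_group[meta2$mutation_group == 3] <- NA
  meta2$mutation_group[1L] <- 3
  expect_warning(res2 <- mutationGroupTest(hitsSep, meta2), "n < 2")
  expect_false(any(res2$group1 == 3 | res2$group2 == 3))
})

test_that("type-I error of the moderated t is calibrated under the null", {
  set.seed(40)
  ng <- 1000L
  x <- matrix(rnorm(ng * 20, 8), ng, 20,
              dimnames = list(paste0("g", seq_len(ng)), paste0("s", 1:20)))
  res <- moderatedT(x, rep(c(FALSE, TRUE), each = 10))
  frac <- mean(res$p < 0.05)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / ng)
  expect_lt(abs(frac - 0.05), ci + 0.01)
})
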
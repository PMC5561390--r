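test_that("hypergeometric enrichment matches worked and boundary cases", {
  universe <- paste0("g", 1:10)
  cats <- data.frame(gene_id = paste0("g", 1:4), namespace = "ns",
                     term = "T")
  res <- hypergeomEnrich(paste0("g", c(1:3, 5, 10)), cats, universe)
  # N=10, K=4, n=5, k=3 -> 66/252, verified by exhaustive enumeration
  expect_equal(res$p_hyper, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_hyper, enumHyperP(10, 4, 5, 3), tolerance = 1e-12)
  expect_equal(res[, c("N", "K", "n", "k")],
               data.frame(N = 10L, K = 4L, n = 5L, k = 3L),
               ignore_attr = TRUE)

  # zero overlap -> upper-tail p = 1; full overlap -> p = 1
  res0 <- hypergeomEnrich(paste0("g", 5:9), data.frame(
    gene_id = paste0("g", 1:4), namespace = "ns", term = "T"), universe)
  expect_equal(res0$p_hyper, 1)
  resAll <- hypergeomEnrich(universe, data.frame(
    gene_id = universe, namespace = "ns", term = "T"), universe)
  expect_equal(resAll$p_hyper, 1)

  expect_error(hypergeomEnrich(character(0), cats, universe), "empty")
  expect_error(hypergeomEnrich("zz", cats, universe), "outside")
  # term with no universe member is skipped
  cats2 <- rbind(cats, data.frame(gene_id = "zz", namespace = "ns",
                                  term = "ghost"))
  expect_false("ghost" %in% hypergeomEnrich(paste0("g", 1:5), cats2,
                                            universe)$term)
})

test_that("hypergeometric p equals enumeration across many small cases", {
  set.seed(51)
  for (i in 1:25) {
    N <- sample(4:9, 1L)
    K <- sample(seq_len(N - 1L), 1L)
    n <- sample(seq_len(N - 1L), 1L)
    kMin <- max(0L, n - (N - K))  # a query needs n - k non-members
    k <- sample(kMin:min(K, n), 1L)
    universe <- paste0("g", seq_len(N))
    cats <- data.frame(gene_id = paste0("g", seq_len(K)),
                       namespace = "ns", term = "T")
    query <- c(if (k > 0) paste0("g", seq_len(k)),
               if (n > k) paste0("g", K + seq_len(n - k)))
    res <- hypergeomEnrich(query, cats, universe)
    expect_equal(res$p_hyper, enumHyperP(N, K, n, k), tolerance = 1e-12,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("resampling null honours direction, ties and the +1 correction", {
  universe <- paste0("g", 1:200)
  flat <- setNames(rep(2.5, 200), universe)
  res <- resamplingNull(paste0("g", 1:20), flat, universe, R = 200,
                        direction = "less", seed = 1)
  expect_equal(res$p_emp, 1)  # all ties count as as-extreme

  prop <- setNames(seq_len(200), universe)
  best <- resamplingNull(paste0("g", 1:20), prop, universe, R = 500,
                         direction = "less", seed = 2)
  expect_equal(best$p_emp, 1 / 501)  # minimal attainable p
  worst <- resamplingNull(paste0("g", 181:200), prop, universe, R = 500,
                          direction = "greater", seed = 3)
  expect_equal(worst$p_emp, 1 / 501)

  expect_warning(resamplingNull(paste0("g", 1:5), prop, universe, R = 50,
                                seed = 4), "unstable")
  expect_error(resamplingNull("zz", prop, universe), "no query gene")
})

test_that("a planted one-SD shift is detected and matches the normal oracle", {
  set.seed(52)
  N <- 5000L; n <- 100L
  universe <- paste0("g", seq_len(N))
  prop <- setNames(rnorm(N, 10, 2), universe)
  query <- sample(universe[prop < 10 - 2], n)  # drawn from the low tail
  res <- resamplingNull(query, prop, universe, R = 2000,
                        direction = "less", seed = 5)
  expect_lt(res$p_emp, 0.01)
  # normal approximation for the mean of a without-replacement sample
  fpc <- sqrt((N - n) / (N - 1))
  zStat <- (res$observed_mean - mean(prop)) / (sd(prop) / sqrt(n) * fpc)
  expect_lt(pnorm(zStat), 1e-6)
})

test_that("empirical p is super-uniform under its own null", {
  set.seed(53)
  N <- 300L; n <- 25L; R <- 60L
  universe <- paste0("g", seq_len(N))
  prop <- setNames(rexp(N), universe)
  pvals <- replicate(150, {
    q <- sample(universe, n)  # query drawn by the null mechanism itself
    suppressWarnings(
      resamplingNull(q, prop, universe, R = R, direction = "less")$p_emp)
  })
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha),
               alpha + 1 / (R + 1) + 3 * sqrt(alpha * (1 - alpha) / 150))
})

test_that("SNP densities normalize by the correct lengths", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    snp_gene_count = c(100L, 0L, 5L),
                    snp_exon_count = c(10L, 0L, 1L),
                    gene_span_length = c(10000L, 5000L, NA),
                    exon_total_length = c(1000L, 500L, 200L))
  suppressMessages(d <- snpDensity(tab))
  expect_equal(d$d_gene[d$gene_id == "a"], 0.01)
  expect_equal(d$d_exon[d$gene_id == "a"], 0.01)
  expect_equal(d$d_gene[d$gene_id == "b"], 0)
  expect_false("c" %in% d$gene_id)        # missing length -> excluded
  expect_identical(attr(d, "excluded"), "c")
})

test_that("TR/NTR split partitions the input exactly", {
  props <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f"),
                      tr_flag = c("TR", "TR", "TR", "NTR", "NTR",
                                  "unknown"))
  sp <- splitTrNtr(c("a", "b", "c", "d", "e", "f", "zz"), props)
  expect_identical(sp$TR, c("a", "b", "c"))
  expect_identical(sp$NTR, c("d", "e"))
  expect_setequal(sp$excluded, c("f", "zz"))
  expect_setequal(unlist(sp), c("a", "b", "c", "d", "e", "f", "zz"))
  allTr <- splitTrNtr(c("a", "b"), props)
  expect_length(allTr$NTR, 0)
})

test_that("list overlap reproduces the enumerated worked example", {
  universe <- paste0("h", 1:20)
  map <- data.frame(from = universe, to = paste0("m", 1:20))
  deList <- paste0("m", 1:6)                      # K = 6
  query <- paste0("h", c(1:4, 10))                # n = 5, k = 4
  res <- listOverlap(query, deList, universe, map)
  expect_equal(res$p_hyper, 216 / 15504, tolerance = 1e-12)
  expect_equal(res$p_hyper, enumHyperP(20, 6, 5, 4), tolerance = 1e-12)

  # disjoint sets give the trivial upper-tail p of 1
  none <- listOverlap(paste0("h", 10:14), paste0("m", 1:5), universe, map)
  expect_equal(none$p_hyper, 1)

  # one-to-many mappings collapse before counting
  map2 <- rbind(map, data.frame(from = "h1", to = "m2"))
  res2 <- listOverlap(paste0("h", 1:2), paste0("m", 1:2), universe, map2)
  expect_equal(res2$k, 2L)
  expect_equal(res2$n, 2L)
})
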
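test_that("log2 transform tracks state and guards its domain", {
  m <- matrix(c(8, 1, 2, 4), 2, 2)
  lt <- log2_transform(m)
  expect_equal(lt[1, 1], 3)
  expect_equal(lt[2, 1], 0)
  expect_equal(attr(lt, "scale"), "log2")
  expect_error(log2_transform(lt), "already")
  expect_error(log2_transform(matrix(c(-1, 2), 1, 2)), "floor")
  floored <- log2_transform(matrix(c(0.001, 2), 1, 2), floor = 1)
  expect_equal(floored[1, 1], 0)
})

test_that("quantile normalization maps columns to the mean quantile vector", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(unname(quantile_normalize(same)), unname(same),
               ignore_attr = TRUE)

  set.seed(3)
  r <- matrix(rnorm(200), 40, 5)
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1])
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "2 samples")
})

test_that("differential-expression calls follow the ratio-and-test rule", {
  de_eff <- data.frame(gene = c(1L, 2L), contrast = "cold",
                       log2_shift = c(0.6, 0.4))
  sim <- generate_expression(expression_sim_spec(
    40, de_effects = de_eff, treatments = c("cold", "salt"), n_reps = 10,
    noise_sd = 0.05, seed = 14))
  de <- de_classify(sim$matrix, sim$design)
  cold <- de[de$contrast == "cold", ]
  expect_equal(cold$call[cold$gene == "GENE0001"], "up")
  # a +0.4 shift never passes the 0.5 ratio gate, whatever its p-value
  expect_equal(cold$call[cold$gene == "GENE0002"], "unchanged")
  expect_lt(cold$q[cold$gene == "GENE0002"], 0.05)
  # unshifted genes stay unchanged in both contrasts
  null_calls <- de$call[!(de$gene %in% c("GENE0001", "GENE0002") &
                            de$contrast == "cold")]
  expect_true(all(null_calls == "unchanged"))
})

test_that("bonferroni adjustment is at least as conservative as BH", {
  de_eff <- data.frame(gene = 1L, contrast = "cold", log2_shift = 0.8)
  sim <- generate_expression(expression_sim_spec(
    30, de_effects = de_eff, treatments = "cold", n_reps = 5, seed = 15))
  bh <- de_classify(sim$matrix, sim$design, method = "BH")
  bf <- de_classify(sim$matrix, sim$design, method = "bonferroni")
  expect_true(all(bf$q >= bh$q - 1e-12))
})

test_that("pearson correlation handles canonical and degenerate inputs", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("pair correlations recover planted targets", {
  targets <- data.frame(gene_i = c(1L, 3L, 5L), gene_j = c(2L, 4L, 6L),
                        target_r = c(0.8, -0.5, 1))
  sim <- generate_expression(expression_sim_spec(
    8, n_samples = 2000, pair_targets = targets, seed = 3))
  pairs <- data.frame(gene_a = c("GENE0001", "GENE0003", "GENE0005"),
                      gene_b = c("GENE0002", "GENE0004", "GENE0006"),
                      stringsAsFactors = FALSE)
  res <- pair_correlations(sim$matrix, pairs = pairs)
  expect_equal(res$n_points, rep(2000L, 3))
  expect_lt(abs(res$r[1] - 0.8), 0.05)
  expect_lt(abs(res$r[2] + 0.5), 0.05)
  expect_equal(res$r[3], 1) # rho = 1 is exact, no independent noise
  expect_true(all(abs(res$r) <= 1))
  expect_error(
    pair_correlations(sim$matrix,
                      pairs = data.frame(gene_a = "nope", gene_b = "GENE0001")),
    "absent")
})

test_that("pair correlations of identical profiles equal one", {
  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  m2 <- m
  rownames(m2) <- c("h1", "h2", "h3")
  res <- pair_correlations(m, m2, pairs = data.frame(gene_a = "g1",
                                                     gene_b = "h1"))
  expect_equal(res$r, 1)
})

test_that("hierarchical clustering matches a brute-force linkage oracle", {
  set.seed(8)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  hc <- hierarchical_cluster(m)
  d <- as.matrix(1 - cor(t(m)))
  coph_naive <- naive_average_cophenetic(d)
  coph_pkg <- as.matrix(stats::cophenetic(hc$hclust))
  ord <- rownames(coph_naive)
  expect_equal(coph_pkg[ord, ord], coph_naive, tolerance = 1e-9)
})

test_that("identical profiles merge first and linkage choice matters", {
  base <- rnorm(8)
  m <- rbind(g1 = base, g2 = base, g3 = -base + rnorm(8, 0, 0.01))
  colnames(m) <- paste0("s", 1:8)
  hc <- hierarchical_cluster(m)
  first <- hc$hclust$merge[1, ]
  expect_setequal(hc$hclust$labels[-first], c("g1", "g2"))

  # constructed counterexample where single and average linkage disagree
  # single linkage chains x3 onto (x1,x2); average linkage pairs (x3,x4)
  dmat <- matrix(c(0, 1, 6, 6.5,
                   1, 0, 2.5, 6,
                   6, 2.5, 0, 3,
                   6.5, 6, 3, 0), 4, 4,
                 dimnames = list(paste0("x", 1:4), paste0("x", 1:4)))
  avg <- stats::hclust(stats::as.dist(dmat), method = "average")
  sing <- stats::hclust(stats::as.dist(dmat), method = "single")
  expect_false(identical(avg$merge, sing$merge))
})

test_that("constant-profile genes are excluded from correlation clustering", {
  m <- rbind(g1 = rnorm(6), g2 = rnorm(6), flat = rep(2, 6))
  colnames(m) <- paste0("s", 1:6)
  expect_warning(hc <- hierarchical_cluster(m), "constant")
  expect_equal(hc$excluded, "flat")
  expect_setequal(hc$order, c("g1", "g2"))
})

test_that("clustering is invariant to gene input order", {
  set.seed(9)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  h1 <- hierarchical_cluster(m)
  h2 <- hierarchical_cluster(m[c(3, 1, 5, 2, 4), ])
  c1 <- as.matrix(stats::cophenetic(h1$hclust))
  c2 <- as.matrix(stats::cophenetic(h2$hclust))
  ord <- rownames(c1)
  expect_equal(c1, c2[ord, ord], tolerance = 1e-12)
})
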
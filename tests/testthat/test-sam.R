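null_matrix <- function(n_genes, seed, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * 6, sd = sd), n_genes, 6,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         c(paste0("c", 1:3), paste0("t", 1:3))))
}
classes33 <- factor(rep(c("control", "treated"), each = 3),
                    levels = c("control", "treated"))

test_that("probe aggregation: identity, mean of two, median of three or more", {
  expect_equal(aggregate_probes(7), 7)
  expect_equal(aggregate_probes(c(2, 4)), 3)
  expect_equal(aggregate_probes(c(1, 2, 9)), 2)
  expect_equal(aggregate_probes(c(1, 2, 9, 100)), 5.5)
  expect_error(aggregate_probes(numeric()), "no probe")
  m <- rbind(p1 = c(2, 10), p2 = c(4, 20), p3 = c(7, 7))
  agg <- aggregate_probes_matrix(m, c("gA", "gA", "gB"))
  expect_equal(agg["gA", ], c(3, 15))
  expect_equal(agg["gB", ], c(7, 7))
})

test_that("log2 normalization transforms and median-centers each sample", {
  m <- matrix(c(8, 2, 4, 16), 2)
  l2 <- log2_normalize(m)
  expect_equal(attr(l2, "log2_transformed"), TRUE)
  expect_equal(apply(l2, 2, median), c(0, 0))
  # log2(8) = 3 before centering
  expect_equal(log2(m)[1, 1], 3)
  const <- matrix(5, 3, 4)
  expect_true(all(log2_normalize(const) == 0))
  expect_error(log2_normalize(matrix(c(-1, 2, 3, 4), 2)), "non-positive")
})

test_that("d-statistic sign matches the mean difference; null genes uncalled", {
  x <- null_matrix(200, seed = 3)
  x["g0001", 4:6] <- x["g0001", 4:6] + 5
  x["g0002", 4:6] <- x["g0002", 4:6] - 5
  res <- sam_two_class(x, classes33, n_permutations = 20, seed = 1)
  g <- res$genes
  md <- rowMeans(x[, 4:6]) - rowMeans(x[, 1:3])
  expect_true(all(sign(g$d) == sign(md[g$gene])))
  expect_equal(g$call[g$gene == "g0001"], "up")
  expect_equal(g$call[g$gene == "g0002"], "down")
  # a gene with identical group means has d = 0 and no call
  y <- x
  y["g0003", ] <- rep(c(1, 2, 3), 2)
  res2 <- sam_two_class(y, classes33, n_permutations = 20, seed = 1, s0 = 0.1)
  expect_equal(res2$genes$d[res2$genes$gene == "g0003"], 0)
  expect_equal(res2$genes$call[res2$genes$gene == "g0003"], "none")
})

test_that("permutation null is seed-deterministic and exhaustive at 3v3", {
  x <- null_matrix(100, seed = 5)
  r1 <- sam_two_class(x, classes33, n_permutations = 20, seed = 7)
  r2 <- sam_two_class(x, classes33, n_permutations = 20, seed = 7)
  expect_identical(r1$genes, r2$genes)
  expect_true(r1$tuning$exhaustive)
  expect_equal(r1$tuning$n_permutations, 20)
  expect_warning(sam_two_class(x, classes33, n_permutations = 1000, seed = 1),
                 "exhaustive")
})

test_that("calls follow the |d - dbar| > delta rule and delta is monotone", {
  x <- null_matrix(300, seed = 11)
  x[1:10, 4:6] <- x[1:10, 4:6] + 3
  res <- sam_two_class(x, classes33, n_permutations = 20, seed = 1)
  g <- res$genes
  expect_setequal(g$gene[g$call != "none"],
                  g$gene[abs(g$d - g$dbar) > res$tuning$delta])
  # increasing delta never increases the number of calls
  n_calls <- vapply(c(0.5, 1, 2, 4), function(dl) {
    r <- sam_two_class(x, classes33, n_permutations = 20, seed = 1,
                       delta = dl)
    sum(r$genes$call != "none")
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("tuned delta controls the estimated FDR at the ceiling", {
  x <- null_matrix(400, seed = 13)
  x[1:20, 4:6] <- x[1:20, 4:6] + 2
  res <- sam_two_class(x, classes33, n_permutations = 20, seed = 1,
                       fdr_ceiling = 0.05)
  expect_lte(res$tuning$fdr, 0.05)
})

test_that("spiked genes are recovered with the correct sign", {
  set.seed(21)
  n <- 400
  x <- null_matrix(n, seed = 21, sd = 0.25)
  x[] <- x + runif(n, 6, 12)           # baseline expression level
  spike <- sample(n, 30)
  sgn <- sample(c(-1, 1), 30, replace = TRUE)
  x[spike, 4:6] <- x[spike, 4:6] + 2 * sgn
  res <- sam_two_class(x, classes33, n_permutations = 20, seed = 2)
  g <- res$genes
  hit <- (g$call[spike] == "up" & sgn > 0) | (g$call[spike] == "down" & sgn < 0)
  expect_gte(mean(hit), 0.9)
})

test_that("clustering is deterministic, complete-linkage on correlation distance", {
  set.seed(31)
  base1 <- rnorm(6)
  base2 <- rnorm(6)
  x <- rbind(
    a1 = base1 + rnorm(6, sd = 0.05), a2 = base1 + rnorm(6, sd = 0.05),
    b1 = -base1 + rnorm(6, sd = 0.05), b2 = -base1 + rnorm(6, sd = 0.05))
  colnames(x) <- paste0("s", 1:6)
  cl <- cluster_significant(x)
  expect_setequal(cl$gene_order, rownames(x))
  # two anti-correlated blocks split at the top
  top <- cutree(cl$gene_hclust, 2)
  expect_equal(top[["a1"]], top[["a2"]])
  expect_equal(top[["b1"]], top[["b2"]])
  expect_false(top[["a1"]] == top[["b1"]])
  # identical profiles merge first (distance 0)
  y <- rbind(g1 = base1, g2 = base1, g3 = base2)
  cl2 <- cluster_significant(y)
  expect_equal(sort(cl2$gene_hclust$labels[abs(cl2$gene_hclust$merge[1, ])]),
               c("g1", "g2"))
  expect_message(cluster_significant(x[1, , drop = FALSE]), "skipped")
})
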
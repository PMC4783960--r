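test_that("generator validates configuration", {
  expect_error(world_config(n_positive_pairs = 0), "positive")
  expect_error(world_config(n_proteins = 10, n_positive_pairs = 100),
               "distinct pairs")
  bad_truth <- default_truth()
  bad_truth$ddi$pos <- c(0.5, 0.4)
  expect_error(world_config(truth = bad_truth), "configuration error")
})

test_that("pair counts are exact and regeneration is seed-deterministic", {
  cfg <- world_config(n_proteins = 100, n_filler = 260,
                      n_positive_pairs = 200, n_negative_pairs = 300,
                      n_genes = 60, n_spiked = 6, seed = 1)
  w1 <- generate_world(cfg)
  expect_equal(nrow(w1$positive_pairs), 200)
  expect_equal(nrow(unique(w1$positive_pairs)), 200)
  expect_true(all(w1$positive_pairs$a < w1$positive_pairs$b))
  w2 <- generate_world(cfg)
  expect_identical(w1[setdiff(names(w1), "config")],
                   w2[setdiff(names(w2), "config")])
  w3 <- generate_world(world_config(n_proteins = 100, n_filler = 260,
                                    n_positive_pairs = 200,
                                    n_negative_pairs = 300,
                                    n_genes = 60, n_spiked = 6, seed = 2))
  expect_false(identical(w1$positive_pairs, w3$positive_pairs))
})

test_that("all referenced identifiers exist in the world's protein universe", {
  w <- random_small_world(12)
  universe <- w$proteins
  expect_true(all(unlist(w$go) %in% universe))
  expect_true(all(names(w$domain_map) %in% universe))
  expect_true(all(c(w$positive_pairs$a, w$positive_pairs$b,
                    w$negative_pairs$a, w$negative_pairs$b) %in% universe))
  expect_true(all(c(w$membrane_set, w$nuclear_set, w$apoptotic) %in% universe))
  for (sp in names(w$ortholog_maps)) {
    expect_true(all(names(w$ortholog_maps[[sp]]) %in% universe))
  }
})

test_that("realized resources reproduce the sampled evidence bins exactly", {
  for (seed in c(2, 5)) {
    w <- random_small_world(seed)
    prof <- evidence_profiles(rbind(w$positive_pairs, w$negative_pairs),
                              world_resources(w), w$config$binning)
    for (ch in setdiff(names(prof), c("a", "b"))) {
      expect_identical(prof[[ch]], w$evidence[[ch]])
    }
  }
})

test_that("empirical bin frequencies converge to the configured truth", {
  cfg <- world_config(n_proteins = 300, n_filler = 260,
                      n_positive_pairs = 10000, n_negative_pairs = 10000,
                      n_genes = 60, n_spiked = 6, seed = 17)
  w <- generate_world(cfg)
  ev <- w$evidence
  for (ch in c("ssbp", "ddi", "coexpr")) {
    for (cl in c("pos", "neg")) {
      truth <- cfg$truth[[ch]][[cl]]
      x <- ev[[ch]][if (cl == "pos") ev$label else !ev$label]
      emp <- table(factor(x, levels = names(truth))) / length(x)
      expect_true(all(abs(as.numeric(emp) - truth) < 0.02))
    }
  }
  # the small-bin fraction of the positive SSBP channel is within the
  # binomial band around its configured probability
  small_frac <- mean(ev$ssbp[ev$label] == "<=10")
  expect_lt(abs(small_frac - cfg$truth$ssbp$pos[["<=10"]]), 0.02)
})

test_that("spiked genes carry the configured log2 effect; expression is well formed", {
  cfg <- world_config(n_proteins = 100, n_filler = 260,
                      n_positive_pairs = 100, n_negative_pairs = 200,
                      n_genes = 500, n_spiked = 40, effect_size = 2,
                      noise_sd = 0.25, seed = 23)
  w <- generate_world(cfg)
  sp <- w$truth$spiked
  trt <- w$condition == "treated"
  diffs <- rowMeans(w$expression[sp$gene, trt]) -
    rowMeans(w$expression[sp$gene, !trt])
  expect_lt(max(abs(diffs - sp$sign * sp$effect)), 4 * 0.25 * sqrt(2 / 3))
  expect_equal(dim(w$expression), c(500, 6))
  # probe-level view aggregates back to approximately the gene-level matrix
  agg <- aggregate_probes_matrix(w$probe_matrix, w$probe_gene)
  expect_lt(max(abs(agg[rownames(w$expression), ] - w$expression)), 0.3)
})

test_that("planted consensus sets are the exact three-tool intersection", {
  w <- random_small_world(29)
  ct <- mirna_consensus(w$mirna_predictions)
  for (g in names(w$truth$consensus)) {
    expect_equal(consensus_mirnas(ct$consensus[ct$gene == g]),
                 sort(normalize_mirna_ids(w$truth$consensus[[g]])))
  }
})

test_that("a written world round-trips losslessly through the readers", {
  w <- random_small_world(31)
  dir <- withr::local_tempdir()
  manifest <- write_world(w, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  r <- read_world(dir)
  expect_identical(r$evidence$ssbp, w$evidence$ssbp)
  expect_identical(r$evidence$label, w$evidence$label)
  expect_setequal(names(r$go), names(w$go))
  expect_identical(r$go[names(w$go)], w$go)
  expect_identical(r$membrane_set, w$membrane_set)
  for (p in names(w$domain_map)) {
    expect_setequal(r$domain_map[[p]], w$domain_map[[p]])
  }
  expect_equal(r$expression, w$expression, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(rownames(r$expression), rownames(w$expression))
  expect_identical(r$condition, w$condition)
  expect_equal(r$pair_rho$rho, w$pair_rho$rho, tolerance = 1e-8)
  expect_identical(r$mirna_predictions$mirna, w$mirna_predictions$mirna)
  # positives file row counts match the world
  src1 <- names(w$interaction_sources)[1]
  expect_equal(nrow(r$interaction_sources[[src1]]),
               nrow(w$interaction_sources[[src1]]))
  # rewriting the same world gives hash-identical files
  dir2 <- withr::local_tempdir()
  manifest2 <- write_world(w, dir2)
  expect_identical(manifest$md5, manifest2$md5)
})

test_that("cross-channel correlation switch induces dependence, default stays independent", {
  base_cfg <- function(rho, seed) {
    world_config(n_proteins = 300, n_filler = 260,
                 n_positive_pairs = 6000, n_negative_pairs = 1000,
                 n_genes = 50, n_spiked = 5, evidence_correlation = rho,
                 seed = seed)
  }
  assoc <- function(w) {
    ev <- w$evidence[w$evidence$label, ]
    # agreement between two boolean channels among positives
    suppressWarnings(abs(stats::cor(ev$ddi == "true",
                                    ev[["interolog.mmusculus"]] == "true")))
  }
  dep <- assoc(generate_world(base_cfg(0.9, 41)))
  indep <- assoc(generate_world(base_cfg(0, 41)))
  expect_gt(dep, indep + 0.1)
})
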
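make_profiles <- function(ssbp, ddi, coexpr, sp1) {
  data.frame(ssbp = ssbp, ddi = ddi, coexpr = coexpr,
             interolog.sp1 = sp1, stringsAsFactors = FALSE)
}
binning1 <- default_binning(species = "sp1")

test_that("estimate_lrs reproduces frequency-ratio likelihood ratios", {
  # bin A: 40/100 in GSP vs 10/1000 in GSN with no smoothing -> LR = 40
  prof <- data.frame(ddi = c(rep("true", 40), rep("false", 60),
                             rep("true", 10), rep("false", 990)))
  labels <- rep(c(TRUE, FALSE), c(100, 1000))
  lt <- estimate_lrs(prof, labels, binning1, pseudo = 0)
  tab <- lt$channels$ddi
  expect_equal(tab$lr[tab$bin == "true"], 40)
  # identical class frequencies give LR = 1
  prof2 <- data.frame(ddi = rep(c("true", "false"), times = c(30, 70)))
  lt2 <- estimate_lrs(rbind(prof2, prof2), rep(c(TRUE, FALSE), each = 100),
                      binning1, pseudo = 0)
  expect_equal(lt2$channels$ddi$lr, c(1, 1))
  # class-conditional frequencies sum to one per channel
  lt3 <- estimate_lrs(prof, labels, binning1, pseudo = 1)
  expect_equal(sum(lt3$channels$ddi$p_pos), 1, tolerance = 1e-9)
  expect_equal(sum(lt3$channels$ddi$p_neg), 1, tolerance = 1e-9)
  # smoothing keeps every LR finite and positive even for empty bins
  prof_s <- data.frame(ssbp = rep(c("<=10", "11-50"), each = 5))
  lt4 <- estimate_lrs(prof_s, rep(c(TRUE, FALSE), 5), binning1, pseudo = 1)
  expect_length(lt4$channels$ssbp$lr, 5)       # all declared bins present
  expect_true(all(is.finite(lt4$channels$ssbp$lr)) &&
              all(lt4$channels$ssbp$lr > 0))
})

test_that("composite_lr multiplies channel ratios and is order-invariant", {
  prof <- make_profiles("<=10", "true", "[0.8,1]", "true")
  labels_prof <- rbind(
    make_profiles(c("<=10", "11-50"), c("true", "false"),
                  c("[0.8,1]", "[-1,0.2)"), c("true", "false")))
  lt <- estimate_lrs(labels_prof, c(TRUE, FALSE), binning1, pseudo = 1)
  got <- composite_lr(prof, lt)
  by_hand <- prod(vapply(names(lt$channels), function(ch) {
    tab <- lt$channels[[ch]]
    tab$lr[match(prof[[ch]], tab$bin)]
  }, numeric(1)))
  expect_equal(got, by_hand)
  # log-domain equivalence
  logsum <- sum(log(vapply(names(lt$channels), function(ch) {
    tab <- lt$channels[[ch]]
    tab$lr[match(prof[[ch]], tab$bin)]
  }, numeric(1))))
  expect_equal(got, exp(logsum), tolerance = 1e-12)
  # channel order invariance
  lt_rev <- lt
  lt_rev$channels <- rev(lt_rev$channels)
  expect_equal(composite_lr(prof, lt_rev), got)
  # unmapped bin is an error
  bad <- prof
  bad$ssbp <- "no-such-bin"
  expect_error(composite_lr(bad, lt), "unmapped")
})

test_that("monotonicity: improving one channel never lowers the composite LR", {
  w <- random_small_world(3)
  prof <- evidence_profiles(w$positive_pairs, world_resources(w),
                            w$config$binning)
  ev <- w$evidence
  lt <- estimate_lrs(ev, ev$label, w$config$binning)
  base <- composite_lr(prof, lt)
  tab <- lt$channels$ssbp
  best_bin <- tab$bin[which.max(tab$lr)]
  bumped <- prof
  bumped$ssbp <- best_bin
  expect_true(all(composite_lr(bumped, lt) >= base - 1e-12))
})

test_that("predict_network applies >= cutoff semantics and posterior odds", {
  labels_prof <- rbind(
    make_profiles(c("<=10", "11-50"), c("true", "false"),
                  c("[0.8,1]", "[-1,0.2)"), c("true", "false")))
  lt <- estimate_lrs(labels_prof, c(TRUE, FALSE), binning1, pseudo = 1)
  prof <- make_profiles(c("<=10", "absent"), c("true", "false"),
                        c("[0.8,1]", "absent"), c("true", "false"))
  lrs <- composite_lr(prof, lt)
  res <- predict_network(prof, lt, lr_cutoff = lrs[1], prior_odds = 2)
  expect_true(res$passed[1])       # boundary value passes (>= semantics)
  expect_equal(res$posterior_odds, 2 * res$composite_lr)
  res2 <- predict_network(prof, lt, lr_cutoff = lrs[1] + 1e-9)
  expect_false(res2$passed[1])
})

test_that("predicted pass set equals a brute-force filter on a synthetic world", {
  w <- random_small_world(6)
  prof <- evidence_profiles(rbind(w$positive_pairs, w$negative_pairs),
                            world_resources(w), w$config$binning)
  ev <- w$evidence
  lt <- estimate_lrs(ev, ev$label, w$config$binning)
  res <- predict_network(prof, lt, lr_cutoff = 5)
  # brute force: per-pair product of looked-up per-channel ratios
  ref <- vapply(seq_len(nrow(prof)), function(i) {
    prod(vapply(names(lt$channels), function(ch) {
      tab <- lt$channels[[ch]]
      tab$lr[tab$bin == prof[[ch]][i]]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$composite_lr, ref)
  expect_identical(res$passed, ref >= 5)
})

test_that("LR estimation error shrinks with training size (parameter recovery)", {
  err_at <- function(n, seed) {
    cfg <- world_config(n_proteins = 150, n_filler = 260,
                        n_positive_pairs = n, n_negative_pairs = n,
                        n_genes = 50, n_spiked = 5, seed = seed)
    w <- generate_world(cfg)
    lt <- estimate_lrs(w$evidence, w$evidence$label, cfg$binning)
    rel <- unlist(lapply(names(lt$channels), function(ch) {
      truth_lr <- cfg$truth[[ch]]$pos / cfg$truth[[ch]]$neg
      abs(lt$channels[[ch]]$lr - truth_lr) / truth_lr
    }))
    mean(rel)
  }
  seeds <- 1:10
  small <- vapply(seeds, function(s) err_at(300, s), numeric(1))
  large <- vapply(seeds, function(s) err_at(3000, s), numeric(1))
  expect_lt(mean(large), mean(small))
})

test_that("single-channel integration ranks identically to that channel's LR", {
  w <- random_small_world(9)
  ev <- w$evidence
  b1 <- w$config$binning
  lt <- estimate_lrs(ev, ev$label, b1)
  only_ssbp <- lt
  only_ssbp$channels <- lt$channels["ssbp"]
  comp <- composite_lr(ev, only_ssbp)
  tab <- lt$channels$ssbp
  direct <- tab$lr[match(ev$ssbp, tab$bin)]
  expect_identical(order(comp), order(direct))
})
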
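#' Configuration for an end-to-end pipeline run
#'
#' One global seed drives every stage deterministically (per-stage seeds are
#' derived by fixed offsets), so a configuration fully reproduces a run.
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Global integer seed.
#' @param world A [world_config()]; its seed is overridden by `seed`.
#' @param sts_fraction Fraction of each gold-standard class held out as the
#'   Standard Test set.
#' @param pseudo Pseudo-count for likelihood-ratio estimation.
#' @param lr_cutoff Composite likelihood-ratio cutoff (default 20).
#' @param prior_odds Prior odds of interaction (default 1).
#' @param candidate_limit Maximum number of non-gold candidate pairs scored
#'   when assembling the predicted network (sampled deterministically from
#'   the remaining pair space).
#' @param degree_cutoff,apoptotic_partner_cutoff,dense_k,hub_criteria Hub
#'   identification settings for the global network (defaults 300 / 300 /
#'   k-core 3, criteria degree+apoptotic+dense).
#' @param sub_degree_cutoff Degree-only cutoff for the apoptotic
#'   sub-network hub report (default 30).
#' @param sam_permutations,sam_fdr_ceiling SAM settings.
#' @param mirna_min_tools Consensus voting threshold (`NULL` = all tools).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, world = world_config(),
                            sts_fraction = 0.2, pseudo = 1, lr_cutoff = 20,
                            prior_odds = 1, candidate_limit = 20000,
                            degree_cutoff = 300,
                            apoptotic_partner_cutoff = 300, dense_k = 3,
                            hub_criteria = c("degree", "apoptotic", "dense"),
                            sub_degree_cutoff = 30,
                            sam_permutations = 1000, sam_fdr_ceiling = 0.05,
                            mirna_min_tools = NULL) {
  stopifnot(is.character(outdir), length(outdir) == 1,
            sts_fraction > 0, sts_fraction < 1, lr_cutoff > 0)
  world$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), world = world,
              sts_fraction = sts_fraction, pseudo = pseudo,
              lr_cutoff = lr_cutoff, prior_odds = prior_odds,
              candidate_limit = candidate_limit,
              degree_cutoff = degree_cutoff,
              apoptotic_partner_cutoff = apoptotic_partner_cutoff,
              dense_k = dense_k, hub_criteria = hub_criteria,
              sub_degree_cutoff = sub_degree_cutoff,
              sam_permutations = sam_permutations,
              sam_fdr_ceiling = sam_fdr_ceiling,
              mirna_min_tools = mirna_min_tools)
  class(cfg) <- "pipeline_config"
  cfg
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full inference pipeline on a synthetic world
#'
#' Executes, under one seeded configuration: synthetic-world generation,
#' gold-standard construction (source union with alias resolution, sampled
#' gold negatives, held-out Standard Test split), evidence-profile
#' computation, likelihood-ratio training, candidate scoring and filtering
#' at the ratio cutoff, ROC/AUC evaluation on the test split, network
#' assembly with global and apoptotic sub-network hub reports, SAM
#' differential expression with probe aggregation and clustering of the
#' significant genes, and miRNA consensus annotation. Each stage writes its
#' artifacts under `outdir`; the returned manifest lists files with MD5
#' checksums so reruns can be compared byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `pipeline_manifest`: per-stage
#'   summaries, the file manifest and the seeds used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir)
  }
  seeds <- list(world = config$seed, split = config$seed + 101L,
                candidates = config$seed + 202L, sam = config$seed + 303L)
  summaries <- list()

  # --- stage 1: synthetic world -------------------------------------------
  wc <- config$world
  wc$seed <- seeds$world
  world <- generate_world(wc)
  write_world(world, file.path(outdir, "world"))
  summaries$world <- c(proteins = length(world$pair_proteins),
                       positives = nrow(world$positive_pairs),
                       negatives = nrow(world$negative_pairs))

  # --- stage 2: gold standards --------------------------------------------
  gold_dir <- file.path(outdir, "gold")
  dir.create(gold_dir, showWarnings = FALSE)
  gsp <- build_gsp(world$interaction_sources, world$aliases)
  gsn <- canonical_pairs(world$negative_pairs$a, world$negative_pairs$b)
  ratio <- gsp_gsn_ratio(nrow(gsp), nrow(gsn))
  split <- split_sts(gsp, gsn,
                     n_pos = round(config$sts_fraction * nrow(gsp)),
                     n_neg = round(config$sts_fraction * nrow(gsn)),
                     seed = seeds$split)
  write_tsv(gsp, file.path(gold_dir, "gsp.tsv"))
  write_tsv(gsn, file.path(gold_dir, "gsn.tsv"))
  write_tsv(split$test$gsp, file.path(gold_dir, "sts_pos.tsv"))
  write_tsv(split$test$gsn, file.path(gold_dir, "sts_neg.tsv"))
  counts <- list(
    gsp = nrow(gsp), gsn = nrow(gsn), ratio = ratio,
    per_source_raw = as.list(attr(gsp, "per_source_raw")),
    per_source_unique = as.list(attr(gsp, "per_source_unique")),
    sts_pos = nrow(split$test$gsp), sts_neg = nrow(split$test$gsn)
  )
  write_json_out(counts, file.path(gold_dir, "counts.json"))
  summaries$gold <- c(gsp = nrow(gsp), gsn = nrow(gsn), ratio = ratio)

  # --- stage 3: evidence profiles -----------------------------------------
  ev_dir <- file.path(outdir, "evidence")
  dir.create(ev_dir, showWarnings = FALSE)
  res <- world_resources(world)
  binning <- config$world$binning
  train_pairs <- rbind(split$train$gsp, split$train$gsn)
  train_labels <- rep(c(TRUE, FALSE),
                      c(nrow(split$train$gsp), nrow(split$train$gsn)))
  test_pairs <- rbind(split$test$gsp, split$test$gsn)
  test_labels <- rep(c(TRUE, FALSE),
                     c(nrow(split$test$gsp), nrow(split$test$gsn)))
  train_prof <- evidence_profiles(train_pairs, res, binning)
  test_prof <- evidence_profiles(test_pairs, res, binning)
  write_tsv(train_prof, file.path(ev_dir, "train_profiles.tsv"))
  write_tsv(test_prof, file.path(ev_dir, "test_profiles.tsv"))
  summaries$evidence <- c(train = nrow(train_prof), test = nrow(test_prof))

  # --- stage 4: likelihood-ratio training ---------------------------------
  bayes_dir <- file.path(outdir, "bayes")
  dir.create(bayes_dir, showWarnings = FALSE)
  lrt <- estimate_lrs(train_prof, train_labels, binning, config$pseudo)
  write_json_out(lapply(lrt$channels, function(d) {
    stats::setNames(as.list(d$lr), d$bin)
  }), file.path(bayes_dir, "likelihood_table.json"))

  # --- stage 5: prediction over candidates + test set ---------------------
  np <- length(world$pair_proteins)
  known <- pair_key(c(train_pairs$a, test_pairs$a),
                    c(train_pairs$b, test_pairs$b))
  set.seed(seeds$candidates)
  total_space <- np * (np - 1) / 2
  n_draw <- min(config$candidate_limit + length(known), total_space)
  kidx <- sample.int(total_space, n_draw)
  ij <- pair_index_to_ij(kidx, np)
  cand <- data.frame(a = world$pair_proteins[ij[, "i"]],
                     b = world$pair_proteins[ij[, "j"]],
                     stringsAsFactors = FALSE)
  cand <- cand[!(pair_key(cand$a, cand$b) %in% known), , drop = FALSE]
  if (nrow(cand) > config$candidate_limit) {
    cand <- cand[seq_len(config$candidate_limit), , drop = FALSE]
  }
  cand_prof <- evidence_profiles(cand, res, binning)
  preds <- predict_network(cand_prof, lrt, config$lr_cutoff,
                           config$prior_odds)
  write_tsv(preds, file.path(bayes_dir, "predictions.tsv"))
  summaries$predict <- attr(preds, "summary")

  # --- stage 6: evaluation on the Standard Test set -----------------------
  eval_dir <- file.path(outdir, "evaluate")
  dir.create(eval_dir, showWarnings = FALSE)
  test_scores <- composite_lr(test_prof, lrt)
  roc <- roc_curve(test_scores, test_labels, cutoff = config$lr_cutoff)
  write_tsv(data.frame(threshold = roc$thresholds,
                       tpr = roc$tpr[-1], fpr = roc$fpr[-1]),
            file.path(eval_dir, "roc.tsv"))
  write_json_out(list(auc = roc$auc, cutoff = config$lr_cutoff,
                      sensitivity = roc$sensitivity,
                      specificity = roc$specificity,
                      confusion = as.list(roc$confusion)),
                 file.path(eval_dir, "metrics.json"))
  summaries$evaluate <- c(auc = roc$auc, sensitivity = roc$sensitivity,
                          specificity = roc$specificity)

  # --- stage 7: network assembly and hub reports --------------------------
  net_dir <- file.path(outdir, "network")
  dir.create(net_dir, showWarnings = FALSE)
  net <- assemble_network(gsp, preds)
  write_tsv(net$edges, file.path(net_dir, "edges.tsv"))
  write_sif(net, file.path(net_dir, "network.sif"))
  sam_res <- NULL  # filled in stage 8; DE status joined afterwards
  hubs_global <- identify_hubs(
    net, apoptotic = world$apoptotic,
    degree_cutoff = config$degree_cutoff,
    apoptotic_partner_cutoff = config$apoptotic_partner_cutoff,
    dense_k = config$dense_k, criteria = config$hub_criteria)
  write_tsv(as.data.frame(hubs_global), file.path(net_dir, "hubs_global.tsv"))
  sub <- extract_subnetwork(net, world$apoptotic)
  hubs_sub <- identify_hubs(sub, apoptotic = world$apoptotic,
                            degree_cutoff = config$sub_degree_cutoff,
                            criteria = "degree")
  write_tsv(as.data.frame(hubs_sub), file.path(net_dir, "hubs_subnetwork.tsv"))
  summaries$network <- c(nodes = nrow(net$nodes), edges = nrow(net$edges),
                         hubs_global = sum(hubs_global$is_hub),
                         hubs_sub = sum(hubs_sub$is_hub))

  # --- stage 8: SAM differential expression -------------------------------
  sam_dir <- file.path(outdir, "sam")
  dir.create(sam_dir, showWarnings = FALSE)
  gene_matrix <- aggregate_probes_matrix(world$probe_matrix, world$probe_gene)
  sam_res <- sam_two_class(gene_matrix, factor(world$condition,
                                               levels = c("control", "treated")),
                           n_permutations = config$sam_permutations,
                           seed = seeds$sam,
                           fdr_ceiling = config$sam_fdr_ceiling)
  write_tsv(sam_res$genes, file.path(sam_dir, "sam_results.tsv"))
  write_json_out(sam_res$tuning, file.path(sam_dir, "tuning.json"))
  calls <- sam_calls(sam_res)
  called <- c(calls$up, calls$down)
  if (length(called) >= 2) {
    cl <- cluster_significant(gene_matrix[called, , drop = FALSE])
    write_matrix_tsv(cl$matrix, file.path(sam_dir, "clustered_matrix.tsv"))
  }
  summaries$sam <- c(up = length(calls$up), down = length(calls$down),
                     delta = sam_res$tuning$delta, fdr = sam_res$tuning$fdr)

  # --- stage 9: miRNA consensus -------------------------------------------
  mi_dir <- file.path(outdir, "mirna")
  dir.create(mi_dir, showWarnings = FALSE)
  cons <- mirna_consensus(world$mirna_predictions,
                          min_tools = config$mirna_min_tools)
  cons <- annotate_regulation(cons, world$gene_roles)
  write_tsv(as.data.frame(cons), file.path(mi_dir, "consensus.tsv"))
  summaries$mirna <- c(genes = nrow(cons),
                       with_consensus = sum(cons$n_consensus > 0))

  # --- manifest ------------------------------------------------------------
  cfg_out <- config
  cfg_out$world$binning <- NULL  # serialized separately below
  write_json_out(list(seed = config$seed,
                      lr_cutoff = config$lr_cutoff,
                      sts_fraction = config$sts_fraction,
                      degree_cutoff = config$degree_cutoff,
                      sub_degree_cutoff = config$sub_degree_cutoff,
                      sam_fdr_ceiling = config$sam_fdr_ceiling),
                 file.path(outdir, "config.json"))
  files <- sort(list.files(outdir, recursive = TRUE))
  manifest_df <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest_df, file.path(outdir, "manifest.tsv"))
  out <- list(summaries = summaries, files = manifest_df, seeds = seeds,
              outdir = outdir)
  class(out) <- "pipeline_manifest"
  invisible(out)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run in", x$outdir, "\n")
  for (st in names(x$summaries)) {
    s <- x$summaries[[st]]
    cat("  ", st, ": ",
        paste(names(s), format(unname(s), digits = 4), sep = "=",
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
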
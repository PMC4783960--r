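#' Default class-conditional bin distributions for the evidence channels
#'
#' These distributions define the study conditions of the synthetic worlds:
#' interacting pairs are enriched for small shared biological processes,
#' supported domain pairs, high co-expression and conserved interologs,
#' while non-interacting pairs skew toward large or absent shared processes
#' and low correlation. Every bin keeps probability mass of at least 0.05 so
#' likelihood ratios for all bins are estimable at moderate training sizes.
#'
#' @param species Model-organism channel suffixes.
#' @param binning Binning configuration whose bin labels the distributions
#'   are aligned to.
#' @return Named list per channel with `pos` and `neg` probability vectors
#'   over that channel's bins.
#' @export
default_truth <- function(species = default_species(),
                          binning = default_binning(species)) {
  bins <- channel_bins(binning)
  truth <- list(
    ssbp = list(pos = c(0.35, 0.25, 0.15, 0.10, 0.15),
                neg = c(0.05, 0.10, 0.20, 0.30, 0.35)),
    ddi = list(pos = c(0.30, 0.70), neg = c(0.05, 0.95)),
    coexpr = list(pos = c(0.15, 0.20, 0.30, 0.25, 0.10),
                  neg = c(0.40, 0.25, 0.15, 0.05, 0.15))
  )
  pos_true <- c(0.20, 0.18, 0.25, 0.15, 0.30, 0.10)
  for (i in seq_along(species)) {
    p <- pos_true[(i - 1) %% length(pos_true) + 1]
    truth[[paste0("interolog.", species[i])]] <-
      list(pos = c(p, 1 - p), neg = c(0.05, 0.95))
  }
  for (ch in names(truth)) {
    names(truth[[ch]]$pos) <- names(truth[[ch]]$neg) <- bins[[ch]]
  }
  truth
}

#' Configuration for the synthetic-world generator
#'
#' Desk-scale defaults (hundreds of proteins, thousands of pairs) mirroring
#' the structure of the real resources: five interaction source databases
#' with identifier aliases, flat biological-process annotation sets, a
#' domain-domain interaction table, per-species ortholog maps and model
#' organism interactomes, a per-pair co-expression resource, a replicated
#' two-condition expression experiment with spiked differentially expressed
#' genes, and per-tool miRNA target lists with planted consensus sets.
#'
#' @param n_proteins Proteins eligible for pair formation.
#' @param n_filler Additional filler proteins used to pad process
#'   memberships (never members of generated pairs).
#' @param n_positive_pairs,n_negative_pairs Interacting / non-interacting
#'   training pairs to generate.
#' @param species Model organisms (one interolog channel each).
#' @param binning Evidence binning configuration.
#' @param truth Class-conditional bin distributions (see [default_truth()]).
#' @param evidence_correlation In `[0, 1]`: probability that a channel's bin
#'   is driven by a pair-level latent quantile shared across channels,
#'   injecting cross-channel dependence to probe the conditional-independence
#'   assumption. Default 0 (conditionally independent channels).
#' @param ortholog_coverage Probability a protein has an ortholog in a
#'   species (forced to 1 for proteins in interolog-positive pairs).
#' @param alias_fraction Fraction of proteins given an alternative identifier
#'   sometimes used by the source databases.
#' @param n_genes,n_spiked,effect_size,noise_sd,n_replicates Expression
#'   experiment: gene count, spiked DE genes, log2 effect size, residual
#'   noise SD, replicates per condition (3 vs 3 by default).
#' @param n_mirna_genes Genes receiving per-tool miRNA predictions.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_proteins = 400, n_filler = 500,
                         n_positive_pairs = 1000, n_negative_pairs = 9000,
                         species = default_species(),
                         binning = default_binning(species),
                         truth = default_truth(species, binning),
                         evidence_correlation = 0,
                         ortholog_coverage = 0.7,
                         alias_fraction = 0.05,
                         n_genes = 1000, n_spiked = 50, effect_size = 2,
                         noise_sd = 0.25, n_replicates = 3,
                         n_mirna_genes = 10, seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_filler = n_filler,
              n_positive_pairs = n_positive_pairs,
              n_negative_pairs = n_negative_pairs,
              species = species, binning = binning, truth = truth,
              evidence_correlation = evidence_correlation,
              ortholog_coverage = ortholog_coverage,
              alias_fraction = alias_fraction,
              n_genes = n_genes, n_spiked = n_spiked,
              effect_size = effect_size, noise_sd = noise_sd,
              n_replicates = n_replicates, n_mirna_genes = n_mirna_genes,
              seed = as.integer(seed))
  counts <- c(n_proteins, n_filler, n_positive_pairs, n_negative_pairs,
              n_genes, n_replicates)
  if (any(counts <= 0)) stop("all generator counts must be positive")
  if (n_spiked > n_genes) stop("cannot spike more genes than exist")
  total <- n_positive_pairs + n_negative_pairs
  if (total > n_proteins * (n_proteins - 1) / 2) {
    stop("requested more distinct pairs than the protein set supports")
  }
  for (ch in names(cfg$truth)) {
    for (cl in c("pos", "neg")) {
      p <- cfg$truth[[ch]][[cl]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop("configuration error: truth distribution for channel '", ch,
             "' (", cl, ") does not sum to 1")
      }
    }
  }
  class(cfg) <- "world_config"
  cfg
}

# Sample bins for n pairs from a channel distribution; when `u` (a latent
# pair-level quantile) is supplied for some pairs, those bins come from the
# distribution's inverse CDF at u, coupling channels.
sample_bins <- function(n, probs, u = NULL) {
  labels <- names(probs)
  out <- sample(labels, n, replace = TRUE, prob = probs)
  if (!is.null(u)) {
    use <- !is.na(u)
    if (any(use)) {
      cdf <- cumsum(probs)
      idx <- findInterval(u[use], c(0, cdf), rightmost.closed = TRUE)
      idx[idx > length(labels)] <- length(labels)
      out[use] <- labels[idx]
    }
  }
  out
}

#' Generate a synthetic world with embedded ground truth
#'
#' Draws distinct interacting (positive) and non-interacting (negative)
#' protein pairs, samples each pair's evidence bin per channel from the
#' configured class-conditional distributions, then *realizes* resources
#' that reproduce those bins exactly when the evidence functions are run:
#' a dedicated biological-process set per pair (smallest-shared-process
#' sizes drawn inside the sampled bin, padded with filler proteins),
#' pair-specific interacting domain pairs, per-pair correlation entries,
#' and per-species ortholog maps plus model-organism interactions. The
#' positive pairs are scattered (with duplications, reversed orders and
#' identifier aliases) across five source databases; negatives are kept as
#' a sampled gold-negative pair list. A replicated two-condition expression
#' experiment with spiked genes, per-tool miRNA hit lists with planted
#' consensus sets, compartment membership sets and gene roles complete the
#' world. Regeneration with the same configuration is deterministic.
#'
#' @param config A [world_config()].
#' @return Object of class `synthetic_world`; see the package vignette for
#'   the component inventory. `world$truth` holds the generating parameters
#'   (channel distributions, per-pair bins, spiked genes, planted consensus
#'   sets).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  core <- sprintf("P%04d", seq_len(np))
  fillers <- sprintf("F%04d", seq_len(config$n_filler))
  species <- config$species
  binning <- config$binning
  chans <- channel_names(binning)

  # --- distinct canonical pairs -------------------------------------------
  n_pos <- config$n_positive_pairs
  n_neg <- config$n_negative_pairs
  k <- sample.int(np * (np - 1) / 2, n_pos + n_neg)
  ij <- pair_index_to_ij(k, np)
  pairs <- data.frame(a = core[ij[, "i"]], b = core[ij[, "j"]],
                      stringsAsFactors = FALSE)
  label <- rep(c(TRUE, FALSE), c(n_pos, n_neg))

  # --- per-pair evidence bins from the class-conditional truth ------------
  rho_mix <- config$evidence_correlation
  latent <- stats::runif(n_pos + n_neg)
  evidence <- data.frame(a = pairs$a, b = pairs$b, label = label,
                         stringsAsFactors = FALSE)
  for (ch in chans) {
    u <- rep(NA_real_, n_pos + n_neg)
    if (rho_mix > 0) {
      drive <- stats::runif(n_pos + n_neg) < rho_mix
      u[drive] <- latent[drive]
    }
    bins <- character(n_pos + n_neg)
    bins[label] <- sample_bins(n_pos, config$truth[[ch]]$pos, u[label])
    bins[!label] <- sample_bins(n_neg, config$truth[[ch]]$neg, u[!label])
    evidence[[ch]] <- bins
  }

  # --- realize SSBP: one dedicated process per pair with a shared process -
  ssbp_cfg <- binning$ssbp
  bin_lo <- ssbp_cfg$breaks[-length(ssbp_cfg$breaks)]
  bin_hi <- ssbp_cfg$breaks[-1] - 1
  bin_hi[!is.finite(bin_hi)] <- bin_lo[!is.finite(bin_hi)] + 49
  if (config$n_filler < max(bin_hi) - 2) {
    stop("n_filler must be at least ", max(bin_hi) - 2,
         " to realize the largest shared-process bin")
  }
  has_proc <- evidence$ssbp != ssbp_cfg$absent
  proc_bin <- match(evidence$ssbp[has_proc], ssbp_cfg$labels)
  lo <- pmax(bin_lo[proc_bin], 2)
  hi <- pmax(bin_hi[proc_bin], lo)
  sizes <- lo + floor(stats::runif(sum(has_proc)) * (hi - lo + 1))
  go <- vector("list", sum(has_proc) + 3)
  which_pairs <- which(has_proc)
  for (i in seq_along(which_pairs)) {
    w <- which_pairs[i]
    extra <- sizes[i] - 2
    mem <- c(evidence$a[w], evidence$b[w],
             if (extra > 0) fillers[sample.int(config$n_filler, extra)])
    go[[i]] <- mem
  }
  # decoy processes over fillers only
  for (j in seq_len(3)) {
    go[[sum(has_proc) + j]] <- fillers[sample.int(config$n_filler,
                                                  min(20, config$n_filler))]
  }
  names(go) <- sprintf("BP%05d", seq_along(go))

  # --- realize DDI: a fresh interacting domain pair per supported pair ----
  ddi_true <- which(evidence$ddi == "true")
  domain_map <- stats::setNames(as.list(paste0("BD_", core)), core)
  ddi_rows <- vector("list", length(ddi_true))
  for (i in seq_along(ddi_true)) {
    w <- ddi_true[i]
    d1 <- sprintf("DM%05da", w)
    d2 <- sprintf("DM%05db", w)
    domain_map[[evidence$a[w]]] <- c(domain_map[[evidence$a[w]]], d1)
    domain_map[[evidence$b[w]]] <- c(domain_map[[evidence$b[w]]], d2)
    ddi_rows[[i]] <- c(d1, d2)
  }
  ddi_table <- if (length(ddi_rows)) {
    as.data.frame(do.call(rbind, ddi_rows), stringsAsFactors = FALSE)
  } else {
    data.frame(V1 = character(), V2 = character(), stringsAsFactors = FALSE)
  }
  names(ddi_table) <- c("domain_a", "domain_b")
  # decoy homotypic contact among unassigned domains
  ddi_table <- rbind(ddi_table,
                     data.frame(domain_a = "DX00001", domain_b = "DX00001",
                                stringsAsFactors = FALSE))

  # --- realize co-expression: per-pair rho drawn inside the sampled bin ---
  cx <- binning$coexpr
  has_rho <- evidence$coexpr != cx$absent
  rb <- match(evidence$coexpr[has_rho], cx$labels)
  r_lo <- cx$breaks[rb]
  r_hi <- cx$breaks[rb + 1]
  eps <- 1e-6
  rho <- r_lo + stats::runif(sum(has_rho)) * (r_hi - r_lo - eps)
  pair_rho <- data.frame(a = evidence$a[has_rho], b = evidence$b[has_rho],
                         rho = rho, stringsAsFactors = FALSE)

  # --- realize interologs -------------------------------------------------
  ortholog_maps <- list()
  species_ppi <- list()
  for (sp in species) {
    ch <- paste0("interolog.", sp)
    flag <- evidence[[ch]] == "true"
    has_orth <- stats::runif(np) < config$ortholog_coverage
    need <- unique(c(evidence$a[flag], evidence$b[flag]))
    has_orth[match(need, core)] <- TRUE
    map <- stats::setNames(paste0(sp, "_", core), core)[has_orth]
    oa <- unname(map[evidence$a[flag]])
    ob <- unname(map[evidence$b[flag]])
    sp_pairs <- data.frame(a = pmin(oa, ob), b = pmax(oa, ob),
                           stringsAsFactors = FALSE)
    # decoy interactions among filler-protein orthologs
    nf <- min(10, config$n_filler - 1)
    decoy <- data.frame(a = paste0(sp, "_", fillers[seq_len(nf)]),
                        b = paste0(sp, "_", fillers[seq_len(nf) + 1]),
                        stringsAsFactors = FALSE)
    species_ppi[[sp]] <- rbind(sp_pairs, decoy)
    ortholog_maps[[sp]] <- map
  }

  # --- identifier aliases and source databases ----------------------------
  n_alias <- round(config$alias_fraction * np)
  alias_prots <- if (n_alias > 0) sort(sample(core, n_alias)) else character()
  aliases <- data.frame(canonical = alias_prots,
                        alias = paste0("ALT_", alias_prots),
                        stringsAsFactors = FALSE)
  source_names <- paste0("ppidb", 1:5)
  n_src <- sample(1:3, n_pos, replace = TRUE)
  src_rows <- data.frame(
    pair = rep(seq_len(n_pos), n_src),
    src = unlist(lapply(n_src, function(m) sample.int(5, m)))
  )
  interaction_sources <- lapply(seq_along(source_names), function(s) {
    idx <- src_rows$pair[src_rows$src == s]
    a <- evidence$a[idx]
    b <- evidence$b[idx]
    flip <- stats::runif(length(idx)) < 0.3
    tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
    use_alias <- function(x) {
      i <- match(x, aliases$canonical)
      sw <- !is.na(i) & stats::runif(length(x)) < 0.5
      x[sw] <- aliases$alias[i[sw]]
      x
    }
    # duplicate a few rows to exercise deduplication
    dup <- sample.int(length(a), size = max(1, length(a) %/% 20))
    data.frame(protein_a = use_alias(c(a, a[dup])),
               protein_b = use_alias(c(b, b[dup])),
               stringsAsFactors = FALSE)
  })
  names(interaction_sources) <- source_names

  # --- compartments (for gold-negative construction) ----------------------
  membrane_set <- sort(sample(core, round(0.30 * np)))
  nuclear_set <- sort(sample(core, round(0.25 * np)))

  # --- expression experiment with spiked DE genes -------------------------
  n_genes <- config$n_genes
  gene_ids <- c(core[seq_len(min(np, n_genes))],
                if (n_genes > np) sprintf("G%04d", seq_len(n_genes - np)))
  nr <- config$n_replicates
  samples <- c(paste0("ctrl", seq_len(nr)), paste0("trt", seq_len(nr)))
  condition <- rep(c("control", "treated"), each = nr)
  mu <- stats::runif(n_genes, 6, 12)
  expr <- matrix(stats::rnorm(n_genes * 2 * nr, mean = mu,
                              sd = config$noise_sd),
                 nrow = n_genes, ncol = 2 * nr,
                 dimnames = list(gene_ids, samples))
  spiked_idx <- sort(sample.int(n_genes, config$n_spiked))
  spike_sign <- sample(c(-1, 1), config$n_spiked, replace = TRUE)
  expr[spiked_idx, condition == "treated"] <-
    expr[spiked_idx, condition == "treated"] +
    spike_sign * config$effect_size
  spiked <- data.frame(gene = gene_ids[spiked_idx], sign = spike_sign,
                       effect = config$effect_size, stringsAsFactors = FALSE)

  # probe-level view: most genes one probe, some 2 or 3
  n_probes_per <- sample(1:3, n_genes, replace = TRUE,
                         prob = c(0.85, 0.10, 0.05))
  probe_gene <- rep(gene_ids, n_probes_per)
  probe_ids <- sprintf("PR%05d", seq_along(probe_gene))
  probe_matrix <- expr[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(probe_gene) * 2 * nr, sd = 0.05),
           nrow = length(probe_gene))
  rownames(probe_matrix) <- probe_ids

  # --- apoptotic seed list and gene roles ---------------------------------
  apoptotic <- sort(sample(core, round(0.25 * np)))
  roles <- sample(c("oncogene", "tumor_suppressor", "none"), n_genes,
                  replace = TRUE, prob = c(0.15, 0.15, 0.70))
  gene_roles <- data.frame(gene = gene_ids, role = roles,
                           stringsAsFactors = FALSE)

  # --- miRNA predictions with planted consensus sets ----------------------
  tools <- c("targetscan", "miranda", "dianamicrot")
  target_genes <- sort(sample(core, min(config$n_mirna_genes, np)))
  mirna_pool <- sprintf("hsa-miR-%d", 100:999)
  planted <- list()
  pred_rows <- list()
  pool_used <- 0
  for (g in target_genes) {
    n_cons <- sample(2:5, 1)
    n_decoy <- sample(3:10, length(tools), replace = TRUE)
    need <- n_cons + sum(n_decoy)
    ids <- mirna_pool[pool_used + seq_len(need)]
    pool_used <- pool_used + need
    cons <- ids[seq_len(n_cons)]
    rest <- ids[-seq_len(n_cons)]
    off <- 0
    for (t in seq_along(tools)) {
      dec <- rest[off + seq_len(n_decoy[t])]
      off <- off + n_decoy[t]
      pred_rows[[length(pred_rows) + 1]] <-
        data.frame(tool = tools[t], gene = g, mirna = c(cons, dec),
                   stringsAsFactors = FALSE)
    }
    planted[[g]] <- sort(cons)
  }
  mirna_predictions <- do.call(rbind, pred_rows)

  world <- list(
    proteins = c(core, fillers),
    pair_proteins = core,
    filler_proteins = fillers,
    interaction_sources = interaction_sources,
    aliases = aliases,
    positive_pairs = pairs[label, , drop = FALSE],
    negative_pairs = pairs[!label, , drop = FALSE],
    membrane_set = membrane_set,
    nuclear_set = nuclear_set,
    go = go,
    domain_map = domain_map,
    ddi_table = ddi_table,
    pair_rho = pair_rho,
    ortholog_maps = ortholog_maps,
    species_ppi = species_ppi,
    expression = expr,
    condition = condition,
    probe_matrix = probe_matrix,
    probe_gene = probe_gene,
    apoptotic = apoptotic,
    gene_roles = gene_roles,
    mirna_predictions = mirna_predictions,
    evidence = evidence,
    truth = list(channels = config$truth, spiked = spiked,
                 consensus = planted),
    config = config
  )
  rownames(world$positive_pairs) <- rownames(world$negative_pairs) <- NULL
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world (seed ", x$config$seed, "): ",
      length(x$pair_proteins), " proteins, ",
      nrow(x$positive_pairs), " positive / ",
      nrow(x$negative_pairs), " negative pairs, ",
      length(x$go), " processes, ",
      nrow(x$expression), " genes x ", ncol(x$expression), " samples\n",
      sep = "")
  invisible(x)
}

#' Evidence resources of a synthetic world
#'
#' Bundles the world components consumed by [evidence_profiles()].
#'
#' @param world A `synthetic_world`.
#' @return Resource list (`go`, `domain_map`, `ddi_table`, `pair_rho`,
#'   `ortholog_maps`, `species_ppi`).
#' @export
world_resources <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  list(go = world$go, domain_map = world$domain_map,
       ddi_table = world$ddi_table, pair_rho = world$pair_rho,
       ortholog_maps = world$ortholog_maps,
       species_ppi = world$species_ppi)
}

#' Generate a network world with planted hubs
#'
#' Builds a `ppi_network` in which a known set of hub proteins satisfies all
#' hub criteria: each hub is wired to the same large block of apoptotic seed
#' proteins (driving both raw degree and apoptotic partner count past their
#' cutoffs) and the hubs interconnect, placing them in the dense k-core.
#' Two decoys probe the criteria individually: one high-degree node attached
#' only to non-apoptotic leaf proteins (fails the apoptotic-partner
#' criterion and sits outside the dense core) and one node wired to a
#' sub-cutoff number of seeds (fails the degree criterion). Background
#' proteins carry sparse random edges. Planted hubs are also marked as
#' differentially expressed.
#'
#' @param n_hubs Number of planted hubs (default 3; must be `>= dense_k` so
#'   hubs can interconnect into the core).
#' @param n_seed_block Apoptotic seed proteins wired to every hub
#'   (default 320, comfortably above the conventional 300 cutoff).
#' @param n_background Background proteins (default 200).
#' @param seed RNG seed.
#' @return List: `network` (a `ppi_network`), `apoptotic` (seed protein
#'   IDs), `de_status` (named vector), `truth` (list with `hubs`).
#' @export
generate_hub_world <- function(n_hubs = 3, n_seed_block = 320,
                               n_background = 200, seed = 1L) {
  stopifnot(n_hubs >= 2, n_seed_block >= 1, n_background >= 10)
  set.seed(seed)
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  seeds <- sprintf("AP%04d", seq_len(n_seed_block))
  bg <- sprintf("BG%04d", seq_len(n_background))
  edges <- list()
  for (h in hubs) {
    edges[[length(edges) + 1]] <- data.frame(a = h, b = seeds,
                                             stringsAsFactors = FALSE)
  }
  hub_pairs <- t(utils::combn(hubs, 2))
  edges[[length(edges) + 1]] <- data.frame(a = hub_pairs[, 1],
                                           b = hub_pairs[, 2],
                                           stringsAsFactors = FALSE)
  # decoy 1: high degree, non-apoptotic leaf partners only
  leaf <- sprintf("LF%04d", seq_len(n_seed_block))
  edges[[length(edges) + 1]] <- data.frame(a = "DECOY_DEGREE", b = leaf,
                                           stringsAsFactors = FALSE)
  # decoy 2: dense wiring to seeds but below the degree cutoff
  edges[[length(edges) + 1]] <- data.frame(
    a = "DECOY_PARTNERS", b = sample(seeds, min(150, n_seed_block)),
    stringsAsFactors = FALSE)
  # sparse background
  n_bg_edges <- n_background
  edges[[length(edges) + 1]] <- data.frame(
    a = sample(bg, n_bg_edges, replace = TRUE),
    b = sample(bg, n_bg_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  net <- ppi_network(do.call(rbind, edges))
  de <- stats::setNames(rep("up", n_hubs), hubs)
  list(network = net, apoptotic = seeds, de_status = de,
       truth = list(hubs = hubs))
}
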
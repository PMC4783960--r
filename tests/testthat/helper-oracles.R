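# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's internal data structures and any
# graph library: plain loops and set arithmetic only.

brute_ssbp <- function(a, b, go) {
  best <- NA_integer_
  for (members in go) {
    if (a %in% members && b %in% members) {
      n <- length(members)
      if (is.na(best) || n < best) best <- n
    }
  }
  best
}

brute_ddi <- function(a, b, domain_map, ddi) {
  da <- domain_map[[a]]
  db <- domain_map[[b]]
  if (is.null(da) || is.null(db)) return(FALSE)
  for (d1 in da) for (d2 in db) {
    for (r in seq_len(nrow(ddi))) {
      x <- ddi[r, 1]
      y <- ddi[r, 2]
      if ((d1 == x && d2 == y) || (d1 == y && d2 == x)) return(TRUE)
    }
  }
  FALSE
}

brute_interolog <- function(a, b, map, sp_pairs) {
  oa <- map[[a]]
  ob <- map[[b]]
  if (is.null(oa) || is.null(ob) || is.na(oa) || is.na(ob)) return(FALSE)
  for (r in seq_len(nrow(sp_pairs))) {
    x <- sp_pairs[r, 1]
    y <- sp_pairs[r, 2]
    if ((oa == x && ob == y) || (oa == y && ob == x)) return(TRUE)
  }
  FALSE
}

# Mann-Whitney AUC: fraction of positive-negative score pairs correctly
# ordered, ties counted one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Degree from an explicit adjacency matrix.
brute_degree <- function(edges, nodes) {
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    adj[edges$a[r], edges$b[r]] <- 1L
    adj[edges$b[r], edges$a[r]] <- 1L
  }
  rowSums(adj)
}

# Neighborhood sub-network membership by direct scan.
brute_neighborhood <- function(edges, seeds_present) {
  keep <- seeds_present
  for (r in seq_len(nrow(edges))) {
    if (edges$a[r] %in% seeds_present) keep <- union(keep, edges$b[r])
    if (edges$b[r] %in% seeds_present) keep <- union(keep, edges$a[r])
  }
  sort(keep)
}

# Strict miRNA intersection across tools for one gene.
brute_consensus <- function(sets) {
  out <- sets[[1]]
  for (s in sets[-1]) out <- intersect(out, s)
  sort(out)
}

# A tiny random world for oracle-equivalence loops.
random_small_world <- function(seed) {
  cfg <- world_config(n_proteins = 20, n_filler = 260,
                      n_positive_pairs = 15, n_negative_pairs = 40,
                      n_genes = 30, n_spiked = 5, n_mirna_genes = 3,
                      seed = seed)
  generate_world(cfg)
}
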
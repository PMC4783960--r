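test_that("assemble_network unions gold and predicted edges with provenance", {
  gsp <- data.frame(a = "a", b = "b")
  preds <- data.frame(a = "b", b = "c", composite_lr = 30, passed = TRUE)
  net <- assemble_network(gsp, preds)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  # same edge in both collapses with provenance "both", keeping the score
  preds2 <- data.frame(a = c("b", "a"), b = c("a", "c"),
                       composite_lr = c(25, 30), passed = TRUE)
  net2 <- assemble_network(gsp, preds2)
  expect_equal(nrow(net2$edges), 2)
  e <- net2$edges[pair_key(net2$edges$a, net2$edges$b) == pair_key("a", "b"), ]
  expect_equal(e$provenance, "both")
  expect_equal(e$lr, 25)
  # failed predictions are excluded
  preds3 <- data.frame(a = "x", b = "y", composite_lr = 1, passed = FALSE)
  expect_equal(nrow(assemble_network(gsp, preds3)$edges), 1)
})

test_that("network assembly counts match set arithmetic on random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    prots <- sprintf("P%02d", 1:15)
    gsp <- canonical_pairs(sample(prots, 30, TRUE), sample(prots, 30, TRUE))
    pred_pairs <- canonical_pairs(sample(prots, 30, TRUE),
                                  sample(prots, 30, TRUE))
    preds <- data.frame(pred_pairs, composite_lr = 21, passed = TRUE)
    net <- assemble_network(gsp, preds)
    ref_edges <- union(pair_key(gsp$a, gsp$b),
                       pair_key(pred_pairs$a, pred_pairs$b))
    expect_setequal(pair_key(net$edges$a, net$edges$b), ref_edges)
    expect_setequal(net$nodes$node,
                    unique(unlist(strsplit(ref_edges, "\t"))))
  }
})

test_that("degree matches an adjacency-matrix oracle and the handshake lemma", {
  for (seed in 1:10) {
    set.seed(seed)
    nodes <- sprintf("N%02d", 1:12)
    edges <- canonical_pairs(sample(nodes, 25, TRUE), sample(nodes, 25, TRUE))
    net <- ppi_network(edges, nodes = nodes)
    deg <- ppi_degree(net)
    ref <- brute_degree(net$edges, net$nodes$node)
    expect_equal(unname(deg[net$nodes$node]),
                 unname(as.integer(ref[net$nodes$node])))
    expect_equal(sum(deg), 2 * nrow(net$edges))
  }
  # star and isolated node
  star <- ppi_network(data.frame(a = "c", b = paste0("l", 1:5)),
                      nodes = c("c", paste0("l", 1:5), "iso"))
  d <- ppi_degree(star)
  expect_equal(unname(d["c"]), 5L)
  expect_equal(unname(d["iso"]), 0L)
})

test_that("extract_subnetwork takes seeds plus direct neighbors, induced", {
  star <- ppi_network(data.frame(a = "a", b = c("b", "c", "d")))
  sub <- extract_subnetwork(star, "a")
  expect_equal(nrow(sub$nodes), 4)
  expect_equal(nrow(sub$edges), 3)
  expect_error(extract_subnetwork(star, "zz"), "no seed")
  # isolated seed retained
  net <- ppi_network(data.frame(a = "a", b = "b"), nodes = c("a", "b", "s"))
  sub2 <- extract_subnetwork(net, "s")
  expect_equal(sub2$nodes$node, "s")
  # brute-force neighborhood on random graphs
  for (seed in 1:10) {
    set.seed(seed)
    nodes <- sprintf("N%02d", 1:14)
    net3 <- ppi_network(canonical_pairs(sample(nodes, 30, TRUE),
                                        sample(nodes, 30, TRUE)))
    seeds_present <- intersect(sample(nodes, 3), net3$nodes$node)
    if (!length(seeds_present)) next
    sub3 <- extract_subnetwork(net3, seeds_present)
    expect_setequal(sub3$nodes$node,
                    brute_neighborhood(net3$edges, seeds_present))
    # induced: every edge of the parent among kept nodes is present
    keep <- sub3$nodes$node
    ref_edges <- net3$edges[net3$edges$a %in% keep & net3$edges$b %in% keep, ]
    expect_setequal(pair_key(sub3$edges$a, sub3$edges$b),
                    pair_key(ref_edges$a, ref_edges$b))
  }
})

test_that("hub criteria use >= cutoffs and conjunction of enabled criteria", {
  # node with degree exactly 30 satisfies the sub-network degree criterion
  edges <- data.frame(a = "hub", b = sprintf("x%02d", 1:30))
  net <- ppi_network(edges)
  rep30 <- identify_hubs(net, degree_cutoff = 30, criteria = "degree")
  expect_true(rep30$is_hub[rep30$node == "hub"])
  rep31 <- identify_hubs(net, degree_cutoff = 31, criteria = "degree")
  expect_false(rep31$is_hub[rep31$node == "hub"])
  # degree 29 fails at cutoff 30
  net29 <- ppi_network(data.frame(a = "h", b = sprintf("x%02d", 1:29)))
  r29 <- identify_hubs(net29, degree_cutoff = 30, criteria = "degree")
  expect_false(r29$is_hub[r29$node == "h"])
})

test_that("raising any cutoff never enlarges the hub set", {
  hw <- generate_hub_world(seed = 2)
  base <- identify_hubs(hw$network, apoptotic = hw$apoptotic,
                        degree_cutoff = 100, apoptotic_partner_cutoff = 100)
  for (dc in c(150, 300, 400)) {
    higher <- identify_hubs(hw$network, apoptotic = hw$apoptotic,
                            degree_cutoff = dc,
                            apoptotic_partner_cutoff = 100)
    expect_true(all(higher$node[higher$is_hub] %in% base$node[base$is_hub]))
  }
  for (ac in c(150, 300, 400)) {
    higher <- identify_hubs(hw$network, apoptotic = hw$apoptotic,
                            degree_cutoff = 100,
                            apoptotic_partner_cutoff = ac)
    expect_true(all(higher$node[higher$is_hub] %in% base$node[base$is_hub]))
  }
})

test_that("planted hubs are exactly recovered under the default criteria", {
  hw <- generate_hub_world(seed = 8)
  rep_ <- identify_hubs(hw$network, apoptotic = hw$apoptotic,
                        de_status = hw$de_status)
  expect_setequal(rep_$node[rep_$is_hub], hw$truth$hubs)
  # layering the differential-expression criterion keeps exactly the hubs,
  # which are the spiked nodes
  rep_de <- identify_hubs(hw$network, apoptotic = hw$apoptotic,
                          de_status = hw$de_status,
                          criteria = c("degree", "apoptotic", "dense", "de"))
  expect_setequal(rep_de$node[rep_de$is_hub], hw$truth$hubs)
})
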
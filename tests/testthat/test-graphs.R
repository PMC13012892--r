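test_that("zone graphs contain exactly the contacting residues and edges", {
  cs <- simulate_complex("strong", synthetic_spec(), seed = 12)
  ct <- detect_contacts(cs, "MHC", "PEPTIDE")
  g <- build_zone_graph(cs, "MHC-PEP")
  expect_equal(tcrgraphs:::n_edges(g), nrow(ct))
  expect_lte(tcrgraphs:::n_nodes(g), 2 * nrow(ct))
  expect_setequal(
    tcrgraphs:::residue_key(g$nodes$chain_id, g$nodes$res_seq, g$nodes$icode),
    unique(c(ct$key_a, ct$key_b)))
  expect_true(all(g$edge_feats[, "dist"] <= 8))
  expect_error(build_zone_graph(cs, "PEP-MHC"), "unknown zone")
})

test_that("merging consolidates shared nodes and removes redundant edges", {
  g1 <- toy_graph(4, rbind(c(1, 2), c(2, 3)), "c:z1", seed = 3)
  g2 <- toy_graph(6, rbind(c(4, 5), c(5, 6)), "c:z2", seed = 4)
  # distinct chains except one shared node with identical key and features
  g2$nodes$chain_id <- "H"
  g1$nodes$res_seq[2] <- 99L
  g2$nodes[4, ] <- g1$nodes[2, ]
  g2$node_feats[4, ] <- g1$node_feats[2, ]
  g2$coords[4, ] <- g1$coords[2, ]
  m <- merge_zone_graphs(list(g1, g2))
  expect_equal(tcrgraphs:::n_nodes(m), 4 + 6 - 1)
  expect_equal(tcrgraphs:::n_edges(m), 4)
  # conflicting features for a shared node must error
  g2$node_feats[4, "sasa"] <- g2$node_feats[4, "sasa"] + 1
  expect_error(merge_zone_graphs(list(g1, g2)), "conflicting")
})

test_that("disjoint zone graphs merge to the sum of their sizes", {
  g1 <- toy_graph(4, rbind(c(1, 2)), "c:z1", seed = 5)
  g2 <- toy_graph(6, rbind(c(1, 4)), "c:z2", seed = 6)
  g2$nodes$chain_id <- "H"   # disjoint keys
  m <- merge_zone_graphs(list(g1, g2))
  expect_equal(tcrgraphs:::n_nodes(m), 10)
  expect_equal(tcrgraphs:::n_edges(m), 2)
})

test_that("merged node and edge sets equal the set-union oracle", {
  spec <- synthetic_spec(n_mhc = 14, n_pep = 9, n_tcr = 8)
  for (s in 1:50) {
    cs <- simulate_complex(ifelse(s %% 2, "strong", "weak"), spec, seed = 400 + s)
    feats <- complex_node_features(cs)
    zgs <- lapply(names(interface_zones()), function(z) {
      suppressWarnings(build_zone_graph(cs, z, features = feats))
    })
    m <- merge_zone_graphs(zgs, graph_id = cs$complex_id)
    key <- function(g) tcrgraphs:::residue_key(g$nodes$chain_id,
                                               g$nodes$res_seq, g$nodes$icode)
    node_union <- unique(unlist(lapply(zgs, key)))
    expect_setequal(key(m), node_union)
    edge_union <- unique(unlist(lapply(zgs, function(g) {
      if (!tcrgraphs:::n_edges(g)) return(character(0))
      k <- key(g)
      apply(g$edge_index, 2, function(e) paste(sort(k[e]), collapse = "--"))
    })))
    mk <- key(m)
    medges <- apply(m$edge_index, 2,
                    function(e) paste(sort(mk[e]), collapse = "--"))
    expect_setequal(medges, edge_union)
    # unified counts bounded by sums over zones
    expect_lte(tcrgraphs:::n_nodes(m),
               sum(vapply(zgs, tcrgraphs:::n_nodes, integer(1))))
    expect_lte(tcrgraphs:::n_edges(m),
               sum(vapply(zgs, tcrgraphs:::n_edges, integer(1))))
  }
})

test_that("strong fixtures are denser with shorter edges than weak ones", {
  spec <- synthetic_spec(n_mhc = 16, n_pep = 9, n_tcr = 8)
  stats <- lapply(c("strong", "weak"), function(cl) {
    deg <- dist <- numeric(0)
    for (s in 1:12) {
      g <- build_complex_graph(simulate_complex(cl, spec, seed = 600 + s))
      deg <- c(deg, 2 * tcrgraphs:::n_edges(g) / tcrgraphs:::n_nodes(g))
      dist <- c(dist, mean(g$edge_feats[, "dist"]))
    }
    list(deg = mean(deg), dist = mean(dist))
  })
  expect_gt(stats[[1]]$deg, stats[[2]]$deg)
  expect_lt(stats[[1]]$dist, stats[[2]]$dist)
})

test_that("z-score normalization fits on train only and flags constants", {
  ds <- planted_dataset()
  train <- ds$graphs[1:30]; held <- ds$graphs[31:40]
  norm <- normalize_features(train, held)
  sch <- feature_schema()
  pooled <- do.call(rbind, lapply(norm$train, `[[`, "node_feats"))
  for (cn in setdiff(sch$node_continuous, c("phi_sin", "phi_cos",
                                            "psi_sin", "psi_cos"))) {
    expect_lt(abs(mean(pooled[, cn])), 1e-8)
    expect_equal(sd(pooled[, cn]), 1, tolerance = 1e-6)
  }
  # one-hot untouched
  expect_true(all(pooled[, grep("^aa_", colnames(pooled))] %in% c(0, 1)))
  # leakage check: stats identical with or without the held-out set
  norm2 <- normalize_features(train)
  expect_identical(norm$stats$node$mean, norm2$stats$node$mean)
  expect_identical(norm$stats$edge$sd, norm2$stats$edge$sd)
  # constant feature (backbone zeros in graph mode) flagged and unscaled
  expect_true(norm$stats$node$constant[["phi_sin"]])
  expect_equal(unique(pooled[, "phi_sin"]), 0)
})

test_that("ablation removes exactly the named feature block", {
  ds <- planted_dataset()
  g <- ds$graphs[1:3]
  sch <- feature_schema()
  a1 <- ablate_feature_group(g, "residue_physchem")
  expect_equal(ncol(a1[[1]]$node_feats),
               ncol(g[[1]]$node_feats) - length(sch$groups$residue_physchem$node))
  a2 <- ablate_feature_group(g, "edge_features")
  expect_equal(ncol(a2[[1]]$edge_feats), 0)
  a3 <- ablate_feature_group(g, "surface_features")
  expect_false(any(c("sasa", "bsa", "depth") %in% colnames(a3[[1]]$node_feats)))
  expect_identical(ablate_feature_group(g, "none"), g)
  expect_error(ablate_feature_group(g, "banana"), "unknown feature group")
})

test_that("graph validation catches malformed graphs", {
  g <- toy_graph(5, rbind(c(1, 2), c(2, 3)))
  bad <- g; bad$edge_index <- rbind(c(2L, 2L), c(1L, 3L))
  expect_error(validate_interface_graph(bad), "canonically ordered")
  bad <- g; bad$edge_index <- cbind(bad$edge_index, c(1L, 2L))
  expect_error(validate_interface_graph(bad), "edge feature row|duplicate")
  bad <- g; bad$nodes$res_seq[2] <- 1L
  expect_error(validate_interface_graph(bad), "duplicate node")
})
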
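# exhaustive all-pairs brute-force oracle over atoms of two roles
brute_contacts <- function(cs, role_a, role_b, cutoff, sidechain = FALSE) {
  ch_a <- names(cs$roles)[cs$roles == role_a]
  ch_b <- names(cs$roles)[cs$roles == role_b]
  a <- cs$atoms[cs$atoms$chain_id == ch_a, ]
  b <- cs$atoms[cs$atoms$chain_id == ch_b, ]
  if (sidechain) {
    bb <- c("N", "CA", "C", "O", "OXT")
    a <- a[!(a$atom_name %in% bb), ]; b <- b[!(b$atom_name %in% bb), ]
  }
  out <- list()
  for (ra in unique(a$res_seq)) for (rb in unique(b$res_seq)) {
    pa <- a[a$res_seq == ra, c("x", "y", "z")]
    pb <- b[b$res_seq == rb, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
      d <- sqrt(sum((as.numeric(pa[i, ]) - as.numeric(pb[j, ]))^2))
      dmin <- min(dmin, d)
    }
    if (is.finite(dmin) && dmin <= cutoff) {
      out[[length(out) + 1]] <- data.frame(
        key_a = paste(ch_a, ra, "", sep = ":"),
        key_b = paste(ch_b, rb, "", sep = ":"), min_dist = dmin)
    }
  }
  if (!length(out)) return(data.frame(key_a = character(0),
                                      key_b = character(0),
                                      min_dist = numeric(0)))
  do.call(rbind, out)
}

test_that("contact detection matches the exhaustive oracle, both conventions", {
  spec <- synthetic_spec(n_mhc = 10, n_pep = 9, n_tcr = 6)
  for (s in 1:6) {
    cs <- simulate_complex(ifelse(s %% 2, "strong", "weak"), spec, seed = s)
    for (conv in c("all_heavy", "sidechain_heavy")) {
      got <- detect_contacts(cs, "MHC", "PEPTIDE", 8,
                             contact_atoms = conv)
      ora <- brute_contacts(cs, "MHC", "PEPTIDE", 8,
                            sidechain = conv == "sidechain_heavy")
      ora <- ora[order(ora$key_a, ora$key_b), ]
      expect_equal(got$key_a, ora$key_a)
      expect_equal(got$key_b, ora$key_b)
      expect_equal(got$min_dist, ora$min_dist, tolerance = 1e-9)
    }
  }
})

test_that("contacts at exactly the cutoff are included, beyond excluded", {
  mk <- function(d) {
    atoms <- data.frame(
      chain_id = c("M", "P", "A", "B"), res_seq = 1L, icode = "",
      res_name = "ALA", atom_name = "CA", element = "C",
      x = c(0, d, 100, 200), y = 0, z = 0, occupancy = 1,
      stringsAsFactors = FALSE)
    structure(list(complex_id = "pair", atoms = atoms, roles = toy_roles(),
                   source = "experimental", resolution = NA_real_),
              class = "complex_structure")
  }
  expect_equal(nrow(detect_contacts(mk(7.9), "MHC", "PEPTIDE")), 1)
  expect_equal(nrow(detect_contacts(mk(8.0), "MHC", "PEPTIDE")), 1)
  expect_equal(nrow(detect_contacts(mk(8.1), "MHC", "PEPTIDE")), 0)
})

test_that("contact detection is symmetric and rigid-invariant", {
  cs <- simulate_complex("strong", synthetic_spec(), seed = 5)
  ab <- detect_contacts(cs, "MHC", "PEPTIDE")
  ba <- detect_contacts(cs, "PEPTIDE", "MHC")
  expect_equal(ab$key_a, sort(ba$key_b)[order(order(ab$key_a))] |> sort())
  m1 <- merge(ab, ba, by.x = c("key_a", "key_b"), by.y = c("key_b", "key_a"))
  expect_equal(nrow(m1), nrow(ab))
  expect_equal(m1$min_dist.x, m1$min_dist.y, tolerance = 1e-12)
  for (s in 1:3) {
    cs2 <- apply_rigid_cs(cs, random_rigid(s))
    ab2 <- detect_contacts(cs2, "MHC", "PEPTIDE")
    expect_equal(ab$key_a, ab2$key_a)
    expect_equal(ab$min_dist, ab2$min_dist, tolerance = 1e-9)
  }
})

test_that("salt-bridge flag matches an independent atom-typing scan", {
  spec <- synthetic_spec(salt_bridge_strong = 0.6)
  acid_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_n <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"))
  for (s in 1:5) {
    cs <- simulate_complex("strong", spec, seed = 100 + s)
    g <- suppressWarnings(build_zone_graph(cs, "MHC-PEP"))
    if (!tcrgraphs:::n_edges(g)) next
    akey <- paste(cs$atoms$chain_id, cs$atoms$res_seq, sep = ":")
    for (e in seq_len(tcrgraphs:::n_edges(g))) {
      nd <- g$nodes[g$edge_index[, e], ]
      ra <- cs$atoms[akey == paste(nd$chain_id[1], nd$res_seq[1], sep = ":"), ]
      rb <- cs$atoms[akey == paste(nd$chain_id[2], nd$res_seq[2], sep = ":"), ]
      found <- FALSE
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
        d <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                         as.numeric(rb[j, c("x", "y", "z")]))^2))
        ok_ij <- (ra$atom_name[i] %in% acid_o[[ra$res_name[i]]] &&
                    rb$atom_name[j] %in% base_n[[rb$res_name[j]]]) ||
          (rb$atom_name[j] %in% acid_o[[rb$res_name[j]]] &&
             ra$atom_name[i] %in% base_n[[ra$res_name[i]]])
        if (ok_ij && d < 4.0) found <- TRUE
      }
      expect_equal(unname(g$edge_feats[e, "salt_bridge"]), as.numeric(found))
    }
  }
})

test_that("Coulomb sign is negative for Asp-Lys, positive for Asp-Glu", {
  mk_res <- function(chain, res, atoms, xoff) {
    data.frame(chain_id = chain, res_seq = 1L, icode = "", res_name = res,
               atom_name = atoms,
               element = tcrgraphs:::.element_from_name(atoms),
               x = xoff + seq_along(atoms) * 0.8, y = 0, z = 0,
               occupancy = 1, stringsAsFactors = FALSE)
  }
  prm <- interaction_params()
  asp <- mk_res("M", "ASP", c("CA", "CB", "OD1", "OD2"), 0)
  lys <- mk_res("P", "LYS", c("CA", "CB", "CE", "NZ"), 5)
  glu <- mk_res("P", "GLU", c("CA", "CB", "OE1", "OE2"), 5)
  chem_lys <- tcrgraphs:::.edge_chemistry(asp, lys, prm)
  chem_glu <- tcrgraphs:::.edge_chemistry(asp, glu, prm)
  expect_lt(chem_lys[["electrostatic"]], 0)
  expect_gt(chem_glu[["electrostatic"]], 0)
})

test_that("edge distances are invariant under rigid motion", {
  cs <- simulate_complex("strong", synthetic_spec(), seed = 8)
  g <- build_complex_graph(cs)
  g2 <- build_complex_graph(apply_rigid_cs(cs, random_rigid(4)))
  expect_equal(g$edge_feats[, "dist"], g2$edge_feats[, "dist"],
               tolerance = 1e-9)
})
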
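# Shared fixture builders. Everything is generated in code at test time.

# hand-written PDB text: 4 chains (M, P, A, B), n residues each, one CA and
# one CB per residue on a regular grid
toy_pdb_text <- function(n_res = 5, spacing = 3.8, gap = 6.0) {
  fmt <- function(serial, name, res, chain, resno, x, y, z, occ = 1, alt = "") {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), alt, res, chain, resno, x, y, z, occ, 0,
            substr(name, 1, 1))
  }
  lines <- character(0); serial <- 0
  chains <- list(M = 0, P = gap, A = 2 * gap, B = 3 * gap)
  for (ch in names(chains)) {
    z <- chains[[ch]]
    for (i in seq_len(n_res)) {
      serial <- serial + 1
      lines <- c(lines, fmt(serial, "CA", "ALA", ch, i, (i - 1) * spacing, 0, z))
      serial <- serial + 1
      lines <- c(lines, fmt(serial, "CB", "ALA", ch, i, (i - 1) * spacing, 1.5,
                            z + ifelse(ch %in% c("M", "A"), 1.5, -1.5)))
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END"), collapse = "\n")
}

toy_roles <- function() chain_roles(M = "MHC", P = "PEPTIDE", A = "TCRA", B = "TCRB")

# a minimal interface graph with explicit edges, for unit tests
toy_graph <- function(n = 6, edges = rbind(c(1, 2), c(2, 3), c(4, 5)),
                      graph_id = "toy", seed = 1, coords = TRUE,
                      label = NA_character_) {
  set.seed(seed)
  sch <- feature_schema()
  aas <- sample(aa_order(), n, replace = TRUE)
  nf <- matrix(rnorm(n * length(sch$node_cols)), n,
               dimnames = list(NULL, sch$node_cols))
  nf[, grep("^aa_", sch$node_cols)] <- 0
  nf[cbind(seq_len(n), match(aas, aa_order()))] <- 1
  ei <- matrix(as.integer(t(edges)), nrow = 2)
  ne <- ncol(ei)
  ef <- matrix(rnorm(ne * length(sch$edge_cols)), ne,
               length(sch$edge_cols), dimnames = list(NULL, sch$edge_cols))
  if (ne) ef[, "dist"] <- runif(ne, 3, 8)
  new_interface_graph(
    graph_id = graph_id,
    nodes = data.frame(chain_id = "G", res_seq = seq_len(n), icode = "",
                       res_name = aas,
                       role = rep(c("MHC", "PEPTIDE", "TCRA", "TCRB"),
                                  length.out = n),
                       stringsAsFactors = FALSE),
    node_feats = nf, coords = if (coords) matrix(rnorm(n * 3), n) else NULL,
    edge_index = ei, edge_feats = ef,
    edge_zone = rep("MHC-PEP", ncol(ei)), label = label,
    provenance = "generated")
}

# random rigid transform (rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 20))
}

apply_rigid_cs <- function(cs, rig) {
  xyz <- as.matrix(cs$atoms[, c("x", "y", "z")]) %*% t(rig$R)
  xyz <- sweep(xyz, 2, rig$t, "+")
  cs$atoms$x <- xyz[, 1]; cs$atoms$y <- xyz[, 2]; cs$atoms$z <- xyz[, 3]
  cs
}

apply_rigid_graph <- function(g, rig) {
  g$coords <- sweep(g$coords %*% t(rig$R), 2, rig$t, "+")
  g
}

# small normalised planted dataset cached for classifier tests
planted_dataset <- local({
  cache <- NULL
  function(n_strong = 100, n_weak = 100, seed = 11) {
    key <- paste(n_strong, n_weak, seed)
    if (!is.null(cache) && cache$key == key) return(cache$val)
    ds <- simulate_graph_dataset(synthetic_spec(n_strong = n_strong,
                                                n_weak = n_weak, seed = seed))
    cache <<- list(key = key, val = ds)
    ds
  }
})
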
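#' Specification for synthetic TCR-pMHC-I fixtures
#'
#' Defines the study conditions emulated by the synthetic generators: chain
#' sizes, the planted interface-tightness contrast between strong- and
#' weak-binding classes, contact density, feature effect sizes and noise.
#' Strong-binding complexes are drawn with a narrower interface gap and
#' denser cross-chain packing, mirroring the qualitative contrast observed
#' between binding classes in real interfaces (denser connectivity, shorter
#' mean inter-residue distances, more salt bridges).
#'
#' @param n_strong,n_weak Number of complexes/graphs per class.
#' @param n_mhc,n_pep,n_tcr Interface residue counts per chain (MHC groove
#'   ~30, peptide 9, each TCR chain ~15).
#' @param gap_strong,gap_weak Mean inter-chain gap (Angstroms) between facing
#'   residues for the two classes; strong < weak.
#' @param density_strong,density_weak Side-chain reach multipliers
#'   controlling cross-chain contact density.
#' @param salt_bridge_strong,salt_bridge_weak Fraction of facing residue
#'   pairs planted as Asp/Glu-Lys/Arg salt bridges.
#' @param edge_dist_shift Downward shift (Angstroms) of the strong-class
#'   edge-distance feature in the direct graph generator.
#' @param vdw_shift Downward shift of the strong-class van der Waals feature
#'   in the direct graph generator (more favorable packing).
#' @param node_effect,surface_effect Class shifts for node physicochemical
#'   and surface features in the direct graph generator (0 = pure noise, so
#'   ablating those blocks is inconsequential by construction).
#' @param topo_effect Extra connection radius (Angstroms) for strong-class
#'   graphs in the direct generator (0 = class-independent topology).
#' @param graph_size_range Node-count range for the direct graph generator.
#' @param noise_sd Coordinate / feature noise standard deviation.
#' @param seed Base RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_strong = 30, n_weak = 30,
                           n_mhc = 30, n_pep = 9, n_tcr = 15,
                           gap_strong = 6.5, gap_weak = 7.6,
                           density_strong = 1.4, density_weak = 1.0,
                           salt_bridge_strong = 0.30, salt_bridge_weak = 0.05,
                           edge_dist_shift = 0.8, vdw_shift = 0.8,
                           node_effect = 0, surface_effect = 0,
                           topo_effect = 0,
                           graph_size_range = c(14, 26),
                           noise_sd = 0.3, seed = 1) {
  stopifnot(gap_strong < gap_weak, n_strong >= 1, n_weak >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# side-chain pseudo-atom names (up to 4) per residue, elements implied
.sidechain_names <- list(
  ALA = "CB", GLY = character(0), VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG", "CD"), PHE = c("CB", "CG", "CD1", "CE1"),
  MET = c("CB", "CG", "SD", "CE"), TRP = c("CB", "CG", "CD1", "NE1"),
  SER = c("CB", "OG"), THR = c("CB", "OG1", "CG2"), CYS = c("CB", "SG"),
  TYR = c("CB", "CG", "CZ", "OH"), ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "OE1", "NE2"), ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "OE1", "OE2"), LYS = c("CB", "CD", "CE", "NZ"),
  ARG = c("CB", "CD", "NE", "NH1"), HIS = c("CB", "CG", "ND1", "NE2")
)

# one synthetic chain: backbone row along +x with side-chain pseudo-atoms
# reaching `reach` Angstroms along `normal` (toward the binding partner)
.synth_chain <- function(chain_id, res_names, origin, step = c(3.6, 0, 0),
                         normal = c(0, 0, 1), reach = 1.8, noise_sd = 0.3) {
  rows <- list()
  for (i in seq_along(res_names)) {
    ca <- origin + (i - 1) * step + rnorm(3, 0, noise_sd)
    rn <- res_names[i]
    sc <- .sidechain_names[[rn]]
    nm <- c("CA", sc)
    k <- length(sc)
    coords <- rbind(ca, if (k) t(vapply(seq_len(k), function(j) {
      ca + normal * (reach * j / k) + rnorm(3, 0, noise_sd * 0.7)
    }, numeric(3))))
    rows[[i]] <- data.frame(
      chain_id = chain_id, res_seq = i, icode = "", res_name = rn,
      atom_name = nm, element = .element_from_name(nm),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a toy TCR-pMHC-I complex
#'
#' Builds four point-cloud chains: an MHC "groove" (two residue rows in the
#' z = 0 plane), a peptide lying along the groove at the class-dependent gap
#' height, and TCR alpha/beta chains docked above the peptide on either
#' side. Each residue carries a Calpha plus 1-4 side-chain pseudo-atoms
#' reaching toward the binding partner; strong-class complexes use a smaller
#' gap and longer side-chain reach, planting denser 8-Angstrom contacts.
#'
#' @param class `"strong"` or `"weak"`.
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed for this complex.
#' @param complex_id Identifier.
#' @return A `complex_structure` with roles M/P/A/B.
#' @export
simulate_complex <- function(class = c("strong", "weak"), spec = synthetic_spec(),
                             seed = spec$seed, complex_id = NULL) {
  class <- match.arg(class)
  set.seed(seed)
  if (is.null(complex_id)) complex_id <- paste0("sim_", class, "_", seed)
  gap <- if (class == "strong") spec$gap_strong else spec$gap_weak
  reach <- 1.8 * (if (class == "strong") spec$density_strong else spec$density_weak)
  sbr <- if (class == "strong") spec$salt_bridge_strong else spec$salt_bridge_weak

  aas <- aa_order()
  pep_res <- sample(aas, spec$n_pep, replace = TRUE)
  mhc_res <- sample(aas, spec$n_mhc, replace = TRUE)
  tca_res <- sample(aas, spec$n_tcr, replace = TRUE)
  tcb_res <- sample(aas, spec$n_tcr, replace = TRUE)

  # plant salt bridges on facing peptide/MHC-row positions
  half <- spec$n_mhc %/% 2
  for (i in seq_len(min(spec$n_pep, half))) {
    if (runif(1) < sbr) {
      pep_res[i] <- sample(c("ASP", "GLU"), 1)
      mhc_res[i] <- sample(c("LYS", "ARG"), 1)
    }
  }

  pep_len_A <- (spec$n_pep - 1) * 3.6
  # MHC: two rows flanking the groove at y = -4 / +4, z = 0
  m1 <- .synth_chain("M", mhc_res[seq_len(half)],
                     origin = c(0, -4, 0), normal = c(0, 0.45, 0.9),
                     reach = reach, noise_sd = spec$noise_sd)
  m2 <- .synth_chain("M", mhc_res[(half + 1):spec$n_mhc],
                     origin = c(0, 4, 0), normal = c(0, -0.45, 0.9),
                     reach = reach, noise_sd = spec$noise_sd)
  m2$res_seq <- m2$res_seq + half
  # peptide along the groove at height `gap`, side chains pointing down
  pp <- .synth_chain("P", pep_res, origin = c(0, 0, gap),
                     normal = c(0, 0, -1), reach = reach,
                     noise_sd = spec$noise_sd)
  # TCR chains above the peptide, side chains pointing down
  ta <- .synth_chain("A", tca_res,
                     origin = c(-2, -2.5, gap + spec$gap_strong),
                     step = c(pep_len_A / (spec$n_tcr - 1), 0.2, 0),
                     normal = c(0, 0.3, -0.95), reach = reach,
                     noise_sd = spec$noise_sd)
  tb <- .synth_chain("B", tcb_res,
                     origin = c(-1, 2.5, gap + spec$gap_strong),
                     step = c(pep_len_A / (spec$n_tcr - 1), -0.2, 0),
                     normal = c(0, -0.3, -0.95), reach = reach,
                     noise_sd = spec$noise_sd)
  atoms <- rbind(m1, m2, pp, ta, tb)
  atoms <- atoms[order(atoms$chain_id, atoms$res_seq, atoms$icode), ]
  rownames(atoms) <- NULL
  structure(
    list(complex_id = complex_id, atoms = atoms,
         roles = chain_roles(M = "MHC", P = "PEPTIDE", A = "TCRA", B = "TCRB"),
         source = "predicted", resolution = NA_real_),
    class = "complex_structure"
  )
}

#' Simulate a labeled interface-graph dataset
#'
#' Two generation modes. `"structure"` simulates 3D complexes via
#' [simulate_complex()] and runs the full graph-construction pipeline, so
#' class signal arises from the planted interface geometry. `"graph"` draws
#' interface graphs directly (random geometric graphs with class-shifted
#' edge features), which is faster and gives exact control over which
#' feature block carries signal: by default topology, node physicochemical
#' and surface features are class-independent and only edge features (and,
#' through the planted salt-bridge rate, edge flags) separate the classes.
#'
#' @param spec A [synthetic_spec()].
#' @param mode `"graph"` or `"structure"`.
#' @return List with `graphs` (list of `interface_graph`) and `labels`
#'   (`"strong"` / `"weak_exp"`).
#' @export
simulate_graph_dataset <- function(spec = synthetic_spec(),
                                   mode = c("graph", "structure")) {
  mode <- match.arg(mode)
  classes <- c(rep("strong", spec$n_strong), rep("weak", spec$n_weak))
  graphs <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    sd_i <- spec$seed * 10000L + i
    if (mode == "structure") {
      cs <- simulate_complex(classes[i], spec, seed = sd_i,
                             complex_id = sprintf("sim_%03d", i))
      graphs[[i]] <- build_complex_graph(cs)
    } else {
      graphs[[i]] <- .simulate_graph(classes[i], spec, seed = sd_i,
                                     graph_id = sprintf("sim_%03d", i))
    }
    graphs[[i]]$label <- ifelse(classes[i] == "strong", "strong", "weak_exp")
  }
  list(graphs = graphs,
       labels = ifelse(classes == "strong", "strong", "weak_exp"))
}

# direct graph-level generator: random geometric graph + class-shifted
# edge features; topology and node features class-independent by default
.simulate_graph <- function(class, spec, seed, graph_id) {
  set.seed(seed)
  n <- sample(spec$graph_size_range[1]:spec$graph_size_range[2], 1)
  coords <- matrix(rnorm(3 * n, 0, 4.5), ncol = 3)
  d <- as.matrix(stats::dist(coords))
  radius <- 7.0 + if (class == "strong") spec$topo_effect else 0
  adj <- d <= radius & upper.tri(d)
  ei <- which(adj, arr.ind = TRUE)
  if (nrow(ei) == 0) {  # guarantee connectivity of at least a chain
    ei <- cbind(seq_len(n - 1), 2:n)
  }
  ei <- ei[order(ei[, 1], ei[, 2]), , drop = FALSE]
  ne <- nrow(ei)
  shift_d <- if (class == "strong") spec$edge_dist_shift else 0
  shift_v <- if (class == "strong") spec$vdw_shift else 0
  sbr <- if (class == "strong") spec$salt_bridge_strong else spec$salt_bridge_weak
  dist_feat <- pmax(2.5, 6.2 - shift_d + rnorm(ne, 0, 0.8))
  ef <- cbind(
    dist = dist_feat,
    angle = runif(ne, 0, 180),
    hbond = as.numeric(runif(ne) < 0.25 + 0.5 * (class == "strong") *
                         (spec$edge_dist_shift > 0) * 0.3),
    salt_bridge = as.numeric(runif(ne) < sbr),
    hydrophobic = as.numeric(runif(ne) < 0.3),
    electrostatic = rnorm(ne, 0, 0.5) - 0.3 * (class == "strong") *
      (spec$edge_dist_shift > 0),
    vdw = rnorm(ne, -0.2, 0.5) - shift_v
  )
  aas <- sample(aa_order(), n, replace = TRUE)
  tab <- aa_table()
  onehot <- matrix(0, n, 20, dimnames = list(NULL, paste0("aa_", aa_order())))
  onehot[cbind(seq_len(n), match(aas, aa_order()))] <- 1
  shift_n <- if (class == "strong") spec$node_effect else 0
  phys <- as.matrix(tab[aas, c("charge", "hydropathy", "polarity",
                               "sidechain_volume", "pI", "mass")]) +
    matrix(rnorm(n * 6, shift_n, spec$noise_sd), n, 6)
  colnames(phys) <- c("charge", "hydropathy", "polarity",
                      "sidechain_volume", "pI", "mass")
  shift_s <- if (class == "strong") spec$surface_effect else 0
  surf <- cbind(sasa = pmax(0, rnorm(n, 60 + shift_s, 25)),
                bsa = pmax(0, rnorm(n, 30 + shift_s, 15)),
                depth = pmax(0, rnorm(n, 4, 1.5)))
  bb <- matrix(0, n, 4,
               dimnames = list(NULL, c("phi_sin", "phi_cos", "psi_sin", "psi_cos")))
  node_feats <- cbind(onehot, phys, surf, bb)
  nodes <- data.frame(chain_id = "G", res_seq = seq_len(n), icode = "",
                      res_name = aas,
                      role = rep(c("MHC", "PEPTIDE", "TCRA", "TCRB"),
                                 length.out = n),
                      stringsAsFactors = FALSE)
  new_interface_graph(
    graph_id = graph_id, nodes = nodes, node_feats = node_feats,
    coords = coords, edge_index = t(unname(ei)), edge_feats = ef,
    edge_zone = rep("MHC-PEP", ne), zone = "UNIFIED",
    label = NA_character_, provenance = "generated"
  )
}
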
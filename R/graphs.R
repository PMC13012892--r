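#' The five interface zones
#'
#' Cross-chain contact sets of a TCR-pMHC-I complex: MHC-peptide,
#' peptide-TCRalpha, peptide-TCRbeta, MHC-TCRalpha, MHC-TCRbeta.
#'
#' @return Named list mapping zone tag to its two chain roles.
#' @export
interface_zones <- function() {
  list("MHC-PEP" = c("MHC", "PEPTIDE"),
       "PEP-TCRA" = c("PEPTIDE", "TCRA"),
       "PEP-TCRB" = c("PEPTIDE", "TCRB"),
       "MHC-TCRA" = c("MHC", "TCRA"),
       "MHC-TCRB" = c("MHC", "TCRB"))
}

#' Node and edge feature schema
#'
#' Column names of the node and edge feature matrices, the continuous
#' subset that is z-score normalized (one-hot and boolean flags are left
#' untouched), and the named feature groups used by the ablation analysis.
#'
#' @return List with `node_cols`, `edge_cols`, `node_continuous`,
#'   `edge_continuous` and `groups`.
#' @export
feature_schema <- function() {
  node_cols <- c(paste0("aa_", aa_order()),
                 c("charge", "hydropathy", "polarity", "sidechain_volume",
                   "pI", "mass"),
                 c("sasa", "bsa", "depth"),
                 c("phi_sin", "phi_cos", "psi_sin", "psi_cos"))
  edge_cols <- c("dist", "angle", "hbond", "salt_bridge", "hydrophobic",
                 "electrostatic", "vdw")
  list(
    node_cols = node_cols,
    edge_cols = edge_cols,
    node_continuous = c("charge", "hydropathy", "polarity",
                        "sidechain_volume", "pI", "mass",
                        "sasa", "bsa", "depth",
                        "phi_sin", "phi_cos", "psi_sin", "psi_cos"),
    edge_continuous = c("dist", "angle", "electrostatic", "vdw"),
    groups = list(
      residue_physchem = list(node = c("charge", "hydropathy", "polarity",
                                       "sidechain_volume", "pI", "mass"),
                              edge = character(0)),
      edge_features = list(node = character(0), edge = edge_cols),
      surface_features = list(node = c("sasa", "bsa", "depth"),
                              edge = character(0))
    )
  )
}

#' Construct an interface graph
#'
#' The unit flowing through the generative and classification stages: a set
#' of residue nodes with feature vectors and optional Calpha coordinates,
#' and undirected typed edges with canonical (i < j) endpoint order.
#'
#' @param graph_id Identifier.
#' @param nodes data.frame with chain_id, res_seq, icode, res_name, role.
#' @param node_feats Numeric matrix, one row per node.
#' @param coords n x 3 matrix of Calpha coordinates, or NULL for
#'   coordinate-free (generated) graphs.
#' @param edge_index 2 x E integer matrix of node indices (1-based).
#' @param edge_feats E x F edge feature matrix.
#' @param edge_zone Character vector of zone tags per edge (multiple zones
#'   joined with `|`).
#' @param zone Zone tag of the graph, or `"UNIFIED"`.
#' @param label `"strong"`, `"weak_exp"`, `"weak_aug"` or NA.
#' @param provenance `"experimental"`, `"predicted"` or `"generated"`.
#' @return An `interface_graph` object.
#' @export
new_interface_graph <- function(graph_id, nodes, node_feats, coords,
                                edge_index, edge_feats, edge_zone,
                                zone = "UNIFIED", label = NA_character_,
                                provenance = "experimental") {
  g <- structure(
    list(graph_id = graph_id, nodes = nodes, node_feats = node_feats,
         coords = coords, edge_index = edge_index, edge_feats = edge_feats,
         edge_zone = edge_zone, zone = zone, label = label,
         provenance = provenance),
    class = "interface_graph"
  )
  validate_interface_graph(g)
  g
}

#' Validate interface-graph invariants
#'
#' Checks: no duplicate node identifiers, canonical (i < j) and unique
#' edges, edge endpoints within range, feature row counts consistent.
#'
#' @param g An `interface_graph`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_interface_graph <- function(g) {
  n <- nrow(g$nodes)
  keys <- residue_key(g$nodes$chain_id, g$nodes$res_seq, g$nodes$icode)
  if (anyDuplicated(keys)) stop("duplicate node ids in graph ", g$graph_id)
  if (nrow(g$node_feats) != n) stop("node feature row mismatch in ", g$graph_id)
  if (!is.null(g$coords) && nrow(g$coords) != n) {
    stop("coordinate row mismatch in ", g$graph_id)
  }
  ne <- ncol(g$edge_index)
  if (!is.null(g$edge_feats) && nrow(g$edge_feats) != ne) {
    stop("edge feature row mismatch in ", g$graph_id)
  }
  if (ne > 0) {
    if (any(g$edge_index < 1 | g$edge_index > n)) {
      stop("edge endpoint out of range in ", g$graph_id)
    }
    if (any(g$edge_index[1, ] >= g$edge_index[2, ])) {
      stop("edges must be canonically ordered (i < j) in ", g$graph_id)
    }
    ek <- paste(g$edge_index[1, ], g$edge_index[2, ])
    if (anyDuplicated(ek)) stop("duplicate edges in graph ", g$graph_id)
  }
  invisible(g)
}

#' @export
print.interface_graph <- function(x, ...) {
  cat(sprintf("interface_graph %s [%s]: %d nodes, %d edges%s, label=%s\n",
              x$graph_id, x$zone, nrow(x$nodes), ncol(x$edge_index),
              if (is.null(x$coords)) " (no coords)" else "",
              x$label))
  invisible(x)
}

n_nodes <- function(g) nrow(g$nodes)
n_edges <- function(g) ncol(g$edge_index)

#' Build one interface-zone graph
#'
#' Nodes are the residues of the zone's two chains participating in at
#' least one cross-chain contact within the cutoff; each contact becomes an
#' undirected edge annotated with geometric (minimum heavy-atom distance,
#' inter-residue side-chain angle), interaction-type (hydrogen bond, salt
#' bridge, hydrophobic contact) and energetic (Coulomb, Lennard-Jones)
#' features.
#'
#' @param cs A `complex_structure`.
#' @param zone One of the five zone tags (see [interface_zones()]).
#' @param cutoff_A Contact cutoff (A).
#' @param contact_atoms Heavy-atom convention, see [detect_contacts()].
#' @param params Interaction parameters ([interaction_params()]).
#' @param features Optional precomputed [complex_node_features()] (computed
#'   on the full complex so node features agree across zones).
#' @return An `interface_graph` for the zone; empty (0 nodes) with a
#'   warning if the zone has no contacts.
#' @export
build_zone_graph <- function(cs, zone, cutoff_A = 8.0,
                             contact_atoms = "all_heavy",
                             params = interaction_params(),
                             features = NULL) {
  zones <- interface_zones()
  if (!zone %in% names(zones)) stop("unknown zone: ", zone)
  roles <- zones[[zone]]
  if (is.null(features)) features <- complex_node_features(cs)
  contacts <- detect_contacts(cs, roles[1], roles[2], cutoff_A, contact_atoms)
  rt <- features$res_tab
  rkeys <- residue_key(rt$chain_id, rt$res_seq, rt$icode)
  gid <- paste0(cs$complex_id, ":", zone)
  if (!nrow(contacts)) {
    warning("zone ", zone, " of ", cs$complex_id, " has no contacts")
    return(new_interface_graph(
      graph_id = gid, nodes = rt[0, ], node_feats = features$features[0, , drop = FALSE],
      coords = features$coords[0, , drop = FALSE],
      edge_index = matrix(integer(0), 2, 0),
      edge_feats = matrix(numeric(0), 0, length(feature_schema()$edge_cols),
                          dimnames = list(NULL, feature_schema()$edge_cols)),
      edge_zone = character(0), zone = zone, provenance = cs$source
    ))
  }
  used <- sort(match(unique(c(contacts$key_a, contacts$key_b)), rkeys))
  idx_of <- stats::setNames(seq_along(used), rkeys[used])
  a <- cs$atoms
  akey <- residue_key(a$chain_id, a$res_seq, a$icode)
  ef <- matrix(0, nrow(contacts), length(feature_schema()$edge_cols),
               dimnames = list(NULL, feature_schema()$edge_cols))
  ei <- matrix(0L, 2, nrow(contacts))
  for (e in seq_len(nrow(contacts))) {
    ra <- a[akey == contacts$key_a[e], , drop = FALSE]
    rb <- a[akey == contacts$key_b[e], , drop = FALSE]
    chem <- .edge_chemistry(ra, rb, params)
    ef[e, ] <- c(contacts$min_dist[e], .edge_angle(ra, rb),
                 chem["hbond"], chem["salt_bridge"], chem["hydrophobic"],
                 chem["electrostatic"], chem["vdw"])
    pair <- sort(c(idx_of[[contacts$key_a[e]]], idx_of[[contacts$key_b[e]]]))
    ei[, e] <- pair
  }
  ord <- order(ei[1, ], ei[2, ])
  new_interface_graph(
    graph_id = gid, nodes = rt[used, , drop = FALSE],
    node_feats = features$features[used, , drop = FALSE],
    coords = features$coords[used, , drop = FALSE],
    edge_index = ei[, ord, drop = FALSE],
    edge_feats = ef[ord, , drop = FALSE],
    edge_zone = rep(zone, nrow(contacts)),
    zone = zone, provenance = cs$source
  )
}

#' Merge zone graphs into the unified interface graph
#'
#' Nodes with identical chain identifier, residue number and insertion code
#' are consolidated (their features must agree exactly across zones, which
#' holds by construction since features are computed on the full complex);
#' redundant edges are removed, retaining the union of zone tags per edge.
#'
#' @param graphs List of `interface_graph`s from the same complex.
#' @param graph_id Identifier for the merged graph (default: complex id).
#' @return A unified `interface_graph`.
#' @export
merge_zone_graphs <- function(graphs, graph_id = NULL) {
  graphs <- Filter(function(g) n_nodes(g) > 0, graphs)
  if (!length(graphs)) stop("no non-empty zone graphs to merge")
  if (is.null(graph_id)) graph_id <- sub(":[^:]*$", "", graphs[[1]]$graph_id)
  all_nodes <- do.call(rbind, lapply(graphs, `[[`, "nodes"))
  all_keys <- residue_key(all_nodes$chain_id, all_nodes$res_seq, all_nodes$icode)
  all_feats <- do.call(rbind, lapply(graphs, `[[`, "node_feats"))
  all_coords <- do.call(rbind, lapply(graphs, `[[`, "coords"))
  ord <- order(all_nodes$chain_id, all_nodes$res_seq, all_nodes$icode)
  first <- ord[!duplicated(all_keys[ord])]
  # assert feature consistency for consolidated nodes
  for (k in unique(all_keys[duplicated(all_keys)])) {
    rows <- which(all_keys == k)
    if (max(abs(sweep(all_feats[rows, , drop = FALSE], 2,
                      all_feats[rows[1], ]))) > 1e-9) {
      stop("conflicting features across zones for node ", k)
    }
  }
  nodes <- all_nodes[first, , drop = FALSE]
  rownames(nodes) <- NULL
  keys <- all_keys[first]
  idx_of <- stats::setNames(seq_along(keys), keys)

  edges <- list()
  for (g in graphs) {
    gkeys <- residue_key(g$nodes$chain_id, g$nodes$res_seq, g$nodes$icode)
    if (!n_edges(g)) next
    for (e in seq_len(n_edges(g))) {
      i <- idx_of[[gkeys[g$edge_index[1, e]]]]
      j <- idx_of[[gkeys[g$edge_index[2, e]]]]
      pair <- sort(c(i, j))
      ek <- paste(pair[1], pair[2])
      if (is.null(edges[[ek]])) {
        edges[[ek]] <- list(i = pair[1], j = pair[2],
                            feats = g$edge_feats[e, ],
                            zones = g$edge_zone[e])
      } else {
        edges[[ek]]$zones <- paste(sort(unique(c(
          strsplit(edges[[ek]]$zones, "|", fixed = TRUE)[[1]], g$edge_zone[e]
        ))), collapse = "|")
      }
    }
  }
  ei <- vapply(edges, function(e) c(e$i, e$j), integer(2))
  ord_e <- order(ei[1, ], ei[2, ])
  new_interface_graph(
    graph_id = graph_id, nodes = nodes,
    node_feats = all_feats[first, , drop = FALSE],
    coords = if (is.null(all_coords)) NULL else all_coords[first, , drop = FALSE],
    edge_index = ei[, ord_e, drop = FALSE],
    edge_feats = do.call(rbind, lapply(edges, `[[`, "feats"))[ord_e, , drop = FALSE],
    edge_zone = vapply(edges, `[[`, character(1), "zones")[ord_e],
    zone = "UNIFIED", label = graphs[[1]]$label,
    provenance = graphs[[1]]$provenance
  )
}

#' Build the unified interface graph of a complex
#'
#' Convenience wrapper: builds all five zone graphs (computing node
#' features once on the full complex) and merges them.
#'
#' @inheritParams build_zone_graph
#' @return A unified `interface_graph`.
#' @export
build_complex_graph <- function(cs, cutoff_A = 8.0, contact_atoms = "all_heavy",
                                params = interaction_params()) {
  features <- complex_node_features(cs)
  gs <- lapply(names(interface_zones()), function(z) {
    suppressWarnings(build_zone_graph(cs, z, cutoff_A, contact_atoms,
                                      params, features))
  })
  merge_zone_graphs(gs, graph_id = cs$complex_id)
}

#' Fit and apply z-score normalization of continuous features
#'
#' Statistics (per-feature mean and standard deviation) are fit on the
#' training graphs only and applied to both sets. One-hot and boolean
#' columns are untouched; zero-variance features are left unscaled and
#' flagged in the returned statistics.
#'
#' @param train_graphs Non-empty list of graphs defining the fit scope.
#' @param apply_graphs Further graphs to transform with the train-fit
#'   statistics (default none).
#' @return List with `stats` (a `normalization_stats` object), `train`
#'   (transformed training graphs) and `apply` (transformed apply graphs).
#' @export
normalize_features <- function(train_graphs, apply_graphs = list()) {
  stopifnot(length(train_graphs) > 0)
  sch <- feature_schema()
  pool <- function(graphs, what) do.call(rbind, lapply(graphs, `[[`, what))
  nf <- pool(train_graphs, "node_feats")
  ef <- pool(train_graphs, "edge_feats")
  fit_block <- function(m, cols) {
    cols <- intersect(cols, colnames(m))
    mu <- colMeans(m[, cols, drop = FALSE])
    sg <- apply(m[, cols, drop = FALSE], 2, stats::sd)
    sg[is.na(sg)] <- 0
    list(cols = cols, mean = mu, sd = sg, constant = sg == 0)
  }
  st <- structure(
    list(node = fit_block(nf, sch$node_continuous),
         edge = fit_block(ef, sch$edge_continuous),
         scope = paste0("fit on ", length(train_graphs), " graphs")),
    class = "normalization_stats"
  )
  list(stats = st,
       train = lapply(train_graphs, apply_normalization, stats = st),
       apply = lapply(apply_graphs, apply_normalization, stats = st))
}

#' Apply fitted normalization statistics to a graph
#' @param g An `interface_graph`.
#' @param stats A `normalization_stats` object from [normalize_features()].
#' @return The transformed graph.
#' @export
apply_normalization <- function(g, stats) {
  tr <- function(m, blk) {
    cols <- intersect(blk$cols, colnames(m))
    for (cn in cols) {
      if (!blk$constant[[cn]]) {
        m[, cn] <- (m[, cn] - blk$mean[[cn]]) / blk$sd[[cn]]
      }
    }
    m
  }
  g$node_feats <- tr(g$node_feats, stats$node)
  if (nrow(g$edge_feats)) g$edge_feats <- tr(g$edge_feats, stats$edge)
  g
}

#' Remove a feature group from graphs (ablation)
#'
#' Drops the named feature block's columns from node and/or edge feature
#' matrices, end to end (the classifier then never sees them).
#'
#' @param graphs List of `interface_graph`s.
#' @param group One of `"residue_physchem"`, `"edge_features"`,
#'   `"surface_features"`, or `"none"` for a no-op.
#' @return The reduced graphs.
#' @export
ablate_feature_group <- function(graphs, group) {
  if (group == "none") return(graphs)
  sch <- feature_schema()
  if (!group %in% names(sch$groups)) stop("unknown feature group: ", group)
  blk <- sch$groups[[group]]
  lapply(graphs, function(g) {
    if (length(blk$node)) {
      g$node_feats <- g$node_feats[, setdiff(colnames(g$node_feats), blk$node),
                                   drop = FALSE]
    }
    if (length(blk$edge)) {
      keep <- setdiff(colnames(g$edge_feats), blk$edge)
      g$edge_feats <- g$edge_feats[, keep, drop = FALSE]
    }
    g
  })
}
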
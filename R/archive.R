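#' Write interface graphs to a JSON archive
#'
#' Single-file archive with one entry per graph containing metadata plus
#' the node-feature matrix, node identifiers, coordinates, edge index and
#' edge-feature matrix. Layout per graph:
#' `graphs/<id>/{meta, node_ids, node_features, coords, edge_index,
#' edge_features}`. Floating-point values are stored at full precision.
#'
#' @param graphs List of `interface_graph`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_archive <- function(graphs, path) {
  ids <- vapply(graphs, `[[`, character(1), "graph_id")
  if (anyDuplicated(ids)) stop("duplicate graph ids in archive")
  entries <- lapply(graphs, function(g) {
    list(
      meta = list(graph_id = g$graph_id, zone = g$zone,
                  label = g$label, provenance = g$provenance,
                  n_nodes = nrow(g$nodes), n_edges = ncol(g$edge_index)),
      node_ids = g$nodes,
      node_features = list(colnames = colnames(g$node_feats),
                           values = unclass(g$node_feats)),
      coords = g$coords,
      edge_index = g$edge_index,
      edge_features = list(colnames = colnames(g$edge_feats),
                           values = unclass(g$edge_feats)),
      edge_zone = g$edge_zone
    )
  })
  names(entries) <- ids
  obj <- list(format = "tcrgraphs-archive", version = 1L, graphs = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.as_matrix <- function(x, ncol_hint = NULL, colnames = NULL) {
  if (is.null(x) || (is.list(x) && !length(x))) {
    m <- matrix(numeric(0), 0, ifelse(is.null(ncol_hint), 0, ncol_hint))
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, unlist))
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(colnames) && length(colnames) == ncol(m)) colnames(m) <- colnames
  m
}

#' Read a graph archive written by [write_graph_archive()]
#'
#' @param path Archive file.
#' @return Named list of `interface_graph`s.
#' @export
read_graph_archive <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("corrupt graph archive ", path, ": ",
                         conditionMessage(e))
                  })
  if (!identical(obj$format, "tcrgraphs-archive")) {
    stop("not a tcrgraphs archive: ", path)
  }
  out <- lapply(names(obj$graphs), function(id) {
    e <- obj$graphs[[id]]
    need <- c("meta", "node_ids", "node_features", "edge_index",
              "edge_features")
    miss <- setdiff(need, names(e))
    if (length(miss)) {
      stop("corrupt archive: graph '", id, "' missing field(s) ",
           paste(miss, collapse = ", "))
    }
    nf <- .as_matrix(e$node_features$values,
                     colnames = e$node_features$colnames)
    ef <- .as_matrix(e$edge_features$values,
                     ncol_hint = length(e$edge_features$colnames),
                     colnames = e$edge_features$colnames)
    ei <- .as_matrix(e$edge_index)
    if (!nrow(ei)) ei <- matrix(integer(0), 2, 0)
    storage.mode(ei) <- "integer"
    nodes <- as.data.frame(e$node_ids, stringsAsFactors = FALSE)
    nodes$res_seq <- as.integer(nodes$res_seq)
    if (nrow(nf) != e$meta$n_nodes || ncol(ei) != e$meta$n_edges) {
      stop("corrupt archive: graph '", id, "' count mismatch with metadata")
    }
    coords <- if (is.null(e$coords) || !length(e$coords)) NULL else .as_matrix(e$coords)
    new_interface_graph(
      graph_id = e$meta$graph_id, nodes = nodes, node_feats = nf,
      coords = coords, edge_index = ei, edge_feats = ef,
      edge_zone = as.character(e$edge_zone %||% character(0)),
      zone = e$meta$zone,
      label = if (is.null(e$meta$label)) NA_character_ else e$meta$label,
      provenance = e$meta$provenance
    )
  })
  names(out) <- names(obj$graphs)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
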
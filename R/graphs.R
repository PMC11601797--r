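# ---------------------------------------------------------------------------
# Molecular graph construction: a documented 28-slot atom feature schema,
# 2D bond graphs and 3D distance-cutoff graphs. Heavy atoms only;
# hydrogens enter the features as attached-H counts.
# ---------------------------------------------------------------------------

#' Graph configuration
#'
#' @param distance_cutoff edge threshold in Angstrom for 3D graphs
#'   (default 6; a pair exactly at the cutoff is connected).
#' @param include_hydrogens reserved; the current featurizer always works
#'   on the heavy-atom graph with implicit hydrogens.
#' @return object of class `graph_config`.
#' @export
graph_config <- function(distance_cutoff = 6.0, include_hydrogens = FALSE) {
  stopifnot(distance_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 include_hydrogens = isTRUE(include_hydrogens)),
            class = "graph_config")
}

.FEATURE_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                       "Se", "Br", "I", "other")

#' The 28-slot atom feature schema
#'
#' Returns the slot layout of the node feature matrix: a 13-way element
#' one-hot (12 organic elements + `other`), a 5-way heavy-atom degree
#' one-hot (0, 1, 2, 3, >=4), a 4-way attached-hydrogen one-hot (0, 1, 2,
#' >=3), a 3-way hybridization one-hot (sp, sp2, sp3; anything else is
#' all-zero), the formal charge as a signed numeric slot, an aromaticity
#' flag and a ring-membership flag — 28 slots in total. The schema is an
#' in-package design (schema version 1), documented here rather than
#' inherited from any external feature set.
#'
#' @return data.frame with columns `slot`, `group`, `meaning`.
#' @export
atom_feature_schema <- function() {
  rbind(
    data.frame(group = "element", meaning = paste0("element=", .FEATURE_ELEMENTS),
               stringsAsFactors = FALSE),
    data.frame(group = "degree", meaning = paste0("degree=", c("0", "1", "2", "3", ">=4")),
               stringsAsFactors = FALSE),
    data.frame(group = "n_hydrogens", meaning = paste0("numH=", c("0", "1", "2", ">=3")),
               stringsAsFactors = FALSE),
    data.frame(group = "hybridization", meaning = paste0("hyb=", c("sp", "sp2", "sp3")),
               stringsAsFactors = FALSE),
    data.frame(group = "formal_charge", meaning = "formal charge (signed)",
               stringsAsFactors = FALSE),
    data.frame(group = "aromatic", meaning = "aromatic atom flag",
               stringsAsFactors = FALSE),
    data.frame(group = "in_ring", meaning = "ring membership flag",
               stringsAsFactors = FALSE)
  ) -> sch
  sch$slot <- seq_len(nrow(sch))
  sch[, c("slot", "group", "meaning")]
}

# ring atoms / ring bonds of a heavy-atom graph: an edge is a ring bond
# iff it is not a bridge
.ring_membership <- function(n_atoms, bonds) {
  if (!nrow(bonds)) {
    return(list(atoms = logical(n_atoms), bonds = logical(0)))
  }
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  ring_bond <- !seq_len(nrow(bonds)) %in% as.integer(br)
  ring_atom <- logical(n_atoms)
  ring_atom[c(bonds[ring_bond, 1], bonds[ring_bond, 2])] <- TRUE
  list(atoms = ring_atom, bonds = ring_bond)
}

.hyb_from_mol2 <- function(types) {
  suffix <- sub("^[A-Za-z]+\\.", "", types)
  suffix[!grepl(".", types, fixed = TRUE)] <- ""
  hyb <- rep(NA_character_, length(types))
  hyb[suffix == "1"] <- "sp"
  hyb[suffix %in% c("2", "ar", "am", "pl3", "cat", "co2")] <- "sp2"
  hyb[suffix %in% c("3", "4", "o", "o2")] <- "sp3"
  hyb
}

#' 28-dimensional atom feature matrix
#'
#' One row per heavy atom, columns following [atom_feature_schema()].
#' Elements outside the schema's organic set map to the `other` slot with
#' a warning.
#'
#' @param smiles a single SMILES string.
#' @return numeric matrix `n_atoms x 28` with schema slot names.
#' @export
atom_feature_matrix <- function(smiles) {
  stopifnot(length(smiles) == 1)
  p <- parse_smiles(smiles)
  if (!p$ok[1]) stop("cannot parse SMILES: ", smiles)
  mol <- p$sdf[[1]]
  el <- .sdf_element(mol)
  ch <- .sdf_charges(mol)
  bonds <- .sdf_bonds(mol)
  n <- length(el)
  deg <- numeric(n)
  if (nrow(bonds)) {
    tab <- tabulate(c(bonds[, 1], bonds[, 2]), n)
    deg <- tab
  }
  hcount <- .implicit_h(mol)
  types <- .mol2_atom_types(p$sdf)[[1]]
  hyb <- if (length(types) == n) .hyb_from_mol2(types)
         else rep(NA_character_, n)
  aromatic <- if (length(types) == n) grepl("\\.ar$", types)
              else rep(FALSE, n)
  rings <- .ring_membership(n, bonds)

  el_slot <- match(el, .FEATURE_ELEMENTS)
  if (anyNA(el_slot)) {
    warning("element(s) outside feature schema mapped to 'other': ",
            paste(unique(el[is.na(el_slot)]), collapse = ", "))
    el_slot[is.na(el_slot)] <- match("other", .FEATURE_ELEMENTS)
  }
  m <- matrix(0, nrow = n, ncol = 28)
  m[cbind(seq_len(n), el_slot)] <- 1
  m[cbind(seq_len(n), 13 + pmin(deg, 4) + 1)] <- 1
  m[cbind(seq_len(n), 18 + pmin(hcount, 3) + 1)] <- 1
  hyb_slot <- match(hyb, c("sp", "sp2", "sp3"))
  ok_h <- !is.na(hyb_slot)
  m[cbind(which(ok_h), 22 + hyb_slot[ok_h])] <- 1
  m[, 26] <- ch
  m[, 27] <- as.numeric(aromatic)
  m[, 28] <- as.numeric(rings$atoms)
  colnames(m) <- c(paste0("el_", .FEATURE_ELEMENTS),
                   paste0("deg_", c(0:3, "4p")),
                   paste0("numH_", c(0:2, "3p")),
                   paste0("hyb_", c("sp", "sp2", "sp3")),
                   "formal_charge", "aromatic", "in_ring")
  rownames(m) <- paste0(el, "_", seq_len(n))
  m
}

.new_mol_graph <- function(node_features, edges, edge_features = NULL,
                           positions = NULL, dimensionality = "2D") {
  stopifnot(ncol(node_features) == 28)
  if (nrow(edges)) {
    stopifnot(all(edges >= 1), all(edges <= nrow(node_features)),
              all(edges[, 1] != edges[, 2]))
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    stopifnot(!anyDuplicated(key))
  }
  if (dimensionality == "3D") stopifnot(!is.null(positions))
  structure(list(node_features = node_features, edges = edges,
                 edge_features = edge_features, positions = positions,
                 dimensionality = dimensionality), class = "mol_graph")
}

#' 2D molecular graph (bond connectivity)
#'
#' Nodes are heavy atoms with 28-slot features; one undirected edge per
#' covalent bond, with edge features bond order, aromatic flag and
#' ring-bond flag. Multi-component (mixture) SMILES are rejected —
#' mixtures must be resolved before featurization.
#'
#' @param smiles a single SMILES string.
#' @return object of class `mol_graph`.
#' @export
build_graph_2d <- function(smiles) {
  stopifnot(length(smiles) == 1)
  if (lengths(smiles_components(smiles)) > 1) {
    stop("disconnected (multi-component) molecule; resolve mixtures first")
  }
  p <- parse_smiles(smiles)
  if (!p$ok[1]) stop("cannot parse SMILES: ", smiles)
  mol <- p$sdf[[1]]
  feats <- atom_feature_matrix(smiles)
  bonds <- .sdf_bonds(mol)
  rings <- .ring_membership(nrow(feats), bonds)
  aromatic_atom <- feats[, "aromatic"] > 0
  edges <- cbind(from = as.integer(bonds[, 1]), to = as.integer(bonds[, 2]))
  efeat <- if (nrow(bonds)) {
    arom_bond <- rings$bonds & aromatic_atom[bonds[, 1]] &
      aromatic_atom[bonds[, 2]]
    cbind(order = ifelse(arom_bond, 1.5, bonds[, "order"]),
          aromatic = as.numeric(arom_bond),
          in_ring = as.numeric(rings$bonds))
  } else {
    matrix(numeric(0), ncol = 3,
           dimnames = list(NULL, c("order", "aromatic", "in_ring")))
  }
  .new_mol_graph(feats, edges, efeat, dimensionality = "2D")
}

#' 3D molecular graph (distance cutoff)
#'
#' Nodes are heavy atoms with 28-slot features; an undirected edge joins
#' every atom pair whose Euclidean distance is at most the cutoff
#' (boundary included). Coordinates are stored verbatim as `positions`.
#'
#' @param smiles a single SMILES string (defines atoms and features).
#' @param coordinates numeric `n_atoms x 3` matrix of positions in
#'   Angstrom, rows in atom order.
#' @param config a [graph_config()].
#' @return object of class `mol_graph`.
#' @export
build_graph_3d <- function(smiles, coordinates, config = graph_config()) {
  feats <- atom_feature_matrix(smiles)
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(feats) || ncol(coordinates) != 3) {
    stop("coordinate matrix must be ", nrow(feats), " x 3, got ",
         nrow(coordinates), " x ", ncol(coordinates))
  }
  edges <- distance_edges(coordinates, config$distance_cutoff)
  .new_mol_graph(feats, edges, positions = coordinates,
                 dimensionality = "3D")
}

#' Distance-cutoff edge list of a point cloud
#'
#' @param coordinates numeric `n x 3` matrix.
#' @param cutoff distance threshold (edges at exactly the cutoff are
#'   included).
#' @return two-column integer matrix of undirected edges (`from < to`).
#' @export
distance_edges <- function(coordinates, cutoff = 6.0) {
  d <- as.matrix(stats::dist(coordinates))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]))
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("Molecular graph (%s): %d nodes, %d edges\n",
              x$dimensionality, nrow(x$node_features), nrow(x$edges)))
  invisible(x)
}

#' Serialize a molecular graph to JSON
#'
#' @param graph a `mol_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mol_graph <- function(graph, path) {
  jsonlite::write_json(list(
    schema_version = 1L,
    dimensionality = graph$dimensionality,
    node_features = graph$node_features,
    edges = graph$edges,
    edge_features = graph$edge_features,
    positions = graph$positions
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
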
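## Molecular graphs with two distinct edge sets: covalent (bond-derived,
## bond-order one-hot features) and non-covalent (distance-derived, Gaussian
## radial-basis features). Both sets are stored symmetrically (i->j and
## j->i) so message passing is directionless.

.element_slots <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "other")

#' Atom feature layout
#'
#' The fixed 28-dimensional per-atom feature vector: element one-hot (11,
#' with an "other" bucket), degree one-hot (0-6), formal-charge one-hot
#' (-2..+2, clamped), aromatic flag (1), origin one-hot (ligand/pocket, 2),
#' and a 2-bucket saturation flag standing in for hybridization.
#'
#' @return Integer, the feature dimension (28).
#' @export
atom_feature_dim <- function() {
  length(.element_slots) + 7L + 5L + 1L + 2L + 2L
}

#' Featurize one atom
#'
#' @param element Element symbol; unknown elements map to the "other" slot.
#' @param formal_charge Integer formal charge (clamped to -2..+2).
#' @param degree Number of covalent neighbors (clamped to 0..6).
#' @param aromatic Logical aromaticity flag.
#' @param origin `"ligand"` or `"pocket"`.
#' @param unsaturated Logical; participates in a multiple/aromatic bond.
#'   Defaults to the aromatic flag.
#' @return Numeric vector of length [atom_feature_dim()].
#' @export
featurize_atom <- function(element, formal_charge = 0L, degree = 0L,
                           aromatic = FALSE, origin = c("ligand", "pocket"),
                           unsaturated = aromatic) {
  origin <- match.arg(origin)
  el <- if (element %in% .element_slots) element else "other"
  v <- numeric(atom_feature_dim())
  off <- 0L
  v[off + match(el, .element_slots)] <- 1; off <- off + length(.element_slots)
  v[off + 1L + max(0L, min(6L, as.integer(degree)))] <- 1; off <- off + 7L
  v[off + 3L + max(-2L, min(2L, as.integer(formal_charge)))] <- 1; off <- off + 5L
  v[off + 1L] <- as.numeric(aromatic); off <- off + 1L
  v[off + match(origin, c("ligand", "pocket"))] <- 1; off <- off + 2L
  v[off + 1L + as.integer(isTRUE(unsaturated))] <- 1
  v
}

# Gaussian radial basis expansion of distances on [0, cutoff].
rbf_expand <- function(x, n_basis, xmax, xmin = 0) {
  centers <- seq(xmin, xmax, length.out = n_basis)
  width <- centers[2] - centers[1]
  exp(-outer(x, centers, "-")^2 / (2 * width^2))
}

.bond_order_onehot <- function(order) {
  slots <- c(1, 2, 3, 4)  # single, double, triple, aromatic; else "other"
  M <- matrix(0, length(order), 5L)
  idx <- match(order, slots)
  for (k in seq_along(order))
    M[k, if (is.na(idx[k])) 5L else idx[k]] <- 1
  M
}

# Per-atom derived flags from a ligand's bond list.
.ligand_atom_props <- function(lig) {
  n <- length(lig$elements)
  degree <- integer(n); aromatic <- logical(n); unsat <- logical(n)
  b <- lig$bonds
  for (k in seq_len(nrow(b))) {
    degree[b$i[k]] <- degree[b$i[k]] + 1L
    degree[b$j[k]] <- degree[b$j[k]] + 1L
    if (b$order[k] == 4) aromatic[c(b$i[k], b$j[k])] <- TRUE
    if (b$order[k] > 1) unsat[c(b$i[k], b$j[k])] <- TRUE
  }
  list(degree = degree, aromatic = aromatic, unsaturated = unsat)
}

# Unordered atom pairs excluded from non-covalent edges: bonded (1-2) and
# separated by two bonds (1-3).
.excluded_pairs <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  keys <- character(0)
  for (k in seq_len(nrow(bonds)))
    keys <- c(keys, paste(pmin(bonds$i[k], bonds$j[k]),
                          pmax(bonds$i[k], bonds$j[k])))
  for (c_at in seq_len(n)) {
    nb <- adj[[c_at]]
    if (length(nb) >= 2) {
      pr <- utils::combn(sort(nb), 2)
      keys <- c(keys, paste(pr[1, ], pr[2, ]))
    }
  }
  unique(keys)
}

.symmetrize <- function(src, dst, feat) {
  list(src = c(src, dst), dst = c(dst, src),
       feat = rbind(feat, feat))
}

.new_graph <- function(node_features, coords, origin, cov, nc, kind) {
  structure(list(
    n = nrow(node_features),
    node_features = node_features,
    coords = coords,
    node_origin = origin,
    cov_src = cov$src, cov_dst = cov$dst, cov_feat = cov$feat,
    nc_src = nc$src, nc_dst = nc$dst, nc_feat = nc$feat,
    nc_dist = nc$dist,
    kind = kind  # "ligand" or "complex"
  ), class = "alch_graph")
}

#' Build the graph of a ligand alone
#'
#' Covalent edges come from the bond list; non-covalent edges connect atom
#' pairs within the cutoff that are neither bonded (1-2) nor two bonds
#' apart (1-3).
#'
#' @param ligand `alch_ligand`.
#' @param cutoff Non-covalent distance cutoff in Angstrom (default 4.5).
#' @param n_dist_basis Number of Gaussian basis functions for non-covalent
#'   edge features (default 16).
#' @return An `alch_graph` with `kind = "ligand"`.
#' @export
build_ligand_graph <- function(ligand, cutoff = 4.5, n_dist_basis = 16L) {
  n <- length(ligand$elements)
  props <- .ligand_atom_props(ligand)
  X <- t(vapply(seq_len(n), function(a)
    featurize_atom(ligand$elements[a], ligand$formal_charges[a],
                   props$degree[a], props$aromatic[a], "ligand",
                   props$unsaturated[a]),
    numeric(atom_feature_dim())))
  X <- matrix(X, nrow = n)
  cov <- .symmetrize(ligand$bonds$i, ligand$bonds$j,
                     .bond_order_onehot(ligand$bonds$order))
  nc <- .intra_noncov(ligand, cutoff, n_dist_basis)
  .new_graph(X, ligand$coords, rep("ligand", n), cov, nc, "ligand")
}

.intra_noncov <- function(ligand, cutoff, n_basis) {
  n <- length(ligand$elements)
  src <- integer(0); dst <- integer(0); dd <- numeric(0)
  if (n >= 2) {
    D <- as.matrix(stats::dist(ligand$coords))
    excl <- .excluded_pairs(n, ligand$bonds)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (D[a, b] <= cutoff && !(paste(a, b) %in% excl)) {
        src <- c(src, a); dst <- c(dst, b); dd <- c(dd, D[a, b])
      }
    }
  }
  feat <- if (length(dd) > 0) rbf_expand(dd, n_basis, cutoff) else
    matrix(0, 0, n_basis)
  s <- .symmetrize(src, dst, feat)
  s$dist <- c(dd, dd)
  s
}

#' Build the graph of a protein-ligand complex
#'
#' Ligand nodes keep their covalent and intramolecular non-covalent edges;
#' pocket nodes carry covalent edges inferred from interatomic distances
#' (<= 1.85 Angstrom heavy-heavy, <= 1.2 Angstrom for X-H); ligand-pocket
#' non-covalent edges connect every cross pair within the cutoff. Pocket
#' internal non-covalent edges are excluded.
#'
#' @param cx `alch_complex` from [complex_structure()].
#' @param cutoff Non-covalent cutoff in Angstrom (default 4.5).
#' @param n_dist_basis Gaussian basis size for distances (default 16).
#' @return An `alch_graph` with `kind = "complex"`.
#' @export
build_complex_graph <- function(cx, cutoff = 4.5, n_dist_basis = 16L) {
  lig <- cx$ligand
  pocket <- cx$pocket
  if (nrow(pocket) == 0)
    alch_stop("empty pocket", "alch_empty_pocket_error")
  nl <- length(lig$elements); np <- nrow(pocket)
  lg <- build_ligand_graph(lig, cutoff, n_dist_basis)

  pk_coords <- cbind(pocket$x, pocket$y, pocket$z)
  pk_bonds <- .pocket_covalent(pocket$element, pk_coords)
  pk_degree <- integer(np)
  for (k in seq_len(nrow(pk_bonds))) {
    pk_degree[pk_bonds$i[k]] <- pk_degree[pk_bonds$i[k]] + 1L
    pk_degree[pk_bonds$j[k]] <- pk_degree[pk_bonds$j[k]] + 1L
  }
  Xp <- t(vapply(seq_len(np), function(a)
    featurize_atom(pocket$element[a], 0L, pk_degree[a], FALSE, "pocket", FALSE),
    numeric(atom_feature_dim())))
  Xp <- matrix(Xp, nrow = np)

  cov_p <- .symmetrize(pk_bonds$i + nl, pk_bonds$j + nl,
                       .bond_order_onehot(rep(1, nrow(pk_bonds))))
  ## cross ligand-pocket non-covalent edges
  cl <- lig$coords
  d2 <- outer(rowSums(cl^2), rowSums(pk_coords^2), "+") -
    2 * cl %*% t(pk_coords)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  cross_d <- sqrt(pmax(d2[hit], 0))
  cross_feat <- if (length(cross_d) > 0) rbf_expand(cross_d, n_dist_basis, cutoff) else
    matrix(0, 0, n_dist_basis)
  cross <- .symmetrize(hit[, 1], hit[, 2] + nl, cross_feat)
  cross$dist <- c(cross_d, cross_d)

  .new_graph(
    rbind(lg$node_features, Xp),
    rbind(cl, pk_coords),
    c(rep("ligand", nl), rep("pocket", np)),
    list(src = c(lg$cov_src, cov_p$src), dst = c(lg$cov_dst, cov_p$dst),
         feat = rbind(lg$cov_feat, cov_p$feat)),
    list(src = c(lg$nc_src, cross$src), dst = c(lg$nc_dst, cross$dst),
         feat = rbind(lg$nc_feat, cross$feat),
         dist = c(lg$nc_dist, cross$dist)),
    "complex")
}

# Distance-heuristic covalent bonds inside the pocket (no residue template
# library is used; toy and real pockets are treated alike).
.pocket_covalent <- function(elements, coords) {
  n <- nrow(coords)
  src <- integer(0); dst <- integer(0)
  if (n >= 2) {
    D <- as.matrix(stats::dist(coords))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      thr <- if (elements[a] == "H" || elements[b] == "H") 1.2 else 1.85
      if (D[a, b] <= thr) { src <- c(src, a); dst <- c(dst, b) }
    }
  }
  data.frame(i = src, j = dst)
}

#' @export
print.alch_graph <- function(x, ...) {
  cat(sprintf(
    "<alch_graph (%s): %d nodes, %d covalent, %d non-covalent directed edges>\n",
    x$kind, x$n, length(x$cov_src), length(x$nc_src)))
  invisible(x)
}

#' Pair two endpoint graphs
#'
#' `kind = "complex-pair"` (RBFE) requires pocket nodes in both graphs;
#' `kind = "complex-ligand-pair"` (ABFE) requires pocket nodes in exactly
#' one.
#'
#' @param graph_a,graph_b `alch_graph` endpoint graphs.
#' @param kind `"complex-pair"` or `"complex-ligand-pair"`.
#' @return Object of class `alch_graph_pair`.
#' @export
graph_pair <- function(graph_a, graph_b,
                       kind = c("complex-pair", "complex-ligand-pair")) {
  kind <- match.arg(kind)
  has_pocket <- function(g) any(g$node_origin == "pocket")
  if (kind == "complex-pair" && !(has_pocket(graph_a) && has_pocket(graph_b)))
    alch_stop("complex-pair requires pocket nodes in both graphs",
              "alch_pair_error")
  if (kind == "complex-ligand-pair" &&
      sum(c(has_pocket(graph_a), has_pocket(graph_b))) != 1L)
    alch_stop("complex-ligand-pair requires pocket nodes in exactly one graph",
              "alch_pair_error")
  structure(list(graph_a = graph_a, graph_b = graph_b, kind = kind),
            class = "alch_graph_pair")
}

#' Dump a graph as JSON for inspection
#'
#' @param graph `alch_graph`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(list(
    kind = graph$kind,
    n = graph$n,
    node_origin = graph$node_origin,
    node_features = graph$node_features,
    coords = graph$coords,
    covalent_edges = data.frame(src = graph$cov_src, dst = graph$cov_dst),
    noncovalent_edges = data.frame(src = graph$nc_src, dst = graph$nc_dst,
                                   dist = graph$nc_dist)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
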
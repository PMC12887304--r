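## Maximum common connected induced substructure between two ligands,
## on heavy atoms, matching element symbols and bond orders. Exact
## branch-and-bound search: mappings grow only through atoms adjacent to
## the current common fragment (connectedness), every new pair must be
## consistent with all mapped pairs (induced: bond present with equal
## order in both, or absent in both), and branches that cannot beat the
## incumbent are pruned. A node-expansion cap bounds worst-case inputs;
## within the cap the result is exact.

.heavy_graph <- function(lig) {
  heavy <- which(lig$elements != "H")
  remap <- integer(length(lig$elements)); remap[heavy] <- seq_along(heavy)
  b <- lig$bonds
  keep <- b$i %in% heavy & b$j %in% heavy
  n <- length(heavy)
  adj <- matrix(0, n, n)
  for (k in which(keep)) {
    i <- remap[b$i[k]]; j <- remap[b$j[k]]
    adj[i, j] <- b$order[k]; adj[j, i] <- b$order[k]
  }
  list(el = lig$elements[heavy], adj = adj, n = n)
}

#' Maximum common substructure size between two ligands
#'
#' Size (heavy-atom count) of the largest connected induced substructure
#' common to both ligands, with element and bond-order matching.
#'
#' @param lig_a,lig_b `alch_ligand` objects.
#' @param max_nodes Branch-and-bound node-expansion cap (default 2e5);
#'   past the cap the best mapping found so far is returned.
#' @return Integer MCS size (0 if no atom is shared).
#' @export
mcs_size <- function(lig_a, lig_b, max_nodes = 2e5) {
  ga <- .heavy_graph(lig_a); gb <- .heavy_graph(lig_b)
  if (ga$n == 0 || gb$n == 0) return(0L)
  best <- 0L
  expanded <- 0L
  upper <- min(ga$n, gb$n)

  compatible <- function(i, j, map_a, map_b) {
    all(ga$adj[i, map_a] == gb$adj[j, map_b])
  }
  extend <- function(map_a, map_b) {
    if (expanded > max_nodes || best == upper) return(invisible(NULL))
    expanded <<- expanded + 1L
    if (length(map_a) > best) best <<- length(map_a)
    cand_a <- setdiff(
      which(colSums(ga$adj[map_a, , drop = FALSE] != 0) > 0), map_a)
    nbh_b <- setdiff(
      which(colSums(gb$adj[map_b, , drop = FALSE] != 0) > 0), map_b)
    for (i in cand_a) {
      ## bound: mapping every remaining atom still cannot beat the incumbent
      if (length(map_a) +
          min(ga$n - length(map_a), gb$n - length(map_b)) <= best) break
      for (j in nbh_b[gb$el[nbh_b] == ga$el[i]]) {
        if (compatible(i, j, map_a, map_b))
          extend(c(map_a, i), c(map_b, j))
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(ga$n)) {
    if (best == upper || expanded > max_nodes) break
    for (j in which(gb$el == ga$el[i])) extend(i, j)
  }
  as.integer(best)
}
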
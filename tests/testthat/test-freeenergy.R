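# Brute-force oracle for the maximum common connected induced substructure:
# enumerate every subset of A's heavy atoms, keep connected induced
# subgraphs, and try all bijections onto same-element subsets of B checking
# bond orders pairwise. Exponential, fine for <= 8 atoms.
brute_mcs <- function(lig_a, lig_b) {
  hg <- function(lig) alchnet:::.heavy_graph(lig)
  ga <- hg(lig_a); gb <- hg(lig_b)
  connected <- function(adj, s) {
    if (length(s) <= 1) return(TRUE)
    seen <- s[1]; frontier <- s[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(s[colSums(adj[frontier, s, drop = FALSE] != 0) > 0], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(s)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  best <- 0L
  for (size in seq_len(min(ga$n, gb$n))) {
    subs_a <- utils::combn(ga$n, size, simplify = FALSE)
    subs_b <- utils::combn(gb$n, size, simplify = FALSE)
    for (sa in subs_a) {
      if (!connected(ga$adj, sa)) next
      for (sb in subs_b) {
        for (pb in perms(sb)) {
          if (any(ga$el[sa] != gb$el[pb])) next
          if (all(ga$adj[sa, sa] == gb$adj[pb, pb])) {
            best <- max(best, size)
            break
          }
        }
        if (best == size) break
      }
      if (best == size) break
    }
    if (best < size) break  # no common substructure of this size exists
  }
  as.integer(best)
}

# Small test molecules built directly (coordinates irrelevant for MCS).
mk <- function(elements, bonds) {
  n <- length(elements)
  ligand_structure(elements, matrix(seq_len(3 * n) * 1.7, n, 3),
                   bonds = bonds, validate = FALSE)
}

test_that("MCS search agrees with exhaustive enumeration on small molecules", {
  propane <- mk(c("C", "C", "C"),
                data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  butane <- mk(c("C", "C", "C", "C"),
               data.frame(i = 1:3, j = 2:4, order = 1))
  ethanol <- mk(c("C", "C", "O"),
                data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  acetone <- mk(c("C", "C", "C", "O"),
                data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                           order = c(1, 1, 2)))
  ring5 <- mk(rep("C", 5),
              data.frame(i = 1:5, j = c(2:5, 1), order = 1))
  cases <- list(list(propane, butane), list(propane, ethanol),
                list(ethanol, acetone), list(butane, acetone),
                list(ring5, butane), list(propane, propane))
  for (cs in cases) {
    expect_equal(mcs_size(cs[[1]], cs[[2]]), brute_mcs(cs[[1]], cs[[2]]),
                 label = paste(cs[[1]]$name, cs[[2]]$name))
  }
  ## bond-order sensitivity: C=O of acetone does not match C-O of ethanol
  expect_equal(mcs_size(ethanol, acetone), 2)
})

test_that("star map picks the common scaffold as reference", {
  scaffold <- mk(c("C", "C", "C"),
                 data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  deco_n <- mk(c("C", "C", "C", "N"),
               data.frame(i = c(1, 2, 3), j = c(2, 3, 4), order = 1))
  deco_o <- mk(c("C", "C", "C", "O"),
               data.frame(i = c(1, 2, 3), j = c(2, 3, 4), order = 1))
  deco_c <- mk(c("C", "C", "C", "C"),
               data.frame(i = c(1, 2, 1), j = c(2, 3, 4), order = 1))
  smap <- star_map(list(a = deco_n, scaf = scaffold, b = deco_o,
                        c = deco_c))
  expect_equal(smap$reference, "scaf")
  expect_equal(nrow(smap$pairs), 3)
  expect_setequal(smap$pairs$ligand, c("a", "b", "c"))
  ## 10 ligands -> 9 star edges through the hub
  ligs <- c(list(scaffold, deco_n, deco_o, deco_c),
            lapply(1:6, function(k) deco_n))
  names(ligs) <- paste0("m", 1:10)
  expect_equal(nrow(star_map(ligs)$pairs), 9)
  ## two identical ligands: tie broken by input order
  two <- star_map(list(x = scaffold, y = scaffold))
  expect_equal(two$reference, "x")
  expect_error(star_map(list(scaffold)), class = "alch_star_error")
})

test_that("RBFE assembly follows the signed-leg arithmetic", {
  data <- tiny_dataset()
  p <- tiny_params()
  pair <- data$pairs[[1]]
  pw <- pathway_spec()
  r <- rbfe(pair, pw, p)
  f1 <- predict_profile(pair, 1, 1, p)$cumulative_dG
  f2 <- predict_profile(pair, 2, 1, p)$cumulative_dG
  expect_equal(r$ddg, f1 - f2, tolerance = 1e-12)
  expect_equal(r$per_leg_terminal, c(f1, f2), tolerance = 1e-12)
  ## wrong pair kind rejected
  gl <- build_ligand_graph(data$ligands[[1]], n_dist_basis = 8L)
  alp <- graph_pair(pair$graph_a, gl, "complex-ligand-pair")
  expect_error(rbfe(alp, pw, p), class = "alch_pair_error")
  a <- abfe(alp, pw, p)
  expect_true(is.finite(a$dg))
  expect_error(abfe(pair, pw, p), class = "alch_pair_error")
})

test_that("symmetric perturbations give exactly zero ddG", {
  data <- tiny_dataset()
  p <- tiny_params()
  g <- data$pairs[[1]]$graph_a
  sym <- graph_pair(g, g, "complex-pair")
  expect_identical(rbfe(sym, pathway_spec(), p)$ddg, 0)
})

test_that("rbfe is antisymmetric under endpoint exchange", {
  data <- tiny_dataset()
  p <- tiny_params()
  pw <- pathway_spec()
  for (pid in names(data$pairs)[1:3]) {
    pair <- data$pairs[[pid]]
    rev <- graph_pair(pair$graph_b, pair$graph_a, "complex-pair")
    expect_equal(rbfe(pair, pw, p)$ddg, -rbfe(rev, pw, p)$ddg,
                 tolerance = 1e-12)
  }
})

test_that("pathway validation catches malformed legs", {
  expect_error(pathway_spec(lam_values_1 = c(0.1, 0.5, 1)),
               class = "alch_pathway_error")
  expect_error(pathway_spec(signs = c(2, -1)), class = "alch_pathway_error")
  expect_error(pathway_spec(lam_values_2 = c(0, 0.5, 0.4)),
               class = "alch_pathway_error")
})

test_that("ddG to dG centering matches the mean of the experimental set", {
  ddg <- c(ref = 0, a = 1, b = -1)
  dg_exp <- c(ref = -7, a = -6.5, b = -7.5)
  dg <- ddg_to_dg(ddg, dg_exp)
  expect_equal(unname(dg), c(-7, -6, -8))
  ## all-zero ddG collapses to the experimental mean
  expect_equal(unname(ddg_to_dg(c(ref = 0, a = 0), dg_exp[1:2])),
               rep(mean(dg_exp[1:2]), 2))
  ## translation equivariance
  expect_equal(ddg_to_dg(ddg, dg_exp + 2), dg + 2)
  ## offset invariance of correlation
  set.seed(8)
  ddg2 <- c(ref = 0, rnorm(5)); names(ddg2) <- c("ref", letters[1:5])
  exp2 <- ddg2 + rnorm(6, sd = 0.2) - 7
  r1 <- cor(ddg_to_dg(ddg2, exp2), exp2)
  r2 <- cor(ddg_to_dg(ddg2, exp2 + 100), exp2 + 100)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(ddg_to_dg(ddg, numeric(0)), class = "alch_fe_error")
})
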
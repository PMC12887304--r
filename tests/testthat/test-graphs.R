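test_that("atom featurization sets the documented one-hot blocks", {
  v <- featurize_atom("C", 0, 3, aromatic = TRUE, origin = "ligand")
  expect_length(v, atom_feature_dim())
  expect_equal(v[2], 1)            # C slot (second element slot)
  expect_equal(v[11 + 4], 1)       # degree-3 slot
  expect_equal(v[11 + 7 + 3], 1)   # charge-0 slot
  expect_equal(v[11 + 7 + 5 + 1], 1)  # aromatic flag
  ## unknown element falls into the "other" bucket
  w <- featurize_atom("Se", 0, 2, FALSE, "pocket")
  expect_equal(w[11], 1)
  ## determinism
  expect_identical(featurize_atom("N", 1, 2, FALSE, "ligand"),
                   featurize_atom("N", 1, 2, FALSE, "ligand"))
})

test_that("ligand graph applies the 1-2/1-3 non-covalent exclusion", {
  ## 3-atom chain, all pairwise distances < cutoff: the only non-bonded
  ## pair (1,3) is a 1-3 pair, so no non-covalent edges at all
  g <- build_ligand_graph(chain3_ligand(), cutoff = 4.5)
  expect_equal(length(g$nc_src), 0)
  expect_equal(length(g$cov_src), 4)  # 2 bonds, both directions

  ## single atom: no edges of either type
  single <- toy_ligand("C", matrix(0, 1, 3),
                       data.frame(i = integer(), j = integer(),
                                  order = numeric()))
  g1 <- build_ligand_graph(single)
  expect_equal(length(g1$cov_src), 0)
  expect_equal(length(g1$nc_src), 0)
})

test_that("benzene non-covalent edges match brute-force pair enumeration", {
  benz <- read_ligand(benzene_sdf())
  cutoff <- 4.5
  g <- build_ligand_graph(benz, cutoff = cutoff)
  ## independent O(n^2) oracle over all 66 pairs
  n <- 12
  D <- as.matrix(dist(benz$coords))
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(benz$bonds$i, benz$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  one_three <- matrix(FALSE, n, n)
  for (m in 1:n) {
    nb <- which(bonded[m, ])
    if (length(nb) >= 2)
      for (a in nb) for (b in nb) if (a != b) one_three[a, b] <- TRUE
  }
  cnt <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    if (D[a, b] <= cutoff && !bonded[a, b] && !one_three[a, b]) cnt <- cnt + 1
  expect_equal(length(g$nc_src), 2 * cnt)  # stored symmetrically
  expect_equal(sum(g$cov_feat[, 4]), 12)   # 6 aromatic bonds x 2 directions
  ## disjointness of the two edge sets as unordered pairs
  covkey <- paste(pmin(g$cov_src, g$cov_dst), pmax(g$cov_src, g$cov_dst))
  nckey <- paste(pmin(g$nc_src, g$nc_dst), pmax(g$nc_src, g$nc_dst))
  expect_length(intersect(covkey, nckey), 0)
  expect_true(all(g$nc_dist <= cutoff))
})

test_that("complex graph cross edges match brute-force distance enumeration", {
  data <- tiny_dataset()
  lig <- data$ligands[[1]]
  pocket <- data$pocket
  cutoff <- 4.5
  g <- build_complex_graph(complex_structure(lig, pocket), cutoff = cutoff)
  nl <- length(lig$elements)
  pk <- cbind(pocket$x, pocket$y, pocket$z)
  cnt <- 0
  for (a in seq_len(nl)) for (b in seq_len(nrow(pk)))
    if (sqrt(sum((lig$coords[a, ] - pk[b, ])^2)) <= cutoff) cnt <- cnt + 1
  is_cross <- (g$nc_src <= nl) != (g$nc_dst <= nl)
  expect_equal(sum(is_cross), 2 * cnt)
  ## no pocket-pocket non-covalent edges
  expect_equal(sum(g$nc_src > nl & g$nc_dst > nl), 0)
  expect_equal(g$node_origin, c(rep("ligand", nl),
                                rep("pocket", nrow(pk))))
})

test_that("single cross pair appears within cutoff and vanishes below it", {
  lig <- toy_ligand("C", matrix(0, 1, 3),
                    data.frame(i = integer(), j = integer(),
                               order = numeric()))
  pocket <- data.frame(element = "O", x = 3, y = 0, z = 0, resno = 1,
                       resid = "POC", chain = "P", elety = "O1")
  class(pocket) <- c("alch_pocket", "data.frame")
  g1 <- build_complex_graph(complex_structure(lig, pocket), cutoff = 4.5)
  expect_equal(length(g1$nc_src), 2)
  g2 <- build_complex_graph(complex_structure(lig, pocket), cutoff = 2)
  expect_equal(length(g2$nc_src), 0)
})

test_that("rigid motions leave features and edge distances unchanged", {
  data <- tiny_dataset()
  lig <- data$ligands[[1]]; pocket <- data$pocket
  g0 <- build_complex_graph(complex_structure(lig, pocket))
  for (s in 1:3) {
    tr <- transform_complex(lig, pocket, seed = 100 + s)
    g1 <- build_complex_graph(complex_structure(tr$ligand, tr$pocket))
    expect_identical(g1$node_features, g0$node_features)
    expect_equal(sort(g1$nc_dist), sort(g0$nc_dist), tolerance = 1e-9)
    expect_identical(g1$cov_src, g0$cov_src)
  }
})

test_that("graph pair kinds enforce pocket placement", {
  data <- tiny_dataset()
  lig <- data$ligands[[1]]
  gc <- build_complex_graph(complex_structure(lig, data$pocket))
  gl <- build_ligand_graph(lig)
  expect_s3_class(graph_pair(gc, gc, "complex-pair"), "alch_graph_pair")
  expect_s3_class(graph_pair(gc, gl, "complex-ligand-pair"),
                  "alch_graph_pair")
  expect_error(graph_pair(gc, gl, "complex-pair"), class = "alch_pair_error")
  expect_error(graph_pair(gc, gc, "complex-ligand-pair"),
               class = "alch_pair_error")
})

test_that("graph JSON dump is valid and complete", {
  g <- build_ligand_graph(chain3_ligand())
  path <- tempfile(fileext = ".json")
  write_graph_json(g, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n, 3)
  expect_equal(nrow(back$node_features), 3)
})
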
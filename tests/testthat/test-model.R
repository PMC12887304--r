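test_that("lambda basis is anchored, deterministic and mirror-symmetric", {
  B <- lambda_basis(c(0, 0.37, 0.63, 1), n_basis = 16)
  expect_equal(B[1, 1], 1.0)            # center at 0, exp(0)
  expect_equal(B[4, 16], 1.0)           # center at 1
  ## mirror symmetry of the raw activations
  expect_equal(B[2, ], rev(B[3, ]), tolerance = 1e-12)
  expect_identical(lambda_basis(0.37), lambda_basis(0.37))
  expect_error(lambda_basis(1.2), class = "alch_domain_error")
  p <- tiny_params()
  expect_identical(embed_lambda(0.37, p), embed_lambda(0.37, p))
})

test_that("fusion is multiplicative: all-ones lambda acts as identity pre-map", {
  p <- tiny_params()
  d <- length(p$fuse.b)
  g <- rnorm(d)
  ones <- rep(1, d)
  ## the product stage is commutative
  expect_identical(fuse(g, ones, p), fuse(ones, g, p))
  ## zero graph embedding leaves only the bias pre-activation
  expect_equal(fuse(rep(0, d), g, p),
               as.numeric(alchnet:::silu(p$fuse.b)))
  expect_error(fuse(g, g[-1], p), class = "alch_dim_error")
})

test_that("leg encoding is concatenation order: identical endpoints collapse legs", {
  p <- tiny_params()
  d <- length(p$pair.b)
  set.seed(2); ha <- rnorm(d); hb <- rnorm(d)
  expect_identical(encode_leg(ha, ha, 1, p), encode_leg(ha, ha, 2, p))
  expect_false(isTRUE(all.equal(encode_leg(ha, hb, 1, p),
                                encode_leg(ha, hb, 2, p))))
  ## swapping endpoint labels exchanges the legs exactly
  expect_identical(encode_leg(ha, hb, 1, p), encode_leg(hb, ha, 2, p))
  expect_identical(encode_leg(ha, hb, 2, p), encode_leg(hb, ha, 1, p))
})

test_that("message passing is permutation-equivariant and origin-sensitive", {
  data <- tiny_dataset()
  p <- tiny_params()
  lig <- data$ligands[[1]]
  g <- build_complex_graph(complex_structure(lig, data$pocket),
                           n_dist_basis = 8L)
  H <- message_pass(g, p)
  expect_equal(dim(H), c(g$n, length(p$enc.b)))
  ## permute ligand atoms: embeddings row-permute
  set.seed(5)
  perm <- sample(length(lig$elements))
  lig2 <- permute_ligand(lig, perm)
  g2 <- build_complex_graph(complex_structure(lig2, data$pocket),
                            n_dist_basis = 8L)
  H2 <- message_pass(g2, p)
  nl <- length(lig$elements)
  expect_equal(H2[seq_len(nl), ], H[perm, ], tolerance = 1e-6)
  ## heterogeneous block reacts to origin flags: relabel pocket as ligand
  g3 <- g
  g3$node_origin <- rep("ligand", g$n)
  g3$kind <- "ligand"
  H3 <- message_pass(g3, p)
  expect_gt(max(abs(H3 - H)), 1e-6)
  ## single isolated atom: self-update only, finite output
  single <- build_ligand_graph(
    toy_ligand("C", matrix(0, 1, 3),
               data.frame(i = integer(), j = integer(), order = numeric())),
    n_dist_basis = 8L)
  expect_true(all(is.finite(message_pass(single, p))))
})

test_that("window predictions anchor at lambda = 0 and batch equals pointwise", {
  data <- tiny_dataset()
  p <- tiny_params()
  pair <- data$pairs[[1]]
  expect_equal(predict_window(pair, lambda_window(1, 0), p)$cumulative_dG, 0)
  expect_equal(predict_window(pair, lambda_window(2, 0), p)$cumulative_dG, 0)
  grid <- c(0, 0.2, 0.5, 0.8, 1)
  prof <- predict_profile(pair, 1, grid, p)
  expect_equal(prof$cumulative_dG[1], 0)
  expect_true(all(is.finite(prof$cumulative_dG)))
  for (k in seq_along(grid)) {
    pw <- predict_window(pair, lambda_window(1, grid[k]), p)
    expect_equal(pw$cumulative_dG, prof$cumulative_dG[k], tolerance = 1e-6)
  }
  expect_error(predict_profile(pair, 1, c(0.5, 0.2), p),
               class = "alch_domain_error")
})

test_that("predictions are invariant under rigid motions (SE(3))", {
  data <- tiny_dataset()
  p <- tiny_params()
  lig_a <- data$ligands[[1]]; lig_b <- data$ligands[[2]]
  g_a <- build_complex_graph(complex_structure(lig_a, data$pocket),
                             n_dist_basis = 8L)
  g_b <- build_complex_graph(complex_structure(lig_b, data$pocket),
                             n_dist_basis = 8L)
  pair <- graph_pair(g_a, g_b, "complex-pair")
  base <- predict_profile(pair, 1, c(0.3, 0.7, 1), p)$cumulative_dG
  for (s in 1:5) {
    tra <- transform_complex(lig_a, data$pocket, seed = 200 + s)
    trb <- transform_complex(lig_b, data$pocket, seed = 300 + s)
    pair2 <- graph_pair(
      build_complex_graph(complex_structure(tra$ligand, tra$pocket),
                          n_dist_basis = 8L),
      build_complex_graph(complex_structure(trb$ligand, trb$pocket),
                          n_dist_basis = 8L),
      "complex-pair")
    moved <- predict_profile(pair2, 1, c(0.3, 0.7, 1), p)$cumulative_dG
    expect_lt(max(abs(moved - base)), 1e-5)
  }
})

test_that("hand-written backward pass matches finite differences", {
  spec <- synthetic_spec(n_pairs = 2, windows_per_leg = 4,
                         heavy_atom_range = c(4L, 6L), seed = 3)
  data <- gen_dataset(spec, n_dist_basis = 6L)
  cfg <- alch_config(overrides = list(d_hidden = 5L, n_layers = 2L,
                                      d_lambda_basis = 6L, d_dist_basis = 6L))
  p <- init_params(cfg, seed = 2)
  rows <- data.frame(pair_id = data$labels$pair_id,
                     leg_id = data$labels$leg_id,
                     lambda = data$labels$lambda,
                     target = data$labels$cumulative_dG_kcal_mol,
                     weight = reliability_weight(data$labels$sigma_kcal_mol))
  lg <- alchnet:::.batch_loss_grad(rows, data$pairs, p)
  eps <- 1e-5
  set.seed(9)
  for (k in names(p)) {
    for (t in sample(length(p[[k]]), min(3, length(p[[k]])))) {
      pp <- p; pp[[k]][t] <- pp[[k]][t] + eps
      pm <- p; pm[[k]][t] <- pm[[k]][t] - eps
      num <- (alchnet:::.batch_loss_grad(rows, data$pairs, pp,
                                         with_grad = FALSE)$loss -
                alchnet:::.batch_loss_grad(rows, data$pairs, pm,
                                           with_grad = FALSE)$loss) / (2 * eps)
      ana <- lg$grads[[k]][t]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", k, t))
    }
  }
})

test_that("checkpoints round-trip through JSON at full precision", {
  p <- tiny_params()
  path <- tempfile(fileext = ".json")
  alch_save_model(p, path)
  q <- alch_load_model(path)
  expect_equal(attr(q, "config")$d_hidden, attr(p, "config")$d_hidden)
  for (k in names(p)) expect_equal(unname(p[[k]]), unname(q[[k]]),
                                   tolerance = 1e-14, label = k)
  data <- tiny_dataset()
  prof_p <- predict_profile(data$pairs[[1]], 1, c(0.5, 1), p)
  prof_q <- predict_profile(data$pairs[[1]], 1, c(0.5, 1), q)
  expect_equal(prof_p$cumulative_dG, prof_q$cumulative_dG, tolerance = 1e-12)
})
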
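## The path-aware free-energy network.
##
## Forward pass (per endpoint graph): atom encoder -> L residual
## message-passing layers with separate covalent / non-covalent message
## functions and, for complex-type graphs only, a heterogeneous block that
## transforms ligand-origin and pocket-origin nodes with distinct weights
## -> origin-separated sum pooling -> graph embedding g.
##
## Per (leg, lambda): the two endpoint embeddings are concatenated in
## leg-dependent order (leg 1: A||B, leg 2: B||A) and projected to a leg
## representation q; lambda is expanded in a Gaussian radial basis and
## linearly mapped to z; q and z are fused multiplicatively and an MLP head
## emits a scalar. The cumulative free energy is head(lambda) - head(0),
## which anchors F(0) = 0 exactly and makes identical endpoints give
## exactly equal legs.
##
## No autodiff framework is used: backward passes are written out by hand
## and checked against finite differences in the test suite.

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

# Scatter-add rows of M into an n-row accumulator by index.
.agg <- function(M, idx, n, d) {
  out <- matrix(0, n, d)
  if (length(idx) == 0) return(out)
  rs <- rowsum(M, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Initialize model parameters
#'
#' Glorot-normal weights, zero biases; fully determined by the seed and the
#' architecture keys of the configuration (`d_hidden`, `n_layers`,
#' `d_lambda_basis`, `d_dist_basis`).
#'
#' @param config Configuration list from [alch_config()].
#' @param seed Integer RNG seed (default `config$seed`).
#' @return Named list of weight matrices/vectors of class `alch_params`,
#'   with the architecture config attached as attribute `"config"`.
#' @export
init_params <- function(config = alch_default_config(), seed = config$seed) {
  d <- as.integer(config$d_hidden)
  L <- as.integer(config$n_layers)
  dl <- as.integer(config$d_lambda_basis)
  dd <- as.integer(config$d_dist_basis)
  da <- atom_feature_dim()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  glorot <- function(nin, nout)
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
  p <- list(enc.W = glorot(da, d), enc.b = numeric(d))
  for (l in seq_len(L)) {
    nm <- function(s) paste0("L", l, ".", s)
    p[[nm("Wself")]] <- glorot(d, d)
    p[[nm("Wch")]] <- glorot(d, d)
    p[[nm("Wce")]] <- glorot(5L, d)
    p[[nm("Wnh")]] <- glorot(d, d)
    p[[nm("Wne")]] <- glorot(dd, d)
    p[[nm("b")]] <- numeric(d)
    p[[nm("Wlig")]] <- glorot(d, d)
    p[[nm("blig")]] <- numeric(d)
    p[[nm("Wpoc")]] <- glorot(d, d)
    p[[nm("bpoc")]] <- numeric(d)
  }
  p$pool.W <- glorot(2L * d, d); p$pool.b <- numeric(d)
  p$pair.W <- glorot(2L * d, d); p$pair.b <- numeric(d)
  p$lam.W <- glorot(dl, d); p$lam.b <- numeric(d)
  p$fuse.W <- glorot(d, d); p$fuse.b <- numeric(d)
  p$head.W1 <- glorot(d, d); p$head.b1 <- numeric(d)
  p$head.W2 <- glorot(d, 1L); p$head.b2 <- numeric(1)
  structure(p, class = "alch_params",
            config = list(d_hidden = d, n_layers = L, d_lambda_basis = dl,
                          d_dist_basis = dd))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

zero_grads <- function(params) {
  g <- lapply(params, function(w) { w[] <- 0; w })
  class(g) <- "list"
  g
}

#' Raw lambda basis activations
#'
#' Gaussian radial basis on \[0, 1\]: centers evenly spaced, width equal to
#' the center spacing. The first activation equals 1 at lambda = 0 and the
#' activations for lambda and 1 - lambda are mirror images.
#'
#' @param lam Numeric vector of lambda values in \[0, 1\].
#' @param n_basis Number of basis functions (default 16).
#' @return Matrix `length(lam) x n_basis`.
#' @export
lambda_basis <- function(lam, n_basis = 16L) {
  if (any(lam < 0 | lam > 1))
    alch_stop("lambda outside [0, 1]", "alch_domain_error")
  rbf_expand(lam, n_basis, 1)
}

#' Embed lambda values
#'
#' Radial basis expansion followed by the learned linear map to the hidden
#' dimension. Deterministic: equal lambda gives an identical embedding.
#'
#' @param lam Numeric vector in \[0, 1\].
#' @param params `alch_params`.
#' @return Matrix `length(lam) x d_hidden`.
#' @export
embed_lambda <- function(lam, params) {
  cfg <- attr(params, "config")
  R <- lambda_basis(lam, cfg$d_lambda_basis)
  sweep(R %*% params$lam.W, 2, params$lam.b, "+")
}

## ---- graph-side forward/backward -------------------------------------

.forward_graph <- function(graph, params, keep_cache = TRUE) {
  cfg <- attr(params, "config")
  d <- cfg$d_hidden; L <- cfg$n_layers; n <- graph$n
  het <- graph$kind == "complex"
  lig_rows <- which(graph$node_origin == "ligand")
  poc_rows <- which(graph$node_origin == "pocket")
  P0 <- sweep(graph$node_features %*% params$enc.W, 2, params$enc.b, "+")
  H <- silu(P0)
  cache <- list(P0 = P0, layers = vector("list", L),
                lig_rows = lig_rows, poc_rows = poc_rows, het = het)
  for (l in seq_len(L)) {
    nm <- function(s) params[[paste0("L", l, ".", s)]]
    Hin <- H
    Pc <- graph$cov_feat %*% nm("Wce")
    if (length(graph$cov_src) > 0)
      Pc <- Pc + Hin[graph$cov_src, , drop = FALSE] %*% nm("Wch")
    Mc <- silu(Pc)
    Pn <- graph$nc_feat %*% nm("Wne")
    if (length(graph$nc_src) > 0)
      Pn <- Pn + Hin[graph$nc_src, , drop = FALSE] %*% nm("Wnh")
    Mn <- silu(Pn)
    U <- sweep(Hin %*% nm("Wself") +
                 .agg(Mc, graph$cov_dst, n, d) +
                 .agg(Mn, graph$nc_dst, n, d), 2, nm("b"), "+")
    A <- silu(U)
    lay <- list(Hin = Hin, Pc = Pc, Pn = Pn, U = U, A = A)
    if (het) {
      B <- A
      PL <- sweep(A[lig_rows, , drop = FALSE] %*% nm("Wlig"), 2, nm("blig"), "+")
      B[lig_rows, ] <- silu(PL)
      lay$PL <- PL
      if (length(poc_rows) > 0) {
        PP <- sweep(A[poc_rows, , drop = FALSE] %*% nm("Wpoc"), 2, nm("bpoc"), "+")
        B[poc_rows, ] <- silu(PP)
        lay$PP <- PP
      }
    } else B <- A
    H <- Hin + B
    if (keep_cache) cache$layers[[l]] <- lay
  }
  s_lig <- if (length(lig_rows) > 0)
    colSums(H[lig_rows, , drop = FALSE]) else numeric(d)
  s_poc <- if (length(poc_rows) > 0)
    colSums(H[poc_rows, , drop = FALSE]) else numeric(d)
  s <- c(s_lig, s_poc)
  Pg <- as.numeric(s %*% params$pool.W) + params$pool.b
  g <- silu(Pg)
  cache$H <- H; cache$s <- s; cache$Pg <- Pg
  list(H = H, g = g, cache = if (keep_cache) cache else NULL)
}

# dL/d(graph params) given dL/dg; accumulates into `grads` (a named list),
# returns the updated list.
.backward_graph <- function(graph, params, cache, dg, grads) {
  cfg <- attr(params, "config")
  d <- cfg$d_hidden; L <- cfg$n_layers; n <- graph$n
  lig_rows <- cache$lig_rows; poc_rows <- cache$poc_rows
  dPg <- dg * dsilu(cache$Pg)
  grads$pool.W <- grads$pool.W + outer(cache$s, dPg)
  grads$pool.b <- grads$pool.b + dPg
  ds <- as.numeric(params$pool.W %*% dPg)
  dH <- matrix(0, n, d)
  if (length(lig_rows) > 0)
    dH[lig_rows, ] <- matrix(ds[1:d], length(lig_rows), d, byrow = TRUE)
  if (length(poc_rows) > 0)
    dH[poc_rows, ] <- matrix(ds[(d + 1):(2 * d)], length(poc_rows), d,
                             byrow = TRUE)
  for (l in rev(seq_len(L))) {
    lay <- cache$layers[[l]]
    nm <- function(s) params[[paste0("L", l, ".", s)]]
    gnm <- function(s) paste0("L", l, ".", s)
    dB <- dH                      # residual: dHin gets dH too, added below
    if (cache$het) {
      dA <- matrix(0, n, d)
      dPL <- dB[lig_rows, , drop = FALSE] * dsilu(lay$PL)
      grads[[gnm("Wlig")]] <- grads[[gnm("Wlig")]] +
        t(lay$A[lig_rows, , drop = FALSE]) %*% dPL
      grads[[gnm("blig")]] <- grads[[gnm("blig")]] + colSums(dPL)
      dA[lig_rows, ] <- dPL %*% t(nm("Wlig"))
      if (length(poc_rows) > 0) {
        dPP <- dB[poc_rows, , drop = FALSE] * dsilu(lay$PP)
        grads[[gnm("Wpoc")]] <- grads[[gnm("Wpoc")]] +
          t(lay$A[poc_rows, , drop = FALSE]) %*% dPP
        grads[[gnm("bpoc")]] <- grads[[gnm("bpoc")]] + colSums(dPP)
        dA[poc_rows, ] <- dPP %*% t(nm("Wpoc"))
      }
    } else dA <- dB
    dU <- dA * dsilu(lay$U)
    grads[[gnm("Wself")]] <- grads[[gnm("Wself")]] + t(lay$Hin) %*% dU
    grads[[gnm("b")]] <- grads[[gnm("b")]] + colSums(dU)
    dHin <- dH + dU %*% t(nm("Wself"))  # residual + self path
    if (length(graph$cov_src) > 0) {
      dMc <- dU[graph$cov_dst, , drop = FALSE]
      dPc <- dMc * dsilu(lay$Pc)
      grads[[gnm("Wch")]] <- grads[[gnm("Wch")]] +
        t(lay$Hin[graph$cov_src, , drop = FALSE]) %*% dPc
      grads[[gnm("Wce")]] <- grads[[gnm("Wce")]] + t(graph$cov_feat) %*% dPc
      dHin <- dHin + .agg(dPc %*% t(nm("Wch")), graph$cov_src, n, d)
    }
    if (length(graph$nc_src) > 0) {
      dMn <- dU[graph$nc_dst, , drop = FALSE]
      dPn <- dMn * dsilu(lay$Pn)
      grads[[gnm("Wnh")]] <- grads[[gnm("Wnh")]] +
        t(lay$Hin[graph$nc_src, , drop = FALSE]) %*% dPn
      grads[[gnm("Wne")]] <- grads[[gnm("Wne")]] + t(graph$nc_feat) %*% dPn
      dHin <- dHin + .agg(dPn %*% t(nm("Wnh")), graph$nc_src, n, d)
    }
    dH <- dHin
  }
  dP0 <- dH * dsilu(cache$P0)
  grads$enc.W <- grads$enc.W + t(graph$node_features) %*% dP0
  grads$enc.b <- grads$enc.b + colSums(dP0)
  grads
}

## ---- head-side forward/backward --------------------------------------

# Forward through leg encoding, lambda fusion and MLP head for a vector of
# lambda values. Row 1 is always lambda = 0 (the anchor); predictions for
# the requested lambdas are Y[-1] - Y[1].
.forward_head <- function(gA, gB, leg_id, lams, params) {
  cfg <- attr(params, "config")
  s_pair <- if (leg_id == 1L) c(gA, gB) else c(gB, gA)
  Pq <- as.numeric(s_pair %*% params$pair.W) + params$pair.b
  q <- silu(Pq)
  lam_all <- c(0, lams)
  R <- lambda_basis(lam_all, cfg$d_lambda_basis)
  Z <- sweep(R %*% params$lam.W, 2, params$lam.b, "+")
  E <- sweep(Z, 2, q, "*")
  PU <- sweep(E %*% params$fuse.W, 2, params$fuse.b, "+")
  U1 <- silu(PU)
  PH <- sweep(U1 %*% params$head.W1, 2, params$head.b1, "+")
  H1 <- silu(PH)
  Y <- as.numeric(H1 %*% params$head.W2) + params$head.b2
  list(F = Y[-1] - Y[1],
       cache = list(s_pair = s_pair, Pq = Pq, q = q, R = R, Z = Z, E = E,
                    PU = PU, U1 = U1, PH = PH, H1 = H1, leg_id = leg_id))
}

# Backward given dL/dF (one value per requested lambda). Returns grads
# (accumulated) plus dL/dgA and dL/dgB.
.backward_head <- function(cache, dF, params, grads) {
  d <- length(cache$q)
  dY <- c(-sum(dF), dF)
  grads$head.W2 <- grads$head.W2 + t(cache$H1) %*% matrix(dY, ncol = 1)
  grads$head.b2 <- grads$head.b2 + sum(dY)
  dH1 <- matrix(dY, ncol = 1) %*% t(params$head.W2)
  dPH <- dH1 * dsilu(cache$PH)
  grads$head.W1 <- grads$head.W1 + t(cache$U1) %*% dPH
  grads$head.b1 <- grads$head.b1 + colSums(dPH)
  dU1 <- dPH %*% t(params$head.W1)
  dPU <- dU1 * dsilu(cache$PU)
  grads$fuse.W <- grads$fuse.W + t(cache$E) %*% dPU
  grads$fuse.b <- grads$fuse.b + colSums(dPU)
  dE <- dPU %*% t(params$fuse.W)
  dZ <- sweep(dE, 2, cache$q, "*")
  dq <- colSums(dE * cache$Z)
  grads$lam.W <- grads$lam.W + t(cache$R) %*% dZ
  grads$lam.b <- grads$lam.b + colSums(dZ)
  dPq <- dq * dsilu(cache$Pq)
  grads$pair.W <- grads$pair.W + outer(cache$s_pair, dPq)
  grads$pair.b <- grads$pair.b + dPq
  dspair <- as.numeric(params$pair.W %*% dPq)
  if (cache$leg_id == 1L) {
    dgA <- dspair[1:d]; dgB <- dspair[(d + 1):(2 * d)]
  } else {
    dgB <- dspair[1:d]; dgA <- dspair[(d + 1):(2 * d)]
  }
  list(grads = grads, dgA = dgA, dgB = dgB)
}

## ---- exported operation surface --------------------------------------

#' Run message passing over a graph
#'
#' @param graph `alch_graph`.
#' @param params `alch_params`.
#' @return Node embedding matrix `n x d_hidden`.
#' @export
message_pass <- function(graph, params) {
  .forward_graph(graph, params, keep_cache = FALSE)$H
}

#' Graph-level embedding
#'
#' Origin-separated sum pooling (ligand-node sum, pocket-node sum,
#' concatenated) followed by a learned projection.
#'
#' @inheritParams message_pass
#' @return Numeric vector of length `d_hidden`.
#' @export
graph_embedding <- function(graph, params) {
  .forward_graph(graph, params, keep_cache = FALSE)$g
}

#' Encode a thermodynamic-cycle leg
#'
#' Leg identity is carried purely by concatenation order: leg 1 encodes
#' (A || B), leg 2 encodes (B || A); all downstream weights are shared
#' between legs. Identical endpoints therefore give identical leg
#' representations, which is what forces exact ddG = 0 for symmetric
#' perturbations.
#'
#' @param h_a,h_b Endpoint graph embeddings (`d_hidden` vectors).
#' @param leg_id 1 or 2.
#' @param params `alch_params`.
#' @return Leg representation vector of length `d_hidden`.
#' @export
encode_leg <- function(h_a, h_b, leg_id, params) {
  stopifnot(leg_id %in% c(1L, 2L))
  s_pair <- if (leg_id == 1L) c(h_a, h_b) else c(h_b, h_a)
  silu(as.numeric(s_pair %*% params$pair.W) + params$pair.b)
}

#' Multiplicative fusion of graph and lambda representations
#'
#' Elementwise product of the two representations followed by a learned
#' linear layer and SiLU nonlinearity.
#'
#' @param graph_embedding Numeric vector (`d_hidden`).
#' @param lambda_embedding Numeric vector (`d_hidden`).
#' @param params `alch_params`.
#' @return Fused vector of length `d_hidden`.
#' @export
fuse <- function(graph_embedding, lambda_embedding, params) {
  if (length(graph_embedding) != length(lambda_embedding))
    alch_stop("fuse: dimension mismatch", "alch_dim_error")
  e <- graph_embedding * lambda_embedding
  silu(as.numeric(e %*% params$fuse.W) + params$fuse.b)
}

#' A lambda window
#'
#' @param leg_id Leg of the thermodynamic cycle (1 or 2).
#' @param lam Alchemical coordinate in \[0, 1\].
#' @return Object of class `alch_window`.
#' @export
lambda_window <- function(leg_id, lam) {
  stopifnot(leg_id %in% c(1L, 2L))
  if (lam < 0 || lam > 1)
    alch_stop("lambda outside [0, 1]", "alch_domain_error")
  structure(list(leg_id = as.integer(leg_id), lam = as.numeric(lam)),
            class = "alch_window")
}

#' Predict the cumulative free energy at one lambda window
#'
#' The prediction is head(lambda) - head(0) on the fused leg
#' representation, so the cumulative free energy at lambda = 0 is exactly 0
#' by construction.
#'
#' @param pair `alch_graph_pair`.
#' @param window `alch_window`.
#' @param params `alch_params`.
#' @return List with `window` and `cumulative_dG` (kcal/mol).
#' @export
predict_window <- function(pair, window, params) {
  prof <- predict_profile(pair, window$leg_id, window$lam, params)
  list(window = window, cumulative_dG = prof$cumulative_dG[1])
}

#' Predict a cumulative free-energy profile along a leg
#'
#' @param pair `alch_graph_pair`.
#' @param leg_id 1 or 2.
#' @param lam_grid Sorted numeric vector of lambda values in \[0, 1\].
#' @param params `alch_params`.
#' @return Data frame with columns `leg_id`, `lambda`, `cumulative_dG`.
#' @export
predict_profile <- function(pair, leg_id, lam_grid, params) {
  stopifnot(leg_id %in% c(1L, 2L))
  if (is.unsorted(lam_grid))
    alch_stop("lambda grid must be sorted increasing", "alch_domain_error")
  fA <- .forward_graph(pair$graph_a, params, keep_cache = FALSE)
  fB <- .forward_graph(pair$graph_b, params, keep_cache = FALSE)
  fh <- .forward_head(fA$g, fB$g, as.integer(leg_id), lam_grid, params)
  data.frame(leg_id = as.integer(leg_id), lambda = lam_grid,
             cumulative_dG = fh$F)
}

## ---- checkpoint serialization ----------------------------------------

#' Save model parameters as JSON
#'
#' Plain-text checkpoint embedding the architecture config; full double
#' precision.
#'
#' @param params `alch_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
alch_save_model <- function(params, path) {
  cfg <- attr(params, "config")
  obj <- list(config = cfg,
              params = lapply(unclass(params), function(w)
                list(dim = if (is.matrix(w)) dim(w) else length(w),
                     data = as.numeric(w))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load model parameters from JSON
#'
#' @param path Checkpoint path written by [alch_save_model()].
#' @return `alch_params`.
#' @export
alch_load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(obj$params, function(w) {
    v <- as.numeric(w$data)
    if (length(w$dim) == 2) matrix(v, w$dim[1], w$dim[2]) else v
  })
  structure(p, class = "alch_params",
            config = lapply(obj$config, function(x)
              if (is.numeric(x)) as.integer(x) else x))
}
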
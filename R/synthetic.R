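## Synthetic alchemical-path data: random small valence-legal molecules in
## a fixed toy pocket shell, smooth per-pair cumulative free-energy
## profiles anchored at F(0) = 0 with a closed-form implied ddG, and
## heteroscedastic Gaussian label noise with the uncertainty stored as the
## reliability field. The statistical structure (cumulative profiles, two
## correlated legs, per-sample sigma) mirrors window-level labels from an
## alchemical transfer calculation; the molecular shapes are deliberately
## simple.

#' Specification of a synthetic dataset
#'
#' @param n_pairs Number of molecular pairs (default 40).
#' @param windows_per_leg Lambda windows per leg, uniform on \[0, 1\]
#'   (default 11).
#' @param heavy_atom_range Heavy atoms per molecule (default 6..20).
#' @param amplitude_per_atom Slope of the shared environment profile per
#'   heavy atom, kcal/mol (default 0.15).
#' @param barrier_prob Probability that a pair's profile carries a
#'   smoothstep barrier (default 0.5).
#' @param barrier_amplitude Maximum barrier height, kcal/mol (default 2).
#' @param shape_jitter Amplitude of the seeded pair-specific slope term,
#'   kcal/mol (default 0.5).
#' @param sigma_range Range of per-sample label uncertainty, kcal/mol
#'   (default c(0.1, 0.5)).
#' @param heteroscedastic Draw sigma per sample (default `TRUE`); otherwise
#'   every sample uses the midpoint of `sigma_range`.
#' @param sigma_cap Quality filter: samples with sigma above the cap are
#'   dropped (default `Inf`, no screening).
#' @param outlier_frac Fraction of samples contaminated with
#'   `outlier_sigma` noise (default 0).
#' @param outlier_sigma Sigma of contaminated samples, kcal/mol (default 5).
#' @param seed RNG seed fixing the entire dataset (default 0).
#' @return List of class `alch_synth_spec`.
#' @export
synthetic_spec <- function(n_pairs = 40L, windows_per_leg = 11L,
                           heavy_atom_range = c(6L, 20L),
                           amplitude_per_atom = 0.15,
                           barrier_prob = 0.5, barrier_amplitude = 2,
                           shape_jitter = 0.5,
                           sigma_range = c(0.1, 0.5),
                           heteroscedastic = TRUE,
                           sigma_cap = Inf,
                           outlier_frac = 0, outlier_sigma = 5,
                           seed = 0L) {
  stopifnot(n_pairs >= 1, windows_per_leg >= 2,
            heavy_atom_range[1] >= 2, diff(heavy_atom_range) >= 0,
            all(sigma_range >= 0), diff(sigma_range) >= 0,
            barrier_prob >= 0, barrier_prob <= 1,
            outlier_frac >= 0, outlier_frac < 1, outlier_sigma >= 0)
  structure(as.list(environment()), class = "alch_synth_spec")
}

## ---- molecules ---------------------------------------------------------

.synth_elements <- c("C", "N", "O")
.synth_valence <- c(C = 4, N = 3, O = 2)

# Random connected valence-legal heavy-atom molecule: random tree grown
# atom by atom, occasional ring closures and double bonds, then a 3D
# embedding by minimizing a bond-length + steric-repulsion objective.
.gen_molecule <- function(n_heavy, name) {
  el <- sample(.synth_elements, n_heavy, replace = TRUE,
               prob = c(0.7, 0.15, 0.15))
  cap <- .synth_valence[el]
  used <- numeric(n_heavy)
  bi <- integer(0); bj <- integer(0); bo <- numeric(0)
  for (a in 2:n_heavy) {
    open <- which(used[seq_len(a - 1)] < cap[seq_len(a - 1)])
    p <- if (length(open) == 1) open else sample(open, 1)
    bi <- c(bi, p); bj <- c(bj, a); bo <- c(bo, 1)
    used[p] <- used[p] + 1; used[a] <- used[a] + 1
  }
  ## ring closures between non-adjacent atoms with spare valence
  n_rings <- sample(0:2, 1)
  for (r in seq_len(n_rings)) {
    open <- which(used < cap)
    if (length(open) < 2) break
    cand <- t(utils::combn(open, 2))
    bonded <- paste(bi, bj) # tree bonds have i < j by construction
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% bonded) &
                   cand[, 2] - cand[, 1] >= 2, , drop = FALSE]
    if (nrow(cand) == 0) break
    k <- sample(seq_len(nrow(cand)), 1)
    bi <- c(bi, cand[k, 1]); bj <- c(bj, cand[k, 2]); bo <- c(bo, 1)
    used[cand[k, ]] <- used[cand[k, ]] + 1
  }
  ## occasional double bonds where valence allows
  for (k in seq_along(bi)) {
    if (bo[k] == 1 && used[bi[k]] < cap[bi[k]] && used[bj[k]] < cap[bj[k]] &&
        stats::runif(1) < 0.15) {
      bo[k] <- 2
      used[c(bi[k], bj[k])] <- used[c(bi[k], bj[k])] + 1
    }
  }
  coords <- .embed_3d(n_heavy, bi, bj)
  ligand_structure(el, coords, bonds = data.frame(i = bi, j = bj, order = bo),
                   name = name)
}

# Distance-geometry-flavored 3D layout: start from a random-walk placement
# along the bond tree, then minimize bond-length deviation plus a soft
# steric repulsion; centered at the origin.
.embed_3d <- function(n, bi, bj, bond_len = 1.5, rep_dist = 2.2) {
  X <- matrix(0, n, 3)
  for (a in 2:n) {
    parent <- bi[match(a, bj)]
    if (is.na(parent)) parent <- a - 1L
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    X[a, ] <- X[parent, ] + bond_len * dir
  }
  obj <- function(x) {
    X <- matrix(x, n, 3)
    db <- sqrt(rowSums((X[bi, , drop = FALSE] - X[bj, , drop = FALSE])^2))
    e <- sum((db - bond_len)^2)
    D <- as.matrix(stats::dist(X))
    pen <- pmax(rep_dist - D, 0)^2  # first arg a matrix so dims survive pmax
    bonded <- matrix(FALSE, n, n)
    bonded[cbind(bi, bj)] <- TRUE; bonded[cbind(bj, bi)] <- TRUE
    diag(pen) <- 0; pen[bonded] <- 0
    e + sum(pen) / 2
  }
  res <- stats::optim(as.numeric(X), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-8))
  X <- matrix(res$par, n, 3)
  sweep(X, 2, colMeans(X))
}

#' Fixed toy pocket shell
#'
#' 30 atoms on a Fibonacci sphere of the given radius, grouped into 10
#' three-atom residues; element pattern C/N/O. Atoms are spaced widely
#' enough that no covalent pocket bonds arise.
#'
#' @param radius Shell radius in Angstrom (default 6).
#' @param n_atoms Number of shell atoms (default 30).
#' @return `alch_pocket` data frame.
#' @export
toy_pocket <- function(radius = 6, n_atoms = 30L) {
  k <- seq_len(n_atoms) - 0.5
  phi <- acos(1 - 2 * k / n_atoms)
  theta <- pi * (1 + sqrt(5)) * k
  el <- rep(c("C", "N", "O"), length.out = n_atoms)
  out <- data.frame(
    element = el,
    x = radius * sin(phi) * cos(theta),
    y = radius * sin(phi) * sin(theta),
    z = radius * cos(phi),
    resno = rep(seq_len(ceiling(n_atoms / 3)), each = 3)[seq_len(n_atoms)],
    resid = "POC",
    chain = "P",
    elety = paste0(el, seq_len(n_atoms)),
    stringsAsFactors = FALSE)
  class(out) <- c("alch_pocket", "data.frame")
  out
}

#' Generate the synthetic molecule set
#'
#' `2 * n_pairs` random small molecules (pair k uses molecules 2k-1 and
#' 2k) plus the shared toy pocket. Fully determined by `spec$seed`.
#'
#' @param spec `alch_synth_spec`.
#' @return List with `ligands` (named list of `alch_ligand`) and `pocket`.
#' @export
gen_molecules <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n_mol <- 2L * spec$n_pairs
  ligands <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    nh <- sample(spec$heavy_atom_range[1]:spec$heavy_atom_range[2], 1)
    ligands[[m]] <- .gen_molecule(nh, sprintf("mol%03d", m))
  }
  names(ligands) <- vapply(ligands, function(l) l$name, character(1))
  list(ligands = ligands, pocket = toy_pocket())
}

## ---- profiles ----------------------------------------------------------

.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  3 * x^2 - 2 * x^3
}

.ring_count <- function(lig) {
  heavy <- sum(lig$elements != "H")
  hb <- lig$bonds[lig$elements[lig$bonds$i] != "H" &
                    lig$elements[lig$bonds$j] != "H", , drop = FALSE]
  nrow(hb) - heavy + 1L  # cycle rank of a connected molecule
}

#' Pair descriptor and ground-truth profile coefficients
#'
#' The implied ddG is a deterministic function of simple graph descriptors
#' (heavy-atom count difference and ring-count difference); the shared
#' environment profile adds a descriptor-driven slope, a seeded jitter
#' slope and an optional smoothstep barrier.
#'
#' @param lig_a,lig_b Endpoint ligands.
#' @param spec `alch_synth_spec`.
#' @return List with descriptors and profile coefficients including
#'   `ddg_true`.
#' @export
pair_descriptor <- function(lig_a, lig_b, spec) {
  ha <- sum(lig_a$elements != "H"); hb <- sum(lig_b$elements != "H")
  ra <- .ring_count(lig_a); rb <- .ring_count(lig_b)
  ddg <- 0.3 * (ha - hb) + 0.7 * (ra - rb)
  list(
    heavy_a = ha, heavy_b = hb, rings_a = ra, rings_b = rb,
    ddg_true = ddg,
    env_slope = spec$amplitude_per_atom * (ha + hb) / 2 +
      stats::runif(1, -spec$shape_jitter, spec$shape_jitter),
    barrier_height = if (stats::runif(1) < spec$barrier_prob)
      stats::runif(1, -spec$barrier_amplitude, spec$barrier_amplitude) else 0,
    barrier_onset = stats::runif(1, 0.2, 0.6),
    barrier_width = stats::runif(1, 0.2, 0.4)
  )
}

#' Ground-truth cumulative profile of one leg
#'
#' Leg 2 carries the pair's shared environment profile E(lambda); leg 1 is
#' E(lambda) + ddG * lambda, so with signs (+1, -1) the implied ddG equals
#' the stored scalar in closed form. Both legs are anchored: F*(0) = 0.
#'
#' @param desc Descriptor list from [pair_descriptor()].
#' @param leg_id 1 or 2.
#' @return A function `F*(lambda)`.
#' @export
gen_profile <- function(desc, leg_id) {
  stopifnot(leg_id %in% c(1L, 2L))
  force(desc); force(leg_id)
  function(lam) {
    env <- desc$env_slope * lam + desc$barrier_height *
      .smoothstep((lam - desc$barrier_onset) / desc$barrier_width)
    if (leg_id == 1L) env + desc$ddg_true * lam else env
  }
}

## ---- dataset -----------------------------------------------------------

#' Generate a complete synthetic training dataset
#'
#' Molecules, complex-pair graphs, per-window labels
#' `F*(lambda) + N(0, sigma)` with sigma stored as the reliability field,
#' optional outlier contamination, and the ground-truth table.
#'
#' @param spec `alch_synth_spec` (default: [synthetic_spec()]).
#' @param noncovalent_cutoff Cutoff for graph construction in Angstrom
#'   (default 4.5).
#' @param n_dist_basis Gaussian distance-basis size for graph edges; must
#'   match the model's `d_dist_basis` (default 16).
#' @return List of class `alch_synth_data`: `pairs` (named list of
#'   `alch_graph_pair`), `labels` (data frame `pair_id`, `leg_id`,
#'   `lambda`, `cumulative_dG_kcal_mol`, `sigma_kcal_mol`), `truth`
#'   (per-pair descriptors incl. `ddg_true`), `ligands`, `pocket`, `spec`.
#' @export
gen_dataset <- function(spec = synthetic_spec(), noncovalent_cutoff = 4.5,
                        n_dist_basis = 16L) {
  mols <- gen_molecules(spec)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)  # label noise stream, separate from molecules
  lam <- seq(0, 1, length.out = spec$windows_per_leg)
  pairs <- list(); truth <- list(); rows <- list()
  for (k in seq_len(spec$n_pairs)) {
    pid <- sprintf("pair%03d", k)
    la <- mols$ligands[[2L * k - 1L]]; lb <- mols$ligands[[2L * k]]
    ga <- build_complex_graph(complex_structure(la, mols$pocket),
                              cutoff = noncovalent_cutoff,
                              n_dist_basis = n_dist_basis)
    gb <- build_complex_graph(complex_structure(lb, mols$pocket),
                              cutoff = noncovalent_cutoff,
                              n_dist_basis = n_dist_basis)
    pairs[[pid]] <- graph_pair(ga, gb, "complex-pair")
    desc <- pair_descriptor(la, lb, spec)
    truth[[pid]] <- data.frame(pair_id = pid, ligand_a = la$name,
                               ligand_b = lb$name, ddg_true = desc$ddg_true,
                               heavy_a = desc$heavy_a, heavy_b = desc$heavy_b,
                               rings_a = desc$rings_a, rings_b = desc$rings_b,
                               env_slope = desc$env_slope,
                               barrier_height = desc$barrier_height,
                               barrier_onset = desc$barrier_onset,
                               barrier_width = desc$barrier_width)
    for (leg in 1:2) {
      fstar <- gen_profile(desc, leg)
      nw <- length(lam)
      sig <- if (spec$heteroscedastic)
        stats::runif(nw, spec$sigma_range[1], spec$sigma_range[2]) else
          rep(mean(spec$sigma_range), nw)
      if (spec$outlier_frac > 0) {
        out_mask <- stats::runif(nw) < spec$outlier_frac
        sig[out_mask] <- spec$outlier_sigma
      }
      rows[[paste(pid, leg)]] <- data.frame(
        pair_id = pid, leg_id = leg, lambda = lam,
        cumulative_dG_kcal_mol = fstar(lam) + stats::rnorm(nw, 0, sig),
        sigma_kcal_mol = sig)
    }
  }
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  keep <- labels$sigma_kcal_mol <= spec$sigma_cap
  if (!any(keep))
    warning("quality filter removed every sample (sigma_cap too low)")
  labels <- labels[keep, , drop = FALSE]
  structure(list(pairs = pairs, labels = labels,
                 truth = do.call(rbind, truth),
                 ligands = mols$ligands, pocket = mols$pocket, spec = spec),
            class = "alch_synth_data")
}

#' Ground-truth ddG recomputed from the leg profiles
#'
#' Internal-consistency check: s1 * F1*(1) + s2 * F2*(1) must equal the
#' stored per-pair scalar.
#'
#' @param desc Descriptor from [pair_descriptor()].
#' @param signs Leg signs (default `c(1, -1)`).
#' @return Numeric ddG.
#' @export
implied_ddg <- function(desc, signs = c(1, -1)) {
  f1 <- gen_profile(desc, 1L); f2 <- gen_profile(desc, 2L)
  signs[1] * f1(1) + signs[2] * f2(1)
}

#' Write a synthetic dataset to disk
#'
#' Structure manifest (one SDF per ligand, one PDB for the pocket), the
#' label table as CSV, and the ground truth as JSON.
#'
#' @param data `alch_synth_data`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sdf_dir <- file.path(dir, "structures")
  dir.create(sdf_dir, showWarnings = FALSE)
  for (lg in data$ligands)
    write_ligand_sdf(lg, file.path(sdf_dir, paste0(lg$name, ".sdf")))
  pk <- data$pocket
  bio3d::write.pdb(file = file.path(sdf_dir, "pocket.pdb"),
                   xyz = as.numeric(t(cbind(pk$x, pk$y, pk$z))),
                   resno = pk$resno, resid = pk$resid, chain = pk$chain,
                   elety = pk$elety, elesy = pk$element)
  utils::write.csv(data$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  manifest <- data.frame(
    pair_id = data$truth$pair_id,
    sdf_a = file.path("structures", paste0(data$truth$ligand_a, ".sdf")),
    sdf_b = file.path("structures", paste0(data$truth$ligand_b, ".sdf")),
    pocket_pdb = file.path("structures", "pocket.pdb"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(data$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
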
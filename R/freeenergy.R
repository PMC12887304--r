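## Assembling relative (ddG) and absolute (dG) binding free energies from
## per-leg terminal cumulative energies of a thermodynamic cycle, plus the
## star-map perturbation network and the mapping of star ddG values onto
## per-ligand dG.

#' Specify the legs of a thermodynamic cycle
#'
#' Each leg carries an ordered lambda grid starting at 0 and a sign with
#' which its terminal cumulative energy enters the combination. The default
#' RBFE convention is two legs of 11 uniform windows with signs (+1, -1),
#' which makes a symmetric perturbation vanish identically.
#'
#' @param lam_values_1,lam_values_2 Sorted lambda grids for legs 1 and 2;
#'   each must start at 0 and lie in \[0, 1\].
#' @param signs Numeric length-2 vector of +1/-1 (default `c(1, -1)`).
#' @return Object of class `alch_pathway`.
#' @export
pathway_spec <- function(lam_values_1 = seq(0, 1, length.out = 11),
                         lam_values_2 = seq(0, 1, length.out = 11),
                         signs = c(1, -1)) {
  check_leg <- function(lv, id) {
    if (length(lv) < 1 || lv[1] != 0 || is.unsorted(lv, strictly = TRUE) ||
        any(lv < 0 | lv > 1))
      alch_stop(sprintf(
        "leg %d lambda grid must be strictly increasing in [0,1] starting at 0",
        id), "alch_pathway_error")
  }
  check_leg(lam_values_1, 1); check_leg(lam_values_2, 2)
  if (length(signs) != 2 || !all(abs(signs) == 1))
    alch_stop("signs must be two values of +1/-1", "alch_pathway_error")
  structure(list(legs = list(
    list(leg_id = 1L, lam_values = as.numeric(lam_values_1), sign = signs[1]),
    list(leg_id = 2L, lam_values = as.numeric(lam_values_2), sign = signs[2])
  )), class = "alch_pathway")
}

# Terminal cumulative energy of each leg plus the signed combination.
.combine_legs <- function(pair, pathway, params) {
  terminal <- numeric(2)
  for (leg in pathway$legs) {
    lam_end <- leg$lam_values[length(leg$lam_values)]
    prof <- predict_profile(pair, leg$leg_id, lam_end, params)
    terminal[leg$leg_id] <- prof$cumulative_dG[1]
  }
  signs <- vapply(pathway$legs, `[[`, numeric(1), "sign")
  list(value = sum(signs * terminal), per_leg_terminal = terminal)
}

#' Relative binding free energy of a perturbation
#'
#' ddG = s1 * F1(lambda_end) + s2 * F2(lambda_end) over the two legs of the
#' cycle. Because legs differ only in concatenation order, identical
#' endpoints give ddG = 0 exactly and swapping the endpoints negates ddG
#' exactly.
#'
#' @param pair `alch_graph_pair` of kind `"complex-pair"`.
#' @param pathway `alch_pathway` (default two uniform 11-window legs).
#' @param params `alch_params`.
#' @return List of class `alch_fe_result` with `ddg` (kcal/mol),
#'   `per_leg_terminal` and `pathway`.
#' @export
rbfe <- function(pair, pathway = pathway_spec(), params) {
  if (!inherits(pair, "alch_graph_pair") || pair$kind != "complex-pair")
    alch_stop("rbfe requires a complex-pair", "alch_pair_error")
  cmb <- .combine_legs(pair, pathway, params)
  structure(list(ddg = cmb$value, per_leg_terminal = cmb$per_leg_terminal,
                 pathway = pathway), class = "alch_fe_result")
}

#' Absolute binding free energy of a ligand (or guest)
#'
#' Same signed leg combination over the complex-ligand decoupling pathway.
#'
#' @param pair `alch_graph_pair` of kind `"complex-ligand-pair"`.
#' @param pathway `alch_pathway`; for ABFE the default signs are
#'   `c(1, -1)` as well (complex leg minus solvent leg).
#' @param params `alch_params`.
#' @return List of class `alch_fe_result` with `dg` (kcal/mol).
#' @export
abfe <- function(pair, pathway = pathway_spec(), params) {
  if (!inherits(pair, "alch_graph_pair") || pair$kind != "complex-ligand-pair")
    alch_stop("abfe requires a complex-ligand-pair", "alch_pair_error")
  cmb <- .combine_legs(pair, pathway, params)
  structure(list(dg = cmb$value, per_leg_terminal = cmb$per_leg_terminal,
                 pathway = pathway), class = "alch_fe_result")
}

#' @export
print.alch_fe_result <- function(x, ...) {
  if (!is.null(x$ddg))
    cat(sprintf("<alch_fe_result: ddG = %+.3f kcal/mol (legs %.3f / %.3f)>\n",
                x$ddg, x$per_leg_terminal[1], x$per_leg_terminal[2]))
  else
    cat(sprintf("<alch_fe_result: dG = %+.3f kcal/mol (legs %.3f / %.3f)>\n",
                x$dg, x$per_leg_terminal[1], x$per_leg_terminal[2]))
  invisible(x)
}

#' Build a star perturbation map over a ligand series
#'
#' Picks the reference (hub) ligand as the one with the largest mean
#' maximum-common-substructure overlap with all others — i.e. the ligand
#' requiring the smallest perturbations — tie-broken by fewest heavy
#' atoms, then input order, and connects every other ligand to it.
#'
#' @param ligands List of `alch_ligand` (length >= 2); names are used as
#'   ligand ids (default `lig1`, `lig2`, ...).
#' @param reference_selector Optional function `(ligands) -> index`
#'   overriding the MCS-based hub choice.
#' @return List of class `alch_star_map` with `reference` (id),
#'   `pairs` (data frame `ref`, `ligand`) and the pairwise `mcs` matrix
#'   (NULL when a custom selector is used).
#' @export
star_map <- function(ligands, reference_selector = NULL) {
  n <- length(ligands)
  if (n < 2) alch_stop("star_map needs at least 2 ligands", "alch_star_error")
  if (is.null(names(ligands)) || any(names(ligands) == ""))
    names(ligands) <- paste0("lig", seq_len(n))
  ids <- names(ligands)
  mcs <- NULL
  if (is.null(reference_selector)) {
    mcs <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      s <- mcs_size(ligands[[a]], ligands[[b]])
      mcs[a, b] <- s; mcs[b, a] <- s
    }
    mean_overlap <- rowSums(mcs) / (n - 1)
    heavy <- vapply(ligands, function(l) sum(l$elements != "H"), integer(1))
    ## max mean overlap; ties: fewest heavy atoms, then input order
    ref_idx <- order(-mean_overlap, heavy, seq_len(n))[1]
  } else {
    ref_idx <- reference_selector(ligands)
  }
  structure(list(
    reference = ids[ref_idx],
    pairs = data.frame(ref = ids[ref_idx], ligand = ids[-ref_idx],
                       stringsAsFactors = FALSE),
    mcs = mcs
  ), class = "alch_star_map")
}

#' Map star-network ddG values onto per-ligand dG
#'
#' Each ligand's predicted dG is its ddG versus the reference plus a single
#' offset chosen so that the mean predicted dG equals the mean experimental
#' dG over the ligands with experimental values. Rank and correlation
#' metrics are invariant to the offset.
#'
#' @param ddg_map Named numeric vector: ddG (kcal/mol) of each ligand
#'   versus the reference; the reference itself may be included with 0.
#' @param experimental_dg Named numeric vector of experimental dG values
#'   (at least one).
#' @return Named numeric vector of predicted dG over the ligands in
#'   `ddg_map`.
#' @export
ddg_to_dg <- function(ddg_map, experimental_dg) {
  if (length(experimental_dg) == 0)
    alch_stop("no experimental dG values provided", "alch_fe_error")
  if (is.null(names(ddg_map)) || is.null(names(experimental_dg)))
    alch_stop("ddg_map and experimental_dg must be named", "alch_fe_error")
  common <- intersect(names(ddg_map), names(experimental_dg))
  if (length(common) == 0)
    alch_stop("no ligand shared between ddG map and experimental set",
              "alch_fe_error")
  offset <- mean(experimental_dg[common]) - mean(ddg_map[common])
  ddg_map + offset
}
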
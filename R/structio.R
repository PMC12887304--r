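## Structure input/output: ligands from SDF/MOL2, proteins from PDB,
## binding-pocket extraction. Parsing is delegated to ChemmineR / bio3d;
## this layer normalizes their output into the package's containers and
## applies the validity screens (valence, finite coordinates).

alch_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "alch_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# V2000 charge codes: 0 none, 1..3 = +3..+1, 4 radical, 5..7 = -1..-3
.sdf_charge_code <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                      `5` = -1, `6` = -2, `7` = -3)

.max_valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                  Cl = 1, Br = 1, I = 1)

#' Construct a ligand structure
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Atom indices are 1-based throughout the package.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix `n x 3` of coordinates in Angstrom.
#' @param formal_charges Integer vector of formal charges (default all 0).
#' @param bonds Data frame with columns `i`, `j` (atom indices) and `order`
#'   (1, 2, 3, or 4 for aromatic).
#' @param name Optional molecule name.
#' @param validate Run the validity screen (finite coordinates, bond
#'   indices in range, valence)? Default `TRUE`.
#' @return An object of class `alch_ligand`.
#' @export
ligand_structure <- function(elements, coords, formal_charges = NULL,
                             bonds = NULL, name = "ligand", validate = TRUE) {
  n <- length(elements)
  coords <- matrix(as.numeric(coords), nrow = n, ncol = 3)
  if (is.null(formal_charges)) formal_charges <- integer(n)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          order = numeric())
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.numeric(bonds$order))
  lig <- structure(list(
    elements = as.character(elements),
    coords = coords,
    formal_charges = as.integer(formal_charges),
    bonds = bonds,
    name = name
  ), class = "alch_ligand")
  if (validate) validate_ligand(lig)
  lig
}

#' Validate a ligand structure
#'
#' Checks finite coordinates, in-range distinct bond endpoints, no duplicate
#' bonds, and element valences. A molecule whose summed bond order at any
#' atom exceeds the element's allowed valence (adjusted by formal charge for
#' N/O/P/S; aromatic bonds count 1.5) is rejected, mirroring the removal of
#' valence-invalid structures from training/benchmark sets.
#'
#' @param lig `alch_ligand`.
#' @return `lig` invisibly; raises a condition of class
#'   `alch_validation_error` on failure.
#' @export
validate_ligand <- function(lig) {
  n <- length(lig$elements)
  if (n < 1) alch_stop("ligand has no atoms", "alch_validation_error")
  if (!all(is.finite(lig$coords)))
    alch_stop("non-finite ligand coordinates", "alch_validation_error")
  b <- lig$bonds
  if (nrow(b) > 0) {
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n))
      alch_stop("bond endpoint out of atom range", "alch_validation_error")
    if (any(b$i == b$j))
      alch_stop("bond with identical endpoints", "alch_validation_error")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key))
      alch_stop("duplicate bond record", "alch_validation_error")
  }
  ## valence screen
  vord <- ifelse(b$order == 4, 1.5, b$order)
  vsum <- numeric(n)
  for (k in seq_len(nrow(b))) {
    vsum[b$i[k]] <- vsum[b$i[k]] + vord[k]
    vsum[b$j[k]] <- vsum[b$j[k]] + vord[k]
  }
  for (a in seq_len(n)) {
    el <- lig$elements[a]
    if (!el %in% names(.max_valence)) next  # unknown elements not screened
    allowed <- .max_valence[[el]]
    if (el %in% c("N", "O", "P", "S"))
      allowed <- allowed + lig$formal_charges[a]
    if (vsum[a] > allowed + 1e-6)
      alch_stop(sprintf(
        "valence violation at atom %d (%s): bond order sum %.1f > allowed %.1f",
        a, el, vsum[a], allowed), "alch_validation_error")
  }
  invisible(lig)
}

#' @export
print.alch_ligand <- function(x, ...) {
  cat(sprintf("<alch_ligand '%s': %d atoms (%d heavy), %d bonds>\n",
              x$name, length(x$elements),
              sum(x$elements != "H"), nrow(x$bonds)))
  invisible(x)
}

#' Read a ligand from SDF or MOL2
#'
#' Hydrogens are kept if present and never added; bond orders are preserved
#' (aromatic bonds carry order 4). Formal charges come from the V2000
#' charge-code column, overridden by `M  CHG` property lines when present.
#'
#' @param path File path.
#' @param format `"sdf"` or `"mol2"`; default inferred from the extension.
#' @param index Which record to read from a multi-record file (default 1).
#' @return An `alch_ligand`.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2"), index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path))
    alch_stop(paste("ligand file not found:", path), "alch_io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", sd = "sdf", mol = "sdf",
                     mol2 = "mol2",
                     alch_stop(paste("cannot infer ligand format from:", path),
                               "alch_format_error"))
  }
  lig <- switch(format,
                sdf = .read_ligand_sdf(path, index),
                mol2 = .read_ligand_mol2(path))
  validate_ligand(lig)
  lig
}

.read_ligand_sdf <- function(path, index) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) alch_stop(
      sprintf("failed to parse SDF '%s': %s", path, conditionMessage(e)),
      "alch_format_error"))
  if (length(sdfset) < index)
    alch_stop(sprintf("SDF '%s' has %d record(s); record %d requested",
                      path, length(sdfset), index), "alch_format_error")
  sdf <- sdfset[[index]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || nrow(ab) == 0 || ncol(ab) < 3)
    alch_stop(sprintf("SDF '%s' record %d has a malformed atom block",
                      path, index), "alch_format_error")
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- .sdf_charge_code[as.character(ab[, "C6"])]
  charges[is.na(charges)] <- 0
  mchg <- .sdf_mchg(path, index)
  if (length(mchg) > 0) {
    charges[] <- 0                       # M CHG supersedes atom-block codes
    charges[mchg$atom] <- mchg$charge
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL else
    data.frame(i = bb[, 1], j = bb[, 2], order = bb[, 3])
  ligand_structure(elements, coords, as.integer(charges), bonds,
                   name = ChemmineR::sdfid(sdf), validate = FALSE)
}

# Scan the raw file for M CHG property lines of the index-th record.
.sdf_mchg <- function(path, index) {
  lines <- readLines(path, warn = FALSE)
  rec_end <- c(0L, which(trimws(lines) == "$$$$"))
  if (length(rec_end) < index + 1) rec_end <- c(rec_end, length(lines))
  span <- lines[(rec_end[index] + 1):rec_end[index + 1]]
  chg_lines <- grep("^M  CHG", span, value = TRUE)
  out <- list(atom = integer(), charge = integer())
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    npair <- f[1]
    for (p in seq_len(npair)) {
      out$atom <- c(out$atom, f[2 * p])
      out$charge <- c(out$charge, f[2 * p + 1])
    }
  }
  if (length(out$atom) == 0) return(list())
  out
}

.read_ligand_mol2 <- function(path) {
  m <- tryCatch(
    bio3d::read.mol2(path),
    error = function(e) alch_stop(
      sprintf("failed to parse MOL2 '%s': %s", path, conditionMessage(e)),
      "alch_format_error"))
  at <- m$atom
  elements <- sub("\\..*$", "", at$elety)
  order <- vapply(as.character(m$bond$type), function(t)
    switch(t, `1` = 1, `2` = 2, `3` = 3, ar = 4, am = 1, du = 1,
           alch_stop(paste("unsupported MOL2 bond type:", t),
                     "alch_format_error")),
    numeric(1))
  ligand_structure(
    elements,
    cbind(at$x, at$y, at$z),
    integer(length(elements)),  # MOL2 charges are partial, not formal: not mapped
    data.frame(i = m$bond$origin, j = m$bond$target, order = order),
    name = "mol2",
    validate = FALSE)
}

#' Write a ligand as an SDF (V2000) record
#'
#' Deterministic writer used for round-tripping and by the synthetic-data
#' generator; emits `M  CHG` lines for non-zero formal charges.
#'
#' @param lig `alch_ligand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(lig, path) {
  n <- length(lig$elements)
  nb <- nrow(lig$bonds)
  lines <- c(
    lig$name, "  alchnet", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            lig$coords[, 1], lig$coords[, 2], lig$coords[, 3], lig$elements))
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", lig$bonds$i, lig$bonds$j,
                              as.integer(lig$bonds$order)))
  chg <- which(lig$formal_charges != 0)
  if (length(chg) > 0) {
    for (start in seq(1, length(chg), by = 8)) {
      idx <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx,
                                              lig$formal_charges[idx]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

.water_resids <- c("HOH", "WAT", "DOD", "H2O", "TIP3", "TIP", "SOL", "SPC")
.ion_resids <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU", "NI",
                 "CO", "CD", "LI", "RB", "CS", "SR", "BA", "IOD", "BR")
.two_letter_elements <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU",
                          "SE", "NI", "CO", "CD", "LI", "SR", "BA", "RB", "CS")

#' Read protein atoms from a PDB file
#'
#' Returns one row per atom with residue metadata. Waters and monoatomic
#' ions are excluded by default. Alternate locations are resolved by
#' highest occupancy, tie-broken by altloc letter order. Missing element
#' symbols are inferred from the atom name.
#'
#' @param path PDB file path.
#' @param exclude_waters,exclude_ions Drop water / monoatomic-ion residues
#'   (default `TRUE`).
#' @return Data frame of class `alch_protein` with columns `element`, `x`,
#'   `y`, `z`, `resno`, `resid`, `chain`, `elety`.
#' @export
read_protein <- function(path, exclude_waters = TRUE, exclude_ions = TRUE) {
  if (!file.exists(path))
    alch_stop(paste("PDB file not found:", path), "alch_io_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                     verbose = FALSE)),
    error = function(e) alch_stop(
      sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)),
      "alch_format_error"))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0)
    alch_stop(sprintf("PDB '%s' contains no ATOM/HETATM records", path),
              "alch_format_error")
  if (exclude_waters) at <- at[!(toupper(at$resid) %in% .water_resids), , drop = FALSE]
  if (exclude_ions) at <- at[!(toupper(at$resid) %in% .ion_resids), , drop = FALSE]
  if (nrow(at) == 0)
    alch_stop(sprintf("PDB '%s' has no protein atoms after filtering", path),
              "alch_format_error")
  at <- .resolve_altloc(at)
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el))
    element[missing_el] <- .infer_element(at$elety[missing_el],
                                          at$type[missing_el])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  out <- data.frame(
    element = element,
    x = at$x, y = at$y, z = at$z,
    resno = at$resno, resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    elety = at$elety,
    stringsAsFactors = FALSE)
  if (!all(is.finite(c(out$x, out$y, out$z))))
    alch_stop(sprintf("non-finite coordinates in PDB '%s'", path),
              "alch_format_error")
  class(out) <- c("alch_protein", "data.frame")
  out
}

# Keep the highest-occupancy conformer per (chain, resno, atom name);
# ties broken by altloc letter order.
.resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1.0, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

.infer_element <- function(elety, type) {
  nm <- gsub("[0-9']", "", toupper(elety))
  vapply(seq_along(nm), function(k) {
    two <- substr(nm[k], 1, 2)
    if (type[k] == "HETATM" && two %in% .two_letter_elements) return(two)
    substr(nm[k], 1, 1)
  }, character(1))
}

#' Extract the binding pocket around a ligand
#'
#' Keeps every protein atom within `cutoff` Angstrom of any ligand atom and
#' then completes residues: if one atom of a residue is in range, the whole
#' residue is kept.
#'
#' @param protein `alch_protein` data frame from [read_protein()].
#' @param ligand `alch_ligand`.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @param complete_residues Apply whole-residue completion (default `TRUE`).
#' @return Data frame of class `alch_pocket` (same columns as the protein
#'   input).
#' @export
extract_pocket <- function(protein, ligand, cutoff = 5.0,
                           complete_residues = TRUE) {
  stopifnot(cutoff > 0)
  P <- cbind(protein$x, protein$y, protein$z)
  L <- ligand$coords
  d2min <- .min_cross_dist2(P, L)
  in_range <- d2min <= cutoff^2
  if (!any(in_range))
    alch_stop(sprintf(
      "no protein atom within %.2f Angstrom of the ligand (closest: %.2f)",
      cutoff, sqrt(min(d2min))), "alch_empty_pocket_error")
  if (complete_residues) {
    reskey <- paste(protein$chain, protein$resno, sep = "|")
    keep <- reskey %in% unique(reskey[in_range])
  } else keep <- in_range
  pocket <- protein[keep, , drop = FALSE]
  rownames(pocket) <- NULL
  class(pocket) <- c("alch_pocket", class(pocket))
  pocket
}

# Squared distance from each row of P to its nearest row of L.
.min_cross_dist2 <- function(P, L) {
  pp <- rowSums(P^2)
  ll <- rowSums(L^2)
  D2 <- outer(pp, ll, "+") - 2 * P %*% t(L)
  pmax(apply(D2, 1, min), 0)
}

#' Bundle a ligand with its pocket
#'
#' Both parts must share one coordinate frame (Angstrom).
#'
#' @param ligand `alch_ligand`.
#' @param pocket `alch_pocket` (or protein data frame already restricted to
#'   the pocket).
#' @return Object of class `alch_complex`.
#' @export
complex_structure <- function(ligand, pocket) {
  if (nrow(pocket) == 0)
    alch_stop("empty pocket in complex", "alch_empty_pocket_error")
  structure(list(ligand = ligand, pocket = pocket), class = "alch_complex")
}
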
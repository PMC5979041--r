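.atomicMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, F = 18.998, CL = 35.45, BR = 79.904,
                   I = 126.904, NA. = 22.99, K = 39.098, MG = 24.305,
                   CA = 40.078, ZN = 65.38, FE = 55.845, SE = 78.971)

elementMass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- .atomicMasses[el]
  if (anyNA(m)) stopf("unknown element symbol: %s",
                      paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a fixed-column PDB file (via bio3d),
#' converts coordinates from Angstrom to nm, flags HETATM records as ligand
#' atoms, keeps only blank/'A' alternate locations and the first model, and
#' ignores all other record types.
#'
#' @param file path to a PDB file
#' @return a [StructureModel-class]
#' @export
readStructure <- function(file) {
  if (!file.exists(file)) stopf("no such file: %s", file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stopf("PDB parse failed for %s: %s", file,
                              conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stopf("zero atoms parsed from %s", file)
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad))
    stopf("malformed coordinate columns at atom record %d of %s", bad[1], file)
  resno <- suppressWarnings(as.integer(a$resno))
  if (anyNA(resno))
    stopf("residue number does not parse as integer at atom record %d",
          which(is.na(resno))[1])
  element <- a$elesy
  noel <- is.na(element) | element == ""
  if (any(noel))  # fall back on the first letter of the atom name
    element[noel] <- substr(gsub("[0-9 ]", "", a$elety[noel]), 1, 1)
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = trimws(element),
    resname = trimws(a$resid), resno = resno, chain = a$chain %||% "",
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    ligand = a$type == "HETATM", stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms, provenance = file)
}

#' Heavy-atom selection helpers
#'
#' `heavyAtoms` returns indices of non-hydrogen atoms; `ligandAtoms` those
#' flagged as ligand (HETATM) records; `proteinHeavyAtoms` heavy atoms not
#' flagged as ligand.
#'
#' @param structure a [StructureModel-class]
#' @return integer atom indices
#' @export
heavyAtoms <- function(structure) {
  which(toupper(atomTable(structure)$element) != "H")
}

#' @rdname heavyAtoms
#' @export
ligandAtoms <- function(structure) which(atomTable(structure)$ligand)

#' @rdname heavyAtoms
#' @export
proteinHeavyAtoms <- function(structure) {
  a <- atomTable(structure)
  which(!a$ligand & toupper(a$element) != "H")
}

#' Define the binding pocket around a bound ligand
#'
#' The binding pocket is the set of protein heavy atoms whose minimum
#' distance to any ligand heavy atom is at most `cutoff` (default 0.5 nm,
#' i.e. 5 Angstrom, threshold inclusive), computed on a holo structure.
#'
#' @param holo a [StructureModel-class] containing the bound ligand
#' @param ligand indices of ligand heavy atoms (default: flagged HETATM heavy
#'   atoms)
#' @param cutoff nm
#' @return integer indices of pocket atoms (rows of the atom table).  An
#'   empty pocket triggers a warning, not an error.
#' @export
definePocket <- function(holo, ligand = NULL, cutoff = 0.5) {
  a <- atomTable(holo)
  if (is.null(ligand)) {
    ligand <- intersect(ligandAtoms(holo), heavyAtoms(holo))
  }
  if (length(ligand) == 0) stopf("empty ligand selection")
  prot <- proteinHeavyAtoms(holo)
  if (length(prot) == 0) stopf("structure has no protein heavy atoms")
  xyzL <- as.matrix(a[ligand, c("x", "y", "z")])
  xyzP <- as.matrix(a[prot, c("x", "y", "z")])
  dmin <- apply(xyzP, 1, function(p)
    sqrt(min(colSums((t(xyzL) - p)^2))))
  sel <- prot[dmin <= cutoff]
  if (length(sel) == 0)
    warning("binding pocket undefined: no protein heavy atom within cutoff")
  sel
}

#' Build a coordinate trajectory from an array or frame list
#'
#' @param coords frames x atoms x 3 array, or list of atoms x 3 matrices (nm)
#' @param frameInterval ns
#' @param atoms atom metadata data.frame (as in [StructureModel-class]);
#'   a minimal table is fabricated when omitted
#' @return a [CoordinateTrajectory-class]
#' @export
coordinateTrajectory <- function(coords, frameInterval, atoms = NULL) {
  if (is.list(coords)) {
    nat <- nrow(coords[[1]])
    arr <- array(NA_real_, c(length(coords), nat, 3))
    for (i in seq_along(coords)) {
      if (nrow(coords[[i]]) != nat) stopf("atom count varies across frames")
      arr[i, , ] <- as.matrix(coords[[i]])
    }
    coords <- arr
  }
  if (is.null(atoms)) {
    nat <- dim(coords)[2]
    atoms <- data.frame(serial = seq_len(nat), name = "X", element = "C",
                        resname = "UNK", resno = seq_len(nat), chain = "A",
                        x = coords[1, , 1], y = coords[1, , 2],
                        z = coords[1, , 3], ligand = FALSE)
  }
  new("CoordinateTrajectory", coords = coords, frameInterval = frameInterval,
      atoms = atoms)
}

frameCoords <- function(traj, i) traj@coords[i, , , drop = TRUE]

#' Binary ligand-residue contact features
#'
#' One feature column per residue group: 1 when the minimum heavy-atom
#' distance between the ligand selection and the group is at most `cutoff`
#' (inclusive), else 0, per frame.  This is the binary nearest-neighbour
#' contact featurization used as Markov-model input coordinates.
#'
#' @param traj a [CoordinateTrajectory-class]
#' @param ligand ligand atom indices
#' @param residueGroups named list of protein atom-index vectors, one per
#'   residue
#' @param cutoff nm (default 0.5)
#' @return a [FeatureTrajectory-class] of 0/1 indicators
#' @export
contactFeatures <- function(traj, ligand, residueGroups, cutoff = 0.5) {
  if (length(ligand) == 0) stopf("empty ligand selection")
  empty <- vapply(residueGroups, length, 1L) == 0
  if (any(empty))
    stopf("empty residue group: %s",
          paste(names(residueGroups)[empty], collapse = ", "))
  nf <- dim(traj@coords)[1]
  ng <- length(residueGroups)
  out <- matrix(0, nf, ng)
  for (f in seq_len(nf)) {
    xyz <- frameCoords(traj, f)
    xl <- xyz[ligand, , drop = FALSE]
    for (g in seq_len(ng)) {
      xg <- xyz[residueGroups[[g]], , drop = FALSE]
      d2 <- outer(rowSums(xl^2), rowSums(xg^2), "+") - 2 * xl %*% t(xg)
      if (sqrt(max(0, min(d2))) <= cutoff) out[f, g] <- 1
    }
  }
  labels <- names(residueGroups) %||% paste0("res", seq_len(ng))
  new("FeatureTrajectory", values = out, labels = labels,
      frameInterval = traj@frameInterval)
}

#' Pocket-ligand center-of-mass distance
#'
#' Per-frame radial distance between the mass-weighted centroids of the
#' binding-pocket selection and the ligand selection.
#'
#' @param traj a [CoordinateTrajectory-class]
#' @param pocket,ligand non-empty atom index sets
#' @return numeric distance series in nm, one value per frame
#' @export
pocketLigandDistance <- function(traj, pocket, ligand) {
  if (length(pocket) == 0 || length(ligand) == 0)
    stopf("pocket and ligand selections must be non-empty")
  a <- atomTable(traj)
  mP <- elementMass(a$element[pocket])
  mL <- elementMass(a$element[ligand])
  nf <- dim(traj@coords)[1]
  vapply(seq_len(nf), function(f) {
    xyz <- frameCoords(traj, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    cP <- colSums(xyz[pocket, , drop = FALSE] * mP) / sum(mP)
    cL <- colSums(xyz[ligand, , drop = FALSE] * mL) / sum(mL)
    sqrt(sum((cP - cL)^2))
  }, numeric(1))
}
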
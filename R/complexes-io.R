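# residue chemistry tables for toy/real receptor side chains
# (donor/acceptor atom names, charged groups, aromatic rings, cation groups)
.RESIDUE_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), TRP = c("NE1"),
  ASN = c("ND2"), GLN = c("NE2"), SER = c("OG"), THR = c("OG1"),
  TYR = c("OH"), CYS = c("SG"), HIS = c("ND1", "NE2"))
.RESIDUE_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2"), MET = c("SD"))
.RESIDUE_NEG_GROUP <- list(ASP = c("CG", "OD1", "OD2"),
                           GLU = c("CD", "OE1", "OE2"))
.RESIDUE_POS_GROUP <- list(ARG = c("CZ", "NE", "NH1", "NH2"),
                           LYS = c("NZ"))
.RESIDUE_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Read a receptor-ligand complex from a PDB file
#'
#' ATOM records become receptor residues; HETATM records (waters skipped)
#' are assembled into the ligand, with connectivity taken from CONECT
#' records when present and otherwise inferred from interatomic distances
#' (covalent radius heuristics). Parsing uses \pkg{bio3d}.
#'
#' @param path PDB file
#' @param ligandCode optional HET residue name to select as ligand; default
#'   takes all non-water HETATM records
#' @param poseId pose identifier (defaults to the file name)
#' @return a \linkS4class{ComplexStructure}
#' @export
readComplex <- function(path, ligandCode = NULL, poseId = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  isWater <- at$resid %in% c("HOH", "WAT")
  het <- at$type == "HETATM" & !isWater
  if (!is.null(ligandCode)) het <- het & at$resid == ligandCode
  if (!any(het))
    stop("no ligand HETATM records found",
         if (!is.null(ligandCode)) paste0(" for HET code '", ligandCode, "'"))
  rec <- at[at$type == "ATOM" & !isWater, , drop = FALSE]
  residues <- data.frame(
    resname = rec$resid, resno = rec$resno, chain = rec$chain,
    atom = rec$elety, element = .guessElement(rec$elety, rec$elesy),
    x = rec$x, y = rec$y, z = rec$z)
  lig <- at[het, , drop = FALSE]
  ligMol <- .ligandFromPdbAtoms(lig, pdb, basename(path))
  if (is.null(poseId)) poseId <- sub("\\.pdb$", "", basename(path))
  new("ComplexStructure", residues = residues, ligand = ligMol,
      poseId = poseId)
}

.guessElement <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- trimws(elesy)
    known <- e %in% names(.ATOMIC_MASS)
    if (all(known) && all(nzchar(e))) return(e)
  }
  nm <- trimws(name)
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "Cl"), "Cl",
    ifelse(two %in% c("BR", "Br"), "Br", substr(nm, 1, 1)))
}

# covalent-distance bond inference for HETATM ligands without CONECT
.COV_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
                 S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84)

.ligandFromPdbAtoms <- function(lig, pdb, fallbackId) {
  el <- .guessElement(lig$elety, lig$elesy)
  xyz <- cbind(lig$x, lig$y, lig$z)
  charge <- ifelse(is.na(lig$charge), 0L, as.integer(lig$charge))
  n <- nrow(lig)
  bonds <- NULL
  # distance-based connectivity (CONECT records are not retained by bio3d's
  # atom table; the heuristic reproduces them for ordinary ligands)
  if (n > 1L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- apply(pairs, 1, function(p) {
      r <- .dist3(xyz[p[1], ], xyz[p[2], ])
      r < (.COV_RADIUS[el[p[1]]] + .COV_RADIUS[el[p[2]]]) * 1.3
    })
    if (any(keep))
      bonds <- data.frame(a1 = pairs[keep, 1], a2 = pairs[keep, 2],
                          order = 1L, aromatic = FALSE)
  }
  id <- unique(lig$resid)[1]
  if (!nzchar(id)) id <- fallbackId
  mol <- newMolecule(id, atoms = data.frame(element = el, charge = charge),
                     bonds = bonds, coords = xyz)
  .perceiveAromaticity(mol)
}

#' Write a complex to a PDB file
#'
#' Receptor atoms as ATOM records, ligand heavy atoms as HETATM records
#' (residue name LIG). Coordinates are written at PDB precision (1e-3 A).
#'
#' @param cx a \linkS4class{ComplexStructure}
#' @param path output file
#' @return invisibly, the path
#' @export
writeComplexPDB <- function(cx, path) {
  r <- cx@residues
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(r))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, r$atom[i], r$resname[i],
      ifelse(is.na(r$chain[i]), "A", r$chain[i]), r$resno[i],
      r$x[i], r$y[i], r$z[i], r$element[i]))
  }
  lig <- cx@ligand
  xyz <- lig@conformers[[1]]$coords
  a <- lig@atoms
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, paste0(a$element[i], i), "LIG", "L", 1L,
      xyz[i, 1], xyz[i, 2], xyz[i, 3], a$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Apply a rigid transform to a whole complex
#'
#' Rotates and translates receptor and ligand coordinates together, keeping
#' them in one frame (all interaction detections are invariant under this).
#'
#' @param cx a \linkS4class{ComplexStructure}
#' @param R 3x3 rotation matrix
#' @param t length-3 translation, Angstrom
#' @return the transformed complex
#' @export
transformComplex <- function(cx, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(cx@residues[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% R, 2, t, `+`)
  cx@residues[, c("x", "y", "z")] <- xyz
  cx@ligand <- transformMolecule(cx@ligand, R = R, t = t)
  cx
}

# per-residue atom table split (residue id "RESNAME:RESNO")
.residueSplit <- function(cx) {
  r <- cx@residues
  split(r, paste(r$resname, r$resno, sep = ":"))
}

# ligand heavy-atom coordinates and elements
.ligandHeavy <- function(cx) {
  a <- cx@ligand@atoms
  xyz <- cx@ligand@conformers[[1]]$coords
  keep <- a$element != "H"
  list(xyz = xyz[keep, , drop = FALSE], atoms = a[keep, , drop = FALSE],
       index = which(keep))
}
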
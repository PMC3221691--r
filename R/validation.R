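#' Symmetry-aware ligand RMSD between a docked and a reference pose
#'
#' Superposes the docked receptor onto the reference receptor (Kabsch on
#' C-alpha atoms; identity when the receptor coordinates already agree),
#' applies the transform to the docked ligand, and returns the heavy-atom
#' RMSD minimized over all graph automorphisms of the ligand (so e.g. a
#' benzene rotated by 60 degrees in place scores 0).
#'
#' @param docked,reference \linkS4class{ComplexStructure} objects with the
#'   same ligand topology and shared residue numbering
#' @return RMSD in Angstrom
#' @export
ligandRmsd <- function(docked, reference) {
  tf <- .receptorTransform(docked, reference)
  ligD <- .ligandHeavy(docked)
  ligR <- .ligandHeavy(reference)
  if (nrow(ligD$xyz) != nrow(ligR$xyz))
    stop("ligand heavy-atom counts differ; no atom correspondence")
  xyzD <- .applyTransform(ligD$xyz, tf)
  maps <- .ligandAutomorphisms(docked@ligand)
  if (!length(maps)) stop("could not resolve a ligand atom correspondence")
  best <- Inf
  heavyIdx <- ligD$index
  for (mp in maps) {
    # mp maps heavy-atom positions of docked onto reference order
    perm <- match(mp, heavyIdx)
    rmsd <- sqrt(mean(rowSums((xyzD[perm, , drop = FALSE] - ligR$xyz)^2)))
    if (rmsd < best) best <- rmsd
  }
  best
}

# Kabsch transform docked -> reference receptor frame (CA atoms, then any
# shared atoms; identity when coordinates already coincide)
.receptorTransform <- function(docked, reference) {
  rd <- docked@residues; rr <- reference@residues
  keyD <- paste(rd$resname, rd$resno, rd$chain, rd$atom)
  keyR <- paste(rr$resname, rr$resno, rr$chain, rr$atom)
  shared <- intersect(keyD, keyR)
  if (length(shared) < 3L)
    return(list(R = diag(3), t = c(0, 0, 0)))
  iD <- match(shared, keyD); iR <- match(shared, keyR)
  ca <- grepl(" CA$", shared)
  if (sum(ca) >= 3L) { iD <- iD[ca]; iR <- iR[ca] }
  fromM <- as.matrix(rd[iD, c("x", "y", "z")])
  toM <- as.matrix(rr[iR, c("x", "y", "z")])
  if (max(abs(fromM - toM)) < 1e-9)
    return(list(R = diag(3), t = c(0, 0, 0)))
  .kabsch(fromM, toM)
}

# heavy-atom automorphisms of the ligand graph (element+charge colored);
# each returned vector maps reference heavy-slot -> docked heavy atom index
.ligandAutomorphisms <- function(lig, cap = 5000L) {
  g <- .molGraph(lig, heavyOnly = TRUE)
  cols <- .vertexColors(g)
  maps <- igraph::subgraph_isomorphisms(pattern = g, target = g,
                                        method = "vf2",
                                        vertex.color1 = cols,
                                        vertex.color2 = cols)
  if (length(maps) > cap) maps <- maps[seq_len(cap)]
  orig <- igraph::V(g)$orig
  lapply(maps, function(m) orig[as.integer(m)])
}

#' Contact and residue recovery of a docked pose
#'
#' Fraction of the reference complex's heavy-atom contacts (pairs under 4
#' Angstrom) reproduced by the docked pose, and the analogous fraction over
#' interacting residues (residues with any atom under 4 Angstrom from the
#' ligand).
#'
#' @param docked,reference \linkS4class{ComplexStructure} objects with
#'   shared residue numbering and ligand topology
#' @param cutoff contact cutoff, Angstrom (default 4.0)
#' @return list(contactRecovery, residueRecovery, rmsd)
#' @export
contactRecovery <- function(docked, reference, cutoff = 4.0) {
  cref <- findContacts(reference, cutoff)
  if (!nrow(cref))
    stop("reference complex has no contacts; recovery is undefined")
  cdoc <- findContacts(docked, cutoff)
  keyRef <- paste(cref$residue, cref$resAtom, cref$ligAtom)
  keyDoc <- paste(cdoc$residue, cdoc$resAtom, cdoc$ligAtom)
  resRef <- unique(cref$residue)
  resDoc <- unique(cdoc$residue)
  list(contactRecovery = length(intersect(keyRef, keyDoc)) / length(keyRef),
       residueRecovery = length(intersect(resRef, resDoc)) / length(resRef),
       rmsd = ligandRmsd(docked, reference))
}
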
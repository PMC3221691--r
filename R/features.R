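#' Perceive chemical features on a conformer
#'
#' Applies the package's declared feature rules to a molecule's conformer:
#' \itemize{
#'   \item HBD: N/O bearing at least one hydrogen (centroid at the atom).
#'   \item HBA: N/O with a lone pair, excluding amide N, aromatic N-H and
#'     nitrogens of positively charged groups; carbonyl oxygens carry a
#'     direction along the C=O axis.
#'   \item POS_IONIZABLE: each group carrying +1 after protonation
#'     (guanidinium, amidinium, protonated amine); centroid of the group.
#'   \item AROMATIC: each smallest aromatic ring; centroid of the ring atoms
#'     with the ring-plane normal as direction.
#'   \item HYDROPHOBIC: contiguous non-aromatic carbon-only fragments of at
#'     least 3 atoms none of which touches a heteroatom; fragment centroid.
#' }
#'
#' @param mol a \linkS4class{Molecule}
#' @param conformerIndex which conformer to use (default 1)
#' @return data.frame with columns kind, x, y, z, dx, dy, dz (unit direction
#'   or NA) and a list column \code{atoms} of supporting atom indices
#' @export
perceiveFeatures <- function(mol, conformerIndex = 1L) {
  if (conformerIndex > length(mol@conformers))
    stop("molecule '", mol@id, "' has no conformer ", conformerIndex)
  xyz <- mol@conformers[[conformerIndex]]$coords
  a <- mol@atoms
  adj <- .adjList(mol)
  om <- .bondOrderMap(mol)
  feats <- list()
  add <- function(kind, center, dir, atoms) {
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = center[1], y = center[2], z = center[3],
      dx = dir[1], dy = dir[2], dz = dir[3],
      atoms = I(list(as.integer(atoms))))
  }
  noDir <- c(NA_real_, NA_real_, NA_real_)

  for (i in .donorAtoms(mol)) {
    dir <- noDir
    hNb <- adj[[i]][a$element[adj[[i]]] == "H"]
    if (length(hNb)) dir <- .unit(xyz[hNb[1], ] - xyz[i, ])
    add("HBD", xyz[i, ], dir, i)
  }
  for (i in .acceptorAtoms(mol)) {
    dir <- noDir
    if (a$element[i] == "O") {
      cNb <- adj[[i]][vapply(adj[[i]], function(j)
        a$element[j] == "C" && .getOrder(om, i, j) == 2L, logical(1))]
      if (length(cNb)) dir <- .unit(xyz[i, ] - xyz[cNb[1], ])
    }
    add("HBA", xyz[i, ], dir, i)
  }
  for (grp in .positiveGroups(mol))
    add("POS_IONIZABLE", colMeans(xyz[grp, , drop = FALSE]), noDir, grp)
  for (ring in .aromaticRings(mol)) {
    ctr <- colMeans(xyz[ring, , drop = FALSE])
    add("AROMATIC", ctr, .planeNormal(xyz[ring, , drop = FALSE]), ring)
  }
  for (frag in .hydrophobicFragments(mol))
    add("HYDROPHOBIC", colMeans(xyz[frag, , drop = FALSE]), noDir, frag)

  if (!length(feats))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), dx = numeric(), dy = numeric(),
                      dz = numeric(), atoms = I(list())))
  do.call(rbind, feats)
}

# contiguous non-aromatic carbon-only fragments, >= 3 atoms, no heteroatom
# attached to any member
.hydrophobicFragments <- function(mol) {
  a <- mol@atoms
  adj <- .adjList(mol)
  eligible <- which(a$element == "C" & !a$aromatic &
    vapply(seq_len(nrow(a)), function(i)
      !any(a$element[adj[[i]]] %in% .HETERO), logical(1)))
  if (length(eligible) < 3L) return(list())
  sub <- igraph::induced_subgraph(.molGraph(mol), eligible)
  comp <- igraph::components(sub)$membership
  # vertices of the induced subgraph preserve the order of `eligible`
  frags <- split(eligible, comp)
  Filter(function(f) length(f) >= 3L, frags)
}

# feature centroid matrix from a feature data frame
.featureCoords <- function(feats) {
  as.matrix(feats[, c("x", "y", "z")])
}

# cached features on all conformers: list of data.frames
.allConformerFeatures <- function(mol) {
  lapply(seq_along(mol@conformers), function(ci) perceiveFeatures(mol, ci))
}
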
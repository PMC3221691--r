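#' Construct a Molecule
#'
#' Low-level constructor assembling a \linkS4class{Molecule} from atom and
#' bond tables plus one or more conformer coordinate sets.
#'
#' @param id molecule identifier
#' @param atoms data.frame with columns \code{element}, and optionally
#'   \code{charge}, \code{aromatic}, \code{hcount} (defaults 0, FALSE, 0)
#' @param bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   and optionally \code{aromatic}; may have zero rows
#' @param coords n x 3 numeric matrix (Angstrom) or a list of such matrices
#' @param energies conformer energies, kcal/mol (recycled 0 when missing)
#' @param ic50 optional IC50 annotation, micromolar
#' @param meta optional list of free-form annotations
#' @return a \linkS4class{Molecule}
#' @export
#' @examples
#' m <- newMolecule("methane",
#'   atoms = data.frame(element = "C", hcount = 4),
#'   bonds = data.frame(a1 = integer(), a2 = integer(), order = integer()),
#'   coords = matrix(0, 1, 3))
newMolecule <- function(id, atoms, bonds = NULL, coords = NULL,
                        energies = NULL, ic50 = numeric(0), meta = list()) {
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$hcount)) atoms$hcount <- 0L
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      aromatic = as.logical(atoms$aromatic),
                      hcount = as.integer(atoms$hcount),
                      stringsAsFactors = FALSE)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical())
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                        order = as.integer(bonds$order),
                        aromatic = as.logical(bonds$aromatic))
  }
  confs <- list()
  if (!is.null(coords)) {
    if (is.matrix(coords)) coords <- list(coords)
    if (is.null(energies)) energies <- rep(0, length(coords))
    confs <- Map(function(xyz, e) {
      xyz <- as.matrix(xyz); dimnames(xyz) <- NULL
      list(coords = xyz, energy = as.numeric(e))
    }, coords, energies)
  }
  new("Molecule", id = as.character(id), atoms = atoms, bonds = bonds,
      conformers = confs, ic50 = as.numeric(ic50), meta = meta)
}

# igraph view of the heavy-atom (or full) molecular graph; vertices carry
# element and charge attributes for colored isomorphism checks
.molGraph <- function(mol, heavyOnly = FALSE) {
  a <- mol@atoms; b <- mol@bonds
  keep <- if (heavyOnly) which(a$element != "H") else seq_len(nrow(a))
  idx <- match(seq_len(nrow(a)), keep)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  igraph::V(g)$element <- a$element[keep]
  igraph::V(g)$charge <- a$charge[keep]
  igraph::V(g)$orig <- keep
  if (nrow(b)) {
    sel <- b$a1 %in% keep & b$a2 %in% keep
    if (any(sel)) {
      e <- rbind(idx[b$a1[sel]], idx[b$a2[sel]])
      g <- igraph::add_edges(g, as.vector(e))
      igraph::E(g)$order <- b$order[sel]
    }
  }
  g
}

# integer vertex colors (element + formal charge sign) for VF2
.vertexColors <- function(g) {
  el <- match(igraph::V(g)$element, names(.ATOMIC_MASS))
  ch <- sign(igraph::V(g)$charge)
  as.integer(el * 8L + ch + 4L)
}

# neighbor list on all atoms
.adjList <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  b <- mol@bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  adj
}

# is bond k part of a cycle? (endpoints still connected with bond removed)
.bondInRing <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(logical(0))
  g <- .molGraph(mol)
  vapply(seq_len(nrow(b)), function(k) {
    h <- igraph::delete_edges(g, k)
    !is.infinite(igraph::distances(h, v = b$a1[k], to = b$a2[k])[1, 1])
  }, logical(1))
}

# smallest rings: for every ring bond, the shortest cycle through it;
# deduplicated. Returns a list of atom-index vectors.
.smallestRings <- function(mol, maxSize = 8L) {
  b <- mol@bonds
  if (!nrow(b)) return(list())
  g <- .molGraph(mol)
  inRing <- .bondInRing(mol)
  rings <- list()
  for (k in which(inRing)) {
    h <- igraph::delete_edges(g, k)
    p <- igraph::shortest_paths(h, from = b$a1[k], to = b$a2[k])$vpath[[1]]
    ring <- as.integer(p)
    if (length(ring) >= 3L && length(ring) <= maxSize) {
      key <- paste(sort(ring), collapse = ",")
      rings[[key]] <- ring
    }
  }
  unname(rings)
}

# aromatic rings: smallest rings whose atoms and bonds are all flagged aromatic
.aromaticRings <- function(mol) {
  rings <- .smallestRings(mol)
  if (!length(rings)) return(list())
  arAtom <- mol@atoms$aromatic
  b <- mol@bonds
  bkey <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  Filter(function(r) {
    if (!all(arAtom[r])) return(FALSE)
    edges <- cbind(r, c(r[-1], r[1]))
    all(paste(pmin(edges[, 1], edges[, 2]),
              pmax(edges[, 1], edges[, 2])) %in% bkey[b$aromatic])
  }, rings)
}

# connected fragments (components) over all atoms
.fragments <- function(mol) {
  g <- .molGraph(mol)
  comp <- igraph::components(g)$membership
  split(seq_along(comp), comp)
}

# heavy-atom degree of each atom (explicit graph, H excluded)
.heavyDegree <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  deg <- integer(nrow(a))
  for (i in seq_len(nrow(b))) {
    if (a$element[b$a2[i]] != "H") deg[b$a1[i]] <- deg[b$a1[i]] + 1L
    if (a$element[b$a1[i]] != "H") deg[b$a2[i]] <- deg[b$a2[i]] + 1L
  }
  deg
}

# total connections including implicit hydrogens
.totalDegree <- function(mol) {
  deg <- integer(nrow(mol@atoms))
  b <- mol@bonds
  for (i in seq_len(nrow(b))) {
    deg[b$a1[i]] <- deg[b$a1[i]] + 1L
    deg[b$a2[i]] <- deg[b$a2[i]] + 1L
  }
  deg + mol@atoms$hcount
}

# bond orders as a lookup: .bondOrder(mol)[["i-j"]]
.bondOrderMap <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(list())
  keys <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2), sep = "-")
  stats::setNames(as.list(b$order), keys)
}

.getOrder <- function(om, i, j) {
  o <- om[[paste(min(i, j), max(i, j), sep = "-")]]
  if (is.null(o)) 0L else o
}

# replace conformers wholesale
.setConformers <- function(mol, coordsList, energies) {
  mol@conformers <- Map(function(xyz, e) list(coords = xyz, energy = e),
                        coordsList, energies)
  methods::validObject(mol)
  mol
}

#' Apply a rigid transform to every conformer of a molecule
#'
#' @param mol a \linkS4class{Molecule}
#' @param R 3x3 rotation matrix
#' @param t length-3 translation (Angstrom)
#' @return the transformed molecule
#' @export
transformMolecule <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  mol@conformers <- lapply(mol@conformers, function(cf) {
    cf$coords <- sweep(cf$coords %*% R, 2, t, `+`)
    cf
  })
  mol
}
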
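#' Rule-based protonation at a fixed pH
#'
#' Sets formal charges with a fixed rule/pKa table rather than per-molecule
#' pKa prediction: at pH below the group pKa, basic groups (guanidine pKa
#' ~13.6, amidine ~11.6, aliphatic amine ~10.6) are protonated to +1; at pH
#' above the acid pKa, carboxylic acids (pKa ~4.8) are deprotonated to -1.
#' Amide and aromatic nitrogens are never protonated. Implicit hydrogen
#' counts and the net formal charge are updated accordingly.
#'
#' @param mol a \linkS4class{Molecule} with explicit connectivity
#' @param pH the pH at which to assign charges (default 7.5, physiological)
#' @return the molecule with updated charges and hydrogen counts
#' @export
#' @examples
#' # acetic acid CC(=O)O -> carboxylate at pH 7.5
#' m <- newMolecule("AcOH",
#'   atoms = data.frame(element = c("C", "C", "O", "O"), hcount = c(3, 0, 0, 1)),
#'   bonds = data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1, 2, 1)),
#'   coords = matrix(rnorm(12), 4, 3))
#' sum(atoms(assignProtonation(m, 7.5))$charge)  # -1
assignProtonation <- function(mol, pH = 7.5) {
  a <- mol@atoms
  om <- .bondOrderMap(mol)
  adj <- .adjList(mol)
  heavy <- a$element != "H"

  guanidineC <- .findGuanidineCarbons(mol, adj, om)
  amidineC <- .findAmidineCarbons(mol, adj, om, exclude = guanidineC)
  amideN <- .findAmideNitrogens(mol, adj, om)

  # basic groups: protonate the (first) double-bonded N of the group
  if (pH < 13.6) for (cIdx in guanidineC)
    mol <- .protonateGroupN(mol, cIdx, adj, om)
  if (pH < 11.6) for (cIdx in amidineC)
    mol <- .protonateGroupN(mol, cIdx, adj, om)
  if (pH < 10.6) {
    a <- mol@atoms
    for (i in which(a$element == "N" & !a$aromatic & a$charge == 0L)) {
      nb <- adj[[i]]
      nbHeavy <- nb[a$element[nb] != "H"]
      isAliphaticAmine <- length(nbHeavy) >= 1L &&
        all(a$element[nbHeavy] == "C" & !a$aromatic[nbHeavy]) &&
        all(vapply(nb, function(j) .getOrder(om, i, j) == 1L, logical(1))) &&
        !(i %in% amideN) &&
        !any(nbHeavy %in% c(guanidineC, amidineC)) &&
        .totalDegree(mol)[i] <= 3L
      if (isAliphaticAmine) {
        mol@atoms$charge[i] <- 1L
        mol@atoms$hcount[i] <- mol@atoms$hcount[i] + 1L
      }
    }
  }
  # carboxylic acids: -COOH -> -COO(-)
  if (pH > 4.8) {
    a <- mol@atoms
    for (cIdx in which(a$element == "C")) {
      nb <- adj[[cIdx]]
      os <- nb[a$element[nb] == "O"]
      if (length(os) < 2L) next
      dblO <- os[vapply(os, function(j) .getOrder(om, cIdx, j) == 2L, logical(1))]
      sngO <- os[vapply(os, function(j) .getOrder(om, cIdx, j) == 1L, logical(1))]
      sngOH <- sngO[mol@atoms$hcount[sngO] > 0L & mol@atoms$charge[sngO] == 0L]
      if (length(dblO) >= 1L && length(sngOH) >= 1L) {
        j <- sngOH[1]
        mol@atoms$charge[j] <- -1L
        mol@atoms$hcount[j] <- mol@atoms$hcount[j] - 1L
      }
    }
  }
  mol
}

# carbons bonded to three nitrogens through single/double bonds (guanidine)
.findGuanidineCarbons <- function(mol, adj, om) {
  a <- mol@atoms
  which(vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] != "C" || a$aromatic[i]) return(FALSE)
    nb <- adj[[i]]
    ns <- nb[a$element[nb] == "N"]
    length(ns) == 3L
  }, logical(1)))
}

# carbons bonded to exactly two nitrogens, one through a double bond (amidine)
.findAmidineCarbons <- function(mol, adj, om, exclude = integer(0)) {
  a <- mol@atoms
  which(vapply(seq_len(nrow(a)), function(i) {
    if (i %in% exclude || a$element[i] != "C" || a$aromatic[i]) return(FALSE)
    nb <- adj[[i]]
    ns <- nb[a$element[nb] == "N"]
    if (length(ns) != 2L) return(FALSE)
    any(vapply(ns, function(j) .getOrder(om, i, j) == 2L, logical(1)))
  }, logical(1)))
}

# nitrogens single-bonded to a carbonyl carbon (amide)
.findAmideNitrogens <- function(mol, adj, om) {
  a <- mol@atoms
  which(vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] != "N") return(FALSE)
    any(vapply(adj[[i]], function(c) {
      a$element[c] == "C" && .getOrder(om, i, c) == 1L &&
        any(vapply(adj[[c]], function(o)
          a$element[o] == "O" && .getOrder(om, c, o) == 2L, logical(1)))
    }, logical(1)))
  }, logical(1)))
}

# put +1 on the double-bonded N of a guanidine/amidine group (first N if none)
.protonateGroupN <- function(mol, cIdx, adj, om) {
  a <- mol@atoms
  ns <- adj[[cIdx]][a$element[adj[[cIdx]]] == "N"]
  if (any(a$charge[ns] != 0L)) return(mol)  # already charged
  dbl <- ns[vapply(ns, function(j) .getOrder(om, cIdx, j) == 2L, logical(1))]
  target <- if (length(dbl)) dbl[1] else ns[1]
  mol@atoms$charge[target] <- 1L
  mol@atoms$hcount[target] <- mol@atoms$hcount[target] + 1L
  mol
}
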
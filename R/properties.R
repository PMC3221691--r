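# simple atomic logP contributions (Crippen-style estimate; see vignette)
.LOGP_CONTRIB <- c(
  C_aromatic = 0.29, C_aliphatic = 0.14, N = -0.60, N_charged = -1.50,
  O = -0.40, O_charged = -1.30, S = 0.40, P = -0.40,
  F = 0.22, Cl = 0.65, Br = 0.90, I = 1.10, H_polar = -0.35, B = 0.0
)

#' Compute a molecular property vector
#'
#' Returns molecular weight (Da, implicit H included), a Crippen-type atomic
#' contribution logP estimate, hydrogen-bond donor and acceptor counts, the
#' rotatable-bond count and the net formal charge. Donors are N/O bearing at
#' least one hydrogen; acceptors are N/O with a lone pair, excluding amide
#' nitrogens, aromatic N-H, and nitrogens in positively charged groups.
#' Rotatable bonds are acyclic single bonds between two non-terminal heavy
#' atoms, excluding amide C-N bonds. Conformer-independent by construction.
#'
#' @param mol a \linkS4class{Molecule} (protonation assigned)
#' @return named numeric vector: mw, logp, hbd, hba, rotatable, formal_charge
#' @export
#' @examples
#' # ethanol: hbd 1, hba 1, rotatable 0
#' m <- newMolecule("EtOH",
#'   atoms = data.frame(element = c("C", "C", "O"), hcount = c(3, 2, 1)),
#'   bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1),
#'   coords = matrix(rnorm(9), 3, 3))
#' computeProperties(m)
computeProperties <- function(mol) {
  a <- mol@atoms
  mw <- sum(.elementMass(a$element)) + sum(a$hcount) * .ATOMIC_MASS[["H"]]
  c(mw = unname(mw),
    logp = .estimateLogP(mol),
    hbd = length(.donorAtoms(mol)),
    hba = length(.acceptorAtoms(mol)),
    rotatable = length(.rotatableBonds(mol)),
    formal_charge = sum(a$charge))
}

.estimateLogP <- function(mol) {
  a <- mol@atoms
  v <- 0
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    v <- v + switch(el,
      C = if (a$aromatic[i]) .LOGP_CONTRIB[["C_aromatic"]]
          else .LOGP_CONTRIB[["C_aliphatic"]],
      N = if (a$charge[i] > 0L) .LOGP_CONTRIB[["N_charged"]]
          else .LOGP_CONTRIB[["N"]],
      O = if (a$charge[i] < 0L) .LOGP_CONTRIB[["O_charged"]]
          else .LOGP_CONTRIB[["O"]],
      H = 0,
      .LOGP_CONTRIB[[el]])
    if (el %in% c("N", "O")) v <- v + a$hcount[i] * .LOGP_CONTRIB[["H_polar"]]
  }
  unname(v)
}

# donors: N or O with at least one (implicit or explicit) hydrogen
.donorAtoms <- function(mol) {
  a <- mol@atoms
  adj <- .adjList(mol)
  expH <- vapply(seq_len(nrow(a)), function(i)
    any(a$element[adj[[i]]] == "H"), logical(1))
  which(a$element %in% c("N", "O") & (a$hcount > 0L | expH))
}

# acceptors per the declared rule set
.acceptorAtoms <- function(mol) {
  a <- mol@atoms
  adj <- .adjList(mol)
  om <- .bondOrderMap(mol)
  amideN <- .findAmideNitrogens(mol, adj, om)
  posGroups <- .positiveGroupAtoms(mol, adj, om)
  which(vapply(seq_len(nrow(a)), function(i) {
    el <- a$element[i]
    if (!el %in% c("N", "O")) return(FALSE)
    if (a$charge[i] > 0L || i %in% posGroups) return(FALSE)
    if (el == "N") {
      if (i %in% amideN) return(FALSE)
      if (a$aromatic[i] && a$hcount[i] > 0L) return(FALSE)  # pyrrole-type
      if (.totalDegree(mol)[i] >= 4L) return(FALSE)
    }
    TRUE
  }, logical(1)))
}

# atoms belonging to a +1 group: a charged atom plus, for guanidinium /
# amidinium, the central carbon and its other nitrogens
.positiveGroupAtoms <- function(mol, adj, om) {
  a <- mol@atoms
  grp <- integer(0)
  for (i in which(a$charge > 0L)) {
    grp <- c(grp, i)
    if (a$element[i] == "N") {
      for (c in adj[[i]][a$element[adj[[i]]] == "C"]) {
        ns <- adj[[c]][a$element[adj[[c]]] == "N"]
        if (length(ns) >= 2L) grp <- c(grp, c, ns)
      }
    }
  }
  unique(grp)
}

# positively charged groups as a list of atom-index vectors (for features)
.positiveGroups <- function(mol) {
  adj <- .adjList(mol)
  om <- .bondOrderMap(mol)
  a <- mol@atoms
  groups <- list()
  seen <- integer(0)
  for (i in which(a$charge > 0L)) {
    if (i %in% seen) next
    grp <- i
    if (a$element[i] == "N") {
      for (c in adj[[i]][a$element[adj[[i]]] == "C"]) {
        ns <- adj[[c]][a$element[adj[[c]]] == "N"]
        if (length(ns) >= 2L) grp <- unique(c(grp, c, ns))
      }
    }
    groups[[length(groups) + 1L]] <- sort(grp)
    seen <- c(seen, grp)
  }
  groups
}

# rotatable: acyclic single bonds between non-terminal heavy atoms, no amides
.rotatableBonds <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(integer(0))
  a <- mol@atoms
  inRing <- .bondInRing(mol)
  deg <- .heavyDegree(mol)
  adj <- .adjList(mol)
  om <- .bondOrderMap(mol)
  isAmideCN <- function(i, j) {
    # C-N single bond where the carbon bears a double-bonded O
    cn <- if (a$element[i] == "C" && a$element[j] == "N") c(i, j)
          else if (a$element[j] == "C" && a$element[i] == "N") c(j, i)
          else return(FALSE)
    any(vapply(adj[[cn[1]]], function(o)
      a$element[o] == "O" && .getOrder(om, cn[1], o) == 2L, logical(1)))
  }
  which(vapply(seq_len(nrow(b)), function(k) {
    i <- b$a1[k]; j <- b$a2[k]
    b$order[k] == 1L && !b$aromatic[k] && !inRing[k] &&
      a$element[i] != "H" && a$element[j] != "H" &&
      deg[i] > 1L && deg[j] > 1L && !isAmideCN(i, j)
  }, logical(1)))
}

#' Reference property statistics over a set of molecules
#'
#' Per-property mean and standard deviation over a reference active set; the
#' basis of the +/- k*SD property window used for library pre-filtering and
#' decoy matching.
#'
#' @param mols list of \linkS4class{Molecule} (at least 2)
#' @return data.frame with rownames mw, logp, hbd, hba, rotatable,
#'   formal_charge and columns mean, sd
#' @export
referenceStats <- function(mols) {
  if (length(mols) < 2L) stop("reference statistics need at least 2 molecules")
  props <- t(vapply(mols, computeProperties, numeric(6)))
  data.frame(mean = colMeans(props), sd = apply(props, 2, stats::sd),
             row.names = colnames(props))
}
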
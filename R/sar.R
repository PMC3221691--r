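#' Classify activity from an IC50 value
#'
#' Actives have IC50 strictly below \code{low} (default 0.05 uM); inactives
#' strictly above \code{high} (default 1 uM); everything in between —
#' boundary values included — is excluded from the SAR analysis.
#'
#' @param ic50uM IC50 in micromolar (positive)
#' @param low active threshold, uM
#' @param high inactive threshold, uM
#' @return "active", "inactive" or "excluded" (vectorized)
#' @export
#' @examples
#' classifyActivity(c(0.01, 0.5, 2)) # active, excluded, inactive
classifyActivity <- function(ic50uM, low = 0.05, high = 1.0) {
  if (any(!is.finite(ic50uM)) || any(ic50uM <= 0))
    stop("IC50 values must be positive and finite")
  ifelse(ic50uM < low, "active", ifelse(ic50uM > high, "inactive", "excluded"))
}

#' Scaffold template for matched-pair analysis
#'
#' A core substructure (given as a small Molecule without conformers is
#' fine) plus labeled variable positions: a named integer vector mapping
#' position labels (e.g. A1, D, L2, Q) to core atom indices at which
#' substituents attach.
#'
#' @param core a \linkS4class{Molecule} describing the shared scaffold
#' @param positions named integer vector label -> core atom index
#' @return a list with class "ScaffoldTemplate"
#' @export
scaffoldTemplate <- function(core, positions) {
  stopifnot(!is.null(names(positions)), !anyDuplicated(names(positions)),
            all(positions >= 1L), all(positions <= nrow(core@atoms)))
  structure(list(core = core, positions = positions),
            class = "ScaffoldTemplate")
}

# match the template core into a molecule; returns the first VF2 mapping
# (core vertex -> molecule atom) or NULL
.matchCore <- function(template, mol) {
  gCore <- .molGraph(template$core, heavyOnly = TRUE)
  gMol <- .molGraph(mol, heavyOnly = TRUE)
  if (igraph::vcount(gCore) > igraph::vcount(gMol)) return(NULL)
  maps <- igraph::subgraph_isomorphisms(
    pattern = gCore, target = gMol, method = "vf2",
    vertex.color1 = .vertexColors(gMol), vertex.color2 = .vertexColors(gCore))
  if (!length(maps)) return(NULL)
  molIdx <- igraph::V(gMol)$orig
  stats::setNames(molIdx[as.integer(maps[[1]])], seq_len(igraph::vcount(gCore)))
}

# decompose a molecule into per-position substituent atom sets given a core
# mapping; each substituent is the connected heavy-atom component attached at
# a labeled core atom after removing the core
.decompose <- function(template, mol) {
  mapping <- .matchCore(template, mol)
  if (is.null(mapping)) return(NULL)
  coreAtoms <- unname(mapping)
  a <- mol@atoms
  adj <- .adjList(mol)
  heavy <- which(a$element != "H")
  rest <- setdiff(heavy, coreAtoms)
  g <- .molGraph(mol, heavyOnly = TRUE)
  hv <- igraph::V(g)$orig
  sub <- igraph::induced_subgraph(g, which(hv %in% rest))
  comp <- if (length(rest)) igraph::components(sub)$membership else integer(0)
  restIdx <- igraph::V(sub)$orig
  out <- lapply(template$positions, function(corePos) integer(0))
  if (length(rest)) {
    for (cmp in unique(comp)) {
      atomsIn <- restIdx[comp == cmp]
      # which labeled core atom does this component attach to?
      attach <- NULL
      for (lbl in names(template$positions)) {
        coreAtom <- mapping[[template$positions[[lbl]]]]
        if (any(vapply(atomsIn, function(x)
          coreAtom %in% adj[[x]], logical(1)))) { attach <- lbl; break }
      }
      if (!is.null(attach)) out[[attach]] <- sort(atomsIn)
    }
  }
  names(out) <- names(template$positions)
  list(mapping = mapping, substituents = out)
}

# canonical descriptor of a substituent: molecular-formula-like string plus
# sorted bond multiset (isomorphism-grade for the small fragments used here,
# backed by a VF2 check when descriptors collide)
.substituentKey <- function(mol, atomsIn) {
  if (!length(atomsIn)) return("-H")
  a <- mol@atoms
  counts <- table(paste0(a$element[atomsIn],
                         ifelse(a$aromatic[atomsIn], "ar", ""),
                         ifelse(a$charge[atomsIn] != 0,
                                sprintf("%+d", a$charge[atomsIn]), "")))
  b <- mol@bonds
  sel <- b$a1 %in% atomsIn & b$a2 %in% atomsIn
  bondSig <- sort(paste0(pmin(a$element[b$a1[sel]], a$element[b$a2[sel]]),
                         b$order[sel],
                         pmax(a$element[b$a1[sel]], a$element[b$a2[sel]])))
  paste(paste(names(counts), as.integer(counts), sep = "", collapse = "."),
        paste(bondSig, collapse = "."), sep = "|")
}

# VF2 isomorphism of two substituent fragments (element+charge colored)
.substituentsIsomorphic <- function(molA, atomsA, molB, atomsB) {
  if (length(atomsA) != length(atomsB)) return(FALSE)
  if (!length(atomsA)) return(TRUE)
  gA <- igraph::induced_subgraph(.molGraph(molA),
                                 which(seq_len(nrow(molA@atoms)) %in% atomsA))
  gB <- igraph::induced_subgraph(.molGraph(molB),
                                 which(seq_len(nrow(molB@atoms)) %in% atomsB))
  igraph::is_isomorphic_to(gA, gB, method = "vf2",
                           vertex.color1 = .vertexColors(gA),
                           vertex.color2 = .vertexColors(gB))
}

#' Find matched active/inactive pairs on a scaffold
#'
#' Decomposes every molecule into the template core plus per-position
#' substituents and emits each (active, inactive) pair whose substituents
#' are identical (graph-isomorphic) at all labeled positions except exactly
#' one. Molecules that do not contain the core are skipped with a message.
#' The per-pair feature delta records the chemical feature kinds present in
#' the active-side substituent and absent from the inactive side (and vice
#' versa), perceived on the substituent atoms.
#'
#' @param actives,inactives lists of \linkS4class{Molecule}
#' @param template a template from \code{scaffoldTemplate}
#' @return data.frame (active, inactive, position, substituent_active,
#'   substituent_inactive, gained, lost) ordered by (active, inactive) id;
#'   \code{gained}/\code{lost} are comma-joined feature kinds on the active
#'   side relative to the inactive side
#' @export
findMatchedPairs <- function(actives, inactives, template) {
  decompose <- function(mols) {
    out <- list()
    for (m in mols) {
      d <- .decompose(template, m)
      if (is.null(d)) {
        message("molecule '", molId(m), "' does not match the scaffold core; skipped")
        next
      }
      out[[molId(m)]] <- list(mol = m, sub = d$substituents)
    }
    out
  }
  da <- decompose(actives); di <- decompose(inactives)
  labels <- names(template$positions)
  rows <- list()
  for (aid in sort(names(da))) for (iid in sort(names(di))) {
    A <- da[[aid]]; I <- di[[iid]]
    same <- vapply(labels, function(lbl)
      .substituentsIsomorphic(A$mol, A$sub[[lbl]], I$mol, I$sub[[lbl]]),
      logical(1))
    if (sum(!same) != 1L) next
    pos <- labels[!same]
    fa <- .substituentFeatureKinds(A$mol, A$sub[[pos]])
    fi <- .substituentFeatureKinds(I$mol, I$sub[[pos]])
    rows[[length(rows) + 1L]] <- data.frame(
      active = aid, inactive = iid, position = pos,
      substituent_active = .substituentKey(A$mol, A$sub[[pos]]),
      substituent_inactive = .substituentKey(I$mol, I$sub[[pos]]),
      kinds_active = paste(sort(fa), collapse = ","),
      kinds_inactive = paste(sort(fi), collapse = ","),
      gained = paste(sort(setdiff(fa, fi)), collapse = ","),
      lost = paste(sort(setdiff(fi, fa)), collapse = ","))
  }
  if (!length(rows))
    return(data.frame(active = character(), inactive = character(),
                      position = character(), substituent_active = character(),
                      substituent_inactive = character(),
                      kinds_active = character(), kinds_inactive = character(),
                      gained = character(), lost = character()))
  do.call(rbind, rows)
}

# feature kinds present on a substituent's atoms (perceived on the whole
# molecule, then restricted to features supported inside the substituent)
.substituentFeatureKinds <- function(mol, atomsIn) {
  if (!length(atomsIn) || !length(mol@conformers)) return(character(0))
  feats <- perceiveFeatures(mol)
  keep <- vapply(seq_len(nrow(feats)), function(i)
    all(feats$atoms[[i]] %in% atomsIn), logical(1))
  unique(feats$kind[keep])
}

#' Per-position activity-feature rules from matched pairs
#'
#' For every scaffold position with at least one matched pair, reports the
#' feature kinds that are present in all active-side substituents at that
#' position and missing from at least one inactive counterpart ("required"
#' kinds), with the supporting pair ids as evidence. Positions whose pairs
#' show no systematic feature difference are flagged "no rule".
#'
#' @param pairs data.frame from \code{findMatchedPairs}
#' @return list keyed by position: list(required = character kinds,
#'   evidence = character pair labels, rule = "required ..." | "no rule")
#' @export
positionFeatureRules <- function(pairs) {
  splitKinds <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) v[nzchar(v)])
  out <- list()
  for (pos in sort(unique(pairs$position))) {
    sub <- pairs[pairs$position == pos, , drop = FALSE]
    act <- splitKinds(sub$kinds_active)
    inact <- splitKinds(sub$kinds_inactive)
    inAllActives <- Reduce(intersect, act)
    required <- Filter(function(k)
      any(!vapply(inact, function(v) k %in% v, logical(1))), inAllActives)
    evidence <- paste(sub$active, sub$inactive, sep = "/")
    out[[pos]] <- list(
      required = sort(required),
      evidence = evidence,
      rule = if (length(required))
        paste("required:", paste(sort(required), collapse = "+"))
      else "no rule")
  }
  out
}
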
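# geometric criteria for interaction detection, one config block
.INTERACTION_GEOMETRY <- list(
  contact = 4.0,        # heavy-atom contact, strict <
  hbond_da = 3.5,       # donor-acceptor heavy-atom distance, <=
  hbond_angle = 120,    # D-H...A angle, >= (checked when H present)
  charged = 5.5,        # opposite-charge group centroid distance, <=
  pipi_parallel = 5.5,  # ring centroid distance, <= (interplanar <= 30 deg)
  pipi_tshape = 6.0,    # ring centroid distance, <= (60-120 deg)
  pication = 6.0,       # cation centroid to ring centroid, <=
  pication_angle = 30   # off ring normal, <=
)

#' Heavy-atom contacts between receptor and ligand
#'
#' All (protein heavy atom, ligand heavy atom) pairs strictly closer than
#' the cutoff, sorted by residue then distance.
#'
#' @param cx a \linkS4class{ComplexStructure}
#' @param cutoff Angstrom (default 4.0, strict inequality)
#' @return data.frame (residue, resAtom, ligAtom, distance)
#' @export
findContacts <- function(cx, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  r <- cx@residues
  rHeavy <- r[r$element != "H", , drop = FALSE]
  lig <- .ligandHeavy(cx)
  if (!nrow(rHeavy) || !nrow(lig$xyz))
    return(data.frame(residue = character(), resAtom = character(),
                      ligAtom = integer(), distance = numeric()))
  pm <- as.matrix(rHeavy[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(pm^2), rowSums(lig$xyz^2), `+`) -
            2 * pm %*% t(lig$xyz))
  hits <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(residue = character(), resAtom = character(),
                      ligAtom = integer(), distance = numeric()))
  out <- data.frame(
    residue = paste(rHeavy$resname[hits[, 1]], rHeavy$resno[hits[, 1]],
                    sep = ":"),
    resAtom = rHeavy$atom[hits[, 1]],
    ligAtom = lig$index[hits[, 2]],
    distance = d[hits])
  out[order(out$residue, out$distance), , drop = FALSE]
}

#' Detect specific receptor-ligand interactions
#'
#' Applies the package's geometric criteria (see
#' \code{PhoreScreen:::.INTERACTION_GEOMETRY}) to emit hydrogen bonds,
#' charged (salt-bridge) contacts, pi-pi stackings and pi-cation
#' interactions between the ligand pose and each residue. Ligand donors,
#' acceptors, charged groups and rings come from the molecule's perception
#' rules; residue groups from fixed side-chain tables. Every interaction
#' implies at least one heavy-atom contact under 4 Angstrom.
#'
#' @param cx a \linkS4class{ComplexStructure} (ligand protonation assigned)
#' @return data.frame (type, residue, detail, distance); type one of HBOND,
#'   CHARGED, PIPI, PICATION
#' @export
detectInteractions <- function(cx) {
  geo <- .INTERACTION_GEOMETRY
  lig <- cx@ligand
  xyz <- lig@conformers[[1]]$coords
  a <- lig@atoms
  rows <- list()
  add <- function(type, residue, detail, distance)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, residue = residue,
                                             detail = detail,
                                             distance = distance)
  ligDonors <- .donorAtoms(lig)
  ligAcceptors <- .acceptorAtoms(lig)
  ligPosGroups <- .positiveGroups(lig)
  ligNegAtoms <- which(a$charge < 0L)
  ligRings <- .aromaticRings(lig)
  adj <- .adjList(lig)

  resList <- .residueSplit(cx)
  for (resKey in names(resList)) {
    res <- resList[[resKey]]
    resName <- res$resname[1]
    rxyz <- as.matrix(res[, c("x", "y", "z")])
    rownames(rxyz) <- res$atom

    # hydrogen bonds: ligand donor -> residue acceptor and the reverse
    accNames <- intersect(.RESIDUE_ACCEPTORS[[resName]], res$atom)
    for (i in ligDonors) for (an in accNames) {
      dDA <- .dist3(xyz[i, ], rxyz[an, ])
      if (dDA <= geo$hbond_da && .hbondAngleOk(lig, i, xyz, rxyz[an, ], adj, geo))
        add("HBOND", resKey, paste0("lig", i, "->", an), dDA)
    }
    donNames <- intersect(.RESIDUE_DONORS[[resName]], res$atom)
    for (an in donNames) for (j in ligAcceptors) {
      dDA <- .dist3(rxyz[an, ], xyz[j, ])
      if (dDA <= geo$hbond_da)  # residue H positions are not modeled
        add("HBOND", resKey, paste0(an, "->lig", j), dDA)
    }

    # charged: ligand positive group vs residue negative group & vice versa
    negNames <- intersect(.RESIDUE_NEG_GROUP[[resName]], res$atom)
    if (length(negNames)) {
      negCtr <- colMeans(rxyz[negNames, , drop = FALSE])
      for (grp in ligPosGroups) {
        dd <- .dist3(colMeans(xyz[grp, , drop = FALSE]), negCtr)
        if (dd <= geo$charged) add("CHARGED", resKey, "lig(+)/res(-)", dd)
      }
    }
    posNames <- intersect(.RESIDUE_POS_GROUP[[resName]], res$atom)
    if (length(posNames) && length(ligNegAtoms)) {
      posCtr <- colMeans(rxyz[posNames, , drop = FALSE])
      for (i in ligNegAtoms) {
        dd <- .dist3(xyz[i, ], posCtr)
        if (dd <= geo$charged) add("CHARGED", resKey, "lig(-)/res(+)", dd)
      }
    }

    # pi-pi: ligand ring vs residue ring
    ringNames <- intersect(.RESIDUE_RINGS[[resName]], res$atom)
    if (length(ringNames) >= 5L) {
      rCtr <- colMeans(rxyz[ringNames, , drop = FALSE])
      rNorm <- .planeNormal(rxyz[ringNames, , drop = FALSE])
      for (ring in ligRings) {
        lCtr <- colMeans(xyz[ring, , drop = FALSE])
        lNorm <- .planeNormal(xyz[ring, , drop = FALSE])
        dd <- .dist3(lCtr, rCtr)
        ang <- .angleBetween(lNorm, rNorm)
        ang <- min(ang, 180 - ang)
        if ((dd <= geo$pipi_parallel && ang <= 30) ||
            (dd <= geo$pipi_tshape && ang >= 60))
          add("PIPI", resKey, "ring/ring", dd)
      }
    }
    # pi-cation: residue cation vs ligand ring
    if (length(posNames)) {
      posCtr <- colMeans(rxyz[posNames, , drop = FALSE])
      for (ring in ligRings) {
        lCtr <- colMeans(xyz[ring, , drop = FALSE])
        lNorm <- .planeNormal(xyz[ring, , drop = FALSE])
        dd <- .dist3(lCtr, posCtr)
        off <- .angleBetween(posCtr - lCtr, lNorm)
        off <- min(off, 180 - off)
        if (dd <= geo$pication && off <= geo$pication_angle)
          add("PICATION", resKey, "res(+)/ligring", dd)
      }
    }
    # pi-cation: ligand cation vs residue ring
    if (length(ringNames) >= 5L && length(ligPosGroups)) {
      rCtr <- colMeans(rxyz[ringNames, , drop = FALSE])
      rNorm <- .planeNormal(rxyz[ringNames, , drop = FALSE])
      for (grp in ligPosGroups) {
        gCtr <- colMeans(xyz[grp, , drop = FALSE])
        dd <- .dist3(gCtr, rCtr)
        off <- .angleBetween(gCtr - rCtr, rNorm)
        off <- min(off, 180 - off)
        if (dd <= geo$pication && off <= geo$pication_angle)
          add("PICATION", resKey, "lig(+)/resring", dd)
      }
    }
  }
  if (!length(rows))
    return(data.frame(type = character(), residue = character(),
                      detail = character(), distance = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$residue, out$type, out$distance), , drop = FALSE]
}

# D-H...A angle >= threshold for a ligand donor when an explicit H exists;
# implicit-H donors pass on the distance criterion alone
.hbondAngleOk <- function(lig, donor, xyz, acceptorPos, adj, geo) {
  hs <- adj[[donor]][lig@atoms$element[adj[[donor]]] == "H"]
  if (!length(hs)) return(TRUE)
  any(vapply(hs, function(h) {
    v1 <- xyz[donor, ] - xyz[h, ]
    v2 <- acceptorPos - xyz[h, ]
    .angleBetween(v1, v2) >= geo$hbond_angle
  }, logical(1)))
}

#' Interaction fingerprint of one pose
#'
#' One bit per (binding-site residue, channel): HBOND when at least one
#' hydrogen bond is formed with the residue, CHARGED for a salt bridge, PI
#' for a pi-pi stacking or pi-cation interaction (the two pi types share a
#' channel). Residues are indexed in the order given.
#'
#' @param cx a \linkS4class{ComplexStructure}
#' @param siteResidues ordered character vector of residue ids ("GLU:119");
#'   defaults to all residues of the complex
#' @return an \linkS4class{InteractionFingerprint}
#' @export
interactionFingerprint <- function(cx, siteResidues = residueIds(cx)) {
  unknown <- setdiff(siteResidues, residueIds(cx))
  if (length(unknown))
    stop("residues not in the complex: ", paste(unknown, collapse = ", "))
  idx <- data.frame(
    residue = rep(siteResidues, each = length(.IFP_CHANNELS)),
    channel = rep(.IFP_CHANNELS, length(siteResidues)))
  bits <- integer(nrow(idx))
  inter <- detectInteractions(cx)
  chan <- c(HBOND = "HBOND", CHARGED = "CHARGED",
            PIPI = "PI", PICATION = "PI")
  for (i in seq_len(nrow(inter))) {
    hit <- idx$residue == inter$residue[i] &
           idx$channel == chan[[inter$type[i]]]
    bits[hit] <- 1L
  }
  new("InteractionFingerprint", bits = bits, indexMap = idx,
      poseId = cx@poseId)
}

#' Normalized Hamming distance between interaction fingerprints
#'
#' The fraction of coordinates at which the two bit vectors differ (the
#' percentage of differing coordinates, expressed as a proportion in
#' [0, 1]). Fingerprints must share an identical index map.
#'
#' @param a,b \linkS4class{InteractionFingerprint} objects
#' @return distance in [0, 1]
#' @export
hammingDistance <- function(a, b) {
  if (!identical(a@indexMap, b@indexMap))
    stop("fingerprint index maps differ; distances are not comparable")
  if (!length(a@bits)) return(0)
  mean(a@bits != b@bits)
}

#' Hierarchical clustering of pose fingerprints
#'
#' Agglomerative clustering (stats::hclust) on the pairwise normalized
#' Hamming distance matrix; average linkage by default. Leaf labels are the
#' pose ids.
#'
#' @param fps list of \linkS4class{InteractionFingerprint} with a shared
#'   index map
#' @param linkage linkage method (default "average")
#' @return an object of class \code{hclust}
#' @export
clusterPoses <- function(fps, linkage = "average") {
  if (length(fps) < 2L) stop("clustering needs at least 2 fingerprints")
  n <- length(fps)
  ids <- vapply(fps, function(f) f@poseId, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- hammingDistance(fps[[i]], fps[[j]])
  stats::hclust(stats::as.dist(m), method = linkage)
}

#' Write a pose dendrogram as Newick
#'
#' @param tree an \code{hclust} from \code{clusterPoses}
#' @param path output file
#' @return invisibly, the path
#' @export
writeClusterNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Cut a pose dendrogram into two groups and measure class purity
#'
#' Convenience for the planted two-class recovery check: cuts the tree into
#' two clusters and returns the mean, over clusters, of the majority-class
#' fraction given the true labels.
#'
#' @param tree an \code{hclust}
#' @param labels named character/logical vector of true classes keyed by
#'   pose id
#' @return list(purity, assignment)
#' @export
subtreePurity <- function(tree, labels) {
  cl <- stats::cutree(tree, k = 2)
  truth <- labels[names(cl)]
  purity <- mean(vapply(split(truth, cl), function(x)
    max(table(x)) / length(x), numeric(1)))
  list(purity = purity, assignment = cl)
}
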
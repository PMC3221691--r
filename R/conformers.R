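#' Generate a low-energy conformer set
#'
#' Conformers are produced by seeded random torsion driving of the rotatable
#' bonds, starting from the molecule's first conformer geometry: each sample
#' assigns every rotatable bond a random torsion increment, the smaller
#' branch is rotated, and the pose is scored with a soft Lennard-Jones-like
#' nonbonded energy (kcal/mol scale) over atom pairs three or more bonds
#' apart. Results are RMSD-deduplicated (0.5 Angstrom), sorted by energy,
#' and truncated to \code{nMax} conformers within \code{window} kcal/mol of
#' the minimum. Rigid molecules return their single input geometry.
#'
#' @param mol a \linkS4class{Molecule} with at least one 3D conformer
#' @param nMax maximum conformers to keep (default 50)
#' @param window energy window above the minimum, kcal/mol (default 20)
#' @param seed integer seed (mandatory: generation is randomized)
#' @param nSamples torsion samples to draw before pruning (default 200)
#' @return the molecule with its conformer list replaced
#' @export
generateConformers <- function(mol, nMax = 50L, window = 20, seed,
                               nSamples = 200L) {
  stopifnot(nMax >= 1L, window > 0)
  if (missing(seed)) stop("a seed is required for conformer generation")
  if (!length(mol@conformers))
    stop("conformer generation failed for '", mol@id,
         "': no starting 3D geometry")
  base <- mol@conformers[[1]]$coords
  rot <- .rotatableBonds(mol)
  if (!length(rot)) {
    e <- .nonbondedEnergy(mol, base)
    return(.setConformers(mol, list(base), e))
  }
  branches <- lapply(rot, function(k) .torsionBranch(mol, k))
  pool <- list(base)
  .withSeed(.deriveSeed(seed, paste0("conf:", mol@id)), {
    for (s in seq_len(nSamples)) {
      xyz <- base
      angles <- stats::runif(length(rot), 0, 2 * pi)
      for (q in seq_along(rot)) {
        k <- rot[q]
        i <- mol@bonds$a1[k]; j <- mol@bonds$a2[k]
        mv <- branches[[q]]
        xyz[mv, ] <- .rotateAboutAxis(xyz[mv, , drop = FALSE],
                                      origin = xyz[i, ],
                                      axis = xyz[j, ] - xyz[i, ],
                                      angle = angles[q])
      }
      pool[[length(pool) + 1L]] <- xyz
    }
  })
  energies <- vapply(pool, function(xyz) .nonbondedEnergy(mol, xyz), numeric(1))
  ord <- order(energies)
  kept <- list(); keptE <- numeric(0)
  for (i in ord) {
    if (length(kept) >= nMax) break
    if (energies[i] - energies[ord[1]] > window) break
    dup <- any(vapply(kept, function(ref)
      .heavyRmsd(mol, ref, pool[[i]]) < 0.5, logical(1)))
    if (!dup) {
      kept[[length(kept) + 1L]] <- pool[[i]]
      keptE <- c(keptE, energies[i])
    }
  }
  .setConformers(mol, kept, keptE)
}

# atoms on the smaller side of rotatable bond k (the side of a2), which move
.torsionBranch <- function(mol, k) {
  b <- mol@bonds
  g <- .molGraph(mol)
  h <- igraph::delete_edges(g, k)
  comp <- igraph::components(h)$membership
  sideA <- which(comp == comp[b$a1[k]])
  sideB <- which(comp == comp[b$a2[k]])
  if (length(sideB) <= length(sideA)) setdiff(sideB, b$a2[k]) else
    setdiff(sideA, b$a1[k])
}

# soft LJ-like nonbonded score over pairs >= 3 bonds apart (kcal/mol scale)
.nonbondedEnergy <- function(mol, xyz, sigma = 3.4, eps = 0.1) {
  g <- .molGraph(mol)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  topo <- igraph::distances(g)
  e <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (is.finite(topo[i, j]) && topo[i, j] < 3) next
    r <- max(.dist3(xyz[i, ], xyz[j, ]), 0.8)
    sr6 <- (sigma / r)^6
    e <- e + eps * (sr6 * sr6 - 2 * sr6)
  }
  e
}

# heavy-atom RMSD after Kabsch superposition (same atom order)
.heavyRmsd <- function(mol, a, b) {
  heavy <- which(mol@atoms$element != "H")
  pa <- a[heavy, , drop = FALSE]; pb <- b[heavy, , drop = FALSE]
  tf <- .kabsch(pb, pa)
  pb2 <- .applyTransform(pb, tf)
  sqrt(mean(rowSums((pa - pb2)^2)))
}
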
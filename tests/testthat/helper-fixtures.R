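# shared fixtures and independent oracles, built in code

mkMol <- function(id, element, hcount, a1 = integer(), a2 = integer(),
                  order = integer(), aromatic = FALSE, charge = 0L,
                  coords = NULL, ic50 = numeric(0)) {
  n <- length(element)
  if (is.null(coords)) coords <- matrix(seq_len(3 * n) * 0.9, n, 3)
  newMolecule(id,
    atoms = data.frame(element = element, hcount = hcount,
                       charge = rep_len(charge, n),
                       aromatic = rep_len(FALSE, n)),
    bonds = if (length(a1))
      data.frame(a1 = a1, a2 = a2, order = order,
                 aromatic = rep_len(aromatic, length(a1))) else NULL,
    coords = coords, ic50 = ic50)
}

fixEthanol <- function() mkMol("ethanol", c("C", "C", "O"), c(3, 2, 1),
                               a1 = c(1, 2), a2 = c(2, 3), order = c(1, 1),
                               coords = cbind(c(0, 1.5, 2.2), c(0, 0, 1.2), 0))

fixButane <- function() mkMol("butane", rep("C", 4), c(3, 2, 2, 3),
                              a1 = 1:3, a2 = 2:4, order = rep(1L, 3),
                              coords = cbind(c(0, 1.5, 2.3, 3.8),
                                             c(0, 0, 1.2, 1.2), 0))

fixAceticAcid <- function() mkMol("acetic-acid", c("C", "C", "O", "O"),
                                  c(3, 0, 0, 1), a1 = c(1, 2, 2),
                                  a2 = c(2, 3, 4), order = c(1, 2, 1))

fixAcetone <- function() mkMol("acetone", c("C", "C", "C", "O"),
                               c(3, 0, 3, 0), a1 = c(1, 2, 2),
                               a2 = c(2, 3, 4), order = c(1, 1, 2),
                               coords = cbind(c(0, 1.5, 2.3, 1.7),
                                              c(0, 0, 1.2, -1.2), 0))

fixGuanidine <- function() mkMol("guanidine", c("C", "N", "N", "N"),
                                 c(0, 1, 2, 2), a1 = c(1, 1, 1),
                                 a2 = c(2, 3, 4), order = c(2, 1, 1),
                                 coords = rbind(c(0, 0, 0), c(1.33, 0, 0),
                                                c(-0.67, 1.15, 0),
                                                c(-0.67, -1.15, 0)))

fixBenzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  newMolecule("benzene",
    atoms = data.frame(element = rep("C", 6), hcount = 1L, charge = 0L,
                       aromatic = TRUE),
    bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = rep(c(1L, 2L), 3),
                       aromatic = TRUE),
    coords = cbind(1.39 * cos(ang), 1.39 * sin(ang), 0))
}

emptyPattern <- function() data.frame(type = character(),
                                      residue = character())

fourFeatureModel <- function(tolerance = 1.6) defaultQueryModel(tolerance)

# a synthetic ligand whose features sit exactly at the model centers
exactLigand <- function(model, seed = 1) genActives(model, 1, 0, seed)[[1]]

# fingerprint with given set bits over the default 9-residue site map
mkIfp <- function(bits01, id = "fp") {
  site <- PhoreScreen:::.DEFAULT_SITE
  idx <- data.frame(residue = rep(site, each = 3),
                    channel = rep(c("HBOND", "CHARGED", "PI"), length(site)))
  new("InteractionFingerprint", bits = as.integer(bits01), indexMap = idx,
      poseId = id)
}

randomIfp <- function(id) mkIfp(stats::rbinom(27, 1, 0.4), id)

# --- independent oracles -----------------------------------------------------

# brute-force contact enumeration, O(N*M) double loop
oracleContacts <- function(cx, cutoff = 4.0) {
  r <- residueAtoms(cx)
  r <- r[r$element != "H", , drop = FALSE]
  lig <- ligand(cx)
  xyz <- conformers(lig)[[1]]$coords
  keep <- atoms(lig)$element != "H"
  xyz <- xyz[keep, , drop = FALSE]
  hits <- 0L
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(xyz))) {
    d <- sqrt(sum((c(r$x[i], r$y[i], r$z[i]) - xyz[j, ])^2))
    if (d < cutoff) hits <- hits + 1L
  }
  hits
}

# brute-force pairwise normalized Hamming matrix
oracleHammingMatrix <- function(fps) {
  n <- length(fps)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- mean(fingerprintBits(fps[[i]]) != fingerprintBits(fps[[j]]))
  m
}

# exhaustive ligand mapping: enumerate every kind-compatible injective
# assignment over every conformer; superposition via bio3d's Kabsch
# (independent of the package's own implementation)
oracleMapFit <- function(model, mol) {
  mf <- features(model)
  centers <- as.matrix(mf[, c("x", "y", "z")])
  best <- -Inf
  for (ci in seq_len(nConformers(mol))) {
    lf <- perceiveFeatures(mol, ci)
    if (!nrow(lf)) next
    lc <- as.matrix(lf[, c("x", "y", "z")])
    cand <- lapply(mf$kind, function(k) which(lf$kind == k))
    if (any(vapply(cand, length, integer(1)) == 0L)) next
    grid <- expand.grid(cand, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      asn <- as.integer(grid[g, ])
      if (anyDuplicated(asn)) next
      from <- lc[asn, , drop = FALSE]
      mob <- as.vector(t(from))
      fix <- as.vector(t(centers))
      # bio3d emits an informational warning when fitting over all positions
      moved <- suppressWarnings(bio3d::fit.xyz(fixed = fix, mobile = mob))
      placed <- matrix(moved, ncol = 3, byrow = TRUE)
      disp <- sqrt(rowSums((placed - centers)^2))
      if (any(disp > mf$tolerance + 1e-9)) next
      fit <- sum(pmax(0, 1 - (disp / mf$tolerance)^2))
      if (fit > best) best <- fit
    }
  }
  if (is.infinite(best)) NULL else best
}
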
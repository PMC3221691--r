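# --- molecular fragment library for the synthetic generators ---------------
# Each builder returns list(atoms, bonds, coords, anchor) where `anchor` is
# the local position that must land on the requested feature center (the
# perceived feature centroid of the fragment).

.fragGuanidinium <- function() {
  # tetramethylguanidinium: C center, three N at 1.33 A (120 deg apart, the
  # protonated NH2 first), the two other N methylated so the group carries a
  # single donor; anchor = centroid of the charged group (C + 3 N)
  ang <- c(90, 210, 330) * pi / 180
  core <- rbind(c(0, 0, 0),
                cbind(1.33 * cos(ang), 1.33 * sin(ang), 0))
  methyls <- rbind(core[3, ] + c(-1.40, -0.50, 0.50),
                   core[3, ] + c(-0.50, -1.40, -0.50),
                   core[4, ] + c(1.40, -0.50, 0.50),
                   core[4, ] + c(0.50, -1.40, -0.50))
  coords <- rbind(core, methyls)
  list(atoms = data.frame(element = c("C", "N", "N", "N", rep("C", 4)),
                          charge = c(0L, 1L, rep(0L, 6)),
                          hcount = c(0L, 2L, 0L, 0L, rep(3L, 4))),
       bonds = data.frame(a1 = c(1, 1, 1, 3, 3, 4, 4),
                          a2 = c(2, 3, 4, 5, 6, 7, 8),
                          order = c(2L, rep(1L, 6))),
       coords = coords, anchor = colMeans(core))
}

.fragKetone <- function() {
  # acetone-like (CH3)2C=O with the acceptor O as anchor
  coords <- rbind(c(0, 0, 0),          # O
                  c(1.22, 0, 0),       # C (carbonyl)
                  c(1.99, 1.26, 0),    # CH3
                  c(1.99, -1.26, 0))   # CH3
  list(atoms = data.frame(element = c("O", "C", "C", "C"),
                          charge = 0L, hcount = c(0L, 0L, 3L, 3L)),
       bonds = data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                          order = c(2L, 1L, 1L)),
       coords = coords, anchor = c(0, 0, 0))
}

.fragBenzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  coords <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  list(atoms = data.frame(element = rep("C", 6), charge = 0L,
                          aromatic = TRUE, hcount = 1L),
       bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                          order = rep(c(1L, 2L), 3), aromatic = TRUE),
       coords = coords, anchor = c(0, 0, 0))
}

.fragAlkane <- function(len = 3L) {
  # zig-zag chain, centroid at the origin
  x <- (seq_len(len) - (len + 1) / 2) * 1.26
  y <- rep(c(0.44, -0.44), length.out = len)
  y <- y - mean(y)
  coords <- cbind(x, y, 0)
  h <- c(3L, rep(2L, max(0, len - 2L)), 3L)[seq_len(len)]
  bonds <- if (len > 1L)
    data.frame(a1 = seq_len(len - 1L), a2 = 2:len, order = 1L) else NULL
  list(atoms = data.frame(element = rep("C", len), charge = 0L, hcount = h),
       bonds = bonds, coords = coords, anchor = colMeans(coords))
}

.fragMethanol <- function() {
  # HBD (and HBA) carrier: O anchor
  coords <- rbind(c(0, 0, 0), c(1.43, 0, 0))
  list(atoms = data.frame(element = c("O", "C"), charge = 0L,
                          hcount = c(1L, 3L)),
       bonds = data.frame(a1 = 1, a2 = 2, order = 1L),
       coords = coords, anchor = c(0, 0, 0))
}

.fragEthane <- function() {
  coords <- rbind(c(-0.76, 0, 0), c(0.76, 0, 0))
  list(atoms = data.frame(element = c("C", "C"), charge = 0L, hcount = 3L),
       bonds = data.frame(a1 = 1, a2 = 2, order = 1L),
       coords = coords, anchor = c(0, 0, 0))
}

.fragForKind <- function(kind, alkaneLen = 3L) {
  switch(kind,
    POS_IONIZABLE = .fragGuanidinium(),
    HBA = .fragKetone(),
    AROMATIC = .fragBenzene(),
    HYDROPHOBIC = .fragAlkane(alkaneLen),
    HBD = .fragMethanol(),
    stop("no fragment builder for feature kind ", kind))
}

# assemble fragments (optionally rigidly placed) into one Molecule
.assembleFragments <- function(id, frags, placements = NULL, ic50 = numeric(0)) {
  atoms <- list(); bonds <- list(); coords <- list()
  offset <- 0L
  for (q in seq_along(frags)) {
    f <- frags[[q]]
    xyz <- f$coords
    if (!is.null(placements)) {
      pl <- placements[[q]]
      xyz <- sweep(sweep(xyz, 2, f$anchor) %*% pl$R, 2, pl$target, `+`)
    }
    atoms[[q]] <- f$atoms
    if (!is.null(f$bonds)) {
      b <- as.data.frame(f$bonds)
      b$a1 <- b$a1 + offset; b$a2 <- b$a2 + offset
      bonds[[q]] <- b
    }
    coords[[q]] <- xyz
    offset <- offset + nrow(f$atoms)
  }
  allAtoms <- do.call(rbind, lapply(atoms, function(a) {
    if (is.null(a$charge)) a$charge <- 0L
    if (is.null(a$aromatic)) a$aromatic <- FALSE
    if (is.null(a$hcount)) a$hcount <- 0L
    a[, c("element", "charge", "aromatic", "hcount")]
  }))
  allBonds <- if (length(bonds)) do.call(rbind, lapply(bonds, function(b) {
    if (is.null(b$aromatic)) b$aromatic <- FALSE
    b[, c("a1", "a2", "order", "aromatic")]
  })) else NULL
  newMolecule(id, atoms = allAtoms, bonds = allBonds,
              coords = do.call(rbind, coords), ic50 = ic50)
}

#' Generate synthetic active molecules embedding a pharmacophore
#'
#' Each active is a multi-fragment feature-carrier molecule: one chemical
#' fragment per model feature (guanidinium for POS_IONIZABLE, a ketone for
#' HBA, benzene for AROMATIC, an alkane chain for HYDROPHOBIC, methanol for
#' HBD), rigidly placed so that the perceived feature centroid sits at the
#' model center plus a uniform jitter of at most \code{noise} Angstrom, with
#' a random fragment orientation. Alkane chain length (3-6) and an optional
#' inert ethane fragment vary the property profile across the set. IC50
#' annotations are drawn below 0.05 uM. Fully seeded and deterministic.
#'
#' @param model a \linkS4class{PharmacophoreModel}
#' @param n number of actives
#' @param noise jitter bound, Angstrom (must be below the smallest feature
#'   tolerance)
#' @param seed integer seed
#' @return list of \linkS4class{Molecule} with ids "active_001", ...
#' @export
genActives <- function(model, n, noise = 0.2, seed) {
  stopifnot(noise >= 0, noise < min(model@features$tolerance))
  centers <- .featureCoords(model@features)
  kinds <- model@features$kind
  .withSeed(.deriveSeed(seed, "gen-actives"), {
    lapply(seq_len(n), function(i) {
      len <- sample(3:6, 1)
      frags <- lapply(kinds, .fragForKind, alkaneLen = len)
      placements <- lapply(seq_along(kinds), function(q) {
        jitter <- .randomUnitVector() * stats::runif(1, 0, noise)
        list(R = .randomRotation(), target = centers[q, ] + jitter)
      })
      if (stats::runif(1) < 0.5) {
        frags <- c(frags, list(.fragEthane()))
        placements <- c(placements, list(list(
          R = .randomRotation(),
          target = colMeans(centers) + .randomUnitVector() * 9)))
      }
      .assembleFragments(sprintf("active_%03d", i), frags, placements,
                         ic50 = stats::runif(1, 0.001, 0.049))
    })
  })
}

.randomUnitVector <- function() .unit(stats::rnorm(3))

#' Generate property-matched synthetic decoys
#'
#' Decoys are built from the same fragment palette as the actives (so their
#' property vectors fall inside the actives' +/- 4 SD window) but with the
#' fragments placed at scrambled positions whose geometry cannot be mapped
#' onto the model: each candidate is re-sampled until \code{mapLigand}
#' rejects it with zero omissions. No IC50 annotation is attached.
#'
#' @param model the \linkS4class{PharmacophoreModel} the decoys must evade
#' @param n number of decoys
#' @param seed integer seed
#' @param stats optional reference statistics; when supplied, each decoy is
#'   additionally required to pass the +/- kSd property window
#' @param kSd window width used with \code{stats} (default 4)
#' @return list of \linkS4class{Molecule} with ids "decoy_0001", ...
#' @export
genDecoys <- function(model, n, seed, stats = NULL, kSd = 4) {
  if (n == 0L) return(list())
  kinds <- model@features$kind
  strict <- model
  strict@maxOmitted <- 0L
  .withSeed(.deriveSeed(seed, "gen-decoys"), {
    lapply(seq_len(n), function(i) {
      for (attempt in 1:60) {
        len <- sample(3:6, 1)
        frags <- lapply(kinds, .fragForKind, alkaneLen = len)
        targets <- .scrambledTargets(length(kinds))
        placements <- lapply(seq_along(kinds), function(q)
          list(R = .randomRotation(), target = targets[q, ]))
        if (stats::runif(1) < 0.5) {
          frags <- c(frags, list(.fragEthane()))
          placements <- c(placements, list(list(
            R = .randomRotation(),
            target = colMeans(targets) + .randomUnitVector() * 9)))
        }
        m <- .assembleFragments(sprintf("decoy_%04d", i), frags, placements)
        okWindow <- is.null(stats) ||
          length(propertyFilter(list(m), stats, kSd = kSd,
                                chargeRule = FALSE)) == 1L
        if (okWindow && is.null(mapLigand(strict, m))) return(m)
      }
      stop("could not generate a non-mapping decoy after 60 attempts")
    })
  })
}

# random fragment-centroid positions: first at the origin, the rest 4-10 A
# away with a 3 A minimum pairwise separation
.scrambledTargets <- function(k) {
  repeat {
    t <- rbind(c(0, 0, 0),
               t(vapply(seq_len(k - 1L), function(i)
                 .randomUnitVector() * stats::runif(1, 4, 10), numeric(3))))
    d <- as.matrix(stats::dist(t)); diag(d) <- Inf
    if (min(d) >= 3) return(t)
  }
}

# --- SAR matched-pair generator ---------------------------------------------

# substituent palette for the scaffold positions; feature kinds are what
# perceiveFeatures reports on the substituent atoms
.SUBSTITUENT_PALETTE <- list(
  none = list(frag = NULL, kinds = character(0)),
  methyl = list(kinds = character(0)),
  ethyl = list(kinds = character(0)),
  propyl = list(kinds = "HYDROPHOBIC"),
  phenyl = list(kinds = "AROMATIC"),
  methoxyphenyl = list(kinds = c("AROMATIC", "HBA")),
  hydroxymethyl = list(kinds = c("HBD", "HBA"))
)

# build substituent atoms/bonds; attachment atom is always index 1
.buildSubstituent <- function(name) {
  switch(name,
    none = NULL,
    methyl = list(atoms = data.frame(element = "C", charge = 0L,
                                     aromatic = FALSE, hcount = 3L),
                  bonds = NULL),
    ethyl = list(atoms = data.frame(element = c("C", "C"), charge = 0L,
                                    aromatic = FALSE, hcount = c(2L, 3L)),
                 bonds = data.frame(a1 = 1, a2 = 2, order = 1L)),
    propyl = list(atoms = data.frame(element = c("C", "C", "C"), charge = 0L,
                                     aromatic = FALSE, hcount = c(2L, 2L, 3L)),
                  bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1L)),
    phenyl = list(atoms = data.frame(element = rep("C", 6), charge = 0L,
                                     aromatic = TRUE,
                                     hcount = c(0L, rep(1L, 5))),
                  bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                     order = rep(c(1L, 2L), 3),
                                     aromatic = TRUE)),
    methoxyphenyl = list(
      atoms = data.frame(element = c(rep("C", 6), "O", "C"), charge = 0L,
                         aromatic = c(rep(TRUE, 6), FALSE, FALSE),
                         hcount = c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 3L)),
      bonds = data.frame(a1 = c(1:6, 4, 7), a2 = c(2:6, 1, 7, 8),
                         order = c(rep(c(1L, 2L), 3), 1L, 1L),
                         aromatic = c(rep(TRUE, 6), FALSE, FALSE))),
    hydroxymethyl = list(
      atoms = data.frame(element = c("C", "O"), charge = 0L,
                         aromatic = FALSE, hcount = c(2L, 1L)),
      bonds = data.frame(a1 = 1, a2 = 2, order = 1L)),
    stop("unknown substituent ", name))
}

#' The default SAR scaffold template
#'
#' A benzene core with four labeled variable positions (A1, D, L2, Q) at
#' ring carbons 1, 3, 5 and 6 — a stand-in for a fixed shared scaffold with
#' four substituent attachment points.
#'
#' @return a ScaffoldTemplate
#' @export
defaultScaffold <- function() {
  core <- .assembleFragments("scaffold-core", list(.fragBenzene()))
  scaffoldTemplate(core, c(A1 = 1L, D = 3L, L2 = 5L, Q = 6L))
}

#' Generate matched active/inactive molecule pairs on a scaffold
#'
#' Each pair shares all substituents except at one planted position, where
#' the active carries a substituent bearing the rule's feature kinds and the
#' inactive a counterpart lacking them. IC50 values are drawn on the active
#' (< 0.05 uM) and inactive (> 1 uM) sides. Pairs cycle through the rule's
#' positions. Molecules get a crude 3D embedding sufficient for feature-kind
#' perception.
#'
#' @param template a ScaffoldTemplate from \code{scaffoldTemplate}
#' @param rule named list: position label -> character vector of planted
#'   feature kinds (must be realizable by the substituent palette)
#' @param nPairs number of pairs
#' @param seed integer seed
#' @return list(actives, inactives): lists of \linkS4class{Molecule}
#' @export
genMatchedPairs <- function(template,
                            rule = list(D = c("AROMATIC", "HBA")),
                            nPairs = 13L, seed) {
  palette <- names(.SUBSTITUENT_PALETTE)
  kindsOf <- function(nm) .SUBSTITUENT_PALETTE[[nm]]$kinds
  positions <- names(template$positions)
  rulePos <- names(rule)
  .withSeed(.deriveSeed(seed, "gen-pairs"), {
    actives <- list(); inactives <- list()
    for (i in seq_len(nPairs)) {
      pos <- rulePos[((i - 1L) %% length(rulePos)) + 1L]
      wanted <- rule[[pos]]
      withKinds <- palette[vapply(palette, function(nm)
        all(wanted %in% kindsOf(nm)), logical(1))]
      without <- palette[vapply(palette, function(nm)
        !all(wanted %in% kindsOf(nm)), logical(1))]
      if (!length(withKinds))
        stop("no palette substituent offers kinds: ",
             paste(wanted, collapse = "+"))
      subActive <- sample(withKinds, 1)
      subInactive <- sample(without, 1)
      shared <- stats::setNames(sample(palette, length(positions),
                                       replace = TRUE), positions)
      subsA <- shared; subsA[pos] <- subActive
      subsI <- shared; subsI[pos] <- subInactive
      actives[[i]] <- .buildScaffoldMolecule(
        sprintf("pair%02d_act", i), template, subsA,
        ic50 = stats::runif(1, 0.001, 0.049))
      inactives[[i]] <- .buildScaffoldMolecule(
        sprintf("pair%02d_inact", i), template, subsI,
        ic50 = stats::runif(1, 1.5, 20))
    }
    list(actives = actives, inactives = inactives)
  })
}

# core + substituents with a crude radial 3D embedding
.buildScaffoldMolecule <- function(id, template, subs, ic50) {
  core <- template$core
  atoms <- core@atoms
  bonds <- core@bonds
  coords <- core@conformers[[1]]$coords
  for (lbl in names(subs)) {
    sub <- .buildSubstituent(subs[[lbl]])
    if (is.null(sub)) next
    attachAt <- template$positions[[lbl]]
    offset <- nrow(atoms)
    atoms <- rbind(atoms, sub$atoms[, c("element", "charge", "aromatic",
                                        "hcount")])
    sb <- if (is.null(sub$bonds)) NULL else {
      b <- as.data.frame(sub$bonds)
      if (is.null(b$aromatic)) b$aromatic <- FALSE
      data.frame(a1 = b$a1 + offset, a2 = b$a2 + offset, order = b$order,
                 aromatic = b$aromatic)
    }
    bonds <- rbind(bonds,
                   data.frame(a1 = attachAt, a2 = offset + 1L, order = 1L,
                              aromatic = FALSE), sb)
    # attachment carbon loses one implicit H
    atoms$hcount[attachAt] <- max(0L, atoms$hcount[attachAt] - 1L)
    coords <- rbind(coords, .radialEmbedding(sub, coords[attachAt, ]))
  }
  newMolecule(id, atoms = atoms, bonds = bonds, coords = coords, ic50 = ic50)
}

# place substituent atoms outward from the attachment point; benzene-like
# rings keep their hexagon shape, chains march radially
.radialEmbedding <- function(sub, attachPos) {
  dir <- .unit(attachPos + c(1e-3, 2e-3, 3e-3))  # radially outward
  n <- nrow(sub$atoms)
  base <- attachPos + dir * 1.5
  if (n >= 6L && all(sub$atoms$aromatic[1:6])) {
    ang <- seq(0, 300, by = 60) * pi / 180
    ref <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    # center the ring so atom 1 is nearest the core
    ringCtr <- base + dir * 1.39
    perp <- .unit(pracma::cross(dir, c(0, 0, 1) +
                                  c(1e-4, 2e-4, 0)))
    up <- .unit(pracma::cross(dir, perp))
    xyz <- t(vapply(seq_len(6), function(i)
      ringCtr + ref[i, 1] * -dir + ref[i, 2] * perp, numeric(3)))
    if (n > 6L) {
      extra <- t(vapply(seq_len(n - 6L), function(k)
        ringCtr + dir * (1.39 + 1.4 * k) + up * 0.2 * k, numeric(3)))
      xyz <- rbind(xyz, extra)
    }
    return(xyz)
  }
  t(vapply(seq_len(n), function(k)
    base + dir * 1.4 * (k - 1L) +
      c(0, 0, 0.3) * ((k - 1L) %% 2L), numeric(3)))
}

# --- toy complex generator ---------------------------------------------------

.SIDECHAIN_FRAGS <- list(
  GLU = list(atoms = c(CD = "C", OE1 = "O", OE2 = "O"),
             coords = rbind(c(0.9, 0, 0), c(-0.45, 1.08, 0),
                            c(-0.45, -1.08, 0))),
  ASP = list(atoms = c(CG = "C", OD1 = "O", OD2 = "O"),
             coords = rbind(c(0.9, 0, 0), c(-0.45, 1.08, 0),
                            c(-0.45, -1.08, 0))),
  ARG = list(atoms = c(CZ = "C", NE = "N", NH1 = "N", NH2 = "N"),
             coords = rbind(c(0, 0, 0), c(1.33, 0, 0),
                            c(-0.665, 1.152, 0), c(-0.665, -1.152, 0))),
  LYS = list(atoms = c(NZ = "N", CE = "C"),
             coords = rbind(c(0, 0, 0), c(1.5, 0, 0))),
  CYS = list(atoms = c(SG = "S", CB = "C"),
             coords = rbind(c(0, 0, 0), c(1.8, 0, 0))),
  THR = list(atoms = c(OG1 = "O", CB = "C", CG2 = "C"),
             coords = rbind(c(0, 0, 0), c(1.43, 0, 0), c(2.2, 1.2, 0))),
  SER = list(atoms = c(OG = "O", CB = "C"),
             coords = rbind(c(0, 0, 0), c(1.43, 0, 0))),
  ASN = list(atoms = c(ND2 = "N", CG = "C", OD1 = "O"),
             coords = rbind(c(0, 0, 0), c(1.33, 0.4, 0), c(2.0, 1.4, 0))),
  MET = list(atoms = c(SD = "S", CG = "C", CE = "C"),
             coords = rbind(c(0, 0, 0), c(1.8, 0, 0), c(-1.2, 1.3, 0))),
  PHE = list(atoms = c(CG = "C", CD1 = "C", CD2 = "C", CE1 = "C",
                       CE2 = "C", CZ = "C"),
             coords = {
               ang <- seq(0, 300, by = 60) * pi / 180
               cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)[c(1, 2, 6, 3, 5, 4), ]
             })
)

.DEFAULT_SITE <- c("GLU:119", "CYS:137", "ASN:141", "ARG:144", "THR:145",
                   "PHE:300", "ARG:307", "PHE:324", "MET:332")

# toy ligand: cationic amine, ketone acceptor, benzene ring, propane, plus a
# small auxiliary carbonyl above the ring (the H-bond partner of a
# ring-stacking Arg); fixed local layout with well-separated anchor groups
.toyLigand <- function() {
  amine <- list(atoms = data.frame(element = c("N", "C"),
                                   charge = c(1L, 0L), aromatic = FALSE,
                                   hcount = c(3L, 3L)),
                bonds = data.frame(a1 = 1, a2 = 2, order = 1L),
                coords = rbind(c(-6, 0, 0), c(-4.6, 0, 0)),
                anchor = NULL)
  ketone <- .fragKetone()
  # O at (6,0,0) with the carbonyl carbon on the +x side, leaving the -x
  # hemisphere and the y/z slots around the O free for donor approaches
  ketone$coords <- sweep(ketone$coords, 2, c(6, 0, 0), `+`)
  ring <- .fragBenzene()
  alkane <- .fragAlkane(3L)
  alkane$coords <- sweep(alkane$coords, 2, c(0, 6, 0), `+`)
  aux <- list(atoms = data.frame(element = c("O", "C"), charge = 0L,
                                 aromatic = FALSE, hcount = c(0L, 2L)),
              bonds = data.frame(a1 = 1, a2 = 2, order = 2L),
              coords = rbind(c(-5, 0, 4.5), c(-6.2, 0, 4.7)),
              anchor = NULL)
  .assembleFragments("toy-ligand", list(amine, ketone, ring, alkane, aux))
}

# anchor coordinates inside the toy ligand
.TOY_ANCHORS <- list(
  posN = c(-6, 0, 0),        # cationic N
  acceptorO = c(6, 0, 0),    # ketone O (carbonyl C at 7.22 -- +x is blocked)
  auxO = c(-5, 0, 4.5),      # auxiliary acceptor for a stacking Arg
  ringCtr = c(0, 0, 0),      # benzene centroid, normal +z
  ringNormal = c(0, 0, 1)
)

# direction slots for hydrogen-bond donors approaching the acceptor O
.HB_SLOTS <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
                   c(0, 0.707, 0.707))

# placement slots for pi interactions over/under the ring: unit directions
# from the ring centroid, all within the 30-degree normal cone
.PI_SLOTS <- rbind(c(0, 0, 1), c(0, 0, -1),
                   c(0.42, 0, 0.91), c(-0.42, 0, -0.91),
                   c(0, 0.42, 0.91), c(0, -0.42, -0.91))

#' Generate a toy receptor-ligand complex realizing an interaction pattern
#'
#' Builds a minimal binding site from isolated amino-acid side-chain
#' fragments (Glu, Arg, Cys, Thr, Phe, Asn, Met analogs) positioned around a
#' fixed multi-fragment ligand (cationic amine, ketone acceptor, aromatic
#' ring, alkane) so that \code{detectInteractions} yields exactly the
#' requested fingerprint bits: residues named in the pattern are placed at
#' interaction geometry, all other site residues on a distant shell. The
#' generated fingerprint is verified internally before returning.
#'
#' @param pattern data.frame (type, residue) with type in HBOND, CHARGED, PI;
#'   e.g. \code{data.frame(type = c("CHARGED", "HBOND", "PI"),
#'   residue = c("GLU:119", "ARG:144", "ARG:307"))}. Zero rows give a
#'   contact-free pose.
#' @param seed integer seed (controls the small placement jitter)
#' @param siteResidues residue ids making up the site (default: the
#'   nine-residue toy TM site)
#' @param poseId pose identifier
#' @return a \linkS4class{ComplexStructure}
#' @export
genToyComplex <- function(pattern, seed,
                          siteResidues = .DEFAULT_SITE,
                          poseId = "pose") {
  pattern <- as.data.frame(pattern)
  if (nrow(pattern)) {
    stopifnot(all(c("type", "residue") %in% names(pattern)))
    bad <- setdiff(pattern$residue, siteResidues)
    if (length(bad))
      stop("pattern references residues outside the site: ",
           paste(bad, collapse = ", "))
  }
  lig <- .toyLigand()
  rows <- list()
  hbSlot <- 0L
  piSlot <- 0L
  shellSlot <- 0L
  .withSeed(.deriveSeed(seed, paste0("toy:", poseId)), {
    for (resKey in siteResidues) {
      reqs <- if (nrow(pattern))
        pattern[pattern$residue == resKey, , drop = FALSE]
      else pattern[0, , drop = FALSE]
      types <- sort(unique(reqs$type))
      if (length(types) == 0L) {
        shellSlot <- shellSlot + 1L
        rows[[length(rows) + 1L]] <- .placeResidueShell(resKey, shellSlot)
      } else if (identical(types, c("HBOND", "PI"))) {
        # one residue realizing both: a cation stacking on the ring while
        # donating a hydrogen bond to the auxiliary carbonyl
        rows[[length(rows) + 1L]] <- .placeResidueStackHB(resKey)
        piSlot <- piSlot + 1L
      } else if (length(types) == 1L) {
        typ <- types[1]
        place <- .placeResidueFor(typ, resKey, hbSlot, piSlot)
        if (typ == "HBOND") hbSlot <- hbSlot + 1L
        if (typ == "PI") piSlot <- piSlot + 1L
        rows[[length(rows) + 1L]] <- place
      } else {
        stop("pattern is geometrically unsatisfiable: cannot combine ",
             paste(types, collapse = "+"), " on one residue (", resKey, ")")
      }
    }
    residues <- do.call(rbind, rows)
    jitter <- matrix(stats::runif(3 * nrow(residues), -0.05, 0.05),
                     ncol = 3)
    residues[, c("x", "y", "z")] <- residues[, c("x", "y", "z")] + jitter
    cx <- new("ComplexStructure", residues = residues, ligand = lig,
              poseId = poseId)
    # internal verification: exactly the requested bits
    fp <- interactionFingerprint(cx, siteResidues)
    want <- rep(0L, length(fp@bits))
    if (nrow(pattern)) {
      chan <- c(HBOND = "HBOND", CHARGED = "CHARGED", PI = "PI")
      for (q in seq_len(nrow(pattern))) {
        hit <- fp@indexMap$residue == pattern$residue[q] &
               fp@indexMap$channel == chan[[pattern$type[q]]]
        want[hit] <- 1L
      }
    }
    if (!identical(fp@bits, want)) {
      got <- paste(fp@indexMap$residue[fp@bits == 1L],
                   fp@indexMap$channel[fp@bits == 1L], sep = "/",
                   collapse = ", ")
      stop("pattern is geometrically unsatisfiable for pose '", poseId,
           "'; realized bits: ", if (nzchar(got)) got else "(none)")
    }
    cx
  })
}

# residue atoms for one interaction request, in the ligand frame
.placeResidueFor <- function(type, resKey, hbSlot, piSlot = 0L) {
  parts <- strsplit(resKey, ":", fixed = TRUE)[[1]]
  resName <- parts[1]; resNo <- as.integer(parts[2])
  frag <- .SIDECHAIN_FRAGS[[resName]]
  if (is.null(frag)) stop("unsupported residue type ", resName)
  A <- .TOY_ANCHORS
  local <- frag$coords
  if (type == "CHARGED") {
    if (!resName %in% names(.RESIDUE_NEG_GROUP))
      stop("CHARGED requires an acidic residue, got ", resName)
    # carboxylate group centroid 3.7 A from the cationic N; the carbon faces
    # the ligand so the O atoms stay > 3.5 A from the amine (salt bridge
    # without a registered hydrogen bond)
    ctr <- A$posN + c(-3.7, 0, 0)
    xyz <- sweep(local, 2, ctr, `+`)
  } else if (type == "HBOND") {
    donorIdx <- which(names(frag$atoms) %in%
                        .RESIDUE_DONORS[[resName]])[1]
    if (is.na(donorIdx))
      stop("HBOND requires a donor-bearing residue, got ", resName)
    d <- .HB_SLOTS[(hbSlot %% nrow(.HB_SLOTS)) + 1L, ]
    reach <- if (frag$atoms[[donorIdx]] == "S") 3.2 else 2.9
    donorPos <- A$acceptorO + d * reach
    # orient the fragment so its bulk points along d, away from the ligand
    shifted <- sweep(local, 2, local[donorIdx, ])
    bulk <- colMeans(shifted)
    R <- if (sqrt(sum(bulk^2)) > 1e-6) .rotationFromTo(.unit(bulk), d)
         else diag(3)
    xyz <- sweep(shifted %*% t(R), 2, donorPos, `+`)
  } else if (type == "PI") {
    d <- .PI_SLOTS[(piSlot %% nrow(.PI_SLOTS)) + 1L, ]
    if (resName %in% names(.RESIDUE_POS_GROUP)) {      # pi-cation
      ctr <- A$ringCtr + d * 3.6
      xyz <- sweep(local, 2, ctr, `+`)
    } else if (resName %in% names(.RESIDUE_RINGS)) {   # pi-pi stack
      ctr <- A$ringCtr + d * 3.8
      xyz <- sweep(local, 2, ctr, `+`)
    } else stop("PI requires a cationic or aromatic residue, got ", resName)
  } else stop("unknown interaction type ", type)
  data.frame(resname = resName, resno = resNo, chain = "A",
             atom = names(frag$atoms), element = unname(frag$atoms),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# combined placement: a cationic side chain stacking over the ligand ring
# (pi-cation) with its NE donor reaching the auxiliary carbonyl oxygen
.placeResidueStackHB <- function(resKey) {
  parts <- strsplit(resKey, ":", fixed = TRUE)[[1]]
  resName <- parts[1]; resNo <- as.integer(parts[2])
  if (!resName %in% names(.RESIDUE_POS_GROUP))
    stop("a combined PI+HBOND placement needs a cationic residue, got ",
         resName)
  frag <- .SIDECHAIN_FRAGS[[resName]]
  A <- .TOY_ANCHORS
  # group centroid off-axis above the ring (24 deg off the normal, within
  # the pi-cation cone) with the donor nitrogen rotated toward the aux O
  ctr <- A$ringCtr + c(-1.5, 0, 3.3)
  R <- .rotationFromTo(c(1, 0, 0), c(-1, 0, 0))
  xyz <- sweep(frag$coords %*% t(R), 2, ctr, `+`)
  data.frame(resname = resName, resno = resNo, chain = "A",
             atom = names(frag$atoms), element = unname(frag$atoms),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# non-interacting residues: distant shell positions
.placeResidueShell <- function(resKey, slot) {
  parts <- strsplit(resKey, ":", fixed = TRUE)[[1]]
  resName <- parts[1]; resNo <- as.integer(parts[2])
  frag <- .SIDECHAIN_FRAGS[[resName]]
  if (is.null(frag)) stop("unsupported residue type ", resName)
  golden <- pi * (3 - sqrt(5))
  zFrac <- 1 - 2 * ((slot %% 9) + 0.5) / 9
  theta <- golden * slot
  dir <- c(sqrt(1 - zFrac^2) * cos(theta), sqrt(1 - zFrac^2) * sin(theta),
           zFrac)
  ctr <- dir * 16
  xyz <- sweep(frag$coords, 2, ctr, `+`)
  data.frame(resname = resName, resno = resNo, chain = "A",
             atom = names(frag$atoms), element = unname(frag$atoms),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# rotation taking unit vector a to unit vector b
.rotationFromTo <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- pracma::cross(a, b)
  c0 <- sum(a * b)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # 180 degrees: rotate about any perpendicular axis
    perp <- .unit(pracma::cross(a, if (abs(a[1]) < 0.9) c(1, 0, 0)
                                   else c(0, 1, 0)))
    return(2 * outer(perp, perp) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

#' Canonical interaction patterns of active- and inactive-like poses
#'
#' The active signature mirrors the pose analysis of potent antagonists: a
#' charged interaction with the acidic anchor (Glu 2.61 role), a hydrogen
#' bond with Cys137, a pi-cation plus hydrogen bond from one Arg anchor
#' (Arg307 6.58 role) and a pi-cation from the other (Arg144 3.32 role) —
#' it satisfies all three structure-based pose constraints. The inactive
#' signature keeps only a hydrogen bond with Arg144 and one with Thr145.
#'
#' @return data.frame (type, residue) usable with \code{genToyComplex}
#' @export
activePosePattern <- function() {
  data.frame(
    type = c("CHARGED", "HBOND", "PI", "HBOND", "PI"),
    residue = c("GLU:119", "CYS:137", "ARG:144", "ARG:307", "ARG:307"))
}

#' @rdname activePosePattern
#' @export
inactivePosePattern <- function() {
  data.frame(type = c("HBOND", "HBOND"),
             residue = c("ARG:144", "THR:145"))
}

#' Generate a labeled set of toy poses (active vs inactive patterns)
#'
#' Actives realize \code{activePosePattern()}, inactives
#' \code{inactivePosePattern()}. Each pose's pattern entries are
#' independently flipped (dropped, or replaced by a random feasible entry)
#' with probability \code{flipProb} to emulate pose noise.
#'
#' @param nActive,nInactive pose counts
#' @param flipProb per-entry flip probability (default 0.05)
#' @param seed integer seed
#' @return list(poses = list of ComplexStructure, labels = named logical
#'   vector, TRUE = active pattern)
#' @export
genPoseSet <- function(nActive = 20L, nInactive = 20L, flipProb = 0.05,
                       seed) {
  activePattern <- activePosePattern()
  inactivePattern <- inactivePosePattern()
  extras <- data.frame(
    type = c("HBOND", "PI", "PI"),
    residue = c("ASN:141", "PHE:300", "PHE:324"))
  feasible <- rbind(activePattern, inactivePattern, extras)
  feasible <- unique(feasible)
  poses <- list(); labels <- logical(0)
  .withSeed(.deriveSeed(seed, "pose-set"), {
    flipSeeds <- sample.int(1e6, nActive + nInactive)
    for (i in seq_len(nActive + nInactive)) {
      isActive <- i <= nActive
      pat <- if (isActive) activePattern else inactivePattern
      keep <- stats::runif(nrow(pat)) >= flipProb
      pat <- pat[keep, , drop = FALSE]
      # additions: any feasible entry not present may flip on
      pool <- feasible[!paste(feasible$type, feasible$residue) %in%
                         paste(pat$type, pat$residue), , drop = FALSE]
      addOn <- stats::runif(nrow(pool)) < flipProb
      pat <- rbind(pat, pool[addOn, , drop = FALSE])
      id <- sprintf("%s_%03d", if (isActive) "act" else "inact", i)
      poses[[length(poses) + 1L]] <- genToyComplex(
        pat, seed = flipSeeds[i], poseId = id)
      labels[id] <- isActive
    }
  })
  list(poses = poses, labels = labels)
}
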
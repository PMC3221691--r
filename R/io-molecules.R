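#' Read molecules from SDF, SMILES or MOL2
#'
#' SDF records are parsed with \pkg{ChemmineR}; SMILES and MOL2 inputs are
#' converted to SDF by OpenBabel via \pkg{ChemmineOB} (which must be
#' installed for those formats). Records that fail sanitization are skipped
#' with a warning naming the record and reason; input order is preserved.
#'
#' @param path input file
#' @param format one of "sdf", "smiles", "mol2"
#' @param gen3d for SMILES input, generate 3D coordinates with OpenBabel
#'   (default TRUE; otherwise the 2D layout is kept)
#' @return list of \linkS4class{Molecule}
#' @export
readMolecules <- function(path, format = c("sdf", "smiles", "mol2"),
                          gen3d = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  sdfText <- switch(format,
    sdf = paste(readLines(path, warn = FALSE), collapse = "\n"),
    smiles = .smilesToSdf(path, gen3d),
    mol2 = .convertWithOB("MOL2", path))
  mols <- .parseSdfText(sdfText)
  if (!length(mols)) stop("no valid molecule records in '", path, "'")
  mols
}

.needOB <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("reading this format requires the ChemmineOB package")
}

.smilesToSdf <- function(path, gen3d) {
  .needOB()
  src <- paste(readLines(path, warn = FALSE), collapse = "\n")
  opts <- if (gen3d) data.frame(names = "gen3D", args = "") else NULL
  ChemmineOB::convertFormat("SMI", "SDF", source = src, options = opts)
}

.convertWithOB <- function(from, path) {
  .needOB()
  src <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ChemmineOB::convertFormat(from, "SDF", source = src)
}

# split raw SDF text into records and parse each; invalid records skipped
.parseSdfText <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  recEnds <- grep("^\\$\\$\\$\\$", lines)
  if (!length(recEnds)) recEnds <- length(lines)
  starts <- c(1L, head(recEnds, -1L) + 1L)
  mols <- list()
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:recEnds[i]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!any(nzchar(trimws(rec)))) next
    m <- tryCatch(.parseSdfRecord(rec, i),
                  error = function(e) {
                    warning("skipping SDF record ", i, ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) mols[[length(mols) + 1L]] <- m
  }
  mols
}

# parse one V2000 molfile record (header + counts + atom/bond blocks + M CHG)
.parseSdfRecord <- function(rec, recno) {
  if (length(rec) < 4L) stop("truncated record")
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- paste0("mol_", recno)
  counts <- rec[4]
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nA) || is.na(nB) || nA < 1L) stop("bad counts line")
  if (length(rec) < 4L + nA + nB) stop("atom/bond block shorter than counts")
  at <- rec[5:(4 + nA)]
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  el <- trimws(substr(at, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z) || !all(el %in% names(.ATOMIC_MASS)))
    stop("unparseable atom block")
  bonds <- NULL
  if (nB > 0L) {
    bl <- rec[(5 + nA):(4 + nA + nB)]
    a1 <- as.integer(substr(bl, 1, 3))
    a2 <- as.integer(substr(bl, 4, 6))
    or <- as.integer(substr(bl, 7, 9))
    if (anyNA(a1) || anyNA(a2) || anyNA(or) ||
        any(a1 < 1L | a1 > nA | a2 < 1L | a2 > nA))
      stop("unparseable bond block")
    bonds <- data.frame(a1 = a1, a2 = a2,
                        order = ifelse(or == 4L, 1L, or),
                        aromatic = or == 4L)
  }
  charge <- integer(nA)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    nEntries <- as.integer(substr(ln, 7, 9))
    for (k in seq_len(nEntries)) {
      off <- 10 + (k - 1) * 8
      ai <- as.integer(substr(ln, off, off + 3))
      cv <- as.integer(substr(ln, off + 4, off + 7))
      charge[ai] <- cv
    }
  }
  mol <- newMolecule(id,
    atoms = data.frame(element = el, charge = charge),
    bonds = bonds, coords = cbind(x, y, z))
  mol <- .perceiveAromaticity(mol)
  mol <- .fillImplicitH(mol)
  ic <- .sdfField(rec, c("IC50_uM", "ic50_uM", "IC50"))
  if (!is.na(ic)) mol@ic50 <- as.numeric(ic)
  mol
}

.sdfField <- function(rec, names) {
  for (nm in names) {
    hit <- grep(paste0("^> *<", nm, ">"), rec)
    if (length(hit) && hit[1] < length(rec)) return(trimws(rec[hit[1] + 1L]))
  }
  NA_character_
}

# flag atoms/bonds aromatic: order-4 bonds from the file, plus rings of
# carbons with alternating single/double (kekulized benzene-like rings)
.perceiveAromaticity <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(mol)
  mol@atoms$aromatic[unique(c(b$a1[b$aromatic], b$a2[b$aromatic]))] <- TRUE
  om <- .bondOrderMap(mol)
  for (ring in .smallestRings(mol)) {
    if (length(ring) != 6L) next
    edges <- cbind(ring, c(ring[-1], ring[1]))
    orders <- vapply(seq_len(6L), function(i)
      .getOrder(om, edges[i, 1], edges[i, 2]), integer(1))
    ok <- all(mol@atoms$element[ring] %in% c("C", "N")) &&
      sum(orders == 2L) == 3L && sum(orders == 1L) == 3L &&
      all(abs(diff(c(orders, orders[1]))) == 1L)
    if (ok) {
      mol@atoms$aromatic[ring] <- TRUE
      bkey <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2), sep = "-")
      rkey <- paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]), sep = "-")
      mol@bonds$aromatic[bkey %in% rkey] <- TRUE
    }
  }
  mol
}

# standard-valence implicit hydrogen fill for atoms with no explicit H
.STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L,
                  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)

.fillImplicitH <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  hasExplicitH <- logical(nrow(a))
  bondOrderSum <- numeric(nrow(a))
  for (i in seq_len(nrow(b))) {
    o <- if (b$aromatic[i]) 1.5 else b$order[i]
    bondOrderSum[b$a1[i]] <- bondOrderSum[b$a1[i]] + o
    bondOrderSum[b$a2[i]] <- bondOrderSum[b$a2[i]] + o
    if (a$element[b$a2[i]] == "H") hasExplicitH[b$a1[i]] <- TRUE
    if (a$element[b$a1[i]] == "H") hasExplicitH[b$a2[i]] <- TRUE
  }
  val <- .STD_VALENCE[a$element]
  h <- pmax(0, round(val + a$charge - bondOrderSum))
  h[a$element == "H" | hasExplicitH] <- 0
  # aromatic ring atoms with two ring bonds: 1.5+1.5 -> one H for carbon
  mol@atoms$hcount <- as.integer(h)
  mol
}

#' Write molecules to an SDF (V2000) file
#'
#' One record per molecule (first conformer) or per conformer when
#' \code{allConformers} is TRUE. Formal charges are written as M CHG lines;
#' aromatic bonds are written with their kekulized orders. An IC50
#' annotation, when present, is written as an \code{IC50_uM} data field.
#'
#' @param mols list of \linkS4class{Molecule}
#' @param path output file
#' @param allConformers write every conformer as its own record
#' @return invisibly, the path
#' @export
writeMoleculesSDF <- function(mols, path, allConformers = FALSE) {
  if (is(mols, "Molecule")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    idx <- if (allConformers) seq_along(mol@conformers) else 1L
    for (ci in idx) out <- c(out, .sdfRecord(mol, ci))
  }
  writeLines(out, path)
  invisible(path)
}

.sdfRecord <- function(mol, ci) {
  a <- mol@atoms; b <- mol@bonds
  xyz <- mol@conformers[[ci]]$coords
  rec <- c(mol@id, "  PhoreScreen", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  rec <- c(rec, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        xyz[, 1], xyz[, 2], xyz[, 3], a$element))
  if (nrow(b))
    rec <- c(rec, sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order))
  chg <- which(a$charge != 0L)
  for (i in chg)
    rec <- c(rec, sprintf("M  CHG%3d%4d%4d", 1L, i, a$charge[i]))
  rec <- c(rec, "M  END")
  if (length(mol@ic50))
    rec <- c(rec, "> <IC50_uM>", format(mol@ic50, digits = 10), "")
  c(rec, "$$$$")
}

#' Write a property table CSV
#'
#' Columns: id, mw, logp, hbd, hba, rotatable, formal_charge.
#'
#' @param mols list of \linkS4class{Molecule}
#' @param path output CSV
#' @return invisibly, the data frame written
#' @export
writePropertyTable <- function(mols, path) {
  tab <- do.call(rbind, lapply(mols, function(m) {
    p <- computeProperties(m)
    data.frame(id = molId(m), mw = p["mw"], logp = p["logp"],
               hbd = p["hbd"], hba = p["hba"], rotatable = p["rotatable"],
               formal_charge = p["formal_charge"], row.names = NULL)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
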
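#' Property-window pre-filter
#'
#' Retains molecules whose every property (mw, logp, hbd, hba, rotatable,
#' formal_charge) lies within mean +/- kSd * SD of the reference statistics,
#' and — when the charge rule is on — whose net formal charge is neutral or
#' positive. Order-preserving and idempotent.
#'
#' @param mols list of \linkS4class{Molecule}
#' @param stats reference statistics from \code{referenceStats}
#' @param kSd window half-width in SD units (default 4)
#' @param chargeRule require formal charge >= 0 (default TRUE)
#' @return the retained molecules, input order preserved
#' @export
propertyFilter <- function(mols, stats, kSd = 4, chargeRule = TRUE) {
  stopifnot(kSd > 0)
  keep <- vapply(mols, function(m) {
    p <- computeProperties(m)
    inWin <- abs(p[rownames(stats)] - stats$mean) <= kSd * stats$sd + 1e-9
    all(inWin) && (!chargeRule || p["formal_charge"] >= 0)
  }, logical(1))
  mols[keep]
}

#' Sample a property-matched decoy set
#'
#' Draws n molecules without replacement from a pool that has already passed
#' the property filter against the actives' statistics; re-asserts the
#' window on every sampled decoy.
#'
#' @param actives list of active \linkS4class{Molecule} (defines the window)
#' @param pool list of candidate decoys
#' @param n decoys to sample
#' @param seed integer seed
#' @param kSd window half-width (default 4)
#' @return list of n decoy molecules
#' @export
buildDecoySet <- function(actives, pool, n, seed, kSd = 4) {
  if (n == 0L) return(list())
  stats <- referenceStats(actives)
  pool <- propertyFilter(pool, stats, kSd = kSd, chargeRule = FALSE)
  if (length(pool) < n)
    stop("decoy pool (", length(pool), " after filtering) smaller than n = ", n)
  idx <- .withSeed(.deriveSeed(seed, "decoy-sample"),
                   sample.int(length(pool), n))
  pool[sort(idx)]
}

#' Screen a library against a pharmacophore model
#'
#' Maps every molecule with \code{mapLigand}; molecules that cannot be
#' mapped are excluded from the hit list. The result is sorted by fit value
#' descending, ties broken by molecule id.
#'
#' @param model a \linkS4class{PharmacophoreModel}
#' @param mols list of \linkS4class{Molecule}
#' @return data.frame (id, fit, conformer) ranked by fit descending
#' @export
screenLibrary <- function(model, mols) {
  rows <- lapply(mols, function(m) {
    res <- mapLigand(model, m)
    if (is.null(res)) return(NULL)
    data.frame(id = molId(m), fit = res@fitValue,
               conformer = res@conformerIndex)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(id = character(), fit = numeric(),
                      conformer = integer()))
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$fit, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' ROC enrichment of a screening run
#'
#' Builds the ROC curve by sweeping the fit threshold downward over the
#' ranked scores; molecules of the screened set that were not retrieved are
#' assigned fit -Inf ("not retrieved"). The AUC is the trapezoid area; the
#' full-recall cutoff is the minimum fit among the actives — the highest
#' threshold at which the true-positive rate is 1 (ties retained on the >=
#' side, mirroring a FitValue >= cutoff hit rule).
#'
#' @param hits data.frame (id, fit) from \code{screenLibrary}
#' @param activeIds character vector of known-active ids
#' @param allIds optional character vector of all screened ids (defaults to
#'   the union of hits and actives); unscored ids enter at fit -Inf
#' @return an \linkS4class{EnrichmentResult}
#' @export
rocEnrichment <- function(hits, activeIds, allIds = NULL) {
  if (!length(activeIds)) stop("ROC is undefined with zero actives")
  if (is.null(allIds)) allIds <- union(hits$id, activeIds)
  fit <- stats::setNames(rep(-Inf, length(allIds)), allIds)
  fit[hits$id] <- hits$fit
  isActive <- names(fit) %in% activeIds
  if (all(isActive)) stop("ROC needs at least one decoy")
  ord <- order(-fit, names(fit))
  ranked <- data.frame(id = names(fit)[ord], fit = unname(fit[ord]),
                       isActive = isActive[ord])
  nA <- sum(ranked$isActive); nD <- nrow(ranked) - nA
  # sweep unique thresholds; tied scores enter the curve together
  uniqFit <- unique(ranked$fit)
  tpr <- c(0, vapply(uniqFit, function(t)
    sum(ranked$isActive & ranked$fit >= t) / nA, numeric(1)))
  fpr <- c(0, vapply(uniqFit, function(t)
    sum(!ranked$isActive & ranked$fit >= t) / nD, numeric(1)))
  aucVal <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  cutoff <- min(ranked$fit[ranked$isActive])
  new("EnrichmentResult", ranked = ranked,
      rocPoints = data.frame(fpr = fpr, tpr = tpr),
      auc = aucVal, fullRecallCutoff = cutoff)
}

#' Hashed path fingerprint
#'
#' A 2048-bit fingerprint over linear heavy-atom paths of up to
#' \code{maxLen} bonds: each path's canonical element/bond-order string is
#' hashed to one bit. Deterministic; used for Tanimoto similarity.
#'
#' @param mol a \linkS4class{Molecule}
#' @param nbits fingerprint length (default 2048)
#' @param maxLen maximum path length in bonds (default 7)
#' @return a \linkS4class{BitFingerprint}
#' @export
pathFingerprint <- function(mol, nbits = 2048L, maxLen = 7L) {
  a <- mol@atoms
  heavy <- which(a$element != "H")
  adj <- .adjList(mol)
  om <- .bondOrderMap(mol)
  label <- function(i) paste0(a$element[i], ifelse(a$aromatic[i], "ar", ""))
  paths <- character(0)
  walk <- function(path, strFwd) {
    paths[[length(paths) + 1L]] <<- strFwd
    if (length(path) > maxLen) return(invisible())
    i <- path[length(path)]
    for (j in adj[[i]]) {
      if (j %in% path || a$element[j] == "H") next
      walk(c(path, j), paste0(strFwd, .getOrder(om, i, j), label(j)))
    }
    invisible()
  }
  for (i in heavy) walk(i, label(i))
  # canonical direction: a path and its reverse hash identically
  canon <- vapply(paths, function(s) {
    r <- .reversePathString(s)
    if (r < s) r else s
  }, character(1))
  bits <- sort(unique(vapply(canon, .stringHash, integer(1), nbits = nbits)))
  new("BitFingerprint", bits = as.integer(bits), length = as.integer(nbits),
      params = list(scheme = "linear-path", maxLen = maxLen))
}

.reversePathString <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]*(ar)?|[0-9]", s))[[1]]
  paste(rev(toks), collapse = "")
}

#' Tanimoto similarity of two bit fingerprints
#'
#' SA / (SA + SB + SC), with SA the bits set in both fingerprints, SB those
#' set only in the first and SC only in the second. Two empty fingerprints
#' score 0 by convention. Symmetric; in [0, 1].
#'
#' @param a,b \linkS4class{BitFingerprint} objects of equal length
#' @return the Tanimoto coefficient
#' @export
tanimoto <- function(a, b) {
  if (a@length != b@length)
    stop("fingerprint lengths differ (", a@length, " vs ", b@length, ")")
  sa <- length(intersect(a@bits, b@bits))
  un <- length(union(a@bits, b@bits))
  if (un == 0L) return(0)
  sa / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param molsA,molsB lists of \linkS4class{Molecule}; fingerprints are
#'   computed with \code{pathFingerprint}
#' @param ... passed to \code{pathFingerprint}
#' @return |A| x |B| matrix with dimnames from the molecule ids
#' @export
similarityMatrix <- function(molsA, molsB = molsA, ...) {
  fa <- lapply(molsA, pathFingerprint, ...)
  fb <- if (identical(molsA, molsB)) fa else lapply(molsB, pathFingerprint, ...)
  m <- matrix(0, length(fa), length(fb),
              dimnames = list(vapply(molsA, molId, character(1)),
                              vapply(molsB, molId, character(1))))
  for (i in seq_along(fa)) for (j in seq_along(fb))
    m[i, j] <- tanimoto(fa[[i]], fb[[j]])
  m
}
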
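#' Construct a PharmacophoreModel
#'
#' @param kinds character vector of feature kinds (HBA, HBD, POS_IONIZABLE,
#'   AROMATIC, HYDROPHOBIC)
#' @param centers k x 3 matrix of feature centers, Angstrom
#' @param tolerance tolerance radius per feature, Angstrom (default 1.6,
#'   recycled)
#' @param directions optional k x 3 matrix of unit directions (NA rows for
#'   undirected features)
#' @param angTol angular tolerance, degrees (default 45, recycled)
#' @param minInterfeatureDistance minimum distance between feature centers,
#'   Angstrom (default 1.0)
#' @param maxOmitted number of features a ligand may omit (default 0)
#' @return a \linkS4class{PharmacophoreModel}
#' @export
newPharmacophoreModel <- function(kinds, centers, tolerance = 1.6,
                                  directions = NULL, angTol = 45,
                                  minInterfeatureDistance = 1.0,
                                  maxOmitted = 0L) {
  k <- length(kinds)
  centers <- as.matrix(centers)
  if (is.null(directions)) directions <- matrix(NA_real_, k, 3)
  f <- data.frame(kind = kinds, x = centers[, 1], y = centers[, 2],
                  z = centers[, 3], tolerance = rep_len(tolerance, k),
                  dx = directions[, 1], dy = directions[, 2],
                  dz = directions[, 3], angTol = rep_len(angTol, k))
  new("PharmacophoreModel", features = f,
      minInterfeatureDistance = minInterfeatureDistance,
      maxOmitted = as.integer(maxOmitted))
}

#' Pharmacophore fit value
#'
#' The fit of a mapped ligand: \code{sum over features of
#' max(0, 1 - (d/r)^2)} where d is the displacement of the matched ligand
#' feature from the model feature center and r the tolerance radius. A
#' perfect mapping of a k-feature model scores k (4 for a four-feature
#' model); a feature displaced beyond its tolerance contributes 0.
#'
#' @param displacements numeric, displacement per matched feature (Angstrom)
#' @param tolerances numeric, tolerance radius per feature (Angstrom)
#' @return the fit value, in [0, k]
#' @export
#' @examples
#' fitValue(c(0, 0, 0, 0), rep(1.6, 4))   # 4
#' fitValue(c(1.6, 0, 0, 0), rep(1.6, 4)) # 3
fitValue <- function(displacements, tolerances) {
  stopifnot(length(displacements) == length(tolerances),
            all(tolerances > 0), all(displacements >= 0))
  sum(pmax(0, 1 - (displacements / tolerances)^2))
}

#' Map a ligand onto a pharmacophore model
#'
#' Searches every conformer and every kind-compatible injective assignment
#' of model features to perceived ligand features. For each assignment the
#' ligand feature centroids are superposed onto the model centers by Kabsch
#' least squares; the assignment is accepted if every non-omitted feature
#' lies within its tolerance radius (and within the angular tolerance when
#' both carry directions), with at most \code{maxOmitted} omissions. The
#' mapping maximizing the fit value is returned; ties break to the lower
#' conformer energy, then to lexicographic assignment order.
#'
#' @param model a \linkS4class{PharmacophoreModel}
#' @param mol a \linkS4class{Molecule} with at least one conformer
#' @param featureCache optional precomputed list of per-conformer feature
#'   data frames (as from \code{perceiveFeatures}) to avoid re-perception
#' @return a \linkS4class{MappingResult}, or NULL when the ligand cannot be
#'   mapped
#' @export
mapLigand <- function(model, mol, featureCache = NULL) {
  mf <- model@features
  k <- nrow(mf)
  centers <- .featureCoords(mf)
  best <- NULL
  featsList <- if (is.null(featureCache)) .allConformerFeatures(mol)
               else featureCache
  for (ci in seq_along(mol@conformers)) {
    lf <- featsList[[ci]]
    if (!nrow(lf)) next
    cand <- lapply(seq_len(k), function(i) which(lf$kind == mf$kind[i]))
    if (sum(vapply(cand, length, integer(1)) == 0L) > model@maxOmitted) next
    energy <- mol@conformers[[ci]]$energy
    lcoords <- .featureCoords(lf)
    for (asn in .enumerateAssignments(cand, model@maxOmitted)) {
      res <- .scoreAssignment(model, centers, lf, lcoords, asn)
      if (is.null(res)) next
      if (is.null(best) ||
          res$fit > best@fitValue + 1e-12 ||
          (abs(res$fit - best@fitValue) <= 1e-12 &&
           energy < mol@conformers[[best@conformerIndex]]$energy - 1e-12)) {
        best <- new("MappingResult", assignment = asn, transform = res$tf,
                    displacements = res$disp, fitValue = res$fit,
                    conformerIndex = as.integer(ci))
      }
    }
  }
  best
}

# all injective assignments model-feature -> ligand-feature row; NA = omitted,
# at most maxOmit NAs. Ordered lexicographically (NA last per slot).
.enumerateAssignments <- function(cand, maxOmit) {
  k <- length(cand)
  out <- list()
  rec <- function(i, used, cur, omitted) {
    if (i > k) { out[[length(out) + 1L]] <<- cur; return(invisible()) }
    for (j in cand[[i]]) {
      if (j %in% used) next
      cur[i] <- j
      rec(i + 1L, c(used, j), cur, omitted)
    }
    if (omitted < maxOmit) {
      cur[i] <- NA_integer_
      rec(i + 1L, used, cur, omitted + 1L)
    }
    invisible()
  }
  rec(1L, integer(0), rep(NA_integer_, k), 0L)
  out
}

# superpose ligand features of one assignment onto model centers and score;
# NULL when a matched feature exceeds tolerance or violates direction
.scoreAssignment <- function(model, centers, lf, lcoords, asn) {
  mf <- model@features
  matched <- which(!is.na(asn))
  if (length(matched) < 2L) return(NULL)
  from <- lcoords[asn[matched], , drop = FALSE]
  to <- centers[matched, , drop = FALSE]
  tf <- .kabsch(from, to)
  placed <- .applyTransform(from, tf)
  disp <- rep(NA_real_, nrow(mf))
  disp[matched] <- sqrt(rowSums((placed - to)^2))
  if (any(disp[matched] > mf$tolerance[matched] + 1e-9)) return(NULL)
  # direction check, post-superposition (rotation part only)
  for (q in seq_along(matched)) {
    i <- matched[q]; j <- asn[i]
    mdir <- c(mf$dx[i], mf$dy[i], mf$dz[i])
    ldir <- c(lf$dx[j], lf$dy[j], lf$dz[j])
    if (!anyNA(mdir) && !anyNA(ldir)) {
      rotated <- drop(ldir %*% tf$R)
      ang <- .angleBetween(rotated, mdir)
      # ring normals are axial: 180-degree flips are equivalent
      if (mf$kind[i] == "AROMATIC") ang <- min(ang, 180 - ang)
      if (ang > mf$angTol[i] + 1e-9) return(NULL)
    }
  }
  fit <- fitValue(disp[matched], mf$tolerance[matched])
  list(fit = fit, disp = disp, tf = tf)
}

#' Build common-feature pharmacophore models from reference actives
#'
#' Enumerates k-subsets of the first (most active) reference's perceived
#' features, k descending over \code{kRange}, and keeps a subset when every
#' other reference carries a kind-matched feature set whose pairwise
#' distance matrix agrees within twice the tolerance. Surviving subsets
#' become models (centers at the first reference's feature positions),
#' ranked by feature count (descending) then by mean cross-reference
#' displacement (ascending); at most \code{maxModels} are returned. Subsets
#' violating the minimum interfeature distance are discarded.
#'
#' @param references list of \linkS4class{Molecule}, most active first, each
#'   with at least one conformer
#' @param kRange integer range of model sizes to try (default 4:5)
#' @param tolerance tolerance radius for emitted features (default 1.6)
#' @param minInterfeatureDistance minimum feature separation (default 1.0)
#' @param maxModels cap on emitted models (default 10)
#' @return list of \linkS4class{PharmacophoreModel} (possibly empty)
#' @export
buildCommonFeatureModel <- function(references, kRange = 4:5,
                                    tolerance = 1.6,
                                    minInterfeatureDistance = 1.0,
                                    maxModels = 10L) {
  if (length(references) < 2L)
    stop("need at least 2 reference molecules")
  refFeats <- lapply(references, perceiveFeatures)
  lead <- refFeats[[1]]
  if (!nrow(lead)) return(list())
  scored <- list()
  for (k in sort(kRange, decreasing = TRUE)) {
    if (k > nrow(lead) || k < 2L) next
    for (subset in utils::combn(nrow(lead), k, simplify = FALSE)) {
      sub <- lead[subset, , drop = FALSE]
      ctr <- .featureCoords(sub)
      d <- as.matrix(stats::dist(ctr)); diag(d) <- Inf
      if (min(d) < minInterfeatureDistance) next
      meanDisp <- .crossReferenceSupport(sub, refFeats[-1], tolerance)
      if (is.na(meanDisp)) next
      # emitted models are positional-only: the subset search assesses
      # distance-matrix consistency, not direction consistency, so copying
      # the lead reference's directions would impose arbitrary constraints
      model <- newPharmacophoreModel(
        kinds = sub$kind, centers = ctr, tolerance = tolerance,
        minInterfeatureDistance = minInterfeatureDistance)
      scored[[length(scored) + 1L]] <- list(model = model, k = k,
                                            disp = meanDisp)
    }
  }
  if (!length(scored)) {
    message("no common feature subset found among the references")
    return(list())
  }
  ord <- order(-vapply(scored, `[[`, numeric(1), "k"),
               vapply(scored, `[[`, numeric(1), "disp"))
  lapply(scored[ord][seq_len(min(maxModels, length(scored)))], `[[`, "model")
}

# can every other reference match the candidate subset? Features matched by
# kind, pairwise distances within 2*tolerance. Returns the mean over
# references of the best assignment's mean |distance difference|, or NA.
.crossReferenceSupport <- function(sub, otherFeats, tolerance) {
  ctr <- .featureCoords(sub)
  dRef <- as.matrix(stats::dist(ctr))
  total <- 0
  for (feats in otherFeats) {
    if (!nrow(feats)) return(NA_real_)
    cand <- lapply(sub$kind, function(kind) which(feats$kind == kind))
    if (any(vapply(cand, length, integer(1)) == 0L)) return(NA_real_)
    bestErr <- NA_real_
    fc <- .featureCoords(feats)
    for (asn in .enumerateAssignments(cand, 0L)) {
      dCand <- as.matrix(stats::dist(fc[asn, , drop = FALSE]))
      diffs <- abs(dCand - dRef)[upper.tri(dRef)]
      if (all(diffs <= 2 * tolerance)) {
        err <- mean(diffs)
        if (is.na(bestErr) || err < bestErr) bestErr <- err
      }
    }
    if (is.na(bestErr)) return(NA_real_)
    total <- total + bestErr
  }
  total / length(otherFeats)
}

#' Write a pharmacophore model to JSON
#'
#' Schema: an object with \code{minInterfeatureDistance}, \code{maxOmitted}
#' and a \code{features} array of \{kind, center, tolerance, direction,
#' angTol\}; round-trips bit-exactly through \code{readPharmacophoreModel}.
#'
#' @param model a \linkS4class{PharmacophoreModel}
#' @param path output JSON file
#' @return invisibly, the path
#' @export
writePharmacophoreModel <- function(model, path) {
  f <- model@features
  feats <- lapply(seq_len(nrow(f)), function(i) {
    entry <- list(kind = f$kind[i], center = c(f$x[i], f$y[i], f$z[i]),
                  tolerance = f$tolerance[i], angTol = f$angTol[i])
    if (!is.na(f$dx[i])) entry$direction <- c(f$dx[i], f$dy[i], f$dz[i])
    entry
  })
  obj <- list(minInterfeatureDistance = model@minInterfeatureDistance,
              maxOmitted = model@maxOmitted, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#'
#' @param path JSON file written by \code{writePharmacophoreModel}
#' @return a \linkS4class{PharmacophoreModel}
#' @export
readPharmacophoreModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  k <- length(obj$features)
  kinds <- vapply(obj$features, `[[`, character(1), "kind")
  centers <- t(vapply(obj$features, function(e) unlist(e$center), numeric(3)))
  tol <- vapply(obj$features, `[[`, numeric(1), "tolerance")
  ang <- vapply(obj$features, `[[`, numeric(1), "angTol")
  dirs <- t(vapply(obj$features, function(e)
    if (is.null(e$direction)) rep(NA_real_, 3) else unlist(e$direction),
    numeric(3)))
  newPharmacophoreModel(kinds, centers, tolerance = tol, directions = dirs,
    angTol = ang,
    minInterfeatureDistance = as.numeric(obj$minInterfeatureDistance),
    maxOmitted = as.integer(obj$maxOmitted))
}
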
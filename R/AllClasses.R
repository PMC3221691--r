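#' @import methods
NULL

#' Molecule: a small molecule with graph, conformers and optional activity
#'
#' The unit flowing through screening. Atoms are stored as a data frame with
#' columns \code{element}, \code{charge} (formal charge, e), \code{aromatic}
#' (logical) and \code{hcount} (implicit hydrogens); bonds as a data frame
#' with columns \code{a1}, \code{a2}, \code{order}, \code{aromatic}.
#' Conformers are a list of \code{list(coords = n x 3 matrix [Angstrom],
#' energy = numeric [kcal/mol])}.
#'
#' @slot id character molecule identifier
#' @slot atoms data.frame of atoms
#' @slot bonds data.frame of bonds
#' @slot conformers list of conformers
#' @slot ic50 numeric, optional IC50 in micromolar (length 0 when absent)
#' @slot meta list of free-form annotations (e.g. SAR position substituents)
#' @exportClass Molecule
setClass("Molecule",
  representation(id = "character", atoms = "data.frame", bonds = "data.frame",
                 conformers = "list", ic50 = "numeric", meta = "list"),
  prototype(ic50 = numeric(0), meta = list())
)

setValidity("Molecule", function(object) {
  msgs <- character(0)
  a <- object@atoms; b <- object@bonds
  need <- c("element", "charge", "aromatic", "hcount")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) && !all(a$element %in% names(.ATOMIC_MASS)))
    msgs <- c(msgs, "unknown element symbol")
  if (nrow(a) && any(abs(a$charge) > 4))
    msgs <- c(msgs, "formal charge outside [-4, 4]")
  if (nrow(b)) {
    if (!all(c("a1", "a2", "order", "aromatic") %in% names(b)))
      msgs <- c(msgs, "bonds must have columns a1, a2, order, aromatic")
    else if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
      msgs <- c(msgs, "bond atom index out of range")
  }
  for (cf in object@conformers) {
    if (!is.matrix(cf$coords) || nrow(cf$coords) != nrow(a) || ncol(cf$coords) != 3L)
      msgs <- c(msgs, "conformer coordinate matrix must be n_atoms x 3")
    else if (!all(is.finite(cf$coords)))
      msgs <- c(msgs, "conformer coordinates must be finite")
    if (!is.null(cf$energy) && !is.finite(cf$energy))
      msgs <- c(msgs, "conformer energy must be finite")
  }
  if (length(object@ic50) && (length(object@ic50) != 1L || object@ic50 <= 0))
    msgs <- c(msgs, "ic50 must be a single positive value (uM)")
  if (length(msgs)) msgs else TRUE
})

#' PharmacophoreModel: a set of spatial chemical features with tolerances
#'
#' The screening query: k features, each with a kind (HBA, HBD,
#' POS_IONIZABLE, AROMATIC, HYDROPHOBIC), a 3D center (Angstrom), a tolerance
#' radius (Angstrom) and an optional unit direction with angular tolerance
#' (degrees). Feature centers must be at least
#' \code{minInterfeatureDistance} apart.
#'
#' @slot features data.frame with columns kind, x, y, z, tolerance, dx, dy,
#'   dz (direction, NA when absent), angTol (degrees)
#' @slot minInterfeatureDistance numeric, Angstrom (default 1.0)
#' @slot maxOmitted integer, features allowed to be omitted during mapping
#'   (default 0)
#' @exportClass PharmacophoreModel
setClass("PharmacophoreModel",
  representation(features = "data.frame",
                 minInterfeatureDistance = "numeric",
                 maxOmitted = "integer"),
  prototype(minInterfeatureDistance = 1.0, maxOmitted = 0L)
)

.FEATURE_KINDS <- c("HBA", "HBD", "POS_IONIZABLE", "AROMATIC", "HYDROPHOBIC")

setValidity("PharmacophoreModel", function(object) {
  f <- object@features
  need <- c("kind", "x", "y", "z", "tolerance")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) < 2L) return("a pharmacophore model needs at least 2 features")
  if (!all(f$kind %in% .FEATURE_KINDS)) return("unknown feature kind")
  if (any(f$tolerance <= 0)) return("tolerances must be positive")
  ctr <- as.matrix(f[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  if (min(d) < object@minInterfeatureDistance - 1e-9)
    return("feature centers closer than the minimum interfeature distance")
  TRUE
})

#' MappingResult: outcome of mapping one ligand onto a pharmacophore model
#'
#' @slot assignment integer vector, model feature index -> ligand feature row
#'   (NA for omitted features)
#' @slot transform list(R, t): rigid transform taking ligand feature
#'   coordinates into the model frame
#' @slot displacements numeric, per-model-feature displacement after
#'   superposition (Angstrom; NA for omitted)
#' @slot fitValue numeric in [0, k]
#' @slot conformerIndex integer, conformer achieving the fit
#' @exportClass MappingResult
setClass("MappingResult",
  representation(assignment = "integer", transform = "list",
                 displacements = "numeric", fitValue = "numeric",
                 conformerIndex = "integer"))

#' EnrichmentResult: ranked screening scores with ROC summary
#'
#' @slot ranked data.frame (id, fit, isActive) sorted by fit descending
#' @slot rocPoints data.frame (fpr, tpr)
#' @slot auc numeric in [0, 1]
#' @slot fullRecallCutoff numeric fit value: the highest threshold at which
#'   every active is retrieved (the minimum active fit)
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(ranked = "data.frame", rocPoints = "data.frame",
                 auc = "numeric", fullRecallCutoff = "numeric"))

setValidity("EnrichmentResult", function(object) {
  if (object@auc < -1e-9 || object@auc > 1 + 1e-9) return("auc outside [0,1]")
  p <- object@rocPoints
  if (nrow(p) && (is.unsorted(p$fpr) || is.unsorted(p$tpr)))
    return("ROC points must be non-decreasing")
  TRUE
})

#' BitFingerprint: fixed-length binary fingerprint
#'
#' @slot bits integer vector of set bit positions (1-based, sorted)
#' @slot length integer total bit length
#' @slot params list describing the generating scheme
#' @exportClass BitFingerprint
setClass("BitFingerprint",
  representation(bits = "integer", length = "integer", params = "list"))

setValidity("BitFingerprint", function(object) {
  if (length(object@bits) &&
      (min(object@bits) < 1L || max(object@bits) > object@length))
    return("bit positions out of range")
  if (is.unsorted(object@bits, strictly = TRUE) && length(object@bits) > 1L)
    return("bits must be sorted and unique")
  TRUE
})

#' ComplexStructure: receptor residues plus one ligand pose
#'
#' Residue atoms are stored as one data frame with columns \code{resname},
#' \code{resno}, \code{chain}, \code{atom} (PDB atom name), \code{element},
#' \code{x}, \code{y}, \code{z}. The ligand is a \linkS4class{Molecule} with
#' exactly one conformer sharing the receptor coordinate frame (Angstrom).
#'
#' @slot residues data.frame of receptor atoms
#' @slot ligand Molecule with one conformer
#' @slot poseId character pose identifier
#' @slot dockingScore numeric (length 0 when absent)
#' @slot bwLabels named character, optional Ballesteros-Weinstein labels
#'   keyed by residue id ("GLU:119")
#' @exportClass ComplexStructure
setClass("ComplexStructure",
  representation(residues = "data.frame", ligand = "Molecule",
                 poseId = "character", dockingScore = "numeric",
                 bwLabels = "character"),
  prototype(dockingScore = numeric(0), bwLabels = character(0)))

setValidity("ComplexStructure", function(object) {
  r <- object@residues
  need <- c("resname", "resno", "chain", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (length(object@ligand@conformers) != 1L)
    return("ligand must carry exactly one conformer (the pose)")
  if (sum(object@ligand@atoms$element != "H") < 1L)
    return("ligand must have at least one heavy atom")
  if (length(object@bwLabels) &&
      !all(grepl("^[0-9]+\\.[0-9]+$", object@bwLabels)))
    return("Ballesteros-Weinstein labels must look like 'X.NN'")
  TRUE
})

#' InteractionFingerprint: per-residue interaction bit vector for one pose
#'
#' One bit per (binding-site residue, channel) pair, channels HBOND, CHARGED
#' and PI (pi-pi and pi-cation merged). The index map records the residue id
#' and channel behind every coordinate so fingerprints from different poses
#' are comparable only when their maps agree.
#'
#' @slot bits integer 0/1 vector
#' @slot indexMap data.frame (residue, channel) of length equal to bits
#' @slot poseId character
#' @exportClass InteractionFingerprint
setClass("InteractionFingerprint",
  representation(bits = "integer", indexMap = "data.frame",
                 poseId = "character"))

setValidity("InteractionFingerprint", function(object) {
  if (length(object@bits) != nrow(object@indexMap))
    return("bits length must equal index map rows")
  if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
    return("bits must be 0/1")
  if (!all(c("residue", "channel") %in% names(object@indexMap)))
    return("index map needs columns residue, channel")
  TRUE
})

.IFP_CHANNELS <- c("HBOND", "CHARGED", "PI")
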
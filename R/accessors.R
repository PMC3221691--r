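#' Accessors for PhoreScreen classes
#'
#' Slot access for the package's S4 objects.
#'
#' @param object a PhoreScreen S4 object
#' @name accessors
NULL

#' @describeIn accessors molecule identifier
#' @export
setGeneric("molId", function(object) standardGeneric("molId"))
#' @rdname accessors
setMethod("molId", "Molecule", function(object) object@id)

#' @describeIn accessors atom table
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
setMethod("atoms", "Molecule", function(object) object@atoms)

#' @describeIn accessors bond table
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))
#' @rdname accessors
setMethod("bonds", "Molecule", function(object) object@bonds)

#' @describeIn accessors list of conformers
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))
#' @rdname accessors
setMethod("conformers", "Molecule", function(object) object@conformers)

#' @describeIn accessors conformer count
#' @export
setGeneric("nConformers", function(object) standardGeneric("nConformers"))
#' @rdname accessors
setMethod("nConformers", "Molecule", function(object) length(object@conformers))

#' @describeIn accessors IC50 annotation in micromolar (NA when absent)
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname accessors
setMethod("ic50", "Molecule", function(object)
  if (length(object@ic50)) object@ic50 else NA_real_)

#' @describeIn accessors feature table of a pharmacophore model
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
setMethod("features", "PharmacophoreModel", function(object) object@features)

#' @describeIn accessors number of features in a model
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname accessors
setMethod("nFeatures", "PharmacophoreModel",
          function(object) nrow(object@features))

#' @describeIn accessors fit value of a mapping result
#' @export
setGeneric("fitValueOf", function(object) standardGeneric("fitValueOf"))
#' @rdname accessors
setMethod("fitValueOf", "MappingResult", function(object) object@fitValue)

#' @describeIn accessors AUC of an enrichment result
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
setMethod("auc", "EnrichmentResult", function(object) object@auc)

#' @describeIn accessors full-recall fit cutoff of an enrichment result
#' @export
setGeneric("fullRecallCutoff", function(object)
  standardGeneric("fullRecallCutoff"))
#' @rdname accessors
setMethod("fullRecallCutoff", "EnrichmentResult",
          function(object) object@fullRecallCutoff)

#' @describeIn accessors ranked score table of an enrichment result
#' @export
setGeneric("rankedScores", function(object) standardGeneric("rankedScores"))
#' @rdname accessors
setMethod("rankedScores", "EnrichmentResult", function(object) object@ranked)

#' @describeIn accessors ROC points (fpr, tpr) of an enrichment result
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
setMethod("rocPoints", "EnrichmentResult", function(object) object@rocPoints)

#' @describeIn accessors 0/1 vector of an interaction fingerprint
#' @export
setGeneric("fingerprintBits", function(object)
  standardGeneric("fingerprintBits"))
#' @rdname accessors
setMethod("fingerprintBits", "InteractionFingerprint",
          function(object) object@bits)

#' @describeIn accessors (residue, channel) index map of a fingerprint
#' @export
setGeneric("indexMap", function(object) standardGeneric("indexMap"))
#' @rdname accessors
setMethod("indexMap", "InteractionFingerprint",
          function(object) object@indexMap)

#' @describeIn accessors receptor atom table of a complex
#' @export
setGeneric("residueAtoms", function(object) standardGeneric("residueAtoms"))
#' @rdname accessors
setMethod("residueAtoms", "ComplexStructure", function(object) object@residues)

#' @describeIn accessors ligand molecule of a complex
#' @export
setGeneric("ligand", function(object) standardGeneric("ligand"))
#' @rdname accessors
setMethod("ligand", "ComplexStructure", function(object) object@ligand)

#' @describeIn accessors pose identifier of a complex
#' @export
setGeneric("poseId", function(object) standardGeneric("poseId"))
#' @rdname accessors
setMethod("poseId", "ComplexStructure", function(object) object@poseId)

#' Residue identifiers of a complex, in file order
#'
#' @param cx a \linkS4class{ComplexStructure}
#' @return character vector like "GLU:119"
#' @export
residueIds <- function(cx) {
  r <- residueAtoms(cx)
  unique(paste(r$resname, r$resno, sep = ":"))
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds, %d conformer(s)",
              object@id, nrow(object@atoms),
              sum(object@atoms$element != "H"), nrow(object@bonds),
              length(object@conformers)))
  if (length(object@ic50)) cat(sprintf(", IC50 %.4g uM", object@ic50))
  cat("\n")
})

setMethod("show", "PharmacophoreModel", function(object) {
  cat(sprintf("PharmacophoreModel: %d features (maxOmitted=%d, minDist=%.2f A)\n",
              nrow(object@features), object@maxOmitted,
              object@minInterfeatureDistance))
  f <- object@features
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-13s (%6.2f, %6.2f, %6.2f)  r=%.2f\n",
                f$kind[i], f$x[i], f$y[i], f$z[i], f$tolerance[i]))
})

setMethod("show", "MappingResult", function(object) {
  cat(sprintf("MappingResult: fit %.4f (conformer %d), displacements: %s\n",
              object@fitValue, object@conformerIndex,
              paste(sprintf("%.2f", object@displacements), collapse = ", ")))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d scored (%d actives), AUC %.4f, full-recall cutoff %.5f\n",
              nrow(object@ranked), sum(object@ranked$isActive),
              object@auc, object@fullRecallCutoff))
})

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure '%s': %d residues, ligand %s (%d heavy atoms)\n",
              object@poseId, length(residueIds(object)),
              object@ligand@id, sum(object@ligand@atoms$element != "H")))
})

setMethod("show", "InteractionFingerprint", function(object) {
  on <- which(object@bits == 1L)
  cat(sprintf("InteractionFingerprint '%s': %d/%d bits set",
              object@poseId, length(on), length(object@bits)))
  if (length(on))
    cat(": ", paste(object@indexMap$residue[on], object@indexMap$channel[on],
                    sep = "/", collapse = ", "), sep = "")
  cat("\n")
})

setMethod("show", "BitFingerprint", function(object) {
  cat(sprintf("BitFingerprint: %d/%d bits set\n",
              length(object@bits), object@length))
})
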
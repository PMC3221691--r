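#' Default pipeline configuration
#'
#' One list of every tunable the two pipelines use, with defaults equal to
#' the study conditions: IC50 cutoffs 0.05/1 uM, +/- 4 SD property window,
#' 1.6 A feature tolerance, 1 A minimum interfeature distance, zero omitted
#' features, 56 actives among 500 decoys at 0.2 A geometric noise.
#'
#' @param seed integer seed governing every random stage
#' @return a named list; any entry may be overridden before running
#' @export
defaultConfig <- function(seed = 7L) {
  list(seed = seed,
       nActives = 56L, nDecoys = 500L, noise = 0.2,
       tolerance = 1.6, minInterfeatureDistance = 1.0, maxOmitted = 0L,
       kSd = 4, ic50Low = 0.05, ic50High = 1.0,
       kRange = 4L, nReferences = 3L, linkage = "average",
       nActivePoses = 20L, nInactivePoses = 20L, flipProb = 0.05,
       model = NULL)
}

#' The package's default four-feature query pharmacophore
#'
#' A hydrogen-bond acceptor, positive ionizable, aromatic ring and
#' hydrophobic feature in a fixed tetrahedron-like arrangement (5-8 A
#' spacing, 1.6 A tolerances) — the synthetic stand-in for a common-feature
#' model derived from potent antagonists.
#'
#' @param tolerance tolerance radius, Angstrom (default 1.6)
#' @return a \linkS4class{PharmacophoreModel}
#' @export
defaultQueryModel <- function(tolerance = 1.6) {
  newPharmacophoreModel(
    kinds = c("HBA", "POS_IONIZABLE", "AROMATIC", "HYDROPHOBIC"),
    centers = rbind(c(0, 0, 0), c(6.5, 0, 0), c(2.8, 5.2, 0),
                    c(3.5, 2.0, 4.6)),
    tolerance = tolerance)
}

#' Run the ligand-based screening pipeline
#'
#' Stages, in order: generate (or accept) reference actives; build a
#' common-feature model from the first references; generate property-matched
#' decoys; screen the combined library; compute ROC enrichment and the
#' full-recall cutoff; keep molecules at or above the cutoff as hits;
#' compute the hit-vs-active Tanimoto similarity matrix. A manifest with the
#' configuration, seeds and per-file MD5 digests is written alongside the
#' outputs.
#'
#' @param config list from \code{defaultConfig}
#' @param outDir output directory (created if needed)
#' @param actives optional list of \linkS4class{Molecule} to use instead of
#'   generated actives
#' @return list(model, enrichment, hits, similarity, manifest)
#' @export
runScreenPipeline <- function(config = defaultConfig(), outDir = tempfile(),
                              actives = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "prepare-actives"
  result <- tryCatch({
    model0 <- if (is.null(config$model)) defaultQueryModel(config$tolerance)
              else config$model
    if (is.null(actives))
      actives <- genActives(model0, config$nActives, config$noise,
                            seed = config$seed)
    if (!length(actives)) stop("no reference actives")
    writeMoleculesSDF(actives, file.path(outDir, "actives.sdf"))

    stage <- "build-model"
    refs <- actives[seq_len(min(config$nReferences, length(actives)))]
    models <- buildCommonFeatureModel(refs, kRange = config$kRange,
      tolerance = config$tolerance,
      minInterfeatureDistance = config$minInterfeatureDistance)
    if (!length(models)) stop("no common-feature model found")
    model <- models[[1]]
    writePharmacophoreModel(model, file.path(outDir, "model.json"))

    stage <- "decoys"
    stats <- referenceStats(actives)
    decoys <- genDecoys(model0, config$nDecoys, seed = config$seed,
                        stats = stats, kSd = config$kSd)

    stage <- "screen"
    library0 <- c(actives, decoys)
    hits <- screenLibrary(model, library0)
    utils::write.csv(hits, file.path(outDir, "fits.csv"), row.names = FALSE)

    stage <- "roc"
    activeIds <- vapply(actives, molId, character(1))
    allIds <- vapply(library0, molId, character(1))
    enr <- rocEnrichment(hits, activeIds, allIds)
    utils::write.csv(rocPoints(enr), file.path(outDir, "roc.csv"),
                     row.names = FALSE)

    stage <- "cutoff"
    cut <- fullRecallCutoff(enr)
    hitTab <- hits[hits$fit >= cut, , drop = FALSE]
    utils::write.csv(hitTab, file.path(outDir, "hits.csv"), row.names = FALSE)

    stage <- "similarity"
    hitMols <- library0[allIds %in% hitTab$id]
    sim <- similarityMatrix(hitMols, actives)
    utils::write.csv(as.data.frame(sim), file.path(outDir, "similarity.csv"))

    list(model = model, enrichment = enr, hits = hitTab, similarity = sim)
  }, error = function(e) {
    .writeManifest(config, outDir, stage = stage, failed = TRUE)
    stop("screen pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result$manifest <- .writeManifest(config, outDir, stage = "complete")
  result
}

#' Run the pose fingerprint / cluster / filter pipeline
#'
#' Stages: compute interaction fingerprints for every pose; hierarchically
#' cluster them on normalized Hamming distance (skipped with a warning for a
#' single pose); apply the structure-based filters, reporting the first
#' violated constraint per failing pose. Outputs: fingerprint CSV + JSON
#' index map, Newick dendrogram, filter report CSV, manifest.
#'
#' @param poses list of \linkS4class{ComplexStructure}
#' @param config list from \code{defaultConfig}
#' @param outDir output directory
#' @param siteResidues ordered residue ids for the fingerprint (default: the
#'   residues of the first pose)
#' @param rules pose filter rules (default \code{defaultPoseRules()})
#' @return list(fingerprints, tree, filterReport, manifest)
#' @export
runPosePipeline <- function(poses, config = defaultConfig(),
                            outDir = tempfile(),
                            siteResidues = NULL,
                            rules = defaultPoseRules()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "fingerprints"
  result <- tryCatch({
    if (!length(poses)) stop("no poses supplied")
    if (is.null(siteResidues)) siteResidues <- residueIds(poses[[1]])
    fps <- lapply(poses, interactionFingerprint, siteResidues = siteResidues)
    m <- do.call(rbind, lapply(fps, fingerprintBits))
    rownames(m) <- vapply(poses, poseId, character(1))
    colnames(m) <- paste(fps[[1]]@indexMap$residue,
                         fps[[1]]@indexMap$channel, sep = "|")
    utils::write.csv(m, file.path(outDir, "fingerprints.csv"))
    jsonlite::write_json(fps[[1]]@indexMap,
                         file.path(outDir, "index_map.json"))

    stage <- "cluster"
    tree <- NULL
    if (length(poses) >= 2L) {
      tree <- clusterPoses(fps, linkage = config$linkage)
      writeClusterNewick(tree, file.path(outDir, "dendrogram.nwk"))
    } else {
      warning("single pose: clustering skipped")
    }

    stage <- "filters"
    report <- applyPoseFilters(poses, rules)
    utils::write.csv(report, file.path(outDir, "filter_report.csv"),
                     row.names = FALSE)
    list(fingerprints = fps, tree = tree, filterReport = report)
  }, error = function(e) {
    .writeManifest(config, outDir, stage = stage, failed = TRUE)
    stop("pose pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result$manifest <- .writeManifest(config, outDir, stage = "complete")
  result
}

# manifest: config echo, seed, package version, per-file MD5s, timestamp
.writeManifest <- function(config, outDir, stage, failed = FALSE) {
  files <- setdiff(list.files(outDir), "manifest.json")
  digests <- if (length(files))
    as.list(tools::md5sum(file.path(outDir, files))) else list()
  names(digests) <- files
  manifest <- list(
    tool = "PhoreScreen",
    version = as.character(utils::packageVersion("PhoreScreen")),
    stage = stage, failed = failed,
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}
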
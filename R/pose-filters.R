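#' Default structure-based pose constraints
#'
#' The three-constraint rule set used to post-process docked poses:
#' \enumerate{
#'   \item a charged (electrostatic) interaction between the ligand and the
#'     acidic anchor residue (the Glu119 2.61 role),
#'   \item at least one hydrogen bond with either cationic anchor residue
#'     (the Arg144 3.32 / Arg307 6.58 roles),
#'   \item at least two pi interactions (pi-pi or pi-cation) with those
#'     cationic anchors.
#' }
#' Roles are mapped to concrete residue ids so the filter applies to any
#' receptor numbering.
#'
#' @param glu residue id filling the acidic-anchor role (e.g. "GLU:119")
#' @param args character vector of residue ids filling the cationic-anchor
#'   roles (e.g. c("ARG:144", "ARG:307"))
#' @return a rule list for \code{applyPoseFilters}
#' @export
defaultPoseRules <- function(glu = "GLU:119",
                             args = c("ARG:144", "ARG:307")) {
  list(chargedWith = glu, hbondWith = args, piWith = args, minPi = 2L)
}

#' Apply structure-based filters to docked poses
#'
#' Evaluates each pose's detected interactions against the rule set; a pose
#' passes when it satisfies all three constraints. Failures carry the first
#' violated constraint ("constraint 1" = missing charged interaction,
#' "constraint 2" = no hydrogen bond with an anchor, "constraint 3" = fewer
#' than the required pi interactions).
#'
#' @param poses list of \linkS4class{ComplexStructure}
#' @param rules rule list from \code{defaultPoseRules}
#' @return data.frame (pose, passed, reason)
#' @export
applyPoseFilters <- function(poses, rules = defaultPoseRules()) {
  needed <- unique(c(rules$chargedWith, rules$hbondWith, rules$piWith))
  for (cx in poses) {
    missing <- setdiff(needed, residueIds(cx))
    if (length(missing))
      stop("pose '", cx@poseId, "' lacks residue(s) referenced by the rules: ",
           paste(missing, collapse = ", "))
  }
  rows <- lapply(poses, function(cx) {
    inter <- detectInteractions(cx)
    reason <- NA_character_
    if (!any(inter$type == "CHARGED" & inter$residue %in% rules$chargedWith)) {
      reason <- "constraint 1: no charged interaction with the acidic anchor"
    } else if (!any(inter$type == "HBOND" &
                    inter$residue %in% rules$hbondWith)) {
      reason <- "constraint 2: no hydrogen bond with a cationic anchor"
    } else {
      nPi <- nrow(unique(inter[inter$type %in% c("PIPI", "PICATION") &
                               inter$residue %in% rules$piWith,
                               c("type", "residue", "detail")]))
      if (nPi < rules$minPi)
        reason <- sprintf("constraint 3: %d pi interaction(s) with the anchors (need >= %d)",
                          nPi, rules$minPi)
    }
    data.frame(pose = cx@poseId, passed = is.na(reason),
               reason = ifelse(is.na(reason), "", reason))
  })
  do.call(rbind, rows)
}
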
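#' @import methods
NULL

## ---------------------------------------------------------------------------
## Structure: an ordered atomic model (chains > residues > atoms)
## ---------------------------------------------------------------------------

#' Atomic structure container
#'
#' Holds an ordered atom table (file order preserved) for one molecule.
#' Residues are contiguous runs of atoms sharing a (chain, residue number,
#' insertion code) key; numbering is taken verbatim from the source file.
#'
#' @slot atoms data.frame with columns serial, name, element, chain, resno,
#'   icode, resname, x, y, z, isBackbone.
#' @slot label character scalar naming the molecule.
#' @export
setClass("Structure", representation(atoms = "data.frame", label = "character"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "chain", "resno", "icode",
            "resname", "x", "y", "z", "isBackbone")
  if (!all(need %in% names(a))) return("atom table is missing columns")
  if (nrow(a) < 1) return("a Structure must contain at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' Construct a Structure from an atom table
#' @param atoms Atom data.frame (see the Structure class).
#' @param label Molecule label.
#' @return A \code{Structure}.
#' @export
Structure <- function(atoms, label = "structure") {
  atoms$icode[is.na(atoms$icode)] <- ""
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, label = label)
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              object@label, nrow(a),
              length(unique(residueKeys(object))),
              paste(sort(unique(a$chain)), collapse = ",")))
})

## ---------------------------------------------------------------------------
## Pose: a rigid-body transform of the ligand relative to its centered frame
## ---------------------------------------------------------------------------

#' Rigid-body pose
#'
#' A translation (Angstrom) plus a unit quaternion (w, x, y, z). Rotation is
#' applied about the molecule's coordinate centroid, then the translation is
#' added, so translation and rotation are approximately decoupled for the
#' optimizer.
#'
#' @slot translation numeric length 3 (Angstrom).
#' @slot rotation numeric length 4, unit quaternion (w, x, y, z).
#' @export
setClass("Pose", representation(translation = "numeric", rotation = "numeric"))

setValidity("Pose", function(object) {
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  if (length(object@rotation) != 4)
    return("rotation must be a quaternion (w, x, y, z)")
  if (abs(sqrt(sum(object@rotation^2)) - 1) > 1e-9)
    return("rotation quaternion is not unit length (within 1e-9)")
  TRUE
})

#' Construct a Pose
#' @param translation 3-vector in Angstrom (default zero).
#' @param rotation Quaternion (w, x, y, z); normalized on construction.
#' @return A \code{Pose}. \code{Pose()} is the identity pose.
#' @export
Pose <- function(translation = c(0, 0, 0), rotation = c(1, 0, 0, 0)) {
  new("Pose", translation = as.numeric(translation),
      rotation = quatNormalize(as.numeric(rotation)))
}

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose: t = (%.3f, %.3f, %.3f) A, q = (%.4f, %.4f, %.4f, %.4f)\n",
              object@translation[1], object@translation[2],
              object@translation[3], object@rotation[1], object@rotation[2],
              object@rotation[3], object@rotation[4]))
})

## ---------------------------------------------------------------------------
## RestraintSet: active/passive interface residues on either partner
## ---------------------------------------------------------------------------

#' Residue restraint set
#'
#' Active restraints feed the scoring bias; passive restraints take part
#' only in the setup steps (swarm filtering and ligand pre-orientation).
#'
#' @slot restraints data.frame with columns side ("receptor"/"ligand"),
#'   chain, resno, icode, resname (may be NA), mode ("active"/"passive").
#' @slot cutoff Contact cutoff in Angstrom (default 3.9).
#' @export
setClass("RestraintSet",
         representation(restraints = "data.frame", cutoff = "numeric"))

setValidity("RestraintSet", function(object) {
  r <- object@restraints
  need <- c("side", "chain", "resno", "icode", "resname", "mode")
  if (!all(need %in% names(r))) return("restraint table is missing columns")
  if (nrow(r) > 0) {
    if (!all(r$side %in% c("receptor", "ligand"))) return("bad side token")
    if (!all(r$mode %in% c("active", "passive"))) return("bad mode token")
    key <- paste(r$side, r$chain, r$resno, r$icode)
    if (anyDuplicated(key)) return("duplicate restraints in set")
  }
  if (length(object@cutoff) != 1 || object@cutoff <= 0)
    return("cutoff must be a single positive value")
  TRUE
})

#' Construct a RestraintSet
#' @param restraints Restraint data.frame (may have zero rows).
#' @param cutoff Contact cutoff in Angstrom.
#' @return A \code{RestraintSet}.
#' @export
RestraintSet <- function(restraints = emptyRestraintFrame(), cutoff = 3.9) {
  restraints$icode[is.na(restraints$icode)] <- ""
  rownames(restraints) <- NULL
  new("RestraintSet", restraints = restraints, cutoff = cutoff)
}

emptyRestraintFrame <- function() {
  data.frame(side = character(), chain = character(), resno = integer(),
             icode = character(), resname = character(), mode = character(),
             stringsAsFactors = FALSE)
}

setMethod("show", "RestraintSet", function(object) {
  r <- object@restraints
  cat(sprintf(
    "RestraintSet: %d receptor (%d active) / %d ligand (%d active), cutoff %.1f A\n",
    sum(r$side == "receptor"),
    sum(r$side == "receptor" & r$mode == "active"),
    sum(r$side == "ligand"),
    sum(r$side == "ligand" & r$mode == "active"), object@cutoff))
})

## ---------------------------------------------------------------------------
## Swarm: a sampling locus on the receptor surface plus its agents
## ---------------------------------------------------------------------------

#' Swarm of glowworm agents
#'
#' One sampling locus outside the receptor surface. Glowworms are stored as
#' a data.frame: one row per agent with its pose (tx, ty, tz, qw, qx, qy,
#' qz), luciferin, vision range, fitness and move count.
#'
#' @slot id integer swarm identifier (unique within a run).
#' @slot center numeric length-3 swarm center (Angstrom).
#' @slot glowworms data.frame of agents (possibly empty before init).
#' @export
setClass("Swarm", representation(id = "integer", center = "numeric",
                                 glowworms = "data.frame"))

setValidity("Swarm", function(object) {
  if (length(object@center) != 3 || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  g <- object@glowworms
  if (nrow(g) > 0) {
    need <- c("id", "tx", "ty", "tz", "qw", "qx", "qy", "qz",
              "luciferin", "vision", "fitness", "moves")
    if (!all(need %in% names(g))) return("glowworm table is missing columns")
    if (any(g$luciferin < 0)) return("luciferin must be non-negative")
  }
  TRUE
})

#' Construct a Swarm
#' @param id Integer swarm id.
#' @param center 3-vector center in Angstrom.
#' @param glowworms Glowworm data.frame (default empty).
#' @return A \code{Swarm}.
#' @export
Swarm <- function(id, center, glowworms = emptyGlowwormFrame()) {
  new("Swarm", id = as.integer(id), center = as.numeric(center),
      glowworms = glowworms)
}

emptyGlowwormFrame <- function() {
  data.frame(id = integer(), tx = numeric(), ty = numeric(), tz = numeric(),
             qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric(),
             luciferin = numeric(), vision = numeric(), fitness = numeric(),
             moves = integer(), stringsAsFactors = FALSE)
}

setMethod("show", "Swarm", function(object) {
  cat(sprintf("Swarm %d at (%.2f, %.2f, %.2f), %d glowworms\n",
              object@id, object@center[1], object@center[2],
              object@center[3], nrow(object@glowworms)))
})

## ---------------------------------------------------------------------------
## GSOParams
## ---------------------------------------------------------------------------

#' Glowworm swarm optimization parameters
#'
#' Defaults follow the standard GSO literature values; translation and
#' rotation step sizes are in Angstrom and slerp fraction respectively.
#'
#' @slot rho luciferin decay in (0,1).
#' @slot gamma luciferin gain (> 0).
#' @slot l0 initial luciferin (>= 0).
#' @slot nt neighbor target count.
#' @slot beta vision-range gain.
#' @slot rs maximum vision range (pose-space units).
#' @slot r0 initial vision range (<= rs).
#' @slot tStep translation step size, Angstrom.
#' @slot rotStep rotation step, slerp fraction in (0,1].
#' @slot steps number of optimization steps (>= 1 for a run).
#' @slot wRot weight (Angstrom per radian) of the orientation term in the
#'   pose-space distance.
#' @export
setClass("GSOParams", representation(
  rho = "numeric", gamma = "numeric", l0 = "numeric", nt = "numeric",
  beta = "numeric", rs = "numeric", r0 = "numeric", tStep = "numeric",
  rotStep = "numeric", steps = "integer", wRot = "numeric"))

setValidity("GSOParams", function(object) {
  if (object@rho <= 0 || object@rho >= 1) return("rho must lie in (0,1)")
  if (object@gamma <= 0) return("gamma must be positive")
  if (object@l0 < 0) return("l0 must be non-negative")
  if (object@rs <= 0) return("rs must be positive")
  if (object@r0 <= 0 || object@r0 > object@rs) return("need 0 < r0 <= rs")
  if (object@tStep <= 0) return("translation step must be positive")
  if (object@rotStep <= 0 || object@rotStep > 1)
    return("rotation step must lie in (0,1]")
  if (object@steps < 0) return("steps must be non-negative")
  TRUE
})

#' Construct GSO parameters
#' @param rho Luciferin decay (default 0.4).
#' @param gamma Luciferin gain (default 0.6).
#' @param l0 Initial luciferin (default 5).
#' @param nt Neighbor target count (default 5).
#' @param beta Vision-range gain (default 0.08).
#' @param rs Maximum vision range; default 4x the translation jitter radius
#'   used at initialization (8 for the default 2 A jitter).
#' @param r0 Initial vision range (default rs).
#' @param tStep Translation step in Angstrom (default 0.5).
#' @param rotStep Rotation slerp fraction (default 0.1).
#' @param steps Optimization steps (default 100).
#' @param wRot Angstrom-per-radian weight of the orientation distance
#'   (default 3, so orientation differences cannot exceed the default
#'   vision range on their own).
#' @return A \code{GSOParams}.
#' @export
GSOParams <- function(rho = 0.4, gamma = 0.6, l0 = 5, nt = 5, beta = 0.08,
                      rs = 8, r0 = rs, tStep = 0.5, rotStep = 0.1,
                      steps = 100, wRot = 3) {
  new("GSOParams", rho = rho, gamma = gamma, l0 = l0, nt = nt, beta = beta,
      rs = rs, r0 = r0, tStep = tStep, rotStep = rotStep,
      steps = as.integer(steps), wRot = wRot)
}

setMethod("show", "GSOParams", function(object) {
  cat(sprintf(paste0(
    "GSOParams: rho=%.2f gamma=%.2f l0=%.1f nt=%d beta=%.2f ",
    "r0=%.1f rs=%.1f tStep=%.2f A rotStep=%.2f steps=%d\n"),
    object@rho, object@gamma, object@l0, as.integer(object@nt), object@beta,
    object@r0, object@rs, object@tStep, object@rotStep, object@steps))
})

## ---------------------------------------------------------------------------
## ScoringTable
## ---------------------------------------------------------------------------

#' Distance-binned atom-pair scoring table
#'
#' Pair energies indexed by (type i, type j, distance bin); the last bin
#' edge is the interaction cutoff and pairs beyond it contribute zero.
#' The energy array is symmetric in (i, j).
#'
#' @slot types named integer vector mapping "RESNAME ATOMNAME" to a type
#'   index.
#' @slot binEdges strictly increasing upper bin edges in Angstrom; bin k
#'   covers [edge[k-1], edge[k]) with an implicit lower edge of 0.
#' @slot energies numeric array [ntype, ntype, nbins].
#' @slot name table name.
#' @export
setClass("ScoringTable", representation(
  types = "integer", binEdges = "numeric", energies = "array",
  name = "character"))

setValidity("ScoringTable", function(object) {
  nt <- length(object@types)
  if (nt < 1) return("empty atom-type alphabet")
  if (is.null(names(object@types))) return("types must be named")
  if (any(diff(object@binEdges) <= 0) || any(object@binEdges <= 0))
    return("bin edges must be positive and strictly increasing")
  d <- dim(object@energies)
  if (length(d) != 3 || d[1] != nt || d[2] != nt ||
      d[3] != length(object@binEdges))
    return("energy array dimensions do not match types/bins")
  for (k in seq_len(d[3]))
    if (max(abs(object@energies[, , k] - t(object@energies[, , k]))) > 1e-9)
      return("energy table is not symmetric in (i, j)")
  TRUE
})

#' Interaction cutoff of a scoring table
#' @param table A \code{ScoringTable}.
#' @return Last bin edge, in Angstrom.
#' @export
tableCutoff <- function(table) {
  stopifnot(is(table, "ScoringTable"))
  object <- table
  object@binEdges[length(object@binEdges)]
}

setMethod("show", "ScoringTable", function(object) {
  cat(sprintf("ScoringTable '%s': %d atom types, %d bins, cutoff %.2f A\n",
              object@name, length(object@types), length(object@binEdges),
              tableCutoff(object)))
})

## ---------------------------------------------------------------------------
## SwarmResult
## ---------------------------------------------------------------------------

#' Result of optimizing one swarm
#'
#' @slot id swarm id.
#' @slot glowworms final glowworm table with rawScore, satFrac and fitness.
#' @slot bestId id of the best (highest-fitness) final glowworm.
#' @slot trajectory best-so-far fitness per step (non-decreasing).
#' @export
setClass("SwarmResult", representation(
  id = "integer", glowworms = "data.frame", bestId = "integer",
  trajectory = "numeric"))

setValidity("SwarmResult", function(object) {
  g <- object@glowworms
  if (nrow(g) < 1) return("no glowworms in result")
  if (!object@bestId %in% g$id) return("bestId not among glowworms")
  best <- g$fitness[match(object@bestId, g$id)]
  if (best < max(g$fitness) - 1e-12)
    return("bestId does not have the maximum fitness")
  TRUE
})

setMethod("show", "SwarmResult", function(object) {
  cat(sprintf("SwarmResult %d: %d glowworms, best fitness %.4f\n",
              object@id, nrow(object@glowworms),
              max(object@glowworms$fitness)))
})
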
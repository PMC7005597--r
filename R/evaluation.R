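# CAPRI-style model quality: fnat, ligand and interface RMSD, quality
# classes, global ranking, Top-N success rates and the a-posteriori
# restraint-filter baseline.

#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' ||mobile %*% R + t - target|| over corresponding rows.
#'
#' @param mobile,target n x 3 coordinate matrices, rows corresponding.
#' @return List with \code{R} (3 x 3, det = +1), \code{t} (length 3) and
#'   \code{transform(xyz)} applying them to any m x 3 matrix.
#' @export
superpose <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  H <- crossprod(sweep(mobile, 2, cm), sweep(target, 2, ct))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- ct - as.vector(cm %*% R)
  list(R = R, t = t,
       transform = function(xyz) sweep(xyz %*% R, 2, t, "+"))
}

rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Fraction of native contacts reproduced by a model
#'
#' Native contacts are the (receptor residue, ligand residue) pairs with
#' any-atom distance below \code{cutoff} in the native complex; fnat is
#' the fraction of those pairs also in contact in the model.
#'
#' @param receptor,ligand Native \code{Structure} objects (bound frame).
#' @param modelLigandCoords Model ligand coordinates (same atom order).
#' @param cutoff Contact cutoff in Angstrom (default 5, the CAPRI
#'   convention).
#' @return fnat in [0, 1].
#' @export
computeFnat <- function(receptor, ligand, modelLigandCoords, cutoff = 5.0) {
  nat <- contactResiduePairs(receptor, ligand, cutoff)
  if (nrow(nat) == 0) stop("degenerate native complex: zero native contacts")
  mod <- contactResiduePairs(receptor, ligand, cutoff,
                             ligCoords = modelLigandCoords)
  natKey <- paste(nat$recKey, nat$ligKey)
  modKey <- paste(mod$recKey, mod$ligKey)
  mean(natKey %in% modKey)
}

#' Ligand RMSD of a model
#'
#' The model receptor is superposed onto the native receptor over backbone
#' atoms (N, CA, C, O); the transform is applied to the model ligand and
#' the RMSD over ligand backbone atoms against the native ligand is
#' returned.
#'
#' @param receptor,ligand Native \code{Structure} objects (bound frame).
#' @param modelLigandCoords Model ligand coordinates.
#' @param modelReceptorCoords Model receptor coordinates (defaults to the
#'   native receptor coordinates, the rigid-body docking case).
#' @return l-RMSD in Angstrom.
#' @export
computeLrmsd <- function(receptor, ligand, modelLigandCoords,
                         modelReceptorCoords = structCoords(receptor)) {
  bbR <- receptor@atoms$isBackbone
  bbL <- ligand@atoms$isBackbone
  fit <- superpose(modelReceptorCoords[bbR, , drop = FALSE],
                   structCoords(receptor)[bbR, , drop = FALSE])
  rmsd(fit$transform(modelLigandCoords[bbL, , drop = FALSE]),
       structCoords(ligand)[bbL, , drop = FALSE])
}

#' Interface RMSD of a model
#'
#' Native interface residues are those with any-atom inter-molecular
#' distance below \code{interfaceCutoff}. The model's backbone atoms of
#' those residues (both molecules jointly) are superposed onto the native
#' ones and the RMSD over the same atoms is returned.
#'
#' @param receptor,ligand Native \code{Structure} objects (bound frame).
#' @param modelLigandCoords Model ligand coordinates.
#' @param modelReceptorCoords Model receptor coordinates (defaults to
#'   native).
#' @param interfaceCutoff Interface definition cutoff (default 10 Angstrom,
#'   the CAPRI convention).
#' @return i-RMSD in Angstrom.
#' @export
computeIrmsd <- function(receptor, ligand, modelLigandCoords,
                         modelReceptorCoords = structCoords(receptor),
                         interfaceCutoff = 10.0) {
  pr <- contactResiduePairs(receptor, ligand, interfaceCutoff)
  if (nrow(pr) == 0) stop("degenerate native complex: empty interface")
  selR <- residueKeys(receptor) %in% unique(pr$recKey) &
    receptor@atoms$isBackbone
  selL <- residueKeys(ligand) %in% unique(pr$ligKey) &
    ligand@atoms$isBackbone
  natIf <- rbind(structCoords(receptor)[selR, , drop = FALSE],
                 structCoords(ligand)[selL, , drop = FALSE])
  modIf <- rbind(modelReceptorCoords[selR, , drop = FALSE],
                 modelLigandCoords[selL, , drop = FALSE])
  fit <- superpose(modIf, natIf)
  rmsd(fit$transform(modIf), natIf)
}

#' CAPRI quality class of a model
#'
#' high: fnat >= 0.5 and (l-RMSD <= 1 or i-RMSD <= 1);
#' medium: fnat >= 0.3 and (l-RMSD <= 5 or i-RMSD <= 2);
#' acceptable: fnat >= 0.1 and (l-RMSD <= 10 or i-RMSD <= 4);
#' otherwise incorrect.
#'
#' @param fnat Fraction of native contacts.
#' @param irmsd Interface RMSD, Angstrom.
#' @param lrmsd Ligand RMSD, Angstrom.
#' @return One of "high", "medium", "acceptable", "incorrect".
#' @export
classifyCapri <- function(fnat, irmsd, lrmsd) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0, lrmsd >= 0)
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' All quality metrics of one model
#'
#' @inheritParams computeIrmsd
#' @param fnatCutoff Contact cutoff for fnat (default 5 Angstrom).
#' @return List with fnat, irmsd, lrmsd and capri class.
#' @export
qualityMetrics <- function(receptor, ligand, modelLigandCoords,
                           modelReceptorCoords = structCoords(receptor),
                           fnatCutoff = 5.0, interfaceCutoff = 10.0) {
  fn <- computeFnat(receptor, ligand, modelLigandCoords, fnatCutoff)
  ir <- computeIrmsd(receptor, ligand, modelLigandCoords,
                     modelReceptorCoords, interfaceCutoff)
  lr <- computeLrmsd(receptor, ligand, modelLigandCoords,
                     modelReceptorCoords)
  list(fnat = fn, irmsd = ir, lrmsd = lr,
       class = classifyCapri(fn, ir, lr))
}

#' Merge and rank models across swarms
#'
#' Takes the best \code{topKPerSwarm} glowworms of every swarm (default:
#' all of them, a global pool), merges and sorts by descending biased
#' fitness with deterministic (swarm id, glowworm id) tie-breaking.
#'
#' @param swarmResults List of \code{SwarmResult} objects.
#' @param topKPerSwarm Glowworms kept per swarm before merging (default
#'   Inf = all).
#' @return data.frame with columns rank, swarm, glowworm, tx..qz,
#'   rawScore, satFrac, fitness.
#' @export
rankModels <- function(swarmResults, topKPerSwarm = Inf) {
  stopifnot(length(swarmResults) >= 1)
  pools <- lapply(swarmResults, function(sr) {
    g <- sr@glowworms
    g <- g[order(-g$fitness, g$id), , drop = FALSE]
    g <- utils::head(g, topKPerSwarm)
    cbind(swarm = sr@id, g)
  })
  all <- do.call(rbind, pools)
  all <- all[order(-all$fitness, all$swarm, all$id), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(all)), swarm = all$swarm,
                    glowworm = all$id, all[, c("tx", "ty", "tz", "qw", "qx",
                                               "qy", "qz")],
                    rawScore = if ("rawScore" %in% names(all)) all$rawScore
                               else NA_real_,
                    satFrac = if ("satFrac" %in% names(all)) all$satFrac
                              else NA_real_,
                    fitness = all$fitness, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-N success rates over a set of cases
#'
#' A case succeeds at N when at least one of its N best-ranked models has
#' a CAPRI class other than incorrect (cases with fewer than N models use
#' all of them). Percentages are reported to one decimal.
#'
#' @param caseClasses List (one element per case) of character vectors of
#'   CAPRI classes in rank order.
#' @param N Integer vector of Top-N levels (default
#'   \code{c(1, 5, 10, 20, 50, 100)}).
#' @return data.frame with columns N and successRate (percent, 1 decimal).
#' @export
successRate <- function(caseClasses, N = c(1, 5, 10, 20, 50, 100)) {
  stopifnot(length(caseClasses) >= 1)
  rates <- vapply(N, function(n) {
    hit <- vapply(caseClasses, function(cl) {
      any(utils::head(cl, n) != "incorrect")
    }, logical(1))
    round(100 * mean(hit), 1)
  }, numeric(1))
  data.frame(N = N, successRate = rates)
}

#' A-posteriori restraint filter over ranked models
#'
#' Keeps the models whose satisfied fraction of active restraints is at
#' least \code{threshold}, preserving the ranking order — the post-docking
#' baseline that a-priori restraint use is compared against.
#'
#' @param models Ranked model data.frame (\code{\link{rankModels}} output)
#'   with a satFrac column, or one to be recomputed via \code{context}.
#' @param restraints A \code{RestraintSet}.
#' @param threshold Minimum satisfied fraction (default 0.3).
#' @param receptor,ligand Structures, required when satFrac must be
#'   recomputed from the model poses.
#' @return The filtered model data.frame (relative order preserved).
#' @export
postFilter <- function(models, restraints, threshold = 0.3,
                       receptor = NULL, ligand = NULL) {
  if (!is.null(receptor) && !is.null(ligand)) {
    # recompute at the set's contact cutoff: run outputs carry the
    # longer-reach in-simulation fraction
    grp <- satisfactionGroups(restraints, receptor, ligand)
    s <- cpp_satisfied_poses(structCoords(receptor), structCoords(ligand),
                             as.matrix(models[, c("qw", "qx", "qy", "qz")]),
                             as.matrix(models[, c("tx", "ty", "tz")]),
                             grp$groups, grp$sides, restraints@cutoff)
  } else {
    s <- models$satFrac
    if (is.null(s) || all(is.na(s)))
      stop("satFrac absent; supply receptor and ligand to recompute")
  }
  models[s >= threshold, , drop = FALSE]
}
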
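# Glowworm swarm optimization over rigid-body pose space, with the
# restraint-satisfaction bias folded into every fitness evaluation.

#' Luciferin update rule
#'
#' \code{(1 - rho) * current + gamma * fitness}, floored at 0 (luciferin
#' is never negative). With constant fitness J the level converges to
#' gamma * J / rho.
#'
#' @param current Current luciferin level(s).
#' @param fitness Fitness value(s) J of the agent's position.
#' @param params A \code{GSOParams}.
#' @return Updated luciferin, same length as the inputs.
#' @export
luciferinUpdate <- function(current, fitness, params) {
  stopifnot(all(is.finite(current)), all(is.finite(fitness)))
  pmax(0, (1 - params@rho) * current + params@gamma * fitness)
}

#' Adaptive vision-range update
#'
#' \code{min(rs, max(0, current + beta * (nt - neighborCount)))}: crowded
#' agents shrink their range, lonely ones grow it up to \code{rs}.
#'
#' @param current Current vision range(s).
#' @param neighborCount Number of neighbors seen this step.
#' @param params A \code{GSOParams}.
#' @return Updated range(s) in [0, rs].
#' @export
updateVisionRange <- function(current, neighborCount, params) {
  pmin(params@rs, pmax(0, current + params@beta * (params@nt - neighborCount)))
}

# pose-space distance matrix: Euclidean on translations plus
# wRot * quaternion geodesic angle (a hybrid SE(3) metric)
poseDistanceMatrix <- function(g, wRot) {
  t <- as.matrix(g[, c("tx", "ty", "tz")])
  q <- as.matrix(g[, c("qw", "qx", "qy", "qz")])
  q <- q / sqrt(rowSums(q^2))
  dt <- as.matrix(stats::dist(t))
  dq <- 2 * acos(pmin(1, abs(tcrossprod(q))))
  dt + wRot * dq
}

#' Select the neighbor a glowworm moves toward
#'
#' Neighbors are agents within the glowworm's vision range carrying
#' strictly greater luciferin; one is drawn with probability proportional
#' to the luciferin difference. Returns NA when the neighbor set is empty.
#'
#' @param i Index of the moving glowworm.
#' @param luciferin Luciferin vector of the swarm.
#' @param distances Pose-space distance matrix (see Details in
#'   \code{\link{runSwarm}}).
#' @param vision Vision range of glowworm i.
#' @return Integer index of the selected neighbor, or NA.
#' @export
selectNeighbor <- function(i, luciferin, distances, vision) {
  nb <- which(distances[i, ] <= vision & luciferin > luciferin[i])
  nb <- nb[nb != i]
  if (length(nb) == 0) return(NA_integer_)
  w <- luciferin[nb] - luciferin[i]
  if (length(nb) == 1) return(nb)
  nb[sample.int(length(nb), 1, prob = w)]
}

#' Move a glowworm toward a target pose
#'
#' The translation advances by the translation step along the unit vector
#' toward the target (or the full gap if smaller); the orientation advances
#' by spherical interpolation toward the target quaternion by the rotation
#' step fraction.
#'
#' @param pose Current \code{Pose}.
#' @param target Target \code{Pose}.
#' @param params A \code{GSOParams}.
#' @return The moved \code{Pose} (unchanged for coincident poses).
#' @export
moveGlowworm <- function(pose, target, params) {
  gap <- target@translation - pose@translation
  gn <- sqrt(sum(gap^2))
  newT <- if (gn < 1e-12) pose@translation
          else pose@translation + gap / gn * min(params@tStep, gn)
  newQ <- quatSlerp(pose@rotation, target@rotation, params@rotStep)
  Pose(translation = newT, rotation = newQ)
}

#' Run glowworm swarm optimization within one swarm
#'
#' Per step, every glowworm's fitness is evaluated on its current pose as
#' \code{biasScore(toFitness(raw energy), satisfied fraction)}; luciferin
#' is updated; each agent picks a brighter neighbor within its vision range
#' (pose-space metric: translation distance + wRot x quaternion geodesic
#' angle) and steps toward it; vision ranges adapt. All moves within a step
#' use the positions at the start of the step. Deterministic given
#' \code{seed}.
#'
#' @param receptor,ligand \code{Structure} objects.
#' @param swarm An initialized \code{Swarm}.
#' @param scoring A \code{\link{scoringContext}}, or a function
#'   \code{f(translations, quaternions) -> fitness vector} for analytic
#'   objectives (then no bias or satisfaction is applied).
#' @param restraints A \code{RestraintSet}; only active restraints bias
#'   the score. An empty set disables the bias (satisfaction 1).
#' @param params A \code{GSOParams}.
#' @param seed Integer seed for this swarm's RNG stream (NULL: use the
#'   current stream).
#' @param biasCutoff Distance (Angstrom) at which a restraint counts as
#'   satisfied for the in-simulation bias (default 10): longer than the
#'   contact cutoff so the bias has reach from clash-free starting poses.
#' @return A \code{SwarmResult}.
#' @export
runSwarm <- function(receptor, ligand, swarm, scoring,
                     restraints = RestraintSet(), params = GSOParams(),
                     seed = NULL, biasCutoff = 10) {
  g <- swarm@glowworms
  if (nrow(g) == 0) stop("swarm has no glowworms; run initGlowworms first")
  run <- function() {
    analytic <- is.function(scoring)
    grp <- if (analytic) NULL else
      satisfactionGroups(restraints, receptor, ligand)
    ligXYZ <- if (analytic) NULL else structCoords(ligand)
    n <- nrow(g)
    tm <- as.matrix(g[, c("tx", "ty", "tz")])
    qm <- as.matrix(g[, c("qw", "qx", "qy", "qz")])
    luc <- g$luciferin
    vis <- g$vision
    moves <- g$moves
    evalFitness <- function(tm, qm) {
      if (analytic) {
        list(raw = rep(NA_real_, n), sat = rep(NA_real_, n),
             fit = scoring(tm, qm))
      } else {
        raw <- cpp_score_poses(scoring$recCoords, scoring$recTypes,
                               ligXYZ, scoring$ligTypes, qm, tm,
                               as.numeric(scoring$table@energies),
                               length(scoring$table@types),
                               scoring$table@binEdges)
        sat <- cpp_satisfied_poses(scoring$recCoords, ligXYZ, qm, tm,
                                   grp$groups, grp$sides, biasCutoff)
        bad <- !is.finite(raw)
        if (any(bad)) {
          warning(sum(bad), " pose(s) failed scoring; fitness set to -Inf")
          raw[bad] <- NA_real_
        }
        fit <- biasScore(toFitness(ifelse(bad, 0, raw)), sat)
        fit[bad] <- -Inf
        list(raw = raw, sat = sat, fit = fit)
      }
    }
    ev <- evalFitness(tm, qm)
    fit <- ev$fit
    traj <- numeric(0)
    best <- max(fit)
    if (params@steps > 0) {
      for (step in seq_len(params@steps)) {
        # luciferin sees the per-step min-shifted fitness: with the zero
        # floor, an all-negative landscape would otherwise darken every
        # agent uniformly and freeze the swarm; shifting preserves the
        # ordering that drives neighbor selection
        fin <- is.finite(fit)
        J <- ifelse(fin, fit, 0)
        if (any(fin)) J[fin] <- J[fin] - min(J[fin])
        luc <- luciferinUpdate(luc, J, params)
        dt <- as.matrix(stats::dist(tm))
        dq <- 2 * acos(pmin(1, abs(tcrossprod(qm))))
        D <- dt + params@wRot * dq
        targets <- rep(NA_integer_, n)
        counts <- integer(n)
        for (i in seq_len(n)) {
          # self never qualifies: its luciferin is not strictly greater
          counts[i] <- sum(D[i, ] <= vis[i] & luc > luc[i])
          if (is.finite(fit[i]))
            targets[i] <- selectNeighbor(i, luc, D, vis[i])
        }
        mv <- which(!is.na(targets))
        if (length(mv)) {
          tg <- targets[mv]
          # translation: step along the unit vector, capped at the gap
          gap <- tm[tg, , drop = FALSE] - tm[mv, , drop = FALSE]
          gn <- sqrt(rowSums(gap^2))
          adv <- ifelse(gn < 1e-12, 0, pmin(params@tStep, gn) /
                          pmax(gn, 1e-12))
          tm[mv, ] <- tm[mv, , drop = FALSE] + gap * adv
          # orientation: vectorized slerp by the rotation step fraction
          qa <- qm[mv, , drop = FALSE]
          qb <- qm[tg, , drop = FALSE]
          dot <- rowSums(qa * qb)
          qb[dot < 0, ] <- -qb[dot < 0, , drop = FALSE]  # shortest arc
          dot <- abs(dot)
          theta <- acos(pmin(1, dot))
          tfrac <- params@rotStep
          wa <- ifelse(dot > 1 - 1e-12, 1 - tfrac,
                       sin((1 - tfrac) * theta) / pmax(sin(theta), 1e-300))
          wb <- ifelse(dot > 1 - 1e-12, tfrac,
                       sin(tfrac * theta) / pmax(sin(theta), 1e-300))
          qn <- qa * wa + qb * wb
          qm[mv, ] <- qn / sqrt(rowSums(qn^2))
          moves[mv] <- moves[mv] + 1L
        }
        vis <- updateVisionRange(vis, counts, params)
        ev <- evalFitness(tm, qm)
        fit <- ev$fit
        best <- max(best, fit)
        traj <- c(traj, best)
      }
    }
    g[, c("tx", "ty", "tz")] <- tm
    g[, c("qw", "qx", "qy", "qz")] <- qm
    g$luciferin <- luc
    g$vision <- vis
    g$fitness <- fit
    g$moves <- moves
    g$rawScore <- ev$raw
    g$satFrac <- ev$sat
    ord <- order(-fit, g$id)
    new("SwarmResult", id = swarm@id, glowworms = g,
        bestId = as.integer(g$id[ord[1]]),
        trajectory = if (length(traj)) traj else best)
  }
  if (is.null(seed)) run() else withRNG(seed, run())
}

#' Deterministic per-swarm sub-seed
#'
#' Fans one global seed out to independent per-swarm streams so results do
#' not depend on swarm execution order.
#'
#' @param seed Global integer seed.
#' @param swarmId Swarm id.
#' @return Integer sub-seed below 2^31.
#' @export
swarmSeed <- function(seed, swarmId) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(swarmId) * 40503) %%
               2147483647)
}
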
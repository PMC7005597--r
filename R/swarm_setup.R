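# Swarm-center generation over the receptor surface, restraint-based swarm
# filtering (setup step S1) and glowworm initialization with ligand
# pre-orientation (setup step S2).

# deterministic quasi-uniform directions on the unit sphere
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate candidate swarm centers over the receptor surface
#'
#' Directions are sampled quasi-uniformly (Fibonacci sphere with a random
#' spin), each point is iteratively projected to \code{surfaceDistance}
#' from its nearest receptor heavy atom, and points closer than
#' \code{minSpacing} to an already accepted point are pruned.
#'
#' @param receptor A \code{Structure}.
#' @param numSwarms Requested number of centers (default 400).
#' @param surfaceDistance Distance from the nearest receptor atom, Angstrom.
#'   A value larger than the ligand's bounding radius keeps initial poses
#'   clash-free.
#' @param minSpacing Minimum inter-center spacing; default derived from the
#'   receptor's surface area and the requested count.
#' @return Matrix (m x 3) of centers, m <= numSwarms (a warning is given
#'   when fewer can be placed at the spacing). Every center's
#'   nearest-receptor-atom distance is surfaceDistance within 0.5 Angstrom.
#' @export
generateSwarmCenters <- function(receptor, numSwarms = 400, surfaceDistance,
                                 minSpacing = NULL) {
  stopifnot(numSwarms >= 1, surfaceDistance > 0)
  a <- receptor@atoms
  xyz <- structCoords(receptor)[a$element != "H", , drop = FALSE]
  ctr <- colMeans(xyz)
  rad <- sqrt(max(colSums((t(xyz) - ctr)^2))) + surfaceDistance
  if (is.null(minSpacing))
    minSpacing <- 0.7 * sqrt(4 * pi * rad^2 / numSwarms)
  # oversample directions, then prune to spacing
  dirs <- fibonacciSphere(max(4 * numSwarms, 64))
  spin <- quatToMatrix(randomQuaternion())
  dirs <- dirs %*% t(spin)
  pts <- sweep(dirs * rad, 2, ctr, "+")
  for (iter in 1:8) {
    for (i in seq_len(nrow(pts))) {
      d2 <- colSums((t(xyz) - pts[i, ])^2)
      j <- which.min(d2)
      v <- pts[i, ] - xyz[j, ]
      pts[i, ] <- xyz[j, ] + v / sqrt(sum(v^2)) * surfaceDistance
    }
    nd <- apply(pts, 1, function(p) sqrt(min(colSums((t(xyz) - p)^2))))
    if (all(abs(nd - surfaceDistance) <= 0.25)) break
  }
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (length(keep) >= numSwarms) break
    if (length(keep) == 0 ||
        min(colSums((t(pts[keep, , drop = FALSE]) - pts[i, ])^2)) >= minSpacing^2)
      keep <- c(keep, i)
  }
  if (length(keep) < numSwarms)
    warning(sprintf("placed %d of %d swarm centers at spacing %.2f A",
                    length(keep), numSwarms, minSpacing))
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- c("x", "y", "z")
  out
}

#' Filter swarm centers by receptor restraints (setup step S1)
#'
#' For every receptor restraint (active or passive alike), the
#' \code{swarmsPerRestraint} centers closest to the restraint residue's
#' representative atom are retained; the result is the de-duplicated union
#' in original center order. With no receptor restraints the input is
#' returned unchanged.
#'
#' @param centers Matrix (m x 3) of candidate centers.
#' @param receptor A \code{Structure}.
#' @param restraints A \code{RestraintSet}.
#' @param swarmsPerRestraint Centers kept per restraint (default 10).
#' @return List with \code{centers} (the retained rows), \code{ids}
#'   (1-based row indices into the input, preserved as swarm ids) and
#'   \code{restraint} (the restraint key generating each retained center,
#'   or NA).
#' @export
filterSwarmsByRestraints <- function(centers, receptor, restraints,
                                     swarmsPerRestraint = 10) {
  keys <- restraintResidueKeys(restraints, "receptor")
  if (length(keys) == 0) {
    return(list(centers = centers, ids = seq_len(nrow(centers)),
                restraint = rep(NA_character_, nrow(centers))))
  }
  restraintAtomGroups(receptor, keys)  # validates existence
  rep <- representativeAtoms(receptor)
  sel <- integer(0)
  gen <- character(0)
  for (k in keys) {
    d2 <- colSums((t(centers) - rep[k, ])^2)
    near <- order(d2)[seq_len(min(swarmsPerRestraint, nrow(centers)))]
    new <- setdiff(near, sel)
    sel <- c(sel, new)
    gen <- c(gen, rep(k, length(new)))
  }
  ord <- order(sel)
  list(centers = centers[sel[ord], , drop = FALSE], ids = sel[ord],
       restraint = gen[ord])
}

#' Initialize the glowworm agents of one swarm (setup step S2)
#'
#' Each glowworm's translation places the ligand centroid at the swarm
#' center plus a uniform jitter inside a ball of radius
#' \code{jitterRadius}; orientations are uniform over rotation space
#' unless ligand restraints are present, in which case each pose is
#' pre-oriented with \code{\link{preorientLigand}}. Luciferin starts at
#' \code{params@l0} and the vision range at \code{params@r0}.
#'
#' @param swarm A \code{Swarm} (its glowworm table is replaced).
#' @param receptor,ligand \code{Structure} objects.
#' @param n Number of glowworms (default 200).
#' @param restraints A \code{RestraintSet} (may be empty).
#' @param params A \code{GSOParams}.
#' @param jitterRadius Translation jitter radius in Angstrom (default 2).
#' @return The \code{Swarm} with an initialized glowworm table.
#' @export
initGlowworms <- function(swarm, receptor, ligand, n = 200,
                          restraints = RestraintSet(), params = GSOParams(),
                          jitterRadius = 2) {
  stopifnot(n >= 1)
  ctr <- structCentroid(ligand)
  base <- swarm@center - ctr
  # uniform in a ball: direction uniform, radius ~ cube root
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- jitterRadius * stats::runif(n)^(1 / 3)
  trans <- sweep(dirs * rad, 2, base, "+")
  quats <- randomQuaternion(n)
  if (n == 1) quats <- matrix(quats, nrow = 1)
  hasLig <- length(restraintResidueKeys(restraints, "ligand")) > 0
  if (hasLig) {
    for (i in seq_len(n)) {
      p <- preorientLigand(Pose(trans[i, ], quats[i, ]), swarm@center,
                           receptor, ligand, restraints)
      trans[i, ] <- p@translation
      quats[i, ] <- p@rotation
    }
  }
  swarm@glowworms <- data.frame(
    id = seq_len(n), tx = trans[, 1], ty = trans[, 2], tz = trans[, 3],
    qw = quats[, 1], qx = quats[, 2], qy = quats[, 3], qz = quats[, 4],
    luciferin = params@l0, vision = params@r0, fitness = NA_real_,
    moves = 0L, stringsAsFactors = FALSE)
  swarm
}

#' Pre-orient a ligand pose toward the restrained receptor surface
#'
#' Draws one receptor restraint and one ligand restraint uniformly at
#' random (passive restraints included: setup steps use them like active
#' ones). The pose's orientation is replaced by the rotation aligning the
#' ligand-centroid-to-ligand-restraint direction with the direction from
#' the swarm center toward the receptor restraint's representative atom,
#' composed with a uniform random spin about that axis. The translation is
#' unchanged. Without receptor restraints the nearest receptor heavy atom
#' to the swarm center serves as the receptor anchor.
#'
#' @param pose The glowworm's current \code{Pose}.
#' @param swarmCenter 3-vector swarm center.
#' @param receptor,ligand \code{Structure} objects.
#' @param restraints A \code{RestraintSet} with at least one ligand
#'   restraint.
#' @return A \code{Pose} with the pre-oriented rotation.
#' @export
preorientLigand <- function(pose, swarmCenter, receptor, ligand, restraints) {
  ligKeys <- restraintResidueKeys(restraints, "ligand")
  if (length(ligKeys) == 0)
    stop("pre-orientation needs at least one ligand restraint")
  recKeys <- restraintResidueKeys(restraints, "receptor")
  pickLig <- ligKeys[sample.int(length(ligKeys), 1)]
  if (length(recKeys) > 0) {
    restraintAtomGroups(receptor, recKeys)
    anchor <- representativeAtoms(receptor)[
      recKeys[sample.int(length(recKeys), 1)], ]
  } else {
    xyz <- structCoords(receptor)[receptor@atoms$element != "H", , drop = FALSE]
    anchor <- xyz[which.min(colSums((t(xyz) - swarmCenter)^2)), ]
  }
  restraintAtomGroups(ligand, pickLig)
  u <- anchor - swarmCenter
  v <- representativeAtoms(ligand)[pickLig, ] - structCentroid(ligand)
  if (sqrt(sum(v^2)) < 1e-6 || sqrt(sum(u^2)) < 1e-6) {
    warning("degenerate restraint geometry; keeping random orientation")
    return(pose)
  }
  align <- quatAlignVectors(v, u)
  spin <- quatFromAxisAngle(u, stats::runif(1, 0, 2 * pi))
  Pose(translation = pose@translation,
       rotation = quatMultiply(spin, align))
}
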
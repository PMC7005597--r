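# Orchestration: setup -> run -> evaluate, with a manifest that makes
# every output reproducible from a single integer seed.

writeManifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

readManifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}

fileChecksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  as.list(tools::md5sum(unlist(paths)))
}

glowwormLines <- function(g) {
  sprintf("%d %.6f %.6f %.6f %.8f %.8f %.8f %.8f",
          g$id, g$tx, g$ty, g$tz, g$qw, g$qx, g$qy, g$qz)
}

#' Set up a docking run (swarm generation, filtering, glowworm init)
#'
#' Generates candidate swarm centers over the receptor surface, filters
#' them to the proximity of the receptor restraints, and initializes
#' restraint-pre-oriented glowworm poses in each retained swarm. Writes one
#' subdirectory per swarm (\code{swarm_<id>/initial_poses.dat}), a center
#' summary table and a manifest with the full configuration, seed and
#' input checksums. Logs swarm counts before and after filtering.
#'
#' @param receptorPdb,ligandPdb PDB file paths.
#' @param outDir Output directory (created).
#' @param restraintsFile Optional restraints file path.
#' @param numSwarms Candidate swarm count before filtering (default 400).
#' @param glowworms Glowworms per swarm (default 200).
#' @param swarmsPerRestraint Swarms kept per receptor restraint (default
#'   10).
#' @param surfaceDistance Swarm-center distance from the receptor surface;
#'   default: ligand bounding-sphere radius + 2 Angstrom.
#' @param jitterRadius Translation jitter radius (default 2 Angstrom).
#' @param seed Global integer seed (default 0).
#' @param params A \code{GSOParams} supplying l0 and r0.
#' @return Invisibly, the setup directory path.
#' @export
cmdSetup <- function(receptorPdb, ligandPdb, outDir, restraintsFile = NULL,
                     numSwarms = 400, glowworms = 200,
                     swarmsPerRestraint = 10, surfaceDistance = NULL,
                     jitterRadius = 2, seed = 0, params = GSOParams()) {
  receptor <- readPDB(receptorPdb)
  ligand <- readPDB(ligandPdb)
  restraints <- if (is.null(restraintsFile)) RestraintSet()
                else parseRestraints(restraintsFile)
  # fail early, naming the restraint, when a residue is absent
  rk <- restraintResidueKeys(restraints, "receptor")
  lk <- restraintResidueKeys(restraints, "ligand")
  if (length(rk)) restraintAtomGroups(receptor, rk)
  if (length(lk)) restraintAtomGroups(ligand, lk)
  if (is.null(surfaceDistance)) {
    lxyz <- structCoords(ligand)
    surfaceDistance <-
      sqrt(max(colSums((t(lxyz) - structCentroid(ligand))^2))) + 2
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  centers <- withRNG(seed, generateSwarmCenters(receptor, numSwarms,
                                                surfaceDistance))
  kept <- filterSwarmsByRestraints(centers, receptor, restraints,
                                   swarmsPerRestraint)
  message(sprintf("swarms generated: %d; after restraint filtering: %d",
                  nrow(centers), nrow(kept$centers)))
  message(sprintf("glowworms per swarm: %d", glowworms))
  ctab <- data.frame(id = kept$ids, x = kept$centers[, 1],
                     y = kept$centers[, 2], z = kept$centers[, 3],
                     restraint = ifelse(is.na(kept$restraint), "-",
                                        kept$restraint))
  utils::write.table(format(ctab, digits = 10),
                     file.path(outDir, "swarm_centers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(kept$centers))) {
    sid <- kept$ids[i]
    sdir <- file.path(outDir, sprintf("swarm_%d", sid))
    dir.create(sdir, showWarnings = FALSE)
    sw <- withRNG(swarmSeed(seed, sid),
                  initGlowworms(Swarm(sid, kept$centers[i, ]), receptor,
                                ligand, n = glowworms,
                                restraints = restraints, params = params,
                                jitterRadius = jitterRadius))
    writeLines(glowwormLines(sw@glowworms),
               file.path(sdir, "initial_poses.dat"))
  }
  writeManifest(outDir, list(
    stage = "setup", version = as.character(utils::packageVersion("glowdock")),
    seed = seed,
    config = list(numSwarms = numSwarms, glowworms = glowworms,
                  swarmsPerRestraint = swarmsPerRestraint,
                  surfaceDistance = surfaceDistance,
                  jitterRadius = jitterRadius,
                  l0 = params@l0, r0 = params@r0),
    inputs = list(receptor = receptorPdb, ligand = ligandPdb,
                  restraints = restraintsFile),
    checksums = fileChecksums(list(receptorPdb, ligandPdb, restraintsFile)),
    swarmsGenerated = nrow(centers), swarmsRetained = nrow(kept$centers),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(outDir)
}

readGlowworms <- function(path, params) {
  m <- utils::read.table(path, col.names = c("id", "tx", "ty", "tz", "qw",
                                             "qx", "qy", "qz"))
  data.frame(m, luciferin = params@l0, vision = params@r0,
             fitness = NA_real_, moves = 0L)
}

#' Run the swarm optimization for every swarm of a setup directory
#'
#' Executes \code{\link{runSwarm}} per swarm with an order-independent
#' per-swarm sub-seed and writes \code{swarm_<id>/gso_result.tsv} (one row
#' per glowworm: pose, raw score, satisfied fraction, fitness) plus an
#' updated manifest.
#'
#' @param setupDir Directory produced by \code{\link{cmdSetup}}.
#' @param scoringTable Path to a scoring-table file, or a
#'   \code{ScoringTable}.
#' @param steps GSO steps (default 100).
#' @param seed Global seed (default: the setup seed).
#' @param params A \code{GSOParams} (its steps slot is overridden by
#'   \code{steps}).
#' @param swarmIds Optional subset/order of swarm ids to run (results are
#'   independent of the order).
#' @param biasCutoff Satisfaction reach of the in-simulation bias
#'   (Angstrom, default 10); see \code{\link{runSwarm}}.
#' @return Invisibly, the setup directory path.
#' @export
cmdRun <- function(setupDir, scoringTable, steps = 100, seed = NULL,
                   params = GSOParams(), swarmIds = NULL, biasCutoff = 10) {
  man <- readManifest(setupDir)
  if (is.null(seed)) seed <- man$seed
  table <- if (is(scoringTable, "ScoringTable")) scoringTable
           else loadScoringTable(scoringTable)
  receptor <- readPDB(man$inputs$receptor)
  ligand <- readPDB(man$inputs$ligand)
  restraints <- if (is.null(man$inputs$restraints) ||
                    length(man$inputs$restraints) == 0) RestraintSet()
                else parseRestraints(man$inputs$restraints)
  params@steps <- as.integer(steps)
  ctx <- scoringContext(receptor, ligand, table)
  ctab <- utils::read.table(file.path(setupDir, "swarm_centers.tsv"),
                            header = TRUE, sep = "\t")
  if (is.null(swarmIds)) swarmIds <- ctab$id
  nEval <- 0L
  for (sid in swarmIds) {
    row <- match(sid, ctab$id)
    if (is.na(row)) stop("unknown swarm id ", sid)
    sdir <- file.path(setupDir, sprintf("swarm_%d", sid))
    g <- readGlowworms(file.path(sdir, "initial_poses.dat"), params)
    sw <- Swarm(sid, c(ctab$x[row], ctab$y[row], ctab$z[row]), g)
    res <- runSwarm(receptor, ligand, sw, ctx, restraints, params,
                    seed = swarmSeed(seed, sid), biasCutoff = biasCutoff)
    nEval <- nEval + nrow(g) * (params@steps + 1L)
    rg <- res@glowworms
    writeLines(c("id tx ty tz qw qx qy qz rawScore satFrac fitness",
                 sprintf("%d %.6f %.6f %.6f %.8f %.8f %.8f %.8f %.6f %.4f %.6f",
                         rg$id, rg$tx, rg$ty, rg$tz, rg$qw, rg$qx, rg$qy,
                         rg$qz, rg$rawScore, rg$satFrac, rg$fitness)),
               file.path(sdir, "gso_result.tsv"))
  }
  message(sprintf("steps: %d; scoring evaluations: %d", steps, nEval))
  man$run <- list(steps = steps, seed = seed, scoringTable =
                    if (is.character(scoringTable)) scoringTable
                    else table@name,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  writeManifest(setupDir, man)
  invisible(setupDir)
}

readSwarmResults <- function(setupDir) {
  ctab <- utils::read.table(file.path(setupDir, "swarm_centers.tsv"),
                            header = TRUE, sep = "\t")
  lapply(ctab$id, function(sid) {
    f <- file.path(setupDir, sprintf("swarm_%d", sid), "gso_result.tsv")
    if (!file.exists(f)) stop("no GSO result for swarm ", sid,
                              "; run cmdRun first")
    g <- utils::read.table(f, header = TRUE)
    g$luciferin <- 0; g$vision <- 0; g$moves <- 0L
    ord <- order(-g$fitness, g$id)
    new("SwarmResult", id = as.integer(sid), glowworms = g,
        bestId = as.integer(g$id[ord[1]]), trajectory = max(g$fitness))
  })
}

#' Evaluate a finished run against a native complex
#'
#' Ranks all glowworms across swarms by biased fitness, computes fnat,
#' i-RMSD, l-RMSD and the CAPRI class of each of the \code{maxModels} best
#' models against the native complex, and writes a report table plus a
#' Top-N success summary (a single case).
#'
#' @param setupDir Directory with setup and run outputs.
#' @param nativeLigandPdb Native (bound-frame) ligand PDB with the same
#'   atoms as the docked ligand; the receptor of the setup is taken as the
#'   native receptor (rigid-body convention).
#' @param topn Top-N levels (default \code{c(1, 5, 10, 20, 50, 100)}).
#' @param maxModels Models to classify, from the top (default
#'   \code{max(topn)}).
#' @return data.frame report (rank, swarm, glowworm, fnat, irmsd, lrmsd,
#'   class), invisibly; files \code{evaluation.tsv} and
#'   \code{success_rates.tsv} are written into \code{setupDir}.
#' @export
cmdEvaluate <- function(setupDir, nativeLigandPdb,
                        topn = c(1, 5, 10, 20, 50, 100),
                        maxModels = max(topn)) {
  man <- readManifest(setupDir)
  receptor <- readPDB(man$inputs$receptor)
  ligand <- readPDB(man$inputs$ligand)
  native <- readPDB(nativeLigandPdb)
  if (atomCount(native) != atomCount(ligand))
    stop("native ligand atom count does not match the docked ligand")
  models <- rankModels(readSwarmResults(setupDir))
  n <- min(nrow(models), maxModels)
  rep <- models[seq_len(n), , drop = FALSE]
  met <- lapply(seq_len(n), function(i) {
    xyz <- applyPose(ligand, Pose(c(rep$tx[i], rep$ty[i], rep$tz[i]),
                                  c(rep$qw[i], rep$qx[i], rep$qy[i],
                                    rep$qz[i])))
    qualityMetrics(receptor, native, xyz)
  })
  rep$fnat <- vapply(met, `[[`, numeric(1), "fnat")
  rep$irmsd <- vapply(met, `[[`, numeric(1), "irmsd")
  rep$lrmsd <- vapply(met, `[[`, numeric(1), "lrmsd")
  rep$class <- vapply(met, `[[`, character(1), "class")
  utils::write.table(format(rep, digits = 6),
                     file.path(setupDir, "evaluation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sr <- successRate(list(rep$class), topn)
  utils::write.table(sr, file.path(setupDir, "success_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' In-memory docking pipeline for one complex
#'
#' Runs setup, optimization and CAPRI classification for a receptor/ligand
#' pair without touching the file system — the workhorse used for
#' synthetic-complex studies and tests.
#'
#' @param receptor,ligand \code{Structure} objects (ligand in its
#'   reference frame; for synthetic complexes, the bound frame).
#' @param restraints A \code{RestraintSet} (may be empty for blind runs).
#' @param table A \code{ScoringTable}.
#' @param native Native ligand \code{Structure} for evaluation (default:
#'   \code{ligand}, the synthetic-complex convention).
#' @param numSwarms Candidate swarm count before filtering.
#' @param glowworms Glowworms per swarm.
#' @param params A \code{GSOParams}.
#' @param seed Global seed.
#' @param surfaceDistance,jitterRadius,swarmsPerRestraint As in
#'   \code{\link{cmdSetup}}.
#' @param maxModels Number of top models to classify (default 100).
#' @param biasCutoff Satisfaction reach of the in-simulation bias
#'   (Angstrom, default 10).
#' @return List with \code{models} (classified ranked data.frame),
#'   \code{classes}, \code{swarms} (retained count), and
#'   \code{swarmResults}.
#' @export
runDocking <- function(receptor, ligand, restraints, table, native = ligand,
                       numSwarms = 400, glowworms = 200,
                       params = GSOParams(), seed = 0,
                       surfaceDistance = NULL, jitterRadius = 2,
                       swarmsPerRestraint = 10, maxModels = 100,
                       biasCutoff = 10) {
  if (is.null(surfaceDistance)) {
    lxyz <- structCoords(ligand)
    surfaceDistance <-
      sqrt(max(colSums((t(lxyz) - structCentroid(ligand))^2))) + 2
  }
  centers <- withRNG(seed, generateSwarmCenters(receptor, numSwarms,
                                                surfaceDistance))
  kept <- filterSwarmsByRestraints(centers, receptor, restraints,
                                   swarmsPerRestraint)
  ctx <- scoringContext(receptor, ligand, table)
  results <- lapply(seq_len(nrow(kept$centers)), function(i) {
    sid <- kept$ids[i]
    ss <- swarmSeed(seed, sid)
    sw <- withRNG(ss, initGlowworms(Swarm(sid, kept$centers[i, ]),
                                    receptor, ligand, n = glowworms,
                                    restraints = restraints,
                                    params = params,
                                    jitterRadius = jitterRadius))
    runSwarm(receptor, ligand, sw, ctx, restraints, params,
             seed = ss + 1L, biasCutoff = biasCutoff)
  })
  models <- rankModels(results)
  n <- min(nrow(models), maxModels)
  models <- models[seq_len(n), , drop = FALSE]
  cls <- character(n)
  for (i in seq_len(n)) {
    xyz <- applyPose(ligand, Pose(c(models$tx[i], models$ty[i],
                                    models$tz[i]),
                                  c(models$qw[i], models$qx[i],
                                    models$qy[i], models$qz[i])))
    m <- qualityMetrics(receptor, native, xyz)
    cls[i] <- m$class
    models$fnat[i] <- m$fnat
    models$irmsd[i] <- m$irmsd
    models$lrmsd[i] <- m$lrmsd
  }
  models$class <- cls
  list(models = models, classes = cls, swarms = nrow(kept$centers),
       swarmResults = results)
}
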
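makeResult <- function(id, fitness, glowworm = seq_along(fitness)) {
  g <- data.frame(id = glowworm, tx = 0, ty = 0, tz = 0, qw = 1, qx = 0,
                  qy = 0, qz = 0, luciferin = 0, vision = 1,
                  fitness = fitness, moves = 0L, rawScore = -fitness,
                  satFrac = 1)
  ord <- order(-fitness, glowworm)
  new("SwarmResult", id = as.integer(id), glowworms = g,
      bestId = as.integer(glowworm[ord[1]]), trajectory = max(fitness))
}

test_that("model ranking merges swarms by fitness with stable ties", {
  one <- makeResult(1, c(3, 7, 5))
  ranked <- rankModels(list(one), topKPerSwarm = 1)
  expect_equal(nrow(ranked), 1)
  expect_equal(ranked$glowworm, 2)

  # equal fitness across swarms: lower swarm id first
  a <- makeResult(2, c(4, 9))
  b <- makeResult(5, c(9, 1))
  ranked <- rankModels(list(b, a))
  expect_equal(ranked$swarm[1:2], c(2, 5))
  expect_equal(ranked$fitness[1:2], c(9, 9))

  # merged ordering equals a full sort of the union
  set.seed(41)
  rs <- lapply(1:4, function(i) makeResult(i, round(stats::runif(6, 0, 5), 1)))
  ranked <- rankModels(rs)
  all <- do.call(rbind, lapply(rs, function(r)
    data.frame(swarm = r@id, fitness = r@glowworms$fitness,
               id = r@glowworms$id)))
  oracle <- all[order(-all$fitness, all$swarm, all$id), ]
  expect_equal(ranked$fitness, oracle$fitness)
  expect_equal(ranked$swarm, oracle$swarm)
  expect_equal(ranked$glowworm, oracle$id)
})

test_that("fnat counts preserved native residue contacts", {
  tc <- generateToyComplex(seed = 17)
  expect_equal(computeFnat(tc$receptor, tc$ligand,
                           structCoords(tc$ligand)), 1.0)
  far <- structCoords(tc$ligand)
  far[, 1] <- far[, 1] + 500
  expect_equal(computeFnat(tc$receptor, tc$ligand, far), 0.0)

  # constructed decoy keeping exactly half the native contacts: six
  # contacting residue pairs, three of which are moved away
  rec <- pointStructure(cbind(seq(0, 50, by = 10), 0, 0), chain = "A")
  lig <- pointStructure(cbind(seq(0, 50, by = 10), 4, 0), chain = "B")
  expect_length(bruteContacts(rec, lig, 5), 6)
  decoy <- structCoords(lig)
  decoy[4:6, 2] <- 200
  expect_equal(computeFnat(rec, lig, decoy), 0.5)
  # oracle agreement on a random perturbation
  set.seed(42)
  lxyz <- applyPose(tc$ligand, Pose(stats::runif(3, -3, 3),
                                    randomQuaternion()))
  natK <- bruteContacts(tc$receptor, tc$ligand, 5)
  modK <- bruteContacts(tc$receptor, tc$ligand, 5, ligCoords = lxyz)
  expect_equal(computeFnat(tc$receptor, tc$ligand, lxyz),
               mean(natK %in% modK))
  # degenerate native: no contacts at all
  aloof <- pointStructure(c(999, 0, 0), chain = "B")
  expect_error(computeFnat(rec, aloof, structCoords(aloof)), "degenerate")
})

test_that("ligand RMSD matches the closed-form superposition oracle", {
  tc <- generateToyComplex(seed = 18)
  expect_equal(computeLrmsd(tc$receptor, tc$ligand,
                            structCoords(tc$ligand)), 0)
  # pure 3 A translation after receptor superposition
  shifted <- sweep(structCoords(tc$ligand), 2, c(0, 3, 0), "+")
  expect_equal(computeLrmsd(tc$receptor, tc$ligand, shifted), 3,
               tolerance = 1e-9)
  # the package Kabsch fit agrees with Horn's quaternion method on
  # randomly perturbed model complexes
  set.seed(43)
  for (rep in 1:6) {
    tr <- randomRigidTransform()
    modelRec <- sweep(structCoords(tc$receptor) %*% t(tr$R), 2, tr$t, "+")
    modelLig <- sweep(applyPose(tc$ligand,
                                Pose(stats::runif(3, -2, 2),
                                     randomQuaternion())) %*% t(tr$R),
                      2, tr$t, "+")
    got <- computeLrmsd(tc$receptor, tc$ligand, modelLig, modelRec)
    bb <- atomTable(tc$receptor)$isBackbone
    horn <- hornSuperpose(modelRec[bb, , drop = FALSE],
                          structCoords(tc$receptor)[bb, , drop = FALSE])
    bbL <- atomTable(tc$ligand)$isBackbone
    oracle <- sqrt(mean(rowSums((horn$transform(modelLig[bbL, , drop = FALSE]) -
                                   structCoords(tc$ligand)[bbL, , drop = FALSE])^2)))
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("interface RMSD is superposed over native interface backbones", {
  tc <- generateToyComplex(seed = 19)
  expect_equal(computeIrmsd(tc$receptor, tc$ligand,
                            structCoords(tc$ligand)), 0, tolerance = 1e-9)
  # a rigid 1 A ligand-only shift: 0 < i-RMSD < 1
  shifted <- sweep(structCoords(tc$ligand), 2, c(1, 0, 0), "+")
  ir <- computeIrmsd(tc$receptor, tc$ligand, shifted)
  expect_gt(ir, 0)
  expect_lt(ir, 1)
  # invariance under global transforms of the model complex
  set.seed(44)
  lxyz <- applyPose(tc$ligand, Pose(c(1, -1, 0.5), randomQuaternion()))
  ref <- computeIrmsd(tc$receptor, tc$ligand, lxyz)
  tr <- randomRigidTransform()
  expect_equal(computeIrmsd(tc$receptor, tc$ligand,
                            sweep(lxyz %*% t(tr$R), 2, tr$t, "+"),
                            sweep(structCoords(tc$receptor) %*% t(tr$R), 2,
                                  tr$t, "+")),
               ref, tolerance = 1e-6)
})

test_that("CAPRI classes follow the fnat/RMSD thresholds", {
  expect_equal(classifyCapri(0.6, 0.8, 12), "high")
  expect_equal(classifyCapri(0.2, 3.5, 8), "acceptable")
  expect_equal(classifyCapri(0.05, 0.1, 0.1), "incorrect")
  expect_equal(classifyCapri(0.35, 1.8, 9), "medium")
  expect_equal(classifyCapri(0.5, 1.0, 1.0), "high")
  expect_equal(classifyCapri(0.1, 4.0, 10), "acceptable")
  expect_equal(classifyCapri(0.09, 0.5, 0.5), "incorrect")
  # improving any metric never demotes the class
  lvl <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  set.seed(45)
  for (rep in 1:200) {
    fn <- stats::runif(1); ir <- stats::runif(1, 0, 12)
    lr <- stats::runif(1, 0, 15)
    base <- lvl[classifyCapri(fn, ir, lr)]
    expect_gte(lvl[classifyCapri(min(1, fn + 0.1), ir, lr)], base)
    expect_gte(lvl[classifyCapri(fn, max(0, ir - 0.5), lr)], base)
    expect_gte(lvl[classifyCapri(fn, ir, max(0, lr - 0.5))], base)
  }
})

test_that("Top-N success rates count cases with a non-incorrect model", {
  # 55 cases, 54 with a hit inside their top 50
  cases <- c(replicate(54, c(rep("incorrect", 49), "acceptable"),
                       simplify = FALSE),
             list(rep("incorrect", 100)))
  sr <- successRate(cases, N = c(1, 5, 10, 20, 50, 100))
  expect_equal(sr$successRate[sr$N == 50], 98.2)
  expect_equal(sr$successRate[sr$N == 10], 0)

  hitAll <- replicate(7, c("high", "incorrect"), simplify = FALSE)
  sr <- successRate(hitAll)
  expect_true(all(sr$successRate == 100))

  # monotone non-decreasing in N on random case sets
  set.seed(46)
  for (rep in 1:10) {
    cases <- replicate(12, sample(c("incorrect", "acceptable"), 100,
                                  replace = TRUE, prob = c(0.97, 0.03)),
                       simplify = FALSE)
    sr <- successRate(cases, N = c(1, 5, 10, 20, 50, 100))
    expect_true(all(diff(sr$successRate) >= 0))
  }
})

test_that("the a-posteriori filter keeps satisfying models in order", {
  tc <- generateToyComplex(seed = 20)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)
  set.seed(47)
  poses <- rbind(c(0, 0, 0), matrix(stats::runif(12, -30, 30), 4))
  models <- data.frame(rank = 1:5, swarm = 1L, glowworm = 1:5,
                       tx = poses[, 1], ty = poses[, 2], tz = poses[, 3],
                       qw = 1, qx = 0, qy = 0, qz = 0,
                       rawScore = NA, satFrac = NA,
                       fitness = seq(5, 1))
  # threshold zero keeps everything
  expect_equal(postFilter(models, ti, threshold = 0,
                          receptor = tc$receptor, ligand = tc$ligand),
               models)
  # per-model brute-force satisfaction oracle decides survival
  s <- vapply(1:5, function(i)
    bruteSatisfied(ti, tc$receptor, tc$ligand,
                   ligCoords = applyPose(tc$ligand,
                                         Pose(poses[i, ]))), numeric(1))
  kept <- postFilter(models, ti, threshold = 0.5,
                     receptor = tc$receptor, ligand = tc$ligand)
  expect_equal(kept$rank, models$rank[s >= 0.5])
  expect_false(is.unsorted(kept$rank))
  # nothing satisfies: empty result
  farModels <- models[-1, ]
  expect_equal(nrow(postFilter(farModels, ti, threshold = 0.5,
                               receptor = tc$receptor,
                               ligand = tc$ligand)), sum(s[-1] >= 0.5))
})

test_that("a-priori restraint use beats post-filtering a blind run", {
  # same compute budget per swarm; the blind run keeps every swarm (more
  # total compute, a conservative comparison) and is filtered afterwards
  # at the contact cutoff
  p <- GSOParams(steps = 60)
  for (s in 2:3) {
    tc <- generateToyComplex(seed = s)
    ti <- computeTrueInterface(tc$receptor, tc$ligand)
    tab <- generateToyScoringTable(seed = s, complex = tc)
    apriori <- suppressWarnings(
      runDocking(tc$receptor, tc$ligand, ti, tab, numSwarms = 80,
                 glowworms = 40, params = p, seed = 100 + s,
                 maxModels = 10))
    aprioriHit <- any(apriori$classes != "incorrect")
    blind <- suppressWarnings(
      runDocking(tc$receptor, tc$ligand, RestraintSet(), tab,
                 numSwarms = 80, glowworms = 40, params = p,
                 seed = 100 + s, maxModels = 200))
    surv <- postFilter(blind$models, ti, threshold = 0.3,
                       receptor = tc$receptor, ligand = tc$ligand)
    blindHit <- nrow(surv) > 0 &&
      any(utils::head(surv$class, 10) != "incorrect")
    expect_gte(aprioriHit, blindHit)
  }
})
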
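test_that("swarm centers sit on the surface shell at the requested spacing", {
  one <- pointStructure(c(1, 2, 3))
  set.seed(1)
  ctr <- generateSwarmCenters(one, 10, surfaceDistance = 10)
  expect_equal(nrow(ctr), 10)
  d <- sqrt(colSums((t(ctr) - c(1, 2, 3))^2))
  expect_equal(d, rep(10, 10), tolerance = 1e-6)

  tc <- generateToyComplex(seed = 11)
  set.seed(2)
  spacing <- 3
  ctr <- suppressWarnings(generateSwarmCenters(tc$receptor, 80,
                                               surfaceDistance = 12,
                                               minSpacing = spacing))
  # distance-to-surface contract
  heavy <- structCoords(tc$receptor)
  nd <- apply(ctr, 1, function(p) sqrt(min(colSums((t(heavy) - p)^2))))
  expect_true(all(abs(nd - 12) <= 0.5))
  # all-pairs spacing contract
  expect_gte(min(dist(ctr)), spacing)
  # coverage: every receptor surface region has a center within reach
  rep <- representativeAtoms(tc$receptor)
  nearest <- apply(rep, 1, function(p)
    sqrt(min(colSums((t(ctr) - p)^2))))
  expect_lt(max(nearest), 12 + 4 * spacing)
})

test_that("restraint filtering keeps the k nearest centers per restraint", {
  tc <- generateToyComplex(seed = 12)
  set.seed(3)
  ctr <- suppressWarnings(generateSwarmCenters(tc$receptor, 400,
                                               surfaceDistance = 12,
                                               minSpacing = 1.5))
  expect_gte(nrow(ctr), 100)
  rt <- residueTable(tc$receptor)
  oneRes <- RestraintSet(data.frame(
    side = "receptor", chain = rt$chain[1], resno = rt$resno[1],
    icode = rt$icode[1], resname = rt$resname[1], mode = "active",
    stringsAsFactors = FALSE))
  kept <- filterSwarmsByRestraints(ctr, tc$receptor, oneRes)
  expect_equal(nrow(kept$centers), 10)
  # brute-force k-nearest oracle
  anchor <- representativeAtoms(tc$receptor)[rt$key[1], ]
  d <- sqrt(colSums((t(ctr) - anchor)^2))
  expect_setequal(kept$ids, order(d)[1:10])

  # no restraints: no filtering
  all <- filterSwarmsByRestraints(ctr, tc$receptor, RestraintSet())
  expect_equal(all$ids, seq_len(nrow(ctr)))

  # two restraints with disjoint top-10 sets: union of both, <= k per
  # restraint, never inventing centers; passive restraints count too
  reps <- representativeAtoms(tc$receptor)
  far <- which.max(colSums((t(reps) - anchor)^2))
  twoRes <- RestraintSet(data.frame(
    side = "receptor", chain = c(rt$chain[1], rt$chain[far]),
    resno = c(rt$resno[1], rt$resno[far]),
    icode = c(rt$icode[1], rt$icode[far]),
    resname = c(rt$resname[1], rt$resname[far]),
    mode = c("active", "passive"), stringsAsFactors = FALSE))
  kept2 <- filterSwarmsByRestraints(ctr, tc$receptor, twoRes)
  d2 <- sqrt(colSums((t(ctr) - reps[far, ])^2))
  oracle <- union(order(d)[1:10], order(d2)[1:10])
  expect_setequal(kept2$ids, oracle)
  expect_true(all(kept2$ids %in% seq_len(nrow(ctr))))
  expect_lte(nrow(kept2$centers), 2 * 10)

  # idempotence: filtering the retained set again changes nothing
  kept3 <- filterSwarmsByRestraints(kept2$centers, tc$receptor, twoRes)
  expect_equal(nrow(kept3$centers), nrow(kept2$centers))
})

test_that("glowworm initialization samples poses as configured", {
  tc <- generateToyComplex(seed = 13)
  swarm <- Swarm(1L, structCentroid(tc$ligand) + c(20, 0, 0))
  set.seed(4)
  sw <- initGlowworms(swarm, tc$receptor, tc$ligand)
  expect_equal(nrow(sw@glowworms), 200)  # default sampling density

  set.seed(5)
  sw <- initGlowworms(swarm, tc$receptor, tc$ligand, n = 20,
                      jitterRadius = 0)
  g <- sw@glowworms
  # zero jitter: identical translations, differing orientations
  expect_equal(max(dist(g[, c("tx", "ty", "tz")])), 0)
  expect_gt(max(dist(g[, c("qw", "qx", "qy", "qz")])), 0.1)
  expect_true(all(g$luciferin == GSOParams()@l0))
  expect_true(all(g$vision == GSOParams()@r0))
  # translations place the ligand centroid at the swarm center
  xyz <- applyPose(tc$ligand, Pose(c(g$tx[1], g$ty[1], g$tz[1]),
                                   c(g$qw[1], g$qx[1], g$qy[1], g$qz[1])))
  expect_equal(colMeans(xyz), swarm@center, tolerance = 1e-9,
               ignore_attr = TRUE)

  # orientation uniformity: mean quaternion outer product approaches I/4
  set.seed(6)
  qm <- randomQuaternion(10000)
  M <- crossprod(qm) / nrow(qm)
  expect_lt(max(abs(M - diag(4) / 4)), 0.02)
})

test_that("pre-orientation points the ligand restraint at the receptor", {
  tc <- generateToyComplex(seed = 14)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)
  expect_error(preorientLigand(Pose(), c(0, 0, 0), tc$receptor, tc$ligand,
                               RestraintSet()), "ligand restraint")

  # single restraint pair: aligned directions have cosine 1
  single <- buildScenario(ti, "TI_SINGLE", tc$receptor, tc$ligand)
  center <- structCentroid(tc$receptor) +
    c(0, 0, 40)
  set.seed(7)
  p <- preorientLigand(Pose(rotation = randomQuaternion()), center,
                       tc$receptor, tc$ligand, single)
  expect_equal(p@translation, c(0, 0, 0))
  expect_equal(sum(p@rotation^2), 1, tolerance = 1e-9)
  lk <- restraintResidueKeys(single, "ligand")
  rk <- restraintResidueKeys(single, "receptor")
  v <- representativeAtoms(tc$ligand)[lk, ] - structCentroid(tc$ligand)
  u <- representativeAtoms(tc$receptor)[rk, ] - center
  got <- as.vector(quatToMatrix(p@rotation) %*% v)
  cosine <- sum(got * u) / sqrt(sum(got^2) * sum(u^2))
  expect_equal(cosine, 1, tolerance = 1e-6)

  # spin randomization: same aligned direction, different orientations
  set.seed(8)
  p2 <- preorientLigand(Pose(rotation = randomQuaternion()), center,
                        tc$receptor, tc$ligand, single)
  got2 <- as.vector(quatToMatrix(p2@rotation) %*% v)
  expect_equal(got2 / sqrt(sum(got2^2)), got / sqrt(sum(got^2)),
               tolerance = 1e-6)
  expect_gt(quatAngle(p@rotation, p2@rotation), 0.01)

  # pre-orientation brings the restraint residues closer than the
  # original random orientation in nearly all draws
  set.seed(9)
  wins <- 0
  n <- 60
  gl <- restraintAtomGroups(tc$ligand, lk)[[1]]
  gr <- restraintAtomGroups(tc$receptor, rk)[[1]]
  anchor <- colMeans(structCoords(tc$receptor)[gr, , drop = FALSE])
  base <- Pose(translation = center - structCentroid(tc$ligand))
  for (i in seq_len(n)) {
    q0 <- randomQuaternion()
    rnd <- Pose(base@translation, q0)
    pre <- preorientLigand(rnd, center, tc$receptor, tc$ligand, single)
    dRnd <- min(sqrt(rowSums(sweep(applyPose(tc$ligand, rnd)[gl, ,
                                                             drop = FALSE],
                                   2, anchor)^2)))
    dPre <- min(sqrt(rowSums(sweep(applyPose(tc$ligand, pre)[gl, ,
                                                             drop = FALSE],
                                   2, anchor)^2)))
    if (dPre <= dRnd + 1e-9) wins <- wins + 1
  }
  expect_gte(wins / n, 0.95)
})

test_that("restraint-filtered swarms sit nearer the native ligand than
          random retention", {
  # with restraints covering the true interface, the nearest retained
  # center to the native ligand centroid beats uniform random retention
  # of the same count (over seeds)
  wins <- 0
  for (s in 1:5) {
    tc <- generateToyComplex(seed = 40 + s)
    ti <- computeTrueInterface(tc$receptor, tc$ligand)
    set.seed(s)
    ctr <- suppressWarnings(generateSwarmCenters(tc$receptor, 80,
                                                 surfaceDistance = 12))
    kept <- filterSwarmsByRestraints(ctr, tc$receptor, ti)
    nat <- structCentroid(tc$ligand)
    dKept <- sqrt(min(colSums((t(kept$centers) - nat)^2)))
    dRand <- replicate(20, {
      pick <- sample(nrow(ctr), nrow(kept$centers))
      sqrt(min(colSums((t(ctr[pick, , drop = FALSE]) - nat)^2)))
    })
    if (dKept <= median(dRand)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
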
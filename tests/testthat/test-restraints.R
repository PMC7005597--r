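test_that("restraints files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# demo", "", "R A.ARG131", "L B.GLU45"), f)
  rs <- parseRestraints(f)
  r <- rs@restraints
  expect_equal(nrow(r), 2)
  expect_equal(r$side, c("receptor", "ligand"))
  expect_equal(r$mode, c("active", "active"))
  expect_equal(r$resno, c(131L, 45L))

  writeLines("L B.GLU45 passive", f)
  expect_equal(parseRestraints(f)@restraints$mode, "passive")

  writeLines(c("R A.ARG131", "R A.ARG131"), f)
  expect_error(parseRestraints(f), "duplicate")

  writeLines("X A.ARG131", f)
  expect_error(parseRestraints(f), "side")

  writeLines("R A.ZZZ13", f)
  expect_error(parseRestraints(f), "residue name")

  # icode, resname-free dialect and write/parse round trip
  writeLines(c("R A.ARG131A", "L B.45 passive"), f)
  rs <- parseRestraints(f)
  expect_equal(rs@restraints$icode, c("A", ""))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeRestraints(rs, f2, header = "scenario demo")
  rs2 <- parseRestraints(f2)
  expect_equal(rs2@restraints, rs@restraints)
})

test_that("true interface is the 3.9 A any-atom residue set", {
  # two single-atom residues straddling the cutoff
  a <- pointStructure(c(0, 0, 0), chain = "A")
  b38 <- pointStructure(c(3.8, 0, 0), chain = "B")
  b40 <- pointStructure(c(4.0, 0, 0), chain = "B")
  ti <- computeTrueInterface(a, b38)
  expect_equal(nrow(ti@restraints), 2)
  expect_setequal(ti@restraints$side, c("receptor", "ligand"))
  expect_warning(ti0 <- computeTrueInterface(a, b40), "empty")
  expect_equal(nrow(ti0@restraints), 0)

  # toy complex equals the brute-force all-pairs oracle
  tc <- generateToyComplex(seed = 2)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)
  pairs <- bruteContacts(tc$receptor, tc$ligand, 3.9)
  recOracle <- unique(vapply(strsplit(pairs, " "), `[`, "", 1))
  ligOracle <- unique(vapply(strsplit(pairs, " "), `[`, "", 2))
  expect_setequal(restraintResidueKeys(ti, "receptor"), recOracle)
  expect_setequal(restraintResidueKeys(ti, "ligand"), ligOracle)

  # symmetry and cutoff monotonicity
  ti_swapped <- computeTrueInterface(tc$ligand, tc$receptor)
  expect_setequal(restraintResidueKeys(ti_swapped, "ligand"), recOracle)
  ti5 <- computeTrueInterface(tc$receptor, tc$ligand, cutoff = 5.0)
  expect_true(all(restraintResidueKeys(ti, "receptor") %in%
                    restraintResidueKeys(ti5, "receptor")))
  expect_true(all(restraintResidueKeys(ti, "ligand") %in%
                    restraintResidueKeys(ti5, "ligand")))
})

test_that("surface residues are the low-neighbor-count residues", {
  single <- pointStructure(c(0, 0, 0))
  expect_equal(surfaceResidues(single), "A|1|")

  tc <- generateToyComplex(seed = 4)
  surf <- surfaceResidues(tc$receptor)
  expect_gte(length(surf), 0.25 * nrow(residueTable(tc$receptor)))

  # the buried centroid residue of a dense globule is not surface
  rep <- representativeAtoms(tc$receptor)
  ctr <- colMeans(rep)
  central <- rownames(rep)[which.min(colSums((t(rep) - ctr)^2))]
  expect_false(central %in% surf)

  # counting oracle: every surface residue has no more neighbors than any
  # excluded residue (ties allowed)
  a <- atomTable(tc$receptor)
  heavy <- structCoords(tc$receptor)[a$element != "H", , drop = FALSE]
  hkey <- residueKeys(tc$receptor)[a$element != "H"]
  counts <- vapply(rownames(rep), function(k) {
    sum(colSums((t(heavy) - rep[k, ])^2) <= 100 & hkey != k)
  }, numeric(1))
  excluded <- setdiff(rownames(rep), surf)
  expect_lte(max(counts[surf]), min(counts[excluded]))
})

test_that("contiguous patches grow greedily and stay connected", {
  # a straight chain of residues, 5 A apart
  chain <- pointStructure(cbind(seq(0, 45, by = 5), 0, 0))
  keys <- rownames(representativeAtoms(chain))
  expect_equal(growContiguousPatch(chain, keys[1], 1, keys[-1]), keys[1])
  expect_equal(growContiguousPatch(chain, keys[1], 3, keys[-1]), keys[1:3])
  expect_error(growContiguousPatch(chain, keys[1], 5, keys[2:3]),
               "exhausted")

  # patch connectivity under the 8 A residue-adjacency graph
  tc <- generateToyComplex(seed = 5)
  rep <- representativeAtoms(tc$receptor)
  surf <- surfaceResidues(tc$receptor)
  patch <- growContiguousPatch(tc$receptor, surf[1], 6, surf[-1])
  expect_length(patch, 6)
  adj <- as.matrix(dist(rep[patch, ])) <= 8
  reached <- 1
  repeat {
    nxt <- unique(c(reached, which(colSums(adj[reached, , drop = FALSE]) > 0)))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  expect_length(reached, length(patch))
})

test_that("restraint scenarios keep the size and disjointness identities", {
  tc <- generateToyComplex(seed = 6, nResReceptor = 48, nResLigand = 24)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)
  nRec <- sum(ti@restraints$side == "receptor")
  nLig <- sum(ti@restraints$side == "ligand")
  tiRec <- restraintResidueKeys(ti, "receptor")
  tiLig <- restraintResidueKeys(ti, "ligand")

  expect_identical(buildScenario(ti, "TI", tc$receptor, tc$ligand), ti)

  for (sc in c("TI_50", "TI_25")) {
    nBlocks <- if (sc == "TI_50") 2 else 4
    trues <- list()
    for (repl in seq_len(nBlocks) - 1) {
      s <- buildScenario(ti, sc, tc$receptor, tc$ligand, replicate = repl,
                         seed = 9)
      # per-side size identity |scenario| = |TI|
      expect_equal(sum(s@restraints$side == "receptor"), nRec)
      expect_equal(sum(s@restraints$side == "ligand"), nLig)
      kRec <- restraintResidueKeys(s, "receptor")
      trueRec <- intersect(kRec, tiRec)
      falseRec <- setdiff(kRec, trueRec)
      # retained fraction (near-equal disjoint blocks) and false
      # positives off the true interface
      sizes <- rep(nRec %/% nBlocks, nBlocks)
      if (nRec %% nBlocks > 0)
        sizes[seq_len(nRec %% nBlocks)] <- sizes[seq_len(nRec %% nBlocks)] + 1
      expect_equal(length(trueRec), sizes[repl + 1])
      expect_length(intersect(falseRec, tiRec), 0)
      trues[[repl + 1]] <- trueRec
    }
    # replicates use disjoint true subsets
    for (i in seq_len(nBlocks - 1))
      for (j in seq((i + 1), nBlocks))
        expect_length(intersect(trues[[i]], trues[[j]]), 0)
  }

  # receptor-only variants carry no ligand restraints
  for (sc in c("TI_REC", "TI_REC_50", "TI_REC_25")) {
    s <- buildScenario(ti, sc, tc$receptor, tc$ligand, replicate = 0,
                       seed = 9)
    expect_equal(sum(s@restraints$side == "ligand"), 0)
    expect_gt(sum(s@restraints$side == "receptor"), 0)
  }
  s <- buildScenario(ti, "TI_REC", tc$receptor, tc$ligand)
  expect_setequal(restraintResidueKeys(s, "receptor"), tiRec)

  # exact spec of the degraded counts when sizes divide evenly: a
  # hand-built 20-residue receptor-side interface
  surf <- surfaceResidues(tc$receptor, fraction = 0.8)
  fake <- residueTable(tc$receptor)
  fake <- fake[match(surf[1:20], fake$key), ]
  ti20 <- RestraintSet(data.frame(
    side = "receptor", chain = fake$chain, resno = fake$resno,
    icode = fake$icode, resname = fake$resname, mode = "active",
    stringsAsFactors = FALSE))
  s50 <- buildScenario(ti20, "TI_REC_50", tc$receptor, tc$ligand, seed = 2)
  k <- restraintResidueKeys(s50, "receptor")
  expect_length(k, 20)
  expect_length(intersect(k, surf[1:20]), 10)
  s25 <- buildScenario(ti20, "TI_REC_25", tc$receptor, tc$ligand, seed = 2)
  k <- restraintResidueKeys(s25, "receptor")
  expect_length(k, 20)
  expect_length(intersect(k, surf[1:20]), 5)
})

test_that("single-pair scenarios pick the closest real contact", {
  tc <- generateToyComplex(seed = 7)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)
  s1 <- buildScenario(ti, "TI_SINGLE", tc$receptor, tc$ligand)
  expect_equal(nrow(s1@restraints), 2)
  expect_setequal(s1@restraints$side, c("receptor", "ligand"))
  # the pair is a real contact
  rk <- restraintResidueKeys(s1, "receptor")
  lk <- restraintResidueKeys(s1, "ligand")
  pairs <- bruteContacts(tc$receptor, tc$ligand, 3.9)
  expect_true(paste(rk, lk) %in% pairs)

  s2 <- buildScenario(ti, "TI_ONE", tc$receptor, tc$ligand)
  expect_equal(nrow(s2@restraints), 1)
  expect_equal(s2@restraints$side, "receptor")
  expect_equal(restraintResidueKeys(s2, "receptor"), rk)

  expect_error(buildScenario(RestraintSet(), "TI", tc$receptor, tc$ligand),
               "empty")
})

test_that("satisfied fraction counts active restraints exactly", {
  tc <- generateToyComplex(seed = 8)
  ti <- computeTrueInterface(tc$receptor, tc$ligand)

  # bound pose: everything satisfied
  expect_equal(satisfiedFraction(ti, tc$receptor, tc$ligand), 1.0)
  # far displacement: nothing satisfied
  far <- structCoords(tc$ligand)
  far[, 1] <- far[, 1] + 500
  expect_equal(satisfiedFraction(ti, tc$receptor, tc$ligand,
                                 ligandCoords = far), 0.0)
  # no active restraints: bias disabled
  passive <- ti@restraints
  passive$mode <- "passive"
  expect_equal(satisfiedFraction(RestraintSet(passive), tc$receptor,
                                 tc$ligand, ligandCoords = far), 1.0)

  # constructed 2-of-4 case: two receptor point-residues near the ligand
  # partner, two far away
  rec <- pointStructure(rbind(c(0, 0, 0), c(0, 5, 0), c(50, 0, 0),
                              c(50, 5, 0)), chain = "A")
  lig <- pointStructure(rbind(c(3, 0, 0), c(3, 5, 0)), chain = "B")
  rs <- RestraintSet(data.frame(
    side = "receptor", chain = "A", resno = 1:4, icode = "",
    resname = "ALA", mode = "active", stringsAsFactors = FALSE))
  expect_equal(satisfiedFraction(rs, rec, lig), 0.5)

  # brute-force oracle over random poses, and joint-transform invariance
  set.seed(21)
  for (rep in 1:5) {
    pose <- Pose(stats::runif(3, -6, 6), randomQuaternion())
    lxyz <- applyPose(tc$ligand, pose)
    got <- satisfiedFraction(ti, tc$receptor, tc$ligand, ligandCoords = lxyz)
    expect_equal(got, bruteSatisfied(ti, tc$receptor, tc$ligand,
                                     ligCoords = lxyz))
    tr <- randomRigidTransform()
    rxyz2 <- sweep(structCoords(tc$receptor) %*% t(tr$R), 2, tr$t, "+")
    lxyz2 <- sweep(lxyz %*% t(tr$R), 2, tr$t, "+")
    expect_equal(satisfiedFraction(ti, tc$receptor, tc$ligand,
                                   receptorCoords = rxyz2,
                                   ligandCoords = lxyz2), got)
  }
})
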
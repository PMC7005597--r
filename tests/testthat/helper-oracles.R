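# Independent oracles kept free of the package's accelerated code paths.

# brute-force double-loop pair-potential score (oracle for scorePose)
bruteScore <- function(receptor, ligand, table, ligCoords = NULL) {
  rxyz <- structCoords(receptor)
  lxyz <- if (is.null(ligCoords)) structCoords(ligand) else ligCoords
  lab <- function(s) paste(atomTable(s)$resname, atomTable(s)$name)
  ri <- unname(table@types[lab(receptor)])
  li <- unname(table@types[lab(ligand)])
  ri[atomTable(receptor)$element == "H"] <- NA
  li[atomTable(ligand)$element == "H"] <- NA
  edges <- table@binEdges
  total <- 0
  for (i in seq_len(nrow(rxyz))) {
    if (is.na(ri[i])) next
    for (j in seq_len(nrow(lxyz))) {
      if (is.na(li[j])) next
      d <- sqrt(sum((rxyz[i, ] - lxyz[j, ])^2))
      if (d >= edges[length(edges)]) next
      k <- which(d < edges)[1]
      total <- total + table@energies[ri[i], li[j], k]
    }
  }
  total
}

# Horn's closed-form quaternion superposition (oracle for superpose())
hornSuperpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  S <- t(A) %*% B
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quatToMatrix(q / sqrt(sum(q^2)))
  # rows transform as x' = R x (column convention): mobile %*% t(R)
  moved <- A %*% t(R)
  list(rmsd = sqrt(mean(rowSums((moved - B)^2))),
       transform = function(xyz) sweep(sweep(xyz, 2, cm) %*% t(R), 2, ct, "+"))
}

# brute-force per-restraint satisfaction scan (oracle for satisfiedFraction)
bruteSatisfied <- function(restraints, receptor, ligand,
                           recCoords = structCoords(receptor),
                           ligCoords = structCoords(ligand),
                           cutoff = restraints@cutoff) {
  r <- restraints@restraints
  r <- r[r$mode == "active", , drop = FALSE]
  if (nrow(r) == 0) return(1.0)
  rkeys <- residueKeys(receptor)
  lkeys <- residueKeys(ligand)
  sat <- 0
  for (i in seq_len(nrow(r))) {
    key <- paste(r$chain[i], r$resno[i], r$icode[i], sep = "|")
    if (r$side[i] == "receptor") {
      own <- recCoords[rkeys == key, , drop = FALSE]; other <- ligCoords
    } else {
      own <- ligCoords[lkeys == key, , drop = FALSE]; other <- recCoords
    }
    dmin <- Inf
    for (a in seq_len(nrow(own)))
      dmin <- min(dmin, sqrt(min(colSums((t(other) - own[a, ])^2))))
    if (dmin <= cutoff) sat <- sat + 1
  }
  sat / nrow(r)
}

# brute-force residue-contact set (oracle for computeTrueInterface / fnat)
bruteContacts <- function(receptor, ligand, cutoff, ligCoords = NULL) {
  rxyz <- structCoords(receptor)
  lxyz <- if (is.null(ligCoords)) structCoords(ligand) else ligCoords
  rk <- residueKeys(receptor); lk <- residueKeys(ligand)
  out <- character(0)
  for (i in seq_len(nrow(rxyz))) for (j in seq_len(nrow(lxyz))) {
    if (sqrt(sum((rxyz[i, ] - lxyz[j, ])^2)) < cutoff)
      out <- c(out, paste(rk[i], lk[j]))
  }
  unique(out)
}
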
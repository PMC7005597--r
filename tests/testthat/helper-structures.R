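# In-code structure fixtures: tiny PDB texts and hand-built Structures.

pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        record = "ATOM  ", altLoc = " ", icode = " ",
                        element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, nm, altLoc, resname, chain, resno, icode,
          x, y, z, element)
}

# five-atom, one-residue fixture used across the IO tests
fiveAtomPDB <- function(path) {
  writeLines(c(
    pdbAtomLine(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 2.000, 3.000, 4.000),
    pdbAtomLine(3, "C", "ALA", "A", 1, 3.100, 3.900, 4.200),
    pdbAtomLine(4, "O", "ALA", "A", 1, 4.000, 3.500, 4.900),
    pdbAtomLine(5, "CB", "ALA", "A", 1, 2.100, 4.100, 2.900),
    "END"), path)
  path
}

# minimal Structure: one atom per residue at given coordinates
pointStructure <- function(xyz, chain = "A", resname = "ALA", name = "CA",
                           label = "points") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  Structure(data.frame(
    serial = seq_len(n), name = name, element = substr(name, 1, 1),
    chain = chain, resno = seq_len(n), icode = "", resname = resname,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    isBackbone = name %in% c("N", "CA", "C", "O"),
    stringsAsFactors = FALSE), label = label)
}

# one-type, n-bin scoring table with the given energies
miniTable <- function(edges, energies, res = "ALA", atom = "CA") {
  nt <- 1L
  e <- array(energies, dim = c(1, 1, length(edges)))
  new("ScoringTable", types = stats::setNames(1L, paste(res, atom)),
      binEdges = edges, energies = e, name = "mini")
}

randomRigidTransform <- function() {
  q <- randomQuaternion()
  list(R = quatToMatrix(q), t = stats::runif(3, -20, 20))
}
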
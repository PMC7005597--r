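# PDB input/output and rigid-body pose algebra.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Number of atoms in a structure
#' @param structure A \code{Structure}.
#' @return Integer atom count.
#' @export
atomCount <- function(structure) nrow(structure@atoms)

#' Atom table of a structure
#' @param structure A \code{Structure}.
#' @return data.frame of atoms in file order.
#' @export
atomTable <- function(structure) structure@atoms

#' Coordinates of a structure
#' @param structure A \code{Structure}.
#' @return n x 3 numeric matrix in Angstrom, file order.
#' @export
structCoords <- function(structure) {
  a <- structure@atoms
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Coordinate centroid
#' @param structure A \code{Structure}.
#' @return 3-vector mean of atom coordinates.
#' @export
structCentroid <- function(structure) colMeans(structCoords(structure))

#' Residue keys in atom order
#'
#' A residue key is "chain|resno|icode"; residues are contiguous runs of
#' atoms sharing a key.
#'
#' @param structure A \code{Structure}.
#' @return Character vector, one key per atom.
#' @export
residueKeys <- function(structure) {
  a <- structure@atoms
  paste(a$chain, a$resno, a$icode, sep = "|")
}

#' Per-residue summary table
#' @param structure A \code{Structure}.
#' @return data.frame with one row per residue: key, chain, resno, icode,
#'   resname, firstAtom, nAtoms, in first-occurrence order.
#' @export
residueTable <- function(structure) {
  a <- structure@atoms
  key <- residueKeys(structure)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             firstAtom = which(first),
             nAtoms = as.vector(table(factor(key, levels = key[first]))),
             stringsAsFactors = FALSE)
}

#' Representative atom coordinates per residue
#'
#' CB when present, else CA, else the residue's first atom — the standard
#' side-chain-direction convention used for restraint anchors and residue
#' adjacency.
#'
#' @param structure A \code{Structure}.
#' @return Matrix (nres x 3) with rownames set to residue keys.
#' @export
representativeAtoms <- function(structure) {
  a <- structure@atoms
  key <- residueKeys(structure)
  keys <- unique(key)
  out <- matrix(NA_real_, length(keys), 3, dimnames = list(keys, c("x", "y", "z")))
  idx <- split(seq_len(nrow(a)), factor(key, levels = keys))
  for (i in seq_along(keys)) {
    rows <- idx[[i]]
    pick <- rows[match("CB", a$name[rows])]
    if (is.na(pick)) pick <- rows[match("CA", a$name[rows])]
    if (is.na(pick)) pick <- rows[1]
    out[i, ] <- c(a$x[pick], a$y[pick], a$z[pick])
  }
  out
}

#' Read a structure from a PDB file
#'
#' Reads the ATOM records of the first MODEL via bio3d, keeping only blank
#' or 'A' alternate locations. HETATM records and waters are skipped unless
#' \code{includeHet} is set.
#'
#' @param path Path to a PDB file.
#' @param includeHet Also keep non-water HETATM records (default FALSE).
#' @param label Structure label (default: file name without extension).
#' @return A \code{Structure}.
#' @export
readPDB <- function(path, includeHet = FALSE, label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom))
    stop("PDB format error: no ATOM/HETATM record in ", path)
  # line-numbered coordinate check before handing off to the parser
  for (i in which(isAtom)) {
    endm <- which(rec == "ENDMDL")
    if (length(endm) && i > endm[1]) break
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- substr(lines[i], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(fld))))
        stop(sprintf("PDB format error: malformed coordinate field on line %d", i))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM"
  if (includeHet) keep <- keep | (a$type == "HETATM" & a$resid != "HOH")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0)
    stop("PDB format error: no parsable ATOM record in ", path)
  elem <- a$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(a$elety[is.na(elem) | elem == ""]), 1, 1)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- " "
  icode <- a$insert
  icode[is.na(icode)] <- ""
  atoms <- data.frame(
    serial = as.integer(a$eleno), name = trimws(a$elety),
    element = trimws(elem), chain = chain, resno = as.integer(a$resno),
    icode = icode, resname = trimws(a$resid),
    x = a$x, y = a$y, z = a$z,
    isBackbone = trimws(a$elety) %in% BACKBONE_NAMES,
    stringsAsFactors = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  Structure(atoms, label = label)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records (3-decimal coordinates) with a TER
#' record at every chain boundary and a final END.
#'
#' @param structure A \code{Structure}.
#' @param path Output file path.
#' @param coordinates Optional n x 3 matrix replacing the structure's own
#'   coordinates (e.g. a posed ligand); must match the atom count.
#' @return Invisibly, the path.
#' @export
writePDB <- function(structure, path, coordinates = NULL) {
  a <- structure@atoms
  xyz <- if (is.null(coordinates)) structCoords(structure) else coordinates
  if (!is.matrix(xyz) || nrow(xyz) != nrow(a) || ncol(xyz) != 3)
    stop("coordinate array must be atom count x 3")
  if (any(abs(xyz) >= 10000))
    stop("format overflow: coordinate magnitude >= 10000 A does not fit PDB columns")
  fmt <- "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  # PDB atom-name column quirk: names of <4 chars start in column 14
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf(fmt, a$serial %% 100000, nm, a$resname,
                   substr(a$chain, 1, 1), a$resno,
                   ifelse(a$icode == "", " ", a$icode),
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   toupper(substr(a$element, 1, 2)))
  ter <- which(diff(match(a$chain, unique(a$chain))) != 0)
  out <- character(0)
  prev <- 1
  for (b in c(ter, nrow(a))) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Apply a rigid-body pose to a structure's coordinates
#'
#' Rotates about the structure's coordinate centroid by the pose rotation,
#' then translates by the pose translation. The structure is not modified.
#'
#' @param structure A \code{Structure}.
#' @param pose A \code{Pose}.
#' @return n x 3 coordinate matrix in Angstrom.
#' @export
applyPose <- function(structure, pose) {
  q <- pose@rotation
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6)
    stop("pose rotation is not a unit quaternion")
  xyz <- structCoords(structure)
  ctr <- colMeans(xyz)
  R <- quatToMatrix(quatNormalize(q))
  out <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + pose@translation, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' Compose two poses
#'
#' \code{composePoses(first, second)} is the pose whose application equals
#' applying \code{first} and then \code{second} (rotations about the same
#' centroid-relative frame; translations add after rotating the first
#' translation by the second rotation).
#'
#' @param first,second \code{Pose} objects.
#' @return A \code{Pose}, quaternion renormalized.
#' @export
composePoses <- function(first, second) {
  q <- quatNormalize(quatMultiply(second@rotation, first@rotation))
  R2 <- quatToMatrix(second@rotation)
  t12 <- as.vector(R2 %*% first@translation) + second@translation
  Pose(translation = t12, rotation = q)
}

#' Inverse of a pose
#' @param pose A \code{Pose}.
#' @return The \code{Pose} undoing it: compose(pose, inverse) = identity.
#' @export
poseInverse <- function(pose) {
  qi <- quatConjugate(pose@rotation)
  Ri <- quatToMatrix(qi)
  Pose(translation = -as.vector(Ri %*% pose@translation), rotation = qi)
}
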
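# Residue restraints: parsing, true-interface computation, degraded
# restraint scenarios and per-pose satisfaction.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

restraintKey <- function(r) paste(r$side, r$chain, r$resno, r$icode)

#' Parse a residue-restraints file
#'
#' One restraint per line in the dialect
#' \code{R|L <chain>.<RESNAME><resnum>[icode] [passive]}, e.g.
#' \code{R A.ARG131} or \code{L B.GLU45 passive}. The residue name is
#' optional (\code{R A.131} is accepted) and validated against the 20
#' standard amino acids when present. Lines starting with '#' and blank
#' lines are ignored.
#'
#' @param path Path to the restraints file.
#' @param cutoff Contact cutoff stored with the set (default 3.9 Angstrom).
#' @return A \code{RestraintSet}.
#' @export
parseRestraints <- function(path, cutoff = 3.9) {
  if (!file.exists(path)) stop("restraints file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  pat <- "^([A-Za-z]+)\\s+(\\S+)\\.([A-Z]{3})?(-?[0-9]+)([A-Za-z]?)(\\s+passive)?\\s*$"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (length(m) == 0)
      stop(sprintf("restraint syntax error on line %d: '%s'", i, ln))
    side <- switch(toupper(m[2]), R = "receptor", L = "ligand",
                   stop(sprintf("unknown side token '%s' on line %d", m[2], i)))
    resname <- if (m[4] == "") NA_character_ else m[4]
    if (!is.na(resname) && !resname %in% AMINO3)
      stop(sprintf("unknown residue name '%s' on line %d", resname, i))
    rows[[length(rows) + 1]] <- data.frame(
      side = side, chain = m[3], resno = as.integer(m[5]), icode = m[6],
      resname = resname, mode = if (m[7] != "") "passive" else "active",
      line = i, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(RestraintSet(cutoff = cutoff))
  r <- do.call(rbind, rows)
  dup <- duplicated(restraintKey(r))
  if (any(dup))
    stop("duplicate restraint(s) at line(s): ",
         paste(r$line[dup], collapse = ", "))
  RestraintSet(r[, setdiff(names(r), "line")], cutoff = cutoff)
}

#' Write a restraint set in the restraints text dialect
#'
#' @param restraints A \code{RestraintSet}.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading '#'), e.g. scenario provenance.
#' @return Invisibly, the path.
#' @export
writeRestraints <- function(restraints, path, header = NULL) {
  r <- restraints@restraints
  lines <- character(0)
  if (!is.null(header)) lines <- paste("#", header)
  if (nrow(r) > 0) {
    side <- ifelse(r$side == "receptor", "R", "L")
    nm <- ifelse(is.na(r$resname), "", r$resname)
    lines <- c(lines, paste0(
      side, " ", r$chain, ".", nm, r$resno, r$icode,
      ifelse(r$mode == "passive", " passive", "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Residue keys of the restraints on one side
#'
#' @param restraints A \code{RestraintSet}.
#' @param side "receptor" or "ligand".
#' @param activeOnly Drop passive restraints (default FALSE).
#' @return Character vector of "chain|resno|icode" residue keys.
#' @export
restraintResidueKeys <- function(restraints, side, activeOnly = FALSE) {
  r <- restraints@restraints
  r <- r[r$side == side, , drop = FALSE]
  if (activeOnly) r <- r[r$mode == "active", , drop = FALSE]
  paste(r$chain, r$resno, r$icode, sep = "|")
}

# atom row indices of a structure, grouped by residue key, for given keys;
# errors (naming the restraint) when a key is absent from the structure
restraintAtomGroups <- function(structure, keys) {
  sk <- residueKeys(structure)
  idx <- split(seq_along(sk), factor(sk, levels = unique(sk)))
  missing <- setdiff(keys, names(idx))
  if (length(missing))
    stop("restraint residue(s) not found in structure '", structure@label,
         "': ", paste(missing, collapse = ", "))
  idx[keys]
}

#' Residues of the true interface of a bound complex
#'
#' A residue belongs to the interface iff any of its atoms lies within
#' \code{cutoff} of any atom of the partner molecule (all atoms present are
#' used). Both sides are returned as active restraints.
#'
#' @param receptor,ligand \code{Structure} objects in the bound (native)
#'   frame.
#' @param cutoff Distance cutoff in Angstrom (default 3.9, the LIGPLOT
#'   contact convention).
#' @return A \code{RestraintSet}; empty (with a warning) when no residue
#'   pair falls within the cutoff.
#' @export
computeTrueInterface <- function(receptor, ligand, cutoff = 3.9) {
  pr <- contactResiduePairs(receptor, ligand, cutoff)
  if (nrow(pr) == 0) {
    warning("no residue pair within ", cutoff, " A; empty interface")
    return(RestraintSet(cutoff = cutoff))
  }
  rt <- residueTable(receptor)
  lt <- residueTable(ligand)
  mk <- function(tab, keys, side) {
    rows <- tab[match(unique(keys), tab$key), , drop = FALSE]
    data.frame(side = side, chain = rows$chain, resno = rows$resno,
               icode = rows$icode, resname = rows$resname, mode = "active",
               stringsAsFactors = FALSE)
  }
  RestraintSet(rbind(mk(rt, pr$recKey, "receptor"),
                     mk(lt, pr$ligKey, "ligand")), cutoff = cutoff)
}

# all (receptor residue, ligand residue) pairs with any-atom distance <
# cutoff; returns data.frame(recKey, ligKey, minDist)
contactResiduePairs <- function(receptor, ligand, cutoff,
                                ligCoords = NULL) {
  rxyz <- structCoords(receptor)
  lxyz <- if (is.null(ligCoords)) structCoords(ligand) else ligCoords
  rk <- residueKeys(receptor)
  lk <- residueKeys(ligand)
  hits <- cpp_residue_contacts(rxyz, match(rk, unique(rk)),
                               lxyz, match(lk, unique(lk)), cutoff)
  if (nrow(hits) == 0)
    return(data.frame(recKey = character(), ligKey = character(),
                      minDist = numeric(), stringsAsFactors = FALSE))
  data.frame(recKey = unique(rk)[hits[, 1]], ligKey = unique(lk)[hits[, 2]],
             minDist = hits[, 3], stringsAsFactors = FALSE)
}

#' Solvent-exposed residues by a neighbor-count proxy
#'
#' Exposure is proxied by the number of heavy atoms (of the same molecule,
#' excluding the residue itself) within \code{radius} of the residue's
#' representative atom: buried residues see many neighbors, exposed ones
#' few. Residues whose count is at or below the \code{fraction} quantile of
#' all counts qualify as surface.
#'
#' @param structure A \code{Structure}.
#' @param radius Neighbor-count radius in Angstrom (default 10).
#' @param fraction Quantile of the neighbor-count distribution used as the
#'   threshold (default 0.5).
#' @return Character vector of residue keys, ranked by increasing neighbor
#'   count (most exposed first).
#' @export
surfaceResidues <- function(structure, radius = 10, fraction = 0.5) {
  rep <- representativeAtoms(structure)
  a <- structure@atoms
  heavy <- a$element != "H"
  xyz <- structCoords(structure)[heavy, , drop = FALSE]
  key <- residueKeys(structure)[heavy]
  counts <- integer(nrow(rep))
  for (i in seq_len(nrow(rep))) {
    d2 <- colSums((t(xyz) - rep[i, ])^2)
    counts[i] <- sum(d2 <= radius^2 & key != rownames(rep)[i])
  }
  thr <- stats::quantile(counts, fraction, type = 1)
  keep <- which(counts <= thr)
  rownames(rep)[keep[order(counts[keep])]]
}

#' Grow a contiguous surface patch of residues
#'
#' Starting from the seed residues, greedily adds the candidate residue
#' whose representative atom is closest to any residue already in the
#' patch, until \code{targetSize} residues (seeds included) are in the
#' patch. The result is connected under an 8 Angstrom residue-adjacency
#' graph of representative atoms.
#'
#' @param structure A \code{Structure}.
#' @param seeds Character vector of residue keys already in the patch.
#' @param targetSize Total patch size to reach (>= length(seeds)).
#' @param pool Candidate residue keys allowed to join (disjoint from any
#'   excluded residues by construction of the caller).
#' @return Character vector of patch residue keys (seeds first, then added
#'   residues in growth order).
#' @export
growContiguousPatch <- function(structure, seeds, targetSize, pool) {
  rep <- representativeAtoms(structure)
  bad <- setdiff(c(seeds, pool), rownames(rep))
  if (length(bad)) stop("unknown residue key(s): ", paste(bad, collapse = ", "))
  patch <- seeds
  pool <- setdiff(pool, seeds)
  while (length(patch) < targetSize) {
    if (length(pool) == 0)
      stop(sprintf("candidate pool exhausted: patch size %d of %d reached",
                   length(patch), targetSize))
    pm <- rep[patch, , drop = FALSE]
    cm <- rep[pool, , drop = FALSE]
    d <- outer(rowSums(cm^2), rowSums(pm^2), "+") - 2 * cm %*% t(pm)
    best <- pool[which.min(apply(d, 1, min))]
    patch <- c(patch, best)
    pool <- setdiff(pool, best)
  }
  patch
}

subsetBySide <- function(ti, side) {
  r <- ti@restraints
  r[r$side == side, , drop = FALSE]
}

# pick replicate block `rep` (0-based) of `nBlocks` from a seeded shuffle
# of the row indices of `df`; blocks are disjoint and near-equal
replicateBlock <- function(n, nBlocks, rep, seed) {
  ord <- withRNG(seed, sample.int(n))
  sizes <- rep(n %/% nBlocks, nBlocks)
  extra <- n %% nBlocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  from <- cumsum(c(1, sizes))[rep + 1]
  ord[seq(from, length.out = sizes[rep + 1])]
}

# evaluate expr with a locally seeded RNG, restoring the caller's stream
withRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

scenarioOneSide <- function(ti, structure, side,
                            replicate, nBlocks, seed) {
  r <- subsetBySide(ti, side)
  n <- nrow(r)
  tab <- residueTable(structure)
  tiKeys <- paste(r$chain, r$resno, r$icode, sep = "|")
  keep <- replicateBlock(n, nBlocks, replicate, seed)
  kept <- r[sort(keep), , drop = FALSE]
  keptKeys <- paste(kept$chain, kept$resno, kept$icode, sep = "|")
  # size identity |scenario side| = |TI side|: false positives fill the
  # complement of the retained block (3x the retained count for quarters
  # when n is divisible by the block count)
  nFalse <- n - nrow(kept)
  # widen the surface definition when the default pool cannot supply
  # enough non-interfacial residues
  frac <- 0.5
  repeat {
    surf <- surfaceResidues(structure, fraction = frac)
    pool <- setdiff(surf, tiKeys)
    if (length(pool) >= nFalse || frac >= 1) break
    frac <- min(1, frac + 0.25)
  }
  patch <- growContiguousPatch(structure, seeds = keptKeys,
                               targetSize = nrow(kept) + nFalse, pool = pool)
  falseKeys <- setdiff(patch, keptKeys)
  rows <- tab[match(falseKeys, tab$key), , drop = FALSE]
  false <- data.frame(side = side, chain = rows$chain, resno = rows$resno,
                      icode = rows$icode, resname = rows$resname,
                      mode = "active", stringsAsFactors = FALSE)
  rbind(kept[, names(false)], false)
}

#' Build a restraint scenario from the true interface
#'
#' Scenario constructors degrade a true-interface (TI) restraint set:
#' \describe{
#'   \item{TI}{the full true interface, unchanged.}
#'   \item{TI_50}{per side, a random half of the TI residues plus an equal
#'     number of non-interfacial surface residues grown as one contiguous
#'     patch seeded at the retained residues; replicates 0 and 1 use
#'     disjoint halves.}
#'   \item{TI_25}{per side, one quarter of the TI plus three times as many
#'     contiguous false positives; replicates 0..3 use disjoint quarters.}
#'   \item{TI_REC, TI_REC_50, TI_REC_25}{as above, receptor side only.}
#'   \item{TI_SINGLE}{exactly one receptor and one ligand residue making a
#'     real contact (the pair with the smallest inter-atomic distance).}
#'   \item{TI_ONE}{the TI_SINGLE receptor residue alone.}
#' }
#' False positives never intersect the true interface.
#'
#' @param ti \code{RestraintSet} computed from the native complex.
#' @param scenario One of "TI", "TI_50", "TI_25", "TI_REC", "TI_REC_50",
#'   "TI_REC_25", "TI_SINGLE", "TI_ONE".
#' @param receptor,ligand Native \code{Structure} objects.
#' @param replicate Replicate index (0-based): < 2 for *_50, < 4 for *_25.
#' @param seed Integer seed controlling the per-side split and patch
#'   growth; the same seed yields disjoint true subsets across replicates.
#' @return A \code{RestraintSet} (all restraints active).
#' @export
buildScenario <- function(ti, scenario, receptor, ligand, replicate = 0,
                          seed = 1) {
  scenario <- match.arg(scenario, c("TI", "TI_50", "TI_25", "TI_REC",
                                    "TI_REC_50", "TI_REC_25", "TI_SINGLE",
                                    "TI_ONE"))
  if (nrow(ti@restraints) == 0) stop("true interface is empty")
  cutoff <- ti@cutoff
  if (scenario == "TI") return(ti)
  if (scenario == "TI_REC") {
    return(RestraintSet(subsetBySide(ti, "receptor"), cutoff = cutoff))
  }
  if (scenario %in% c("TI_SINGLE", "TI_ONE")) {
    pr <- contactResiduePairs(receptor, ligand, cutoff)
    rk <- restraintResidueKeys(ti, "receptor")
    lk <- restraintResidueKeys(ti, "ligand")
    pr <- pr[pr$recKey %in% rk & pr$ligKey %in% lk, , drop = FALSE]
    if (nrow(pr) == 0) stop("no contacting restraint pair found")
    best <- pr[order(pr$minDist, pr$recKey, pr$ligKey)[1], ]
    r <- ti@restraints
    recRow <- r[r$side == "receptor" &
                  paste(r$chain, r$resno, r$icode, sep = "|") == best$recKey, ]
    ligRow <- r[r$side == "ligand" &
                  paste(r$chain, r$resno, r$icode, sep = "|") == best$ligKey, ]
    out <- if (scenario == "TI_SINGLE") rbind(recRow, ligRow) else recRow
    return(RestraintSet(out, cutoff = cutoff))
  }
  nBlocks <- if (scenario %in% c("TI_50", "TI_REC_50")) 2L else 4L
  if (replicate < 0 || replicate >= nBlocks)
    stop("replicate index must be in [0, ", nBlocks - 1, "] for ", scenario)
  recOnly <- scenario %in% c("TI_REC_50", "TI_REC_25")
  parts <- list(scenarioOneSide(ti, receptor, "receptor",
                                replicate, nBlocks, seed))
  if (!recOnly && nrow(subsetBySide(ti, "ligand")) > 0) {
    parts <- c(parts, list(scenarioOneSide(ti, ligand, "ligand",
                                           replicate, nBlocks, seed + 101)))
  }
  RestraintSet(do.call(rbind, parts), cutoff = cutoff)
}

#' Fraction of satisfied active restraints for a pose
#'
#' An active restraint is satisfied iff any atom of its residue lies within
#' \code{cutoff} of any atom of the partner molecule under the supplied
#' coordinates. Passive restraints are never counted. With zero active
#' restraints the bias is disabled and 1.0 is returned.
#'
#' @param restraints A \code{RestraintSet}.
#' @param receptor,ligand \code{Structure} objects (atom order defines the
#'   coordinate rows).
#' @param receptorCoords,ligandCoords Coordinate matrices for the current
#'   pose; default to the structures' own coordinates.
#' @param cutoff Contact cutoff in Angstrom; defaults to the set's cutoff.
#' @return Fraction in [0, 1].
#' @export
satisfiedFraction <- function(restraints, receptor, ligand,
                              receptorCoords = structCoords(receptor),
                              ligandCoords = structCoords(ligand),
                              cutoff = restraints@cutoff) {
  grp <- satisfactionGroups(restraints, receptor, ligand)
  if (length(grp$groups) == 0) return(1.0)
  cpp_satisfied_fraction(receptorCoords, ligandCoords, grp$groups,
                         grp$sides, cutoff)
}

# precompute atom groups for the active restraints: list(groups = list of
# 1-based atom index vectors, sides = integer 0 receptor / 1 ligand)
satisfactionGroups <- function(restraints, receptor, ligand) {
  rk <- restraintResidueKeys(restraints, "receptor", activeOnly = TRUE)
  lk <- restraintResidueKeys(restraints, "ligand", activeOnly = TRUE)
  groups <- c(if (length(rk)) restraintAtomGroups(receptor, rk),
              if (length(lk)) restraintAtomGroups(ligand, lk))
  list(groups = unname(lapply(groups, as.integer)),
       sides = as.integer(c(rep(0L, length(rk)), rep(1L, length(lk)))))
}
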
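# Distance-binned atom-pair statistical potential (DFIRE-style tables are
# consumed in a documented text format) plus the restraint-satisfaction
# bias applied to every fitness evaluation.

#' Load a scoring table from its text format
#'
#' Format: comment lines start with '#'; a header line
#' \code{bins: e1 e2 ... en} gives the strictly increasing upper bin edges
#' in Angstrom (the last edge is the interaction cutoff); an optional
#' \code{name: <label>} line; then one row per entry:
#' \code{RESNAME ATOMNAME RESNAME ATOMNAME bin_index energy} with 1-based
#' bin indices. Entries are symmetrized; missing (i, j, bin) combinations
#' default to 0 and their count is reported as a message. Rows with residue
#' names outside the 20 standard amino acids are collected, reported and
#' skipped.
#'
#' A small synthetic demonstration table ships with the package:
#' \code{system.file("extdata", "demo_scoring_table.tbl",
#' package = "glowdock")}. Published statistical-potential parameter
#' sets (e.g. DFIRE) can be converted into this format.
#'
#' @param path Path to a scoring-table file.
#' @return A \code{ScoringTable}.
#' @export
loadScoringTable <- function(path) {
  if (!file.exists(path)) stop("scoring table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  hdr <- grep("^bins:", lines, value = TRUE)
  if (length(hdr) != 1) stop("scoring-table format error: need one 'bins:' header")
  edges <- as.numeric(strsplit(sub("^bins:\\s*", "", hdr), "\\s+")[[1]])
  if (any(is.na(edges)) || any(edges <= 0) || any(diff(edges) <= 0))
    stop("scoring-table format error: bin edges must be positive and strictly increasing")
  nameLn <- grep("^name:", lines, value = TRUE)
  name <- if (length(nameLn)) sub("^name:\\s*", "", nameLn[1]) else "unnamed"
  rows <- lines[!grepl("^(bins|name):", lines)]
  if (length(rows) == 0) stop("scoring-table format error: no energy rows")
  parts <- strsplit(rows, "\\s+")
  bad <- which(vapply(parts, length, 1L) != 6)
  if (length(bad)) stop("scoring-table format error: malformed row(s) ",
                        paste(bad, collapse = ", "))
  m <- do.call(rbind, parts)
  resOK <- m[, 1] %in% AMINO3 & m[, 3] %in% AMINO3
  if (any(!resOK)) {
    message(sum(!resOK), " row(s) with unknown residue tokens skipped: ",
            paste(unique(c(m[!resOK, 1], m[!resOK, 3])[
              !unique(c(m[!resOK, 1], m[!resOK, 3])) %in% AMINO3]),
              collapse = ", "))
    m <- m[resOK, , drop = FALSE]
  }
  typeNames <- sort(unique(c(paste(m[, 1], m[, 2]), paste(m[, 3], m[, 4]))))
  types <- stats::setNames(seq_along(typeNames), typeNames)
  nt <- length(types)
  nb <- length(edges)
  bin <- as.integer(m[, 5])
  if (any(is.na(bin)) || any(bin < 1) || any(bin > nb))
    stop("scoring-table format error: bin index out of range")
  e <- array(NA_real_, dim = c(nt, nt, nb))
  i <- types[paste(m[, 1], m[, 2])]
  j <- types[paste(m[, 3], m[, 4])]
  val <- as.numeric(m[, 6])
  e[cbind(i, j, bin)] <- val
  e[cbind(j, i, bin)] <- val
  nMissing <- sum(is.na(e))
  if (nMissing > 0) {
    message(nMissing, " of ", length(e), " (type, type, bin) entries ",
            "absent from table; defaulting to 0")
    e[is.na(e)] <- 0
  }
  new("ScoringTable", types = types, binEdges = edges, energies = e,
      name = name)
}

#' Write a scoring table in the loadable text format
#' @param table A \code{ScoringTable}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeScoringTable <- function(table, path) {
  tn <- names(table@types)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("name:", table@name),
               paste("bins:", paste(format(table@binEdges, trim = TRUE),
                                    collapse = " "))), con)
  nt <- length(tn)
  for (i in seq_len(nt)) for (j in i:nt) for (k in seq_along(table@binEdges)) {
    v <- table@energies[i, j, k]
    if (v != 0)
      writeLines(sprintf("%s %s %d %.10g", tn[i], tn[j], k, v), con)
  }
  invisible(path)
}

# map "RESNAME ATOMNAME" atom labels to 0-based type indices (-1 untyped);
# hydrogens are always untyped
atomTypeIndex <- function(structure, table) {
  a <- structure@atoms
  lab <- paste(a$resname, a$name)
  idx <- unname(table@types[lab]) - 1L
  idx[is.na(idx) | a$element == "H"] <- -1L
  as.integer(idx)
}

#' Precomputed scoring context for a receptor/ligand pair
#'
#' Types both molecules against the table alphabet once; untyped atoms
#' (hydrogens, unknown residue/atom names) are skipped and their count
#' reported.
#'
#' @param receptor,ligand \code{Structure} objects.
#' @param table A \code{ScoringTable}.
#' @return A list used by \code{\link{scorePose}} and
#'   \code{\link{runSwarm}}.
#' @export
scoringContext <- function(receptor, ligand, table) {
  rt <- atomTypeIndex(receptor, table)
  lt <- atomTypeIndex(ligand, table)
  nSkip <- sum(rt < 0) + sum(lt < 0)
  if (nSkip > 0)
    message(nSkip, " atom(s) without a table type are excluded from scoring")
  list(receptor = receptor, ligand = ligand, table = table,
       recCoords = structCoords(receptor), recTypes = rt, ligTypes = lt,
       nUntyped = nSkip)
}

#' Raw pair-potential energy of a pose
#'
#' Sum of table energies over all receptor/ligand atom pairs within the
#' table cutoff, each binned by distance. Intra-molecular pairs are never
#' scored; 0 when no pair is in range. Accelerated by a cell grid; equal to
#' the brute-force double loop to numerical precision.
#'
#' @param context A \code{\link{scoringContext}}.
#' @param ligandCoords Posed ligand coordinate matrix (atom order of the
#'   context ligand).
#' @return Raw energy in table units (lower = more favourable).
#' @export
scorePose <- function(context, ligandCoords) {
  stopifnot(all(is.finite(ligandCoords)))
  cpp_score_coords(context$recCoords, context$recTypes,
                   ligandCoords, context$ligTypes,
                   as.numeric(context$table@energies),
                   length(context$table@types), context$table@binEdges)
}

#' Convert an energy to a fitness
#'
#' The optimizer maximizes fitness; energy-like scores are negated so that
#' lower energy means higher fitness.
#'
#' @param energy Raw energy (table units).
#' @return Fitness = -energy.
#' @export
toFitness <- function(energy) -energy

#' Bias a fitness by the restraint-satisfaction fraction
#'
#' Full satisfaction (s = 1) leaves the fitness unchanged; any s < 1
#' strictly worsens a nonzero fitness, continuously in s: positive fitness
#' is scaled by s, negative fitness by (2 - s).
#'
#' @param fitness Fitness value (higher is better).
#' @param s Satisfied fraction of active restraints, in [0, 1].
#' @return Biased fitness.
#' @export
biasScore <- function(fitness, s) {
  if (any(s < 0 | s > 1)) stop("satisfied fraction must lie in [0, 1]")
  ifelse(fitness >= 0, fitness * s, fitness * (2 - s))
}
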
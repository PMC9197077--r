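## Interaction hot-spot statistics: per-atom occurrence frequencies,
## nucleobase face assignment, unique-residue counts and distance
## histograms, aggregated from detailed interaction records (possibly
## pooled over many complexes).

#' Default nucleobase face map
#'
#' Maps the hydrogen-bond-capable base atoms of each nucleotide to the
#' Watson-Crick, Hoogsteen or sugar edge. Atoms shared between edges are
#' assigned to a single face; the table is a documented default, and any
#' user-supplied map of the same shape can replace it.
#'
#' @return Named list (per base letter) of named character vectors
#'   (atom name -> face).
#' @export
defaultFaceMap <- function() {
  list(
    A = c(N1 = "WatsonCrick", N6 = "WatsonCrick", N7 = "Hoogsteen",
          N3 = "Sugar"),
    G = c(N1 = "WatsonCrick", N2 = "WatsonCrick", O6 = "Hoogsteen",
          N7 = "Hoogsteen", N3 = "Sugar"),
    C = c(N3 = "WatsonCrick", N4 = "WatsonCrick", O2 = "Sugar"),
    U = c(N3 = "WatsonCrick", O4 = "WatsonCrick", O2 = "Sugar"),
    T = c(N3 = "WatsonCrick", O4 = "WatsonCrick", O2 = "Sugar"))
}

#' Nucleobase face of a base atom
#'
#' @param base Base letter (A, C, G, U, T).
#' @param atomName Base atom name (e.g. \code{"N7"}).
#' @param facemap Face map as returned by [defaultFaceMap()].
#' @return \code{"WatsonCrick"}, \code{"Hoogsteen"} or \code{"Sugar"}.
#' @examples
#' faceOf("G", "N7")
#' @export
faceOf <- function(base, atomName, facemap = defaultFaceMap()) {
  fm <- facemap[[base]]
  if (is.null(fm) || !atomName %in% names(fm))
    siftStop("siftna_face_error", "no face assignment for %s atom %s",
             base, atomName)
  unname(fm[[atomName]])
}

#' Per-atom interaction statistics
#'
#' Counts interaction records per (residue name, receptor atom,
#' interaction type), pooled over all complexes present in the input, with
#' each count's percentage of its interaction type's total
#' (\code{pct_of_type}) and of its residue name's total
#' (\code{pct_of_residue}). This is the computation behind receptor
#' interaction hot spots (sphere radii proportional to the percentages).
#'
#' @param records data.frame of interaction records (ring records count
#'   under their ring atom label).
#' @return data.frame with columns \code{residue_name}, \code{atom_name},
#'   \code{itype}, \code{count}, \code{pct_of_type}, \code{pct_of_residue}.
#' @export
atomInteractionStats <- function(records) {
  if (!nrow(records))
    return(emptyDf(residue_name = character(), atom_name = character(),
                   itype = character(), count = integer(),
                   pct_of_type = numeric(), pct_of_residue = numeric()))
  key <- paste(records$resname, records$receptorAtoms, records$itype,
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    residue_name = vapply(parts, `[`, "", 1),
    atom_name = vapply(parts, `[`, "", 2),
    itype = vapply(parts, `[`, "", 3),
    count = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL)
  typeTot <- tapply(out$count, out$itype, sum)
  resTot <- tapply(out$count, out$residue_name, sum)
  out$pct_of_type <- 100 * out$count / as.numeric(typeTot[out$itype])
  out$pct_of_residue <- 100 * out$count / as.numeric(resTot[out$residue_name])
  out[order(out$itype, -out$count, out$residue_name, out$atom_name), ,
      drop = FALSE]
}

#' Group-level rollup of interaction statistics
#'
#' Shares of each interaction type carried by the phosphate, sugar and
#' base fragments, computed from the per-atom table.
#'
#' @param records data.frame of interaction records.
#' @return data.frame with \code{itype}, \code{group}, \code{count},
#'   \code{pct}.
#' @export
groupInteractionStats <- function(records) {
  if (!nrow(records))
    return(emptyDf(itype = character(), group = character(),
                   count = integer(), pct = numeric()))
  firstAtom <- vapply(strsplit(records$receptorAtoms, "+", fixed = TRUE),
                      `[`, "", 1)
  grp <- classifyAtomName(sub("^O([123])P$", "OP\\1", firstAtom))
  key <- paste(records$itype, grp, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(itype = vapply(parts, `[`, "", 1),
                    group = vapply(parts, `[`, "", 2),
                    count = as.integer(tab), stringsAsFactors = FALSE,
                    row.names = NULL)
  tot <- tapply(out$count, out$itype, sum)
  out$pct <- 100 * out$count / as.numeric(tot[out$itype])
  out
}

#' Unique-residue interaction counts
#'
#' For each interaction type, the number of distinct residues (identified
#' by complex, chain and residue number) forming at least one interaction
#' of that type — i.e. only one interaction of a given type with a given
#' residue is counted.
#'
#' @param records data.frame of interaction records; an optional
#'   \code{complex} column separates pooled complexes.
#' @return Named integer vector per interaction type.
#' @export
uniqueResidueCounts <- function(records) {
  if (!nrow(records)) return(stats::setNames(integer(0), character(0)))
  cx <- records$complex %||% rep("", nrow(records))
  key <- paste(records$itype, cx, records$chain, records$resno, sep = "\r")
  u <- !duplicated(key)
  tab <- table(records$itype[u])
  stats::setNames(as.integer(tab), names(tab))
}

#' Distance histogram for one interaction type
#'
#' Bins the recorded distances of one interaction type over a fixed range
#' (by default 0 to the type's configured cutoff) with a constant bin
#' width (0.2 Angstrom by default). Counts conserve the number of records
#' inside the range.
#'
#' @param records data.frame of interaction records.
#' @param itype Interaction type to histogram.
#' @param binWidth Bin width in Angstrom.
#' @param range Numeric length-2; defaults to c(0, max cutoff observed
#'   rounded up to a bin edge).
#' @return data.frame with \code{lower}, \code{upper}, \code{count}.
#' @export
distanceHistogram <- function(records, itype, binWidth = 0.2, range = NULL) {
  if (binWidth <= 0)
    siftStop("siftna_usage_error", "binWidth must be positive")
  d <- records$distance[records$itype == itype]
  if (is.null(range)) {
    hi <- if (length(d)) ceiling(max(d) / binWidth) * binWidth else binWidth
    range <- c(0, hi)
  }
  edges <- seq(range[1], range[2], by = binWidth)
  if (utils::tail(edges, 1) < range[2]) edges <- c(edges, range[2])
  counts <- if (length(d))
    as.integer(table(cut(d, edges, include.lowest = TRUE,
                         labels = seq_len(length(edges) - 1))))
  else integer(length(edges) - 1)
  data.frame(lower = edges[-length(edges)], upper = edges[-1], count = counts)
}

#' Pool detail records of many complexes and aggregate hot spots
#'
#' Reads one or more detail TSV files (as written by [writeDetailTSV()]),
#' pools the records with a \code{complex} column naming the source, and
#' returns the per-atom statistics, the group rollup, the unique-residue
#' counts, and total counts per interaction type.
#'
#' @param paths Character vector of detail TSV paths.
#' @return list(records, atoms, groups, uniqueResidues, totals).
#' @export
surveyInteractions <- function(paths) {
  recs <- do.call(rbind, lapply(paths, function(p) {
    tab <- utils::read.table(p, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!nrow(tab)) return(NULL)
    data.frame(itype = tab$interaction_type, subtype = tab$subtype,
               chain = as.character(tab$chain), resno = tab$residue_number,
               resname = as.character(tab$residue_name),
               receptorAtoms = tab$receptor_atoms,
               distance = as.numeric(tab$distance),
               complex = basename(p), stringsAsFactors = FALSE)
  }))
  if (is.null(recs)) recs <- cbind(emptyRecords(), complex = character(0))
  list(records = recs,
       atoms = atomInteractionStats(recs),
       groups = groupInteractionStats(recs),
       uniqueResidues = uniqueResidueCounts(recs),
       totals = if (nrow(recs)) table(recs$itype) else table(character(0)))
}
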
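## Feature perception: interaction-capable atoms and rings on ligand
## records (through OpenBabel perception + SMARTS) and on receptor
## residues (through canonical nucleotide tables, with a geometric
## fallback for modified residues).

featureDf <- function(atoms, idx) {
  if (!length(idx))
    return(emptyDf(idx = integer(), name = character(),
                   x = numeric(), y = numeric(), z = numeric()))
  data.frame(idx = as.integer(idx), name = atoms$name[idx],
             x = atoms$x[idx], y = atoms$y[idx], z = atoms$z[idx],
             stringsAsFactors = FALSE)
}

emptyFeatureSet <- local({
  proto <- NULL
  function() {
    if (is.null(proto)) proto <<- emptyFeatureSetBuild()
    proto
  }
})

emptyFeatureSetBuild <- function() {
  new("FeatureSet",
      donors = featureDf(NULL, integer(0)),
      donorH = emptyDf(donorIdx = integer(), x = numeric(), y = numeric(),
                       z = numeric()),
      acceptors = emptyDf(idx = integer(), name = character(), x = numeric(),
                          y = numeric(), z = numeric(), nx = numeric(),
                          ny = numeric(), nz = numeric(), hasNbr = logical()),
      halogenDonors = emptyDf(idx = integer(), name = character(),
                              x = numeric(), y = numeric(), z = numeric(),
                              cx = numeric(), cy = numeric(), cz = numeric()),
      cations = featureDf(NULL, integer(0)),
      anions = featureDf(NULL, integer(0)),
      rings = list(),
      lipophilic = featureDf(NULL, integer(0)))
}

## neighbour lookup from a bond table
bondNeighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Perceive interaction features of a ligand record
#'
#' Identifies hydrogen-bond donors (N/O/S bearing at least one hydrogen,
#' with explicit hydrogen positions when present), acceptors (O and N with
#' a free lone pair; positively charged, quaternary, amide and pyrrole
#' nitrogens excluded), halogen-bond donors (C-Cl/Br/I pairs; fluorine's
#' sigma-hole is too weak and is excluded), charged centres (formal
#' charges, plus bare metal atoms as cations), aromatic rings of size 5-6
#' (fused systems decomposed into SSSR rings, each with centroid and
#' best-fit normal), and lipophilic atoms (C/S bonded only to C, H, S or
#' halogen). The donor/acceptor/lipophilic definitions are SMARTS patterns
#' in the [GeometryConfig-class] and can be overridden.
#'
#' @param x A [Ligand-class] object.
#' @param cfg A [GeometryConfig-class] supplying the perception SMARTS.
#' @return A [FeatureSet-class] object.
#' @examples
#' lig <- readLigands(probeLigandSDF("benzene"))[[1]]
#' perceiveFeatures(lig)
#' @export
perceiveFeatures <- function(x, cfg = geometryConfig()) {
  stopifnot(is(x, "Ligand"))
  atoms <- x@atoms
  bonds <- x@bonds
  nb <- bondNeighbors(bonds, nrow(atoms))
  heavyNb <- lapply(nb, function(v) v[!atoms$isH[v]])
  hNb <- lapply(nb, function(v) v[atoms$isH[v]])

  ## one OpenBabel parse serves every SMARTS query and ring perception
  queries <- withOBMol(x@molBlock, "SDF", function(m) {
    list(donor = obSmartsMatch(m, cfg@hb_donor_smarts),
         acceptor = obSmartsMatch(m, cfg@hb_acceptor_smarts),
         halogen = obSmartsMatch(m, "[#6][Cl,Br,I]"),
         lipophilic = obSmartsMatch(m, cfg@lipophilic_smarts),
         rings = obMolRings(m))
  })
  matched <- function(maps, pos = 1L)
    sort(unique(vapply(maps, `[`, 0L, pos)))

  donorIdx <- matched(queries$donor)
  donorH <- do.call(rbind, c(list(emptyDf(donorIdx = integer(), x = numeric(),
                                          y = numeric(), z = numeric())),
    lapply(donorIdx, function(i) {
      hs <- hNb[[i]]
      if (!length(hs)) return(NULL)
      data.frame(donorIdx = i, x = atoms$x[hs], y = atoms$y[hs], z = atoms$z[hs])
    })))
  accIdx <- matched(queries$acceptor)
  acceptors <- featureDf(atoms, accIdx)
  if (nrow(acceptors)) {
    nbr <- vapply(accIdx, function(i)
      if (length(heavyNb[[i]])) heavyNb[[i]][1] else NA_integer_, 0L)
    acceptors$nx <- ifelse(is.na(nbr), NA_real_, atoms$x[nbr])
    acceptors$ny <- ifelse(is.na(nbr), NA_real_, atoms$y[nbr])
    acceptors$nz <- ifelse(is.na(nbr), NA_real_, atoms$z[nbr])
    acceptors$hasNbr <- !is.na(nbr)
  } else {
    acceptors <- emptyFeatureSet()@acceptors
  }
  halMaps <- queries$halogen
  halogenDonors <- if (length(halMaps)) {
    do.call(rbind, lapply(halMaps, function(mm) {
      cI <- mm[1]; xI <- mm[2]
      data.frame(idx = xI, name = atoms$name[xI], x = atoms$x[xI],
                 y = atoms$y[xI], z = atoms$z[xI], cx = atoms$x[cI],
                 cy = atoms$y[cI], cz = atoms$z[cI], stringsAsFactors = FALSE)
    }))
  } else emptyFeatureSet()@halogenDonors
  catIdx <- which(atoms$charge > 0 |
                    (!atoms$isH & atoms$element %in% cfg@metal_set))
  anIdx <- which(atoms$charge < 0)
  lipIdx <- setdiff(matched(queries$lipophilic), c(catIdx, anIdx))
  rings <- Filter(function(r) r$aromatic && length(r$members) %in% c(5, 6),
                  queries$rings %||% list())
  rings <- lapply(rings, function(r) {
    m <- sort(r$members)
    geo <- ringGeometry(as.matrix(atoms[m, c("x", "y", "z")]))
    list(members = m, names = atoms$name[m],
         centroid = geo$centroid, normal = geo$normal)
  })
  new("FeatureSet",
      donors = featureDf(atoms, donorIdx),
      donorH = donorH,
      acceptors = acceptors,
      halogenDonors = halogenDonors,
      cations = featureDf(atoms, catIdx),
      anions = featureDf(atoms, anIdx),
      rings = rings,
      lipophilic = featureDf(atoms, lipIdx))
}

#' Centroid and best-fit plane normal of a ring
#'
#' The centroid is the coordinate mean; the normal is the unit eigenvector
#' of the smallest covariance eigenvalue (best-fit plane). The sign of the
#' normal carries no meaning: all angle criteria fold to \code{[0, 90]}
#' degrees.
#'
#' @param coords Numeric matrix (>= 3 rows, 3 columns) of atom positions.
#' @return list(centroid, normal).
#' @examples
#' hexagon <- cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6), 0)
#' ringGeometry(hexagon)
#' @export
ringGeometry <- function(coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) < 3)
    siftStop("siftna_geometry_error", "need at least 3 atoms for a ring plane")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    siftStop("siftna_geometry_error", "ring atoms are collinear")
  list(centroid = centroid, normal = unit(sv$v[, 3]))
}

#' SMARTS substructure matches in a ligand
#'
#' Matches a SMARTS pattern against a ligand record through OpenBabel and
#' returns all unique matches, each a 1-based atom index tuple in pattern
#' atom order, deterministically ordered by first atom index.
#'
#' @param x A [Ligand-class] object.
#' @param pattern A SMARTS string.
#' @return List of integer vectors (possibly empty).
#' @examples
#' lig <- readLigands(probeLigandSDF("methanol"))[[1]]
#' matchSmarts(lig, "[OX2H]")
#' @export
matchSmarts <- function(x, pattern) {
  stopifnot(is(x, "Ligand"))
  withOBMol(x@molBlock, "SDF", function(m) obSmartsMatch(m, pattern))
}

#' SMARTS substructure matches in a receptor residue
#'
#' For canonical nucleotides the residue is rebuilt as a molecule with its
#' known topology and the phosphodiester charge, so SMARTS semantics
#' (valence, aromaticity, charge) are well defined; modified residues fall
#' back to OpenBabel's PDB bond perception. Returned indices are row
#' numbers of [residueAtoms()].
#'
#' @param receptor A [Receptor-class] object.
#' @param number Residue number.
#' @param pattern A SMARTS string.
#' @return List of integer vectors (possibly empty).
#' @export
matchResidueSmarts <- function(receptor, number, pattern) {
  atoms <- residueAtoms(receptor, number)
  base <- normalizeBaseName(atoms$resname[1])
  if (!is.na(base)) {
    block <- residueMolBlock(atoms, base)
    withOBMol(block, "SDF", function(m) obSmartsMatch(m, pattern))
  } else {
    rec <- new("Receptor", atoms = atoms,
               waters = emptyReceptorAtoms(), ions = emptyReceptorAtoms(),
               sourcePath = "")
    txt <- paste(writeReceptorPDB(rec), collapse = "\n")
    withOBMol(txt, "PDB", function(m) obSmartsMatch(m, pattern))
  }
}

emptyReceptorAtoms <- function() {
  emptyDf(serial = integer(), name = character(), element = character(),
          x = numeric(), y = numeric(), z = numeric(), chain = character(),
          resno = integer(), resname = character(), isH = logical(),
          group = character())
}

## ---------------------------------------------------------------------------
## Receptor residue features

## Nucleobase rings are treated as aromatic planar systems; purines
## contribute their 5- and 6-membered rings separately. OP1/OP2 (and a
## 5'-terminal OP3) are anions regardless of recorded charge. The
## lipophilic rule on the receptor side admits carbons with at most one
## single-bonded N/O neighbour and no multiple bond to oxygen (ribose
## C2'-C5', pyrimidine C5/C6, thymine methyl).
residueFeatures <- function(receptor, number, cfg = geometryConfig()) {
  atoms <- residueAtoms(receptor, number)
  rownames(atoms) <- NULL
  base <- normalizeBaseName(atoms$resname[1])
  heavy <- which(!atoms$isH)
  byName <- function(nms) which(atoms$name %in% nms & !atoms$isH)
  if (!is.na(base)) {
    topo <- nucleotideTopology(base)
    donorNames <- intersect(c(BASE_HB[[base]]$donors, SUGAR_DONORS), atoms$name)
    ## terminal hydroxyls (3'-OH, 5'-OH, protonated OP3) donate when their
    ## hydrogen is present
    oxy <- which(!atoms$isH & atoms$element == "O" &
                   !atoms$name %in% donorNames)
    donorNames <- c(donorNames,
                    atoms$name[oxy][vapply(oxy, function(i)
                      anyHWithin(atoms, i), TRUE)])
    accNames <- intersect(c(BASE_HB[[base]]$acceptors, SUGAR_ACCEPTORS), atoms$name)
    anionNames <- intersect(PHOSPHATE_ANIONS, atoms$name)
    ringDefs <- baseRings(base)
    lipNames <- receptorLipophilicNames(atoms$name, topo)
    nbrOf <- function(nm) {
      cand <- c(topo$b[topo$a == nm], topo$a[topo$b == nm])
      cand <- cand[!startsWith(cand, "H")]
      cand[cand %in% atoms$name][1] %||% NA_character_
    }
  } else {
    ## modified residue fallback: geometric typing by element/name
    donorNames <- atoms$name[heavy][atoms$element[heavy] %in% c("N", "O") &
      vapply(heavy, function(i) anyHWithin(atoms, i), TRUE)]
    accNames <- atoms$name[heavy][atoms$element[heavy] %in% c("N", "O")]
    anionNames <- intersect(PHOSPHATE_ANIONS, atoms$name)
    ringDefs <- list()
    lipNames <- character(0)
    nbrOf <- function(nm) {
      i <- which(atoms$name == nm)[1]
      d <- crossDist(as.matrix(atoms[i, c("x", "y", "z")]),
                     as.matrix(atoms[heavy, c("x", "y", "z")]))
      ord <- order(d)
      cand <- heavy[ord][d[ord] > 0.1 & d[ord] < 1.8][1]
      if (is.na(cand)) NA_character_ else atoms$name[cand]
    }
  }
  donIdx <- byName(donorNames)
  donorH <- do.call(rbind, c(
    list(emptyDf(donorIdx = integer(), x = numeric(), y = numeric(), z = numeric())),
    lapply(donIdx, function(i) {
      hs <- which(atoms$isH)
      if (!length(hs)) return(NULL)
      d <- crossDist(as.matrix(atoms[hs, c("x", "y", "z")]),
                     as.matrix(atoms[i, c("x", "y", "z")]))
      hs <- hs[d[, 1] < 1.25]
      if (!length(hs)) return(NULL)
      data.frame(donorIdx = i, x = atoms$x[hs], y = atoms$y[hs], z = atoms$z[hs])
    })))
  accIdx <- byName(accNames)
  acceptors <- featureDf(atoms, accIdx)
  if (nrow(acceptors)) {
    nbrName <- vapply(acceptors$name, nbrOf, "")
    nbrRow <- match(nbrName, atoms$name)
    acceptors$nx <- atoms$x[nbrRow]; acceptors$ny <- atoms$y[nbrRow]
    acceptors$nz <- atoms$z[nbrRow]
    acceptors$hasNbr <- !is.na(nbrRow)
  } else acceptors <- emptyFeatureSet()@acceptors
  rings <- list()
  for (rd in ringDefs) {
    idx <- match(rd$names, atoms$name)
    if (anyNA(idx)) next
    geo <- ringGeometry(as.matrix(atoms[idx, c("x", "y", "z")]))
    rings[[length(rings) + 1]] <- list(members = idx, names = rd$names,
                                       centroid = geo$centroid,
                                       normal = geo$normal)
  }
  new("FeatureSet",
      donors = featureDf(atoms, donIdx),
      donorH = donorH,
      acceptors = acceptors,
      halogenDonors = emptyFeatureSet()@halogenDonors,
      cations = featureDf(atoms, integer(0)),
      anions = featureDf(atoms, byName(anionNames)),
      rings = rings,
      lipophilic = featureDf(atoms, byName(lipNames)))
}

anyHWithin <- function(atoms, i, rmax = 1.25) {
  hs <- which(atoms$isH)
  if (!length(hs)) return(FALSE)
  d <- crossDist(as.matrix(atoms[hs, c("x", "y", "z")]),
                 as.matrix(atoms[i, c("x", "y", "z")]))
  any(d < rmax)
}

receptorLipophilicNames <- function(present, topo) {
  carbons <- grep("^C", present, value = TRUE)
  carbons <- setdiff(carbons, "C1'")
  keep <- vapply(carbons, function(nm) {
    rows <- topo$a == nm | topo$b == nm
    other <- ifelse(topo$a[rows] == nm, topo$b[rows], topo$a[rows])
    ord <- topo$order[rows]
    het <- grepl("^[NO]", other)
    if (any(het & ord > 1)) return(FALSE)
    sum(het) <= 1
  }, TRUE)
  carbons[keep]
}
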
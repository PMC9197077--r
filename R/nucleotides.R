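## Canonical nucleotide chemistry: atom-name group rules, base topology
## (bonds in Kekule form), donor/acceptor tables, and idealized 3D
## templates used by the probe-complex generator and for rebuilding a
## residue as a mol block for SMARTS matching.

PHOSPHATE_NAMES <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
                     "O5'", "O3'")
SUGAR_NAMES <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'")

## Map residue names (incl. common PDB variants) to one-letter base codes.
normalizeBaseName <- function(resname) {
  up <- toupper(resname)
  map <- c(A = "A", ADE = "A", DA = "A", RA = "A", "A5" = "A", "A3" = "A",
           C = "C", CYT = "C", DC = "C", RC = "C",
           G = "G", GUA = "G", DG = "G", RG = "G",
           U = "U", URA = "U", URI = "U", RU = "U",
           T = "T", THY = "T", DT = "T")
  unname(map[up])
}

isPurine <- function(base) base %in% c("A", "G")

## Kekule bond list for base + sugar + 5'-phosphate of each nucleotide.
## Orders: 1 single, 2 double. Hydrogens bond to their parent heavy atom.
nucleotideTopology <- function(base) {
  sugar <- list(
    c("P", "OP1", 1), c("P", "OP2", 2), c("P", "O5'", 1),
    c("O5'", "C5'", 1), c("C5'", "C4'", 1), c("C4'", "C3'", 1),
    c("C4'", "O4'", 1), c("O4'", "C1'", 1), c("C3'", "O3'", 1),
    c("C3'", "C2'", 1), c("C2'", "C1'", 1), c("C2'", "O2'", 1),
    c("O2'", "HO2'", 1), c("O3'", "HO3'", 1),
    c("C1'", "H1'", 1), c("C2'", "H2'", 1), c("C3'", "H3'", 1),
    c("C4'", "H4'", 1), c("C5'", "H5'", 1), c("C5'", "H5''", 1)
  )
  bb <- switch(base,
    A = list(c("N1", "C6", 2), c("C6", "C5", 1), c("C5", "C4", 2),
             c("C4", "N3", 1), c("N3", "C2", 2), c("C2", "N1", 1),
             c("C5", "N7", 1), c("N7", "C8", 2), c("C8", "N9", 1),
             c("N9", "C4", 1), c("C6", "N6", 1), c("C1'", "N9", 1),
             c("N6", "H61", 1), c("N6", "H62", 1), c("C2", "H2", 1),
             c("C8", "H8", 1)),
    G = list(c("C6", "O6", 2), c("C6", "N1", 1), c("N1", "C2", 1),
             c("C2", "N3", 2), c("N3", "C4", 1), c("C4", "C5", 2),
             c("C5", "C6", 1), c("C5", "N7", 1), c("N7", "C8", 2),
             c("C8", "N9", 1), c("N9", "C4", 1), c("C2", "N2", 1),
             c("C1'", "N9", 1), c("N1", "H1", 1), c("N2", "H21", 1),
             c("N2", "H22", 1), c("C8", "H8", 1)),
    C = list(c("C2", "O2", 2), c("C2", "N1", 1), c("C2", "N3", 1),
             c("N3", "C4", 2), c("C4", "N4", 1), c("C4", "C5", 1),
             c("C5", "C6", 2), c("C6", "N1", 1), c("C1'", "N1", 1),
             c("N4", "H41", 1), c("N4", "H42", 1), c("C5", "H5", 1),
             c("C6", "H6", 1)),
    U = list(c("C2", "O2", 2), c("C2", "N1", 1), c("C2", "N3", 1),
             c("N3", "C4", 1), c("C4", "O4", 2), c("C4", "C5", 1),
             c("C5", "C6", 2), c("C6", "N1", 1), c("C1'", "N1", 1),
             c("N3", "H3", 1), c("C5", "H5", 1), c("C6", "H6", 1)),
    T = list(c("C2", "O2", 2), c("C2", "N1", 1), c("C2", "N3", 1),
             c("N3", "C4", 1), c("C4", "O4", 2), c("C4", "C5", 1),
             c("C5", "C6", 2), c("C6", "N1", 1), c("C5", "C7", 1),
             c("C1'", "N1", 1), c("N3", "H3", 1), c("C6", "H6", 1),
             c("C7", "H71", 1), c("C7", "H72", 1), c("C7", "H73", 1)),
    siftStop("siftna_unsupported_residue_error", "unknown base: %s", base))
  bonds <- do.call(rbind, lapply(c(sugar, bb), function(b)
    data.frame(a = b[1], b = b[2], order = as.integer(b[3]),
               stringsAsFactors = FALSE)))
  bonds
}

## Hydrogen-bonding tables per base letter. Acceptor neighbour (for halogen
## acceptor angles) is derived from the topology at perception time.
BASE_HB <- list(
  A = list(donors = "N6", acceptors = c("N1", "N3", "N7")),
  G = list(donors = c("N1", "N2"), acceptors = c("N3", "N7", "O6")),
  C = list(donors = "N4", acceptors = c("N3", "O2")),
  U = list(donors = "N3", acceptors = c("O2", "O4")),
  T = list(donors = "N3", acceptors = c("O2", "O4"))
)

SUGAR_ACCEPTORS <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2", "OP3")
SUGAR_DONORS <- "O2'"
PHOSPHATE_ANIONS <- c("OP1", "OP2", "OP3")

baseRings <- function(base) {
  if (isPurine(base))
    list(list(names = c("N1", "C2", "N3", "C4", "C5", "C6")),
         list(names = c("C4", "C5", "N7", "C8", "N9")))
  else
    list(list(names = c("N1", "C2", "N3", "C4", "C5", "C6")))
}

#' Classify a nucleotide atom name into its structural group
#'
#' Phosphate: P, OP1/OP2/OP3 (and O1P/O2P/O3P variants) plus the bridging
#' O5' and O3'; sugar: C1'-C5', O4', O2'; all remaining heavy-atom names of
#' nucleobase shape go to BASE. The rule is name-based, not a residue
#' whitelist, so standard-named modified nucleotides classify without a
#' dictionary.
#'
#' @param name PDB atom name(s).
#' @return Character vector of \code{"PHOSPHATE"}, \code{"SUGAR"},
#'   \code{"BASE"}; signals an error for names matching no rule.
#' @examples
#' classifyAtomName(c("OP1", "C2'", "N7"))
#' @export
classifyAtomName <- function(name) {
  grp <- ifelse(name %in% PHOSPHATE_NAMES, "PHOSPHATE",
         ifelse(name %in% SUGAR_NAMES, "SUGAR", NA_character_))
  rest <- is.na(grp)
  baseLike <- grepl("^[CNOS][0-9]{1,2}[A-Z]?$", name) & rest
  grp[baseLike] <- "BASE"
  bad <- is.na(grp)
  if (any(bad))
    siftStop("siftna_unclassifiable_atom_error",
             "cannot classify atom name(s): %s",
             paste(unique(name[bad]), collapse = ", "))
  grp
}

## ---------------------------------------------------------------------------
## Idealized 3D templates

regularPolygon <- function(n, side) {
  r <- side / (2 * sin(pi / n))
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(r * cos(ang), r * sin(ang), 0)
}

## Fuse a regular pentagon onto edge (p1, p2), on the side away from `away`.
fusePentagon <- function(p1, p2, away) {
  s <- vnorm(p2 - p1)
  mid <- (p1 + p2) / 2
  perp <- unit(pracmaCross(p2 - p1, c(0, 0, 1)))
  if (sum(perp * (away - mid)) > 0) perp <- -perp
  apo <- s / (2 * tan(pi / 5))
  circ <- s / (2 * sin(pi / 5))
  center <- mid + apo * perp
  edgeAng <- atan2(p1[2] - center[2], p1[1] - center[1])
  endAng <- atan2(p2[2] - center[2], p2[1] - center[1])
  dd <- endAng - edgeAng
  dd <- atan2(sin(dd), cos(dd))
  step <- -sign(dd) * 2 * pi / 5
  pts <- sapply(1:3, function(k) {
    a <- edgeAng + step * k
    center + circ * c(cos(a), sin(a), 0)
  })
  t(pts)
}

#' Idealized nucleotide template coordinates
#'
#' Builds a chemically sensible single 5'-phosphate nucleotide with
#' canonical atom names and explicit hydrogens: the base as an idealized
#' planar polygon in the z = 0 plane (normal +z; the +z half-space is kept
#' free for ring-face probes), the ribose below it, and the phosphate group
#' with OP1 pointing into open space. Geometry is idealized (planar rings,
#' standard bond lengths), not energy-minimized.
#'
#' @param base One of \code{"A"}, \code{"C"}, \code{"G"}, \code{"U"}, \code{"T"}.
#' @return data.frame with columns \code{name}, \code{element},
#'   \code{x}, \code{y}, \code{z}.
#' @examples
#' g <- nucleotideTemplate("G")
#' @export
nucleotideTemplate <- function(base) {
  if (!base %in% c("A", "C", "G", "U", "T"))
    siftStop("siftna_unsupported_residue_error", "unknown base: %s", base)
  side <- 1.39
  hex <- regularPolygon(6, side)
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  coords <- list()
  for (nm in rownames(hex)) coords[[nm]] <- hex[nm, ]
  hexCenter <- colMeans(hex)
  if (isPurine(base)) {
    pent <- fusePentagon(coords$C5, coords$C4, hexCenter)
    coords$N7 <- pent[1, ]; coords$C8 <- pent[2, ]; coords$N9 <- pent[3, ]
  }
  outward <- function(atom, center = hexCenter, len = 1.35)
    coords[[atom]] + len * unit(coords[[atom]] - center)
  ## exocyclic substituents, radially outward in the base plane
  glyN <- if (isPurine(base)) "N9" else "N1"
  if (base == "A") { coords$N6 <- outward("C6") }
  if (base == "G") { coords$O6 <- outward("C6", len = 1.23); coords$N2 <- outward("C2") }
  if (base == "C") { coords$O2 <- outward("C2", len = 1.23); coords$N4 <- outward("C4") }
  if (base %in% c("U", "T")) {
    coords$O2 <- outward("C2", len = 1.23); coords$O4 <- outward("C4", len = 1.23)
  }
  if (base == "T") coords$C7 <- outward("C5", len = 1.50)
  ## base hydrogens: on ring CH/NH radially outward; NH2 as a split pair
  inPlaneRot <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], v[3])
  }
  addH2 <- function(parent, h1, h2) {
    d <- unit(coords[[parent]] - hexCenter)
    coords[[h1]] <<- coords[[parent]] + 1.01 * inPlaneRot(d, 60)
    coords[[h2]] <<- coords[[parent]] + 1.01 * inPlaneRot(d, -60)
  }
  addH1 <- function(parent, h, len = 1.01, center = hexCenter)
    coords[[h]] <<- coords[[parent]] + len * unit(coords[[parent]] - center)
  if (base == "A") { addH2("N6", "H61", "H62"); addH1("C2", "H2", 1.08); addH1("C8", "H8", 1.08) }
  if (base == "G") { addH1("N1", "H1"); addH2("N2", "H21", "H22"); addH1("C8", "H8", 1.08) }
  if (base == "C") { addH2("N4", "H41", "H42"); addH1("C5", "H5", 1.08); addH1("C6", "H6", 1.08) }
  if (base == "U") { addH1("N3", "H3"); addH1("C5", "H5", 1.08); addH1("C6", "H6", 1.08) }
  if (base == "T") {
    addH1("N3", "H3"); addH1("C6", "H6", 1.08)
    d <- unit(coords$C7 - coords$C5)
    coords$H71 <- coords$C7 + 1.09 * unit(d + c(0, 0, 0.9))
    coords$H72 <- coords$C7 + 1.09 * unit(d + c(0, 0, -0.9))
    coords$H73 <- coords$C7 + 1.09 * unit(inPlaneRot(d, 75))
  }
  ## ribose: regular pentagon parallel to the base plane, 1.45 A below the
  ## glycosidic nitrogen; C1' sits directly under it
  gly <- coords[[glyN]]
  away <- unit(c((gly - hexCenter)[1:2], 0))
  p5 <- regularPolygon(5, 1.45)
  cent5 <- gly + 1.233 * away + c(0, 0, -1.45)
  ring5names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  start <- gly + c(0, 0, -1.45)
  ang0 <- atan2(start[2] - cent5[2], start[1] - cent5[1])
  r5 <- 1.45 / (2 * sin(pi / 5))
  for (k in seq_along(ring5names)) {
    a <- ang0 + (k - 1) * 2 * pi / 5
    coords[[ring5names[k]]] <- cent5 + c(r5 * cos(a), r5 * sin(a), 0)
  }
  sugarOut <- function(atom, len) coords[[atom]] + len * unit(coords[[atom]] - cent5)
  coords[["O2'"]] <- sugarOut("C2'", 1.41) + c(0, 0, -0.45)
  coords[["O3'"]] <- sugarOut("C3'", 1.42) + c(0, 0, -0.45)
  coords[["HO2'"]] <- coords[["O2'"]] + 0.97 * unit(coords[["O2'"]] - coords[["C2'"]])
  coords[["HO3'"]] <- coords[["O3'"]] + 0.97 * unit(coords[["O3'"]] - coords[["C3'"]])
  for (h in c("H1'", "H2'", "H3'", "H4'")) {
    parent <- paste0("C", substr(h, 2, 2), "'")
    coords[[h]] <- coords[[parent]] + 1.09 * c(0, 0, -1) +
      0.35 * unit(coords[[parent]] - cent5)
    coords[[h]] <- coords[[parent]] + 1.09 * unit(coords[[h]] - coords[[parent]])
  }
  ## exocyclic C5' and the phosphate chain, stepping away from the sugar
  c4 <- coords[["C4'"]]
  dir5 <- unit(unit(c4 - cent5) + c(0, 0, -0.8))
  coords[["C5'"]] <- c4 + 1.51 * dir5
  coords[["H5'"]] <- coords[["C5'"]] + 1.09 * unit(c(0, 0, 1) + 0.3 * unit(c4 - cent5))
  coords[["H5''"]] <- coords[["C5'"]] + 1.09 * unit(pracmaCross(dir5, c(0, 0, 1)))
  coords[["O5'"]] <- coords[["C5'"]] + 1.44 * unit(unit(c4 - cent5) + c(0, 0, -1.6))
  coords[["P"]] <- coords[["O5'"]] + 1.60 * unit(unit(c4 - cent5) + c(0, 0, -1.2))
  pdir <- unit(c((coords[["P"]] - cent5)[1:2], 0))
  coords[["OP1"]] <- coords[["P"]] + 1.48 * pdir
  coords[["OP2"]] <- coords[["P"]] + 1.48 * unit(pracmaCross(pdir, c(0, 0, 1)) - c(0, 0, 0.7))
  nm <- names(coords)
  data.frame(name = nm,
             element = ifelse(startsWith(nm, "H"), "H", substr(nm, 1, 1)),
             x = round(vapply(coords, `[`, 0, 1), 3),
             y = round(vapply(coords, `[`, 0, 2), 3),
             z = round(vapply(coords, `[`, 0, 3), 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

## V2000 mol block for a residue whose atoms follow canonical naming.
## Bonds come from the canonical topology (restricted to atoms present);
## OP1 carries the formal -1 of the phosphodiester. Used to rebuild a
## residue as a molecule for SMARTS matching.
residueMolBlock <- function(atoms, base) {
  topo <- nucleotideTopology(base)
  idx <- stats::setNames(seq_len(nrow(atoms)), atoms$name)
  keep <- topo$a %in% atoms$name & topo$b %in% atoms$name
  topo <- topo[keep, , drop = FALSE]
  lines <- c("residue", "  SIFtNA", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(atoms), nrow(topo)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            atoms$x, atoms$y, atoms$z, atoms$element))
  if (nrow(topo))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              idx[topo$a], idx[topo$b], topo$order))
  if ("OP1" %in% atoms$name)
    lines <- c(lines, sprintf("M  CHG  1 %3d  -1", idx[["OP1"]]))
  lines <- c(lines, "M  END", "$$$$", "")
  paste(lines, collapse = "\n")
}
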
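## Synthetic probe complexes: a nucleotide receptor template plus a
## minimal ligand (methanol, ammonium, benzene, chlorobenzene, acetate,
## methane) placed at an exactly specified geometry, emitted in the same
## PDB/SDF dialects the parsers read. Probes make every detector testable
## without external structures. The hydrogen-bond probe approaches the
## receptor donor along the +x axis so that its defining distance survives
## the PDB three-decimal format exactly; other defining quantities are
## reproduced from the emitted files to within the format precision
## (~2e-3 Angstrom / 0.05 degree), and exactly in the returned in-memory
## geometry.

PROBE_ITYPES <- c(FULL_CHANNELS, "Contact")

## per-base probe sites: donor (with its hydrogen), acceptor
PROBE_SITES <- list(
  A = list(donor = c("N6", "H61"), acceptor = "N1"),
  G = list(donor = c("N1", "H1"), acceptor = "N7"),
  C = list(donor = c("N4", "H41"), acceptor = "N3"),
  U = list(donor = c("N3", "H3"), acceptor = "O4"),
  T = list(donor = c("N3", "H3"), acceptor = "O4"))

#' Specification of a synthetic probe complex
#'
#' Describes the interaction geometry a probe complex must realize: the
#' channel, the defining distance, optional angle/offset, the mediator
#' element for mediated channels, and the receptor template (one or more
#' nucleotide letters; two letters give a dinucleotide).
#'
#' @param itype One of the twelve FULL channels or \code{"Contact"}.
#' @param distance Defining distance in Angstrom (> 0). For mediated
#'   channels this is the receptor-side leg.
#' @param angle Optional defining angle in degrees, in \code{[0, 180]}:
#'   the D-H...A angle (HB), the normal angle (Pi-ion), or the interplanar
#'   angle (Pi-stacking).
#' @param offset In-plane centroid offset for Pi-stacking (Angstrom).
#' @param mediator Element of the mediating species (default by channel;
#'   \code{"HOH"} for water).
#' @param distance2 Ligand-side leg for mediated channels (defaults to
#'   \code{distance}).
#' @param receptorTemplate Character vector of base letters (default "G").
#' @param targetResidue Residue (1-based) the probe is placed against.
#' @param direction For hydrogen bonds, \code{"receptor_donor"} or
#'   \code{"ligand_donor"}.
#' @return A validated probe specification (list).
#' @examples
#' probeSpec("HB", distance = 3.9)
#' @export
probeSpec <- function(itype, distance, angle = NULL, offset = NULL,
                      mediator = NULL, distance2 = NULL,
                      receptorTemplate = "G", targetResidue = 1L,
                      direction = c("receptor_donor", "ligand_donor")) {
  direction <- match.arg(direction)
  if (!itype %in% PROBE_ITYPES)
    siftStop("siftna_spec_error", "unknown probe channel: %s", itype)
  if (!is.numeric(distance) || distance <= 0)
    siftStop("siftna_spec_error", "distance must be positive")
  if (!is.null(angle) && (angle < 0 || angle > 180))
    siftStop("siftna_spec_error", "angle must lie in [0, 180]")
  if (!is.null(offset) && offset < 0)
    siftStop("siftna_spec_error", "offset must be non-negative")
  if (!all(receptorTemplate %in% c("A", "C", "G", "U", "T")))
    siftStop("siftna_spec_error", "receptor template bases must be A/C/G/U/T")
  if (targetResidue < 1 || targetResidue > length(receptorTemplate))
    siftStop("siftna_spec_error", "targetResidue outside template")
  if (itype == "PiStacking" && !is.null(offset) && offset > distance)
    siftStop("siftna_spec_error",
             "offset cannot exceed the centroid distance")
  if (itype == "Water_mediated" && !is.null(mediator) && mediator != "HOH")
    siftStop("siftna_spec_error",
             "water-mediated probes require mediator HOH")
  if (itype %in% c("Mg_mediated", "K_mediated", "Na_mediated",
                   "OtherMetal_mediated", "Water_mediated")) {
    mediator <- mediator %||% switch(itype,
      Mg_mediated = "Mg", K_mediated = "K", Na_mediated = "Na",
      OtherMetal_mediated = "Zn", Water_mediated = "HOH")
  }
  list(itype = itype, distance = distance, angle = angle, offset = offset,
       mediator = mediator, distance2 = distance2 %||% distance,
       receptorTemplate = receptorTemplate,
       targetResidue = as.integer(targetResidue), direction = direction)
}

orthonormalBasis <- function(w, psi = 0) {
  w <- unit(w)
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(pracmaCross(ref, w))
  v <- pracmaCross(w, u)
  list(u = cos(psi) * u + sin(psi) * v,
       v = -sin(psi) * u + cos(psi) * v,
       w = w)
}

## place point P at |P - from| = dist with angle(ref, vertex, P) = ang;
## `perp` is orthogonalized against the reference direction first
placeAtAngle <- function(vertex, refDir, perp, dist, ang, from = vertex) {
  refDir <- unit(refDir)
  perp <- perp - sum(perp * refDir) * refDir
  v <- cos(ang * pi / 180) * refDir + sin(ang * pi / 180) * unit(perp)
  if (identical(from, vertex)) return(vertex + dist * v)
  ## solve |vertex + t v - from| = dist for t > 0
  h <- vertex - from
  b <- sum(h * v)
  disc <- b * b - (sum(h * h) - dist * dist)
  if (disc < 0)
    siftStop("siftna_spec_error", "requested geometry is not realizable")
  t <- -b + sqrt(disc)
  if (t <= 0)
    siftStop("siftna_spec_error", "requested geometry is not realizable")
  vertex + t * v
}

## minimal ligand builders ---------------------------------------------------

ligandAtomsDf <- function(el, pos, charge = NULL) {
  pos <- do.call(rbind, pos)
  data.frame(element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             charge = charge %||% rep(0L, length(el)),
             stringsAsFactors = FALSE)
}

buildMethanol <- function(oPos, awayDir, hDir, basis) {
  awayDir <- unit(awayDir)
  cPos <- oPos + 1.43 * awayDir
  hO <- oPos + 0.96 * unit(hDir)
  hC <- lapply(1:3, function(k) {
    d <- unit(awayDir + 0.9 * (cos(2 * pi * k / 3) * basis$u +
                               sin(2 * pi * k / 3) * basis$v))
    cPos + 1.09 * d
  })
  list(atoms = ligandAtomsDf(c("O", "C", "H", "H", "H", "H"),
                             c(list(oPos, cPos, hO), hC)),
       bonds = data.frame(i = c(1, 1, 2, 2, 2), j = c(2, 3, 4, 5, 6),
                          order = 1L))
}

buildAmmonium <- function(nPos, basis) {
  dirs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  hs <- lapply(dirs, function(d) {
    v <- unit(d[1] * basis$u + d[2] * basis$v + d[3] * basis$w)
    nPos + 1.02 * v
  })
  list(atoms = ligandAtomsDf(c("N", rep("H", 4)), c(list(nPos), hs),
                             charge = c(1L, 0L, 0L, 0L, 0L)),
       bonds = data.frame(i = rep(1L, 4), j = 2:5, order = 1L))
}

buildBenzene <- function(centroid, normal, psi = 0, clPos = NULL) {
  b <- orthonormalBasis(normal, psi)
  ring <- lapply(0:5, function(k) {
    a <- 2 * pi * k / 6
    centroid + 1.39 * (cos(a) * b$u + sin(a) * b$v)
  })
  hs <- lapply(0:5, function(k) {
    a <- 2 * pi * k / 6
    centroid + 2.47 * (cos(a) * b$u + sin(a) * b$v)
  })
  if (is.null(clPos)) {
    atoms <- ligandAtomsDf(c(rep("C", 6), rep("H", 6)), c(ring, hs))
    bonds <- data.frame(i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
                        order = c(2, 1, 2, 1, 2, 1, rep(1, 6)))
  } else {
    atoms <- ligandAtomsDf(c(rep("C", 6), "Cl", rep("H", 5)),
                           c(ring, list(clPos), hs[2:6]))
    bonds <- data.frame(i = c(1:6, 1, 2:6), j = c(2:6, 1, 7, 8:12),
                        order = c(2, 1, 2, 1, 2, 1, rep(1, 6)))
  }
  list(atoms = atoms, bonds = bonds)
}

## chlorobenzene oriented so that Cl sits at clPos and its ipso carbon at
## cPos; the ring extends away from the receptor
buildChlorobenzene <- function(clPos, cPos, perp) {
  axis <- unit(cPos - clPos)
  centroid <- cPos + 1.39 * axis
  normal <- unit(pracmaCross(axis, perp))
  b <- orthonormalBasis(normal, 0)
  ## ring with vertex 1 at cPos: align basis so that angle 0 points to cPos
  ang0 <- atan2(sum((cPos - centroid) * b$v), sum((cPos - centroid) * b$u))
  ring <- lapply(0:5, function(k) {
    a <- ang0 + 2 * pi * k / 6
    centroid + 1.39 * (cos(a) * b$u + sin(a) * b$v)
  })
  hs <- lapply(1:5, function(k) {
    a <- ang0 + 2 * pi * k / 6
    centroid + 2.47 * (cos(a) * b$u + sin(a) * b$v)
  })
  atoms <- ligandAtomsDf(c(rep("C", 6), "Cl", rep("H", 5)),
                         c(ring, list(clPos), hs))
  bonds <- data.frame(i = c(1:6, 1, 2:6), j = c(2:6, 1, 7, 8:12),
                      order = c(2, 1, 2, 1, 2, 1, rep(1, 6)))
  list(atoms = atoms, bonds = bonds)
}

buildAcetate <- function(oPos, awayDir, basis) {
  awayDir <- unit(awayDir)
  cPos <- oPos + 1.26 * awayDir
  o2 <- cPos + 1.26 * unit(awayDir + 1.2 * basis$u)
  c2 <- cPos + 1.52 * unit(awayDir - 1.2 * basis$u)
  hs <- lapply(1:3, function(k) {
    d <- unit(unit(c2 - cPos) + 0.9 * (cos(2 * pi * k / 3) * basis$v +
                                       sin(2 * pi * k / 3) * basis$w))
    c2 + 1.09 * d
  })
  list(atoms = ligandAtomsDf(c("O", "C", "O", "C", "H", "H", "H"),
                             c(list(oPos, cPos, o2, c2), hs),
                             charge = c(-1L, 0L, 0L, 0L, 0L, 0L, 0L)),
       bonds = data.frame(i = c(1, 2, 2, 4, 4, 4), j = c(2, 3, 4, 5, 6, 7),
                          order = c(1L, 2L, 1L, 1L, 1L, 1L)))
}

buildMethane <- function(cPos, basis) {
  dirs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  hs <- lapply(dirs, function(d) {
    v <- unit(d[1] * basis$u + d[2] * basis$v + d[3] * basis$w)
    cPos + 1.09 * v
  })
  list(atoms = ligandAtomsDf(c("C", rep("H", 4)), c(list(cPos), hs)),
       bonds = data.frame(i = rep(1L, 4), j = 2:5, order = 1L))
}

## V2000 writer for probe ligands
writeMolBlock <- function(lig, title = "probe") {
  a <- lig$atoms; b <- lig$bonds
  lines <- c(title, "  SIFtNA", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element),
             sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order))
  chg <- which(a$charge != 0)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                                    collapse = "")))
  c(lines, "M  END", "$$$$")
}

#' Synthetic PDB text for a probe receptor
#'
#' One residue per base letter, spaced 16 Angstrom apart along y, chain A,
#' residues numbered from 1, with explicit hydrogens.
#'
#' @param bases Character vector of base letters.
#' @return list(atoms = data.frame, pdb = character lines).
#' @export
probeReceptor <- local({
  cache <- new.env(parent = emptyenv())
  function(bases) {
    key <- paste(bases, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- probeReceptorBuild(bases)
    cache[[key]]
  }
})

probeReceptorBuild <- function(bases) {
  all <- do.call(rbind, lapply(seq_along(bases), function(k) {
    t <- nucleotideTemplate(bases[k])
    t$y <- t$y + 16 * (k - 1)
    t$resno <- k
    t$resname <- bases[k]
    t
  }))
  all$chain <- "A"
  all$isH <- all$element == "H"
  all$serial <- seq_len(nrow(all))
  rec <- new("Receptor",
             atoms = cbind(all[, c("serial", "name", "element", "x", "y",
                                   "z", "chain", "resno", "resname", "isH")],
                           group = classifyResidueAtomsByRes(all)),
             waters = emptyReceptorAtoms(), ions = emptyReceptorAtoms(),
             sourcePath = "")
  list(atoms = rec@atoms, pdb = writeReceptorPDB(rec))
}

classifyResidueAtomsByRes <- function(all) {
  grp <- rep(NA_character_, nrow(all))
  for (rn in unique(all$resno)) {
    sel <- all$resno == rn
    grp[sel] <- classifyResidueAtoms(all[sel, , drop = FALSE])
  }
  grp
}

templateAtom <- function(atoms, resno, name) {
  row <- atoms[atoms$resno == resno & atoms$name == name, , drop = FALSE]
  if (!nrow(row))
    siftStop("siftna_spec_error", "template lacks atom %s", name)
  as.numeric(row[1, c("x", "y", "z")])
}

#' Generate a synthetic probe complex
#'
#' Emits a (PDB text, SDF text) pair realizing the geometry requested in
#' the [probeSpec()]: a nucleotide receptor template and a minimal ligand
#' probe placed at the defining distance/angle/offset, with mediating
#' waters or ions written into the PDB when the channel requires them. All
#' randomness (the azimuthal orientation of the probe about its approach
#' axis) is controlled by \code{seed}; identical spec + seed give
#' byte-identical output.
#'
#' @param spec A probe specification from [probeSpec()].
#' @param seed Integer seed.
#' @return list(pdb = character lines, sdf = character lines,
#'   realized = list of exact in-memory defining quantities,
#'   receptor = the [Receptor-class], ligand = the [Ligand-class]
#'   with unrounded coordinates).
#' @examples
#' probe <- makeProbeComplex(probeSpec("CationAnion", distance = 4.0))
#' rec <- readReceptor(probe$pdb)
#' @export
makeProbeComplex <- function(spec, seed = 1L) {
  rt <- probeReceptor(spec$receptorTemplate)
  atoms <- rt$atoms
  tr <- spec$targetResidue
  base <- spec$receptorTemplate[tr]
  psi <- (seed %% 360) * pi / 180
  d <- spec$distance
  waters <- emptyReceptorAtoms()
  ions <- emptyReceptorAtoms()
  realized <- list(distance = d)
  at <- function(name) templateAtom(atoms, tr, name)
  pdir <- unit(at("OP1") - at("P"))
  lig <- switch(spec$itype,
    HB = {
      if (spec$direction == "receptor_donor") {
        site <- PROBE_SITES[[base]]$donor
        D <- at(site[1]); H <- at(site[2])
        dir <- unit(H - D)
        b <- orthonormalBasis(dir, psi)
        ang <- spec$angle %||% 180
        A <- if (ang >= 179.999) D + d * dir
             else placeAtAngle(H, -dir, b$u, d, ang, from = D)
        realized$angle <- angle3(D, H, A)
        buildMethanol(A, unit(A - D), unit(pracmaCross(unit(A - D), b$u)),
                      orthonormalBasis(unit(A - D), psi))
      } else {
        A <- at(PROBE_SITES[[base]]$acceptor)
        ## outward: away from the base centroid, in-plane
        cent <- ringGeometry(do.call(rbind, lapply(
          baseRings(base)[[1]]$names, at)))$centroid
        dir <- unit(A - cent)
        Dpos <- A + d * dir
        b <- orthonormalBasis(dir, psi)
        ang <- spec$angle %||% 180
        H <- placeHForAngle(Dpos, A, 0.96, ang, b$u)
        realized$angle <- angle3(Dpos, H, A)
        m <- buildMethanol(Dpos, dir, unit(H - Dpos),
                           orthonormalBasis(dir, psi))
        m
      }
    },
    HAL = {
      A <- at("OP1"); Y <- at("P")
      uYA <- unit(Y - A)
      b <- orthonormalBasis(uYA, psi)
      accAng <- 120
      X <- placeAtAngle(A, uYA, b$u, d, accAng)
      donAng <- spec$angle %||% 170
      Cpos <- placeAtAngle(X, unit(A - X), b$u, 1.77, donAng)
      realized$angle <- angle3(Cpos, X, A)
      realized$acceptorAngle <- angle3(X, A, Y)
      buildChlorobenzene(X, Cpos, b$u)
    },
    CationAnion = {
      N <- at("OP1") + d * pdir
      buildAmmonium(N, orthonormalBasis(pdir, psi))
    },
    PiCation = ,
    PiAnion = {
      cent <- ringGeometry(do.call(rbind, lapply(
        baseRings(base)[[1]]$names, at)))$centroid
      ang <- (spec$angle %||% 0) * pi / 180
      b <- orthonormalBasis(c(0, 0, 1), psi)
      pos <- cent + d * (cos(ang) * c(0, 0, 1) + sin(ang) * b$u)
      realized$angle <- spec$angle %||% 0
      if (spec$itype == "PiCation")
        buildAmmonium(pos, orthonormalBasis(c(0, 0, 1), psi))
      else buildAcetate(pos, c(0, 0, 1), orthonormalBasis(c(0, 0, 1), psi))
    },
    PiStacking = {
      cent <- ringGeometry(do.call(rbind, lapply(
        baseRings(base)[[1]]$names, at)))$centroid
      o <- spec$offset %||% 0
      h <- sqrt(max(d^2 - o^2, 0))
      b <- orthonormalBasis(c(0, 0, 1), psi)
      c2 <- cent + o * b$u + h * c(0, 0, 1)
      theta <- (spec$angle %||% 0) * pi / 180
      normal2 <- cos(theta) * c(0, 0, 1) + sin(theta) * b$u
      realized$angle <- spec$angle %||% 0
      realized$offset <- o
      buildBenzene(c2, normal2, psi)
    },
    Mg_mediated = ,
    K_mediated = ,
    Na_mediated = ,
    OtherMetal_mediated = {
      M <- at("OP1") + d * pdir
      O <- M + spec$distance2 * pdir
      ions <- data.frame(serial = 9000L, name = toupper(spec$mediator),
                         element = spec$mediator, x = M[1], y = M[2],
                         z = M[3], chain = "A", resno = 201L,
                         resname = toupper(spec$mediator), isH = FALSE,
                         group = NA_character_, stringsAsFactors = FALSE)
      realized$distance2 <- spec$distance2
      buildMethanol(O, pdir, unit(pracmaCross(pdir, c(0, 0, 1))),
                    orthonormalBasis(pdir, psi))
    },
    Water_mediated = {
      W <- at("OP1") + d * pdir
      O <- W + spec$distance2 * pdir
      waters <- data.frame(serial = 9000L, name = "O", element = "O",
                           x = W[1], y = W[2], z = W[3], chain = "A",
                           resno = 101L, resname = "HOH", isH = FALSE,
                           group = NA_character_, stringsAsFactors = FALSE)
      realized$distance2 <- spec$distance2
      buildMethanol(O, pdir, unit(pracmaCross(pdir, c(0, 0, 1))),
                    orthonormalBasis(pdir, psi))
    },
    Lipophilic = {
      dir <- unit(at("C5'") - at("C4'"))
      buildMethane(at("C5'") + d * dir, orthonormalBasis(dir, psi))
    },
    Contact = {
      pos <- at("C5") + d * c(0, 0, 1)
      buildMethane(pos, orthonormalBasis(c(0, 0, 1), psi))
    })
  rec <- new("Receptor", atoms = atoms, waters = waters, ions = ions,
             sourcePath = "")
  ligAtoms <- lig$atoms
  ligAtoms$isH <- ligAtoms$element == "H"
  ligAtoms$aromatic <- FALSE
  ligAtoms$name <- paste0(ligAtoms$element, seq_len(nrow(ligAtoms)))
  sdf <- writeMolBlock(lig, title = paste0(spec$itype, "_probe"))
  bonds <- lig$bonds
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  bonds$aromatic <- FALSE
  ligObj <- new("Ligand", title = paste0(spec$itype, "_probe"),
                poseIndex = 1L, atoms = ligAtoms, bonds = bonds,
                molBlock = paste(c(sdf, ""), collapse = "\n"))
  list(pdb = writeReceptorPDB(rec), sdf = sdf, realized = realized,
       receptor = rec, ligand = ligObj)
}

## Position the donor hydrogen so that angle(D, H, A) equals `ang`.
placeHForAngle <- function(D, A, bondLen, ang, perp) {
  if (ang >= 179.999) return(D + bondLen * unit(A - D))
  f <- function(phi) {
    w <- cos(phi) * unit(A - D) + sin(phi) * unit(perp)
    angle3(D, D + bondLen * w, A) - ang
  }
  ## phi = 0 gives 180 deg; increase phi to shrink the angle
  lo <- 0; hi <- pi - 1e-6
  if (f(hi) > 0)
    siftStop("siftna_spec_error", "requested D-H...A angle not realizable")
  phi <- stats::uniroot(f, c(lo + 1e-9, hi), tol = 1e-12)$root
  D + bondLen * (cos(phi) * unit(A - D) + sin(phi) * unit(perp))
}

#' SDF text for a minimal probe ligand
#'
#' Returns a single-record SDF of one of the probe molecules in a
#' canonical local frame (contact atom at the origin): methanol, ammonium,
#' benzene, chlorobenzene, acetate or methane.
#'
#' @param kind Probe molecule name.
#' @return Character vector of SDF lines.
#' @examples
#' lig <- readLigands(probeLigandSDF("benzene"))[[1]]
#' @export
probeLigandSDF <- function(kind = c("methanol", "ammonium", "benzene",
                                    "chlorobenzene", "acetate", "methane")) {
  kind <- match.arg(kind)
  ex <- orthonormalBasis(c(1, 0, 0))
  ez <- orthonormalBasis(c(0, 0, 1))
  lig <- switch(kind,
    methanol = buildMethanol(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), ex),
    ammonium = buildAmmonium(c(0, 0, 0), ez),
    benzene = buildBenzene(c(0, 0, 0), c(0, 0, 1)),
    chlorobenzene = buildChlorobenzene(c(0, 0, 0), c(1.77, 0, 0), c(0, 1, 0)),
    acetate = buildAcetate(c(0, 0, 0), c(1, 0, 0), ex),
    methane = buildMethane(c(0, 0, 0), ez))
  writeMolBlock(lig, kind)
}

#' Random binary fingerprint population
#'
#' Generates \code{n} independent Bernoulli(\code{density}) bit vectors of
#' the given length, reproducibly from \code{seed}; used for similarity
#' and wrapper testing.
#'
#' @param n Number of vectors.
#' @param density Bit density in \code{[0, 1]}.
#' @param length Vector length.
#' @param seed Integer seed.
#' @return Integer matrix of 0/1 with \code{n} rows.
#' @export
makeFingerprintPopulation <- function(n, density, length, seed = 1L) {
  if (density < 0 || density > 1)
    siftStop("siftna_usage_error", "density must lie in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  matrix(as.integer(stats::runif(n * length) < density), nrow = n)
}
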
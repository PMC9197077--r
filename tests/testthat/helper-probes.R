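## Shared test scaffolding: hand-built feature sets, randomized probe
## specifications straddling the decision boundaries, rigid-motion
## transforms, and the donor/acceptor cross-check plugin definitions.

emptyFeat <- function() SIFtNA:::emptyFeatureSet()

## build a FeatureSet from plain coordinate lists
makeFeat <- function(donors = NULL, donorH = NULL, acceptors = NULL,
                     halogenDonors = NULL, cations = NULL, anions = NULL,
                     rings = NULL, lipophilic = NULL) {
  f <- emptyFeat()
  asFeat <- function(lst, prefix) {
    if (is.null(lst)) return(NULL)
    do.call(rbind, lapply(seq_along(lst), function(i)
      data.frame(idx = i, name = paste0(prefix, i), x = lst[[i]][1],
                 y = lst[[i]][2], z = lst[[i]][3], stringsAsFactors = FALSE)))
  }
  if (!is.null(donors)) f@donors <- asFeat(donors, "D")
  if (!is.null(donorH))
    f@donorH <- do.call(rbind, lapply(seq_along(donorH), function(i) {
      if (is.null(donorH[[i]])) return(NULL)
      data.frame(donorIdx = i, x = donorH[[i]][1], y = donorH[[i]][2],
                 z = donorH[[i]][3])
    }))
  if (!is.null(acceptors)) {
    acc <- asFeat(lapply(acceptors, `[[`, 1), "A")
    nbr <- lapply(acceptors, `[[`, 2)
    acc$nx <- vapply(nbr, function(v) if (is.null(v)) NA_real_ else v[1], 0)
    acc$ny <- vapply(nbr, function(v) if (is.null(v)) NA_real_ else v[2], 0)
    acc$nz <- vapply(nbr, function(v) if (is.null(v)) NA_real_ else v[3], 0)
    acc$hasNbr <- !vapply(nbr, is.null, TRUE)
    f@acceptors <- acc
  }
  if (!is.null(halogenDonors))
    f@halogenDonors <- do.call(rbind, lapply(seq_along(halogenDonors),
      function(i) {
        h <- halogenDonors[[i]]   # list(X, C)
        data.frame(idx = i, name = paste0("X", i), x = h[[1]][1],
                   y = h[[1]][2], z = h[[1]][3], cx = h[[2]][1],
                   cy = h[[2]][2], cz = h[[2]][3], stringsAsFactors = FALSE)
      }))
  if (!is.null(cations)) f@cations <- asFeat(cations, "K")
  if (!is.null(anions)) f@anions <- asFeat(anions, "M")
  if (!is.null(rings))
    f@rings <- lapply(seq_along(rings), function(i) {
      r <- rings[[i]]   # list(centroid, normal) or member matrix
      if (is.matrix(r)) {
        geo <- ringGeometry(r)
        list(members = seq_len(nrow(r)), names = paste0("R", i, letters[seq_len(nrow(r))]),
             centroid = geo$centroid, normal = geo$normal)
      } else {
        list(members = 1:6, names = paste0("R", i, letters[1:6]),
             centroid = r[[1]], normal = r[[2]] / sqrt(sum(r[[2]]^2)))
      }
    })
  if (!is.null(lipophilic)) f@lipophilic <- asFeat(lipophilic, "L")
  f
}

## hexagon coordinates: centroid ct, unit normal nm, radius 1.39
hexRing <- function(ct = c(0, 0, 0), nm = c(0, 0, 1)) {
  b <- SIFtNA:::orthonormalBasis(nm)
  t(sapply(0:5, function(k)
    ct + 1.39 * (cos(pi * k / 3) * b$u + sin(pi * k / 3) * b$v)))
}

## randomized probe specification for a channel, straddling its cutoffs
randomProbeSpec <- function(itype, seed) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "U"), 1)
  switch(itype,
    HB = probeSpec("HB", runif(1, 2.6, 4.6), receptorTemplate = base,
                   direction = sample(c("receptor_donor", "ligand_donor"), 1)),
    HAL = probeSpec("HAL", runif(1, 2.8, 4.6), angle = runif(1, 120, 180),
                    receptorTemplate = base),
    CationAnion = probeSpec("CationAnion", runif(1, 0.6, 6.5),
                            receptorTemplate = base),
    PiCation = probeSpec("PiCation", runif(1, 2.8, 7), angle = runif(1, 0, 60),
                         receptorTemplate = base),
    PiAnion = probeSpec("PiAnion", runif(1, 2.8, 7), angle = runif(1, 0, 60),
                        receptorTemplate = base),
    PiStacking = {
      d <- runif(1, 2.8, 6.5)
      probeSpec("PiStacking", d, angle = runif(1, 0, 90),
                offset = runif(1, 0, min(2.8, d - 0.2)),
                receptorTemplate = base)
    },
    Mg_mediated = probeSpec("Mg_mediated", runif(1, 1.8, 4),
                            distance2 = runif(1, 1.8, 4),
                            receptorTemplate = base),
    K_mediated = probeSpec("K_mediated", runif(1, 1.8, 4.4),
                           distance2 = runif(1, 1.8, 4.4),
                           receptorTemplate = base),
    Na_mediated = probeSpec("Na_mediated", runif(1, 1.8, 4),
                            distance2 = runif(1, 1.8, 4),
                            receptorTemplate = base),
    OtherMetal_mediated = probeSpec("OtherMetal_mediated", runif(1, 1.8, 4),
                                    distance2 = runif(1, 1.8, 4),
                                    mediator = sample(c("Zn", "Ca", "Mn"), 1),
                                    receptorTemplate = base),
    Water_mediated = probeSpec("Water_mediated", runif(1, 2.2, 4.3),
                               distance2 = runif(1, 2.2, 4.3),
                               receptorTemplate = base),
    Lipophilic = probeSpec("Lipophilic", runif(1, 3, 4.8),
                           receptorTemplate = base),
    stop("unknown itype"))
}

## compare package detectors against the brute-force oracle on one probe;
## residue features are cached per template base (the receptor geometry of
## a single-nucleotide template is deterministic)
.featRCache <- new.env(parent = emptyenv())

cachedResidueFeatures <- function(rec, spec, cfg) {
  key <- paste(spec$receptorTemplate, collapse = "")
  if (length(spec$receptorTemplate) == 1 && spec$targetResidue == 1) {
    if (is.null(.featRCache[[key]]))
      .featRCache[[key]] <- SIFtNA:::residueFeatures(rec, 1, cfg)
    .featRCache[[key]]
  } else SIFtNA:::residueFeatures(rec, spec$targetResidue, cfg)
}

probeAgreesWithOracle <- function(spec, seed, cfg = geometryConfig(),
                                  hbMode = "distance") {
  p <- makeProbeComplex(spec, seed)
  rec <- p$receptor
  featL <- perceiveFeatures(p$ligand, cfg)
  featR <- cachedResidueFeatures(rec, spec, cfg)
  det <- SIFtNA:::bindRecords(list(
    detectHydrogenBonds(featR, featL, cfg, hbMode),
    detectHalogenBonds(featR, featL, cfg),
    detectCationAnion(featR, featL, cfg),
    detectPiIon(featR, featL, cfg, "cation"),
    detectPiIon(featR, featL, cfg, "anion"),
    detectPiStacking(featR, featL, cfg),
    detectIonMediated(featR, featL, rec@ions, cfg),
    detectWaterMediated(featR, featL, rec@waters, cfg),
    detectLipophilic(featR, featL, cfg)))
  ora <- oracleKeys(featR, featL, rec@waters, rec@ions, cfg, hbMode)
  identical(detectorKeys(det), ora)
}

## rigid motion: random rotation + translation from a seed
randomRigidMotion <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 8))
}

transformReceptor <- function(rec, motion) {
  tx <- function(df) {
    if (!nrow(df)) return(df)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(motion$R)
    df$x <- xyz[, 1] + motion$t[1]
    df$y <- xyz[, 2] + motion$t[2]
    df$z <- xyz[, 3] + motion$t[3]
    df
  }
  rec@atoms <- tx(rec@atoms)
  rec@waters <- tx(rec@waters)
  rec@ions <- tx(rec@ions)
  rec
}

transformLigand <- function(lig, motion) {
  xyz <- as.matrix(lig@atoms[, c("x", "y", "z")]) %*% t(motion$R)
  lig@atoms$x <- xyz[, 1] + motion$t[1]
  lig@atoms$y <- xyz[, 2] + motion$t[2]
  lig@atoms$z <- xyz[, 3] + motion$t[3]
  lig
}

## plugin pair expressing the built-in donor/acceptor tables, for the
## hydrogen-bond cross-validation
hbCrossPluginYaml <- function(dmax = 3.9) {
  paste(
    "plugins:",
    "  - name: hb_rdon",
    sprintf("    receptor_smarts: \"%s\"", RECEPTOR_HB_DONOR_SMARTS),
    paste0("    ligand_smarts: \"[$([#8;!$([#8+])]),",
           "$([#7;!$([#7+]);!$([NX4]);!$([nX3H1]);!$([NX3][CX3]=[OX1])])]\""),
    sprintf("    criterion: {type: distance, dmin: 0.0, dmax: %.2f}", dmax),
    "  - name: hb_racc",
    sprintf("    receptor_smarts: \"%s\"", RECEPTOR_HB_ACCEPTOR_SMARTS),
    "    ligand_smarts: \"[#7,#8,#16;!H0]\"",
    sprintf("    criterion: {type: distance, dmin: 0.0, dmax: %.2f}", dmax),
    sep = "\n")
}

## canned multi-residue probe complex with one H-bond to a chosen residue
hbComplexAtResidue <- function(bases = c("G", "G", "G"), target = 2,
                               distance = 3.0) {
  makeProbeComplex(probeSpec("HB", distance, receptorTemplate = bases,
                             targetResidue = target))
}

## SDF text for simple molecules used in perception tests
probeLigandText <- function(kind) probeLigandSDF(kind)
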
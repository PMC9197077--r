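## The interaction detectors. Each takes the perceived FeatureSets of one
## receptor residue and one ligand record plus the geometric criteria, and
## returns a data frame of interaction records. Both interaction
## directions are always evaluated (the receptor acts as donor and
## acceptor, anion "acceptor" and anion "donor", etc.). Records are keyed
## by (itype, receptor side, ligand side, mediator); duplicates collapse.

RECORD_COLUMNS <- c("itype", "subtype", "chain", "resno", "resname",
                    "receptorAtoms", "rx", "ry", "rz", "ligandAtoms",
                    "lx", "ly", "lz", "mediator", "mx", "my", "mz",
                    "distance", "angle")

emptyRecords <- function() {
  emptyDf(itype = character(), subtype = character(), chain = character(),
          resno = integer(), resname = character(),
          receptorAtoms = character(), rx = numeric(), ry = numeric(),
          rz = numeric(), ligandAtoms = character(), lx = numeric(),
          ly = numeric(), lz = numeric(), mediator = character(),
          mx = numeric(), my = numeric(), mz = numeric(),
          distance = numeric(), angle = numeric())
}

## one record as a plain list; columns are assembled once per detector call
makeRecord <- function(itype, recAtoms, rxyz, ligAtoms, lxyz, distance,
                       angle = NA_real_, subtype = NA_character_,
                       mediator = NA_character_, mxyz = c(NA_real_, NA_real_, NA_real_)) {
  list(itype = itype, subtype = subtype, receptorAtoms = recAtoms,
       rx = rxyz[1], ry = rxyz[2], rz = rxyz[3], ligandAtoms = ligAtoms,
       lx = lxyz[1], ly = lxyz[2], lz = lxyz[3], mediator = mediator,
       mx = mxyz[1], my = mxyz[2], mz = mxyz[3],
       distance = distance, angle = angle)
}

recordsFromList <- function(recs) {
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) return(emptyRecords())
  col <- function(nm, proto) vapply(recs, function(r) r[[nm]], proto)
  out <- data.frame(
    itype = col("itype", ""), subtype = col("subtype", ""),
    chain = NA_character_, resno = NA_integer_, resname = NA_character_,
    receptorAtoms = col("receptorAtoms", ""),
    rx = col("rx", 0), ry = col("ry", 0), rz = col("rz", 0),
    ligandAtoms = col("ligandAtoms", ""),
    lx = col("lx", 0), ly = col("ly", 0), lz = col("lz", 0),
    mediator = col("mediator", ""),
    mx = col("mx", 0), my = col("my", 0), mz = col("mz", 0),
    distance = col("distance", 0), angle = col("angle", 0),
    stringsAsFactors = FALSE)
  dedupRecords(out)
}

dedupRecords <- function(out) {
  key <- paste(out$itype, out$receptorAtoms, out$ligandAtoms, out$mediator)
  out[!duplicated(key), , drop = FALSE]
}

bindRecords <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x), lst)
  if (!length(lst)) return(emptyRecords())
  dedupRecords(do.call(rbind, lst))
}

coordsOf <- function(df) as.matrix(df[, c("x", "y", "z"), drop = FALSE])

## ---------------------------------------------------------------------------

#' Detect hydrogen bonds between a residue and a ligand
#'
#' In \code{mode = "distance"} a bond fires when the donor heavy atom to
#' acceptor distance D...A is at most \code{hb_dist_max} (default 3.9
#' Angstrom). In \code{mode = "dha"} the donor must additionally carry an
#' explicit hydrogen with a D-H...A angle of at least
#' \code{hb_dha_angle_min} degrees. Both directions (receptor donor to
#' ligand acceptor and vice versa) are evaluated; one record is emitted
#' per donor-acceptor pair.
#'
#' @param featR [FeatureSet-class] of the receptor residue.
#' @param featL [FeatureSet-class] of the ligand.
#' @param cfg A [GeometryConfig-class].
#' @param mode \code{"distance"} (D...A) or \code{"dha"} (D-H...A).
#' @return data.frame of interaction records.
#' @export
detectHydrogenBonds <- function(featR, featL, cfg = geometryConfig(),
                                mode = c("distance", "dha")) {
  mode <- match.arg(mode)
  oneWay <- function(don, donH, acc, tagD, tagA) {
    if (!nrow(don) || !nrow(acc)) return(NULL)
    dm <- crossDist(coordsOf(don), coordsOf(acc))
    hits <- which(dm <= cfg@hb_dist_max, arr.ind = TRUE)
    if (!nrow(hits)) return(NULL)
    recs <- lapply(seq_len(nrow(hits)), function(r) {
      di <- hits[r, 1]; ai <- hits[r, 2]
      ang <- NA_real_
      if (mode == "dha") {
        hs <- donH[donH$donorIdx == don$idx[di], , drop = FALSE]
        if (!nrow(hs))
          siftStop("siftna_missing_hydrogen_error",
                   "donor %s has no explicit hydrogen; add hydrogens for D-H...A mode",
                   don$name[di])
        angs <- vapply(seq_len(nrow(hs)), function(h)
          angle3(as.numeric(don[di, c("x", "y", "z")]),
                 as.numeric(hs[h, c("x", "y", "z")]),
                 as.numeric(acc[ai, c("x", "y", "z")])), 0)
        ang <- max(angs)
        if (ang < cfg@hb_dha_angle_min) return(NULL)
      }
      if (tagD == "R")
        makeRecord("HB", don$name[di], as.numeric(don[di, c("x", "y", "z")]),
                   acc$name[ai], as.numeric(acc[ai, c("x", "y", "z")]),
                   dm[di, ai], ang)
      else
        makeRecord("HB", acc$name[ai], as.numeric(acc[ai, c("x", "y", "z")]),
                   don$name[di], as.numeric(don[di, c("x", "y", "z")]),
                   dm[di, ai], ang)
    })
    recordsFromList(recs)
  }
  bindRecords(list(
    oneWay(featR@donors, featR@donorH, featL@acceptors, "R", "L"),
    oneWay(featL@donors, featL@donorH, featR@acceptors, "L", "R")))
}

#' Detect halogen bonds
#'
#' A halogen bond C-X...A fires when the halogen-acceptor distance is at
#' most \code{hal_dist_max}, the donor angle C-X...A lies within
#' \code{hal_don_angle +/- hal_don_angle_window}, and the acceptor angle
#' X...A-Y (Y = the acceptor's bonded heavy neighbour) lies within
#' \code{hal_acc_angle +/- hal_acc_angle_window}. Halogen donors on either
#' side are evaluated against acceptors on the other.
#'
#' @inheritParams detectHydrogenBonds
#' @return data.frame of interaction records.
#' @export
detectHalogenBonds <- function(featR, featL, cfg = geometryConfig()) {
  oneWay <- function(hal, acc, halIsLigand) {
    if (!nrow(hal) || !nrow(acc)) return(NULL)
    recs <- list()
    for (i in seq_len(nrow(hal))) {
      X <- as.numeric(hal[i, c("x", "y", "z")])
      C <- as.numeric(hal[i, c("cx", "cy", "cz")])
      for (j in seq_len(nrow(acc))) {
        if (!isTRUE(acc$hasNbr[j])) next
        A <- as.numeric(acc[j, c("x", "y", "z")])
        Y <- as.numeric(acc[j, c("nx", "ny", "nz")])
        d <- vnorm(X - A)
        if (d > cfg@hal_dist_max) next
        donAng <- angle3(C, X, A)
        if (abs(donAng - cfg@hal_don_angle) > cfg@hal_don_angle_window) next
        accAng <- angle3(X, A, Y)
        if (abs(accAng - cfg@hal_acc_angle) > cfg@hal_acc_angle_window) next
        recs[[length(recs) + 1]] <- if (halIsLigand)
          makeRecord("HAL", acc$name[j], A, hal$name[i], X, d, donAng)
        else
          makeRecord("HAL", hal$name[i], X, acc$name[j], A, d, donAng)
      }
    }
    recordsFromList(recs)
  }
  bindRecords(list(oneWay(featL@halogenDonors, featR@acceptors, TRUE),
                   oneWay(featR@halogenDonors, featL@acceptors, FALSE)))
}

#' Detect cation-anion interactions
#'
#' Fires for each cation-anion pair with distance in
#' \code{(ca_dist_min, ca_dist_max]} (the lower bound guards against
#' recorded clashes). Receptor phosphate OP1/OP2(/OP3) oxygens count as
#' anions regardless of recorded charge; both charge directions are
#' evaluated.
#'
#' @inheritParams detectHydrogenBonds
#' @return data.frame of interaction records.
#' @export
detectCationAnion <- function(featR, featL, cfg = geometryConfig()) {
  oneWay <- function(recSide, ligSide, recDf, ligDf) {
    if (!nrow(recDf) || !nrow(ligDf)) return(NULL)
    dm <- crossDist(coordsOf(recDf), coordsOf(ligDf))
    hits <- which(dm > cfg@ca_dist_min & dm <= cfg@ca_dist_max, arr.ind = TRUE)
    if (!nrow(hits)) return(NULL)
    recordsFromList(lapply(seq_len(nrow(hits)), function(r) {
      i <- hits[r, 1]; j <- hits[r, 2]
      makeRecord("CationAnion", recDf$name[i],
                 as.numeric(recDf[i, c("x", "y", "z")]),
                 ligDf$name[j], as.numeric(ligDf[j, c("x", "y", "z")]),
                 dm[i, j])
    }))
  }
  bindRecords(list(oneWay("anion", "cation", featR@anions, featL@cations),
                   oneWay("cation", "anion", featR@cations, featL@anions)))
}

#' Detect Pi-cation and Pi-anion interactions
#'
#' A charged atom over an aromatic ring face fires when its distance to
#' the ring centroid is at most \code{pi_ion_dist_max} and the angle
#' between the ring normal and the centroid-to-ion vector (folded to
#' \code{[0, 90]}) is at most \code{pi_ion_angle_max}. Rings on either
#' side are paired with ions of the requested kind on the other side, so
#' both "nucleobase ring over ligand ion" and "ligand ring over phosphate
#' anion" geometries are covered.
#'
#' @inheritParams detectHydrogenBonds
#' @param ionKind \code{"cation"} or \code{"anion"}.
#' @return data.frame of interaction records.
#' @export
detectPiIon <- function(featR, featL, cfg = geometryConfig(),
                        ionKind = c("cation", "anion")) {
  ionKind <- match.arg(ionKind)
  itype <- if (ionKind == "cation") "PiCation" else "PiAnion"
  oneWay <- function(rings, ions, ringIsReceptor) {
    if (!length(rings) || !nrow(ions)) return(NULL)
    recs <- list()
    for (k in seq_along(rings)) {
      rg <- rings[[k]]
      ringLabel <- paste(rg$names, collapse = "+")
      for (j in seq_len(nrow(ions))) {
        ion <- as.numeric(ions[j, c("x", "y", "z")])
        d <- vnorm(ion - rg$centroid)
        if (d > cfg@pi_ion_dist_max || d < 1e-6) next
        ang <- foldedAngle(rg$normal, ion - rg$centroid)
        if (ang > cfg@pi_ion_angle_max) next
        recs[[length(recs) + 1]] <- if (ringIsReceptor)
          makeRecord(itype, ringLabel, rg$centroid, ions$name[j], ion, d, ang,
                     subtype = itype)
        else
          makeRecord(itype, ions$name[j], ion, ringLabel, rg$centroid, d, ang,
                     subtype = itype)
      }
    }
    recordsFromList(recs)
  }
  ionsOf <- function(f) if (ionKind == "cation") f@cations else f@anions
  bindRecords(list(oneWay(featR@rings, ionsOf(featL), TRUE),
                   oneWay(featL@rings, ionsOf(featR), FALSE)))
}

#' Detect Pi-stacking interactions
#'
#' For each ring pair let d be the centroid distance, theta the
#' interplanar angle folded to \code{[0, 90]}, and o the smaller in-plane
#' offset of one centroid projected onto the other ring's plane. A stack
#' fires when \code{d <= pi_stack_dist_max} and either theta is at most
#' \code{pi_stack_parallel_angle_max} with \code{o <= pi_stack_offset_max}
#' (subtype \code{sandwich} when o < 0.5 Angstrom, else
#' \code{parallel-displaced}), or theta lies in the T-shape window
#' (subtype \code{T-shaped}). Purine bases contribute their 5- and
#' 6-membered rings independently.
#'
#' @inheritParams detectHydrogenBonds
#' @return data.frame of interaction records.
#' @export
detectPiStacking <- function(featR, featL, cfg = geometryConfig()) {
  if (!length(featR@rings) || !length(featL@rings)) return(emptyRecords())
  recs <- list()
  for (r1 in featR@rings) {
    for (r2 in featL@rings) {
      v <- r2$centroid - r1$centroid
      d <- vnorm(v)
      if (d > cfg@pi_stack_dist_max || d < 1e-6) next
      theta <- foldedAngle(r1$normal, r2$normal)
      off1 <- vnorm(v - sum(v * r1$normal) * r1$normal)
      off2 <- vnorm(-v - sum(-v * r2$normal) * r2$normal)
      off <- min(off1, off2)
      subtype <- NULL
      if (theta <= cfg@pi_stack_parallel_angle_max && off <= cfg@pi_stack_offset_max)
        subtype <- if (off < 0.5) "sandwich" else "parallel-displaced"
      else if (theta >= cfg@pi_stack_tshape_angle_min &&
               theta <= cfg@pi_stack_tshape_angle_max)
        subtype <- "T-shaped"
      if (is.null(subtype)) next
      recs[[length(recs) + 1]] <-
        makeRecord("PiStacking", paste(r1$names, collapse = "+"), r1$centroid,
                   paste(r2$names, collapse = "+"), r2$centroid, d, theta,
                   subtype = subtype)
    }
  }
  recordsFromList(recs)
}

metalChannel <- function(element) {
  switch(toupper(element),
         MG = "Mg_mediated", K = "K_mediated", "NA" = "Na_mediated",
         "OtherMetal_mediated")
}

metalCutoff <- function(element, cfg) {
  v <- cfg@ion_mediated_dist_max
  el <- toupper(element)
  if (el %in% names(v)) v[[el]] else v[["OTHER"]]
}

#' Detect metal cation-mediated interactions
#'
#' Fires when an inorganic ion M from the receptor file coordinates both a
#' receptor partner and a ligand partner (N/O acceptors or anions on each
#' side) within the element-specific cutoff. The channel is selected by
#' the metal: magnesium, potassium, sodium, or other-metal. The recorded
#' distance is the longer of the two coordination legs.
#'
#' @inheritParams detectHydrogenBonds
#' @param ions data.frame of receptor ions (element, x, y, z).
#' @return data.frame of interaction records.
#' @export
detectIonMediated <- function(featR, featL, ions, cfg = geometryConfig()) {
  if (is.null(ions) || !nrow(ions)) return(emptyRecords())
  partnersOf <- function(f) {
    p <- rbind(f@acceptors[, c("idx", "name", "x", "y", "z")],
               f@anions[, c("idx", "name", "x", "y", "z")])
    p[!duplicated(p$idx), , drop = FALSE]
  }
  pR <- partnersOf(featR); pL <- partnersOf(featL)
  if (!nrow(pR) || !nrow(pL)) return(emptyRecords())
  recs <- list()
  for (m in seq_len(nrow(ions))) {
    M <- as.numeric(ions[m, c("x", "y", "z")])
    cut <- metalCutoff(ions$element[m], cfg)
    dR <- crossDist(coordsOf(pR), matrix(M, ncol = 3))[, 1]
    dL <- crossDist(coordsOf(pL), matrix(M, ncol = 3))[, 1]
    okR <- which(dR <= cut); okL <- which(dL <= cut)
    for (i in okR) for (j in okL)
      recs[[length(recs) + 1]] <-
        makeRecord(metalChannel(ions$element[m]), pR$name[i],
                   as.numeric(pR[i, c("x", "y", "z")]), pL$name[j],
                   as.numeric(pL[j, c("x", "y", "z")]), max(dR[i], dL[j]),
                   mediator = ions$element[m], mxyz = M)
  }
  recordsFromList(recs)
}

#' Detect water-mediated interactions
#'
#' Fires when a water oxygen from the receptor file bridges a receptor
#' partner and a ligand partner (hydrogen-bond donors or acceptors on each
#' side), both legs within \code{water_mediated_dist_max}. The recorded
#' distance is the longer leg.
#'
#' @inheritParams detectHydrogenBonds
#' @param waters data.frame of receptor water oxygens (x, y, z).
#' @return data.frame of interaction records.
#' @export
detectWaterMediated <- function(featR, featL, waters, cfg = geometryConfig()) {
  if (is.null(waters) || !nrow(waters)) return(emptyRecords())
  partnersOf <- function(f) {
    p <- rbind(f@donors[, c("idx", "name", "x", "y", "z")],
               f@acceptors[, c("idx", "name", "x", "y", "z")])
    p[!duplicated(p$idx), , drop = FALSE]
  }
  pR <- partnersOf(featR); pL <- partnersOf(featL)
  if (!nrow(pR) || !nrow(pL)) return(emptyRecords())
  recs <- list()
  for (m in seq_len(nrow(waters))) {
    W <- as.numeric(waters[m, c("x", "y", "z")])
    cut <- cfg@water_mediated_dist_max
    dR <- crossDist(coordsOf(pR), matrix(W, ncol = 3))[, 1]
    dL <- crossDist(coordsOf(pL), matrix(W, ncol = 3))[, 1]
    okR <- which(dR <= cut); okL <- which(dL <= cut)
    for (i in okR) for (j in okL)
      recs[[length(recs) + 1]] <-
        makeRecord("Water_mediated", pR$name[i],
                   as.numeric(pR[i, c("x", "y", "z")]), pL$name[j],
                   as.numeric(pL[j, c("x", "y", "z")]), max(dR[i], dL[j]),
                   mediator = "HOH", mxyz = W)
  }
  recordsFromList(recs)
}

#' Detect lipophilic contacts
#'
#' Fires per pair of lipophilic atoms (one on each side) within
#' \code{lipophilic_dist_max}. Charged atoms never enter the lipophilic
#' sets at perception time.
#'
#' @inheritParams detectHydrogenBonds
#' @return data.frame of interaction records.
#' @export
detectLipophilic <- function(featR, featL, cfg = geometryConfig()) {
  if (!nrow(featR@lipophilic) || !nrow(featL@lipophilic)) return(emptyRecords())
  dm <- crossDist(coordsOf(featR@lipophilic), coordsOf(featL@lipophilic))
  hits <- which(dm <= cfg@lipophilic_dist_max, arr.ind = TRUE)
  if (!nrow(hits)) return(emptyRecords())
  recordsFromList(lapply(seq_len(nrow(hits)), function(r) {
    i <- hits[r, 1]; j <- hits[r, 2]
    makeRecord("Lipophilic", featR@lipophilic$name[i],
               as.numeric(featR@lipophilic[i, c("x", "y", "z")]),
               featL@lipophilic$name[j],
               as.numeric(featL@lipophilic[j, c("x", "y", "z")]),
               dm[i, j])
  }))
}

#' Any-contact bits for the SIMPLE and PBS resolutions
#'
#' \code{granularity = "residue"} returns one bit: 1 iff any heavy-atom
#' pair between the residue and the ligand is within
#' \code{simple_contact_dist_max}. \code{granularity = "group"} returns
#' three bits in P, S, B order, applying the same cutoff per
#' phosphate/sugar/base group.
#'
#' @param residueAtoms data.frame of one residue's atoms (with
#'   \code{group} and \code{isH} columns).
#' @param ligand A [Ligand-class] object.
#' @param cfg A [GeometryConfig-class].
#' @param granularity \code{"residue"} or \code{"group"}.
#' @return Integer vector of bits (length 1 or 3).
#' @export
detectContact <- function(residueAtoms, ligand, cfg = geometryConfig(),
                          granularity = c("residue", "group")) {
  granularity <- match.arg(granularity)
  ra <- residueAtoms[!residueAtoms$isH, , drop = FALSE]
  la <- ligand@atoms[!ligand@atoms$isH, , drop = FALSE]
  if (!nrow(ra) || !nrow(la))
    return(if (granularity == "residue") 0L else c(P = 0L, S = 0L, B = 0L))
  dm <- crossDist(as.matrix(ra[, c("x", "y", "z")]),
                  as.matrix(la[, c("x", "y", "z")]))
  if (granularity == "residue")
    return(as.integer(min(dm) <= cfg@simple_contact_dist_max))
  grp <- c(P = "PHOSPHATE", S = "SUGAR", B = "BASE")
  vapply(grp, function(g) {
    rows <- ra$group == g
    if (!any(rows)) return(0L)
    as.integer(min(dm[rows, , drop = FALSE]) <= cfg@simple_contact_dist_max)
  }, 0L)
}
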
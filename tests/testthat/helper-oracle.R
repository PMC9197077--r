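## Independent brute-force oracle: re-derives the interaction record set
## of one residue-ligand pair by direct scalar evaluation of every
## geometric predicate over all qualifying feature pairs. Shares only the
## perceived FeatureSets with the package detectors; all geometry is
## recomputed here with plain loops.

oDist <- function(p, q) sqrt(sum((p - q)^2))

oAngle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oFold <- function(u, v) {
  cu <- u / sqrt(sum(u^2)); cv <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(cu * cv)))) * 180 / pi
}

featCoord <- function(df, i) as.numeric(df[i, c("x", "y", "z")])

## returns a character vector of record keys "itype|rec|lig|mediator"
oracleKeys <- function(featR, featL, waters, ions, cfg, hbMode = "distance") {
  keys <- character(0)
  add <- function(itype, rec, lig, med = NA)
    keys <<- c(keys, paste(itype, rec, lig, med, sep = "|"))

  ## hydrogen bonds, both directions
  hbDir <- function(don, donH, acc, recIsDonor) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(invisible(NULL))
    for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
      d <- oDist(featCoord(don, i), featCoord(acc, j))
      if (d > cfg@hb_dist_max) next
      if (hbMode == "dha") {
        hs <- donH[donH$donorIdx == don$idx[i], , drop = FALSE]
        ok <- FALSE
        for (h in seq_len(nrow(hs)))
          if (oAngle(featCoord(don, i), featCoord(hs, h),
                     featCoord(acc, j)) >= cfg@hb_dha_angle_min) ok <- TRUE
        if (!ok) next
      }
      if (recIsDonor) add("HB", don$name[i], acc$name[j])
      else add("HB", acc$name[j], don$name[i])
    }
  }
  hbDir(featR@donors, featR@donorH, featL@acceptors, TRUE)
  hbDir(featL@donors, featL@donorH, featR@acceptors, FALSE)

  ## halogen bonds
  halDir <- function(hal, acc, halIsLigand) {
    if (nrow(hal) == 0 || nrow(acc) == 0) return(invisible(NULL))
    for (i in seq_len(nrow(hal))) for (j in seq_len(nrow(acc))) {
      if (!isTRUE(acc$hasNbr[j])) next
      X <- featCoord(hal, i)
      C <- as.numeric(hal[i, c("cx", "cy", "cz")])
      A <- featCoord(acc, j)
      Y <- as.numeric(acc[j, c("nx", "ny", "nz")])
      if (oDist(X, A) > cfg@hal_dist_max) next
      if (abs(oAngle(C, X, A) - cfg@hal_don_angle) > cfg@hal_don_angle_window) next
      if (abs(oAngle(X, A, Y) - cfg@hal_acc_angle) > cfg@hal_acc_angle_window) next
      if (halIsLigand) add("HAL", acc$name[j], hal$name[i])
      else add("HAL", hal$name[i], acc$name[j])
    }
  }
  halDir(featL@halogenDonors, featR@acceptors, TRUE)
  halDir(featR@halogenDonors, featL@acceptors, FALSE)

  ## cation-anion, both directions
  caDir <- function(recDf, ligDf) {
    if (nrow(recDf) == 0 || nrow(ligDf) == 0) return(invisible(NULL))
    for (i in seq_len(nrow(recDf))) for (j in seq_len(nrow(ligDf))) {
      d <- oDist(featCoord(recDf, i), featCoord(ligDf, j))
      if (d > cfg@ca_dist_min && d <= cfg@ca_dist_max)
        add("CationAnion", recDf$name[i], ligDf$name[j])
    }
  }
  caDir(featR@anions, featL@cations)
  caDir(featR@cations, featL@anions)

  ## Pi-ion, both directions and both kinds
  piIon <- function(rings, ions, itype, ringIsReceptor) {
    for (rg in rings) {
      lbl <- paste(rg$names, collapse = "+")
      if (nrow(ions) == 0) next
      for (j in seq_len(nrow(ions))) {
        ion <- featCoord(ions, j)
        d <- oDist(ion, rg$centroid)
        if (d > cfg@pi_ion_dist_max || d < 1e-6) next
        if (oFold(rg$normal, ion - rg$centroid) > cfg@pi_ion_angle_max) next
        if (ringIsReceptor) add(itype, lbl, ions$name[j])
        else add(itype, ions$name[j], lbl)
      }
    }
  }
  piIon(featR@rings, featL@cations, "PiCation", TRUE)
  piIon(featL@rings, featR@cations, "PiCation", FALSE)
  piIon(featR@rings, featL@anions, "PiAnion", TRUE)
  piIon(featL@rings, featR@anions, "PiAnion", FALSE)

  ## Pi-stacking
  for (r1 in featR@rings) for (r2 in featL@rings) {
    v <- r2$centroid - r1$centroid
    d <- sqrt(sum(v^2))
    if (d > cfg@pi_stack_dist_max || d < 1e-6) next
    theta <- oFold(r1$normal, r2$normal)
    o1 <- sqrt(sum((v - sum(v * r1$normal) * r1$normal)^2))
    o2 <- sqrt(sum((-v - sum(-v * r2$normal) * r2$normal)^2))
    o <- min(o1, o2)
    par <- theta <= cfg@pi_stack_parallel_angle_max && o <= cfg@pi_stack_offset_max
    tsh <- theta >= cfg@pi_stack_tshape_angle_min &&
      theta <= cfg@pi_stack_tshape_angle_max
    if (par || tsh)
      add("PiStacking", paste(r1$names, collapse = "+"),
          paste(r2$names, collapse = "+"))
  }

  ## mediated interactions
  partners <- function(f, withDonors) {
    p <- rbind(if (withDonors) f@donors[, c("idx", "name", "x", "y", "z")],
               f@acceptors[, c("idx", "name", "x", "y", "z")],
               if (!withDonors) f@anions[, c("idx", "name", "x", "y", "z")])
    p[!duplicated(p$idx), , drop = FALSE]
  }
  if (!is.null(ions) && nrow(ions)) {
    pR <- partners(featR, FALSE); pL <- partners(featL, FALSE)
    for (m in seq_len(nrow(ions))) {
      M <- as.numeric(ions[m, c("x", "y", "z")])
      el <- toupper(ions$element[m])
      cut <- if (el %in% names(cfg@ion_mediated_dist_max))
        cfg@ion_mediated_dist_max[[el]] else cfg@ion_mediated_dist_max[["OTHER"]]
      chan <- switch(el, MG = "Mg_mediated", K = "K_mediated",
                     "NA" = "Na_mediated", "OtherMetal_mediated")
      if (nrow(pR) && nrow(pL))
        for (i in seq_len(nrow(pR))) for (j in seq_len(nrow(pL)))
          if (oDist(featCoord(pR, i), M) <= cut &&
              oDist(featCoord(pL, j), M) <= cut)
            add(chan, pR$name[i], pL$name[j], ions$element[m])
    }
  }
  if (!is.null(waters) && nrow(waters)) {
    pR <- partners(featR, TRUE); pL <- partners(featL, TRUE)
    for (m in seq_len(nrow(waters))) {
      W <- as.numeric(waters[m, c("x", "y", "z")])
      if (nrow(pR) && nrow(pL))
        for (i in seq_len(nrow(pR))) for (j in seq_len(nrow(pL)))
          if (oDist(featCoord(pR, i), W) <= cfg@water_mediated_dist_max &&
              oDist(featCoord(pL, j), W) <= cfg@water_mediated_dist_max)
            add("Water_mediated", pR$name[i], pL$name[j], "HOH")
    }
  }

  ## lipophilic
  if (nrow(featR@lipophilic) && nrow(featL@lipophilic))
    for (i in seq_len(nrow(featR@lipophilic)))
      for (j in seq_len(nrow(featL@lipophilic)))
        if (oDist(featCoord(featR@lipophilic, i),
                  featCoord(featL@lipophilic, j)) <= cfg@lipophilic_dist_max)
          add("Lipophilic", featR@lipophilic$name[i], featL@lipophilic$name[j])

  sort(unique(keys))
}

detectorKeys <- function(records) {
  if (!nrow(records)) return(character(0))
  sort(unique(paste(records$itype, records$receptorAtoms,
                    records$ligandAtoms,
                    ifelse(is.na(records$mediator), NA, records$mediator),
                    sep = "|")))
}
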
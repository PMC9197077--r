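cfg <- geometryConfig()

test_that("hydrogen-bond distance criterion is inclusive at 3.9 A", {
  fR <- makeFeat(donors = list(c(0, 0, 0)), donorH = list(c(1.01, 0, 0)))
  fLin <- makeFeat(acceptors = list(list(c(3.9, 0, 0), c(4.9, 0, 0))))
  fLout <- makeFeat(acceptors = list(list(c(3.91, 0, 0), c(4.9, 0, 0))))
  expect_equal(nrow(detectHydrogenBonds(fR, fLin, cfg)), 1)
  expect_equal(nrow(detectHydrogenBonds(fR, fLout, cfg)), 0)
  ## symmetric direction: ligand donor to receptor acceptor
  fR2 <- makeFeat(acceptors = list(list(c(0, 0, 0), c(-1, 0, 0))))
  fL2 <- makeFeat(donors = list(c(3.9, 0, 0)), donorH = list(c(2.94, 0, 0)))
  expect_equal(nrow(detectHydrogenBonds(fR2, fL2, cfg)), 1)
})

test_that("D-H...A mode adds the angle predicate and needs hydrogens", {
  D <- c(0, 0, 0); H <- c(1.01, 0, 0)
  fR <- makeFeat(donors = list(D), donorH = list(H))
  collinear <- makeFeat(acceptors = list(list(c(3, 0, 0), c(4, 0, 0))))
  expect_equal(nrow(detectHydrogenBonds(fR, collinear, cfg, "dha")), 1)
  ## acceptor at 90 degrees from the D-H axis, still within distance
  perp <- H + c(0, 2.8, 0)
  bent <- makeFeat(acceptors = list(list(perp, perp + c(0, 1, 0))))
  expect_equal(nrow(detectHydrogenBonds(fR, bent, cfg, "dha")), 0)
  ## same geometry passes in distance-only mode (subset property)
  expect_equal(nrow(detectHydrogenBonds(fR, bent, cfg, "distance")), 1)
  noH <- makeFeat(donors = list(D))
  expect_error(detectHydrogenBonds(noH, collinear, cfg, "dha"),
               class = "siftna_missing_hydrogen_error")
})

test_that("halogen bonds require distance and both angle windows", {
  A <- c(0, 0, 0); Y <- c(0, 1.5, 0)
  mk <- function(d, donAng) {
    ## X placed at acceptor angle 120 from Y, then C at the donor angle
    uYA <- SIFtNA:::unit(Y - A)
    X <- SIFtNA:::placeAtAngle(A, uYA, c(1, 0, 0), d, 120)
    C <- SIFtNA:::placeAtAngle(X, SIFtNA:::unit(A - X), c(1, 0, 0), 1.77,
                               donAng)
    makeFeat(halogenDonors = list(list(X, C)))
  }
  fR <- makeFeat(acceptors = list(list(A, Y)))
  expect_equal(nrow(detectHalogenBonds(fR, mk(3.3, 170), cfg)), 1)
  expect_equal(nrow(detectHalogenBonds(fR, mk(4.5, 170), cfg)), 0)
  expect_equal(nrow(detectHalogenBonds(fR, mk(3.3, 90), cfg)), 0)
  ## acceptor angle outside its window: place X along the A-Y axis
  Xbad <- A - c(0, 3.3, 0)   # X...A-Y angle = 180
  Cbad <- Xbad - c(0, 1.77, 0)
  expect_equal(nrow(detectHalogenBonds(
    fR, makeFeat(halogenDonors = list(list(Xbad, Cbad))), cfg)), 0)
})

test_that("cation-anion fires inside the (0.5, 5.5] window only", {
  fR <- makeFeat(anions = list(c(0, 0, 0)))
  at <- function(d) makeFeat(cations = list(c(d, 0, 0)))
  expect_equal(nrow(detectCationAnion(fR, at(4.0), cfg)), 1)
  expect_equal(nrow(detectCationAnion(fR, at(5.5), cfg)), 1)
  expect_equal(nrow(detectCationAnion(fR, at(5.6), cfg)), 0)
  expect_equal(nrow(detectCationAnion(fR, at(0.4), cfg)), 0)
  ## reversed charges: receptor cation - ligand anion
  fR2 <- makeFeat(cations = list(c(0, 0, 0)))
  fL2 <- makeFeat(anions = list(c(3, 0, 0)))
  expect_equal(nrow(detectCationAnion(fR2, fL2, cfg)), 1)
})

test_that("Pi-ion detection uses distance and ring-normal angle", {
  ring <- makeFeat(rings = list(hexRing()))
  above <- makeFeat(cations = list(c(0, 0, 4)))
  expect_equal(nrow(detectPiIon(ring, above, cfg, "cation")), 1)
  inPlane <- makeFeat(cations = list(c(4, 0, 0)))
  expect_equal(nrow(detectPiIon(ring, inPlane, cfg, "cation")), 0)
  far <- makeFeat(cations = list(c(0, 0, 6.5)))
  expect_equal(nrow(detectPiIon(ring, far, cfg, "cation")), 0)
  ## anion over a ring face, and the reverse direction
  anionAbove <- makeFeat(anions = list(c(0, 0, 4.5)))
  r <- detectPiIon(ring, anionAbove, cfg, "anion")
  expect_equal(r$itype, "PiAnion")
  ligRing <- makeFeat(rings = list(hexRing(c(0, 0, 0), c(0, 0, 1))))
  recAnion <- makeFeat(anions = list(c(0, 0, 4.5)))
  expect_equal(nrow(detectPiIon(recAnion, ligRing, cfg, "anion")), 1)
})

test_that("Pi-stacking classifies sandwich, displaced and T-shaped", {
  rec <- makeFeat(rings = list(hexRing()))
  stack <- function(ct, nm) makeFeat(rings = list(list(ct, nm)))
  s <- detectPiStacking(rec, stack(c(0, 0, 3.5), c(0, 0, 1)), cfg)
  expect_equal(s$subtype, "sandwich")
  expect_equal(s$distance, 3.5, tolerance = 1e-9)
  pd <- detectPiStacking(rec, stack(c(1.5, 0, 3.5), c(0, 0, 1)), cfg)
  expect_equal(pd$subtype, "parallel-displaced")
  expect_equal(nrow(detectPiStacking(rec, stack(c(0, 0, 8), c(0, 0, 1)), cfg)), 0)
  t <- detectPiStacking(rec, stack(c(0, 0, 5), c(1, 0, 0)), cfg)
  expect_equal(t$subtype, "T-shaped")
  ## 45 degrees falls between the parallel and T windows
  mid <- stack(c(0, 0, 4), c(sin(pi / 4), 0, cos(pi / 4)))
  expect_equal(nrow(detectPiStacking(rec, mid, cfg)), 0)
})

test_that("metal-mediated interactions route by element with per-metal cutoffs", {
  fR <- makeFeat(anions = list(c(0, 0, 0)))
  fL <- makeFeat(acceptors = list(list(c(4.2, 0, 0), c(5.2, 0, 0))))
  ion <- function(el, x = 2.1)
    data.frame(element = el, x = x, y = 0, z = 0, name = el)
  r <- detectIonMediated(fR, fL, ion("Mg"), cfg)
  expect_equal(r$itype, "Mg_mediated")
  expect_equal(detectIonMediated(fR, fL, ion("Zn"), cfg)$itype,
               "OtherMetal_mediated")
  expect_equal(detectIonMediated(fR, fL, ion("K"), cfg)$itype, "K_mediated")
  expect_equal(detectIonMediated(fR, fL, ion("Na"), cfg)$itype, "Na_mediated")
  ## ligand leg beyond the Mg cutoff
  fLfar <- makeFeat(acceptors = list(list(c(6.2, 0, 0), c(7.2, 0, 0))))
  expect_equal(nrow(detectIonMediated(fR, fLfar, ion("Mg"), cfg)), 0)
  ## K has a wider coordination sphere than Mg
  fR33 <- makeFeat(anions = list(c(-3.3, 0, 0)))
  expect_equal(nrow(detectIonMediated(fR33, fL, ion("Mg", 0), cfg)), 0)
  fL33 <- makeFeat(acceptors = list(list(c(3.3, 0, 0), c(4.3, 0, 0))))
  expect_equal(nrow(detectIonMediated(fR33, fL33, ion("K", 0), cfg)), 1)
})

test_that("water bridges need both legs within 3.5 A", {
  fR <- makeFeat(acceptors = list(list(c(0, 0, 0), c(-1, 0, 0))))
  fL <- makeFeat(donors = list(c(5.6, 0, 0)), donorH = list(c(4.65, 0, 0)))
  w <- function(x) data.frame(x = x, y = 0, z = 0)
  expect_equal(nrow(detectWaterMediated(fR, fL, w(2.8), cfg)), 1)
  expect_equal(nrow(detectWaterMediated(fR, fL, w(3.6), cfg)), 0)
  none <- SIFtNA:::emptyReceptorAtoms()
  expect_equal(nrow(detectWaterMediated(fR, fL, none, cfg)), 0)
})

test_that("lipophilic contacts fire per atom pair within 4.0 A", {
  fR <- makeFeat(lipophilic = list(c(0, 0, 0)))
  expect_equal(nrow(detectLipophilic(
    fR, makeFeat(lipophilic = list(c(3.8, 0, 0))), cfg)), 1)
  expect_equal(nrow(detectLipophilic(
    fR, makeFeat(lipophilic = list(c(4.1, 0, 0))), cfg)), 0)
  fR2 <- makeFeat(lipophilic = list(c(0, 0, 0), c(1.5, 0, 0)))
  fL2 <- makeFeat(lipophilic = list(c(3.8, 0, 0), c(3.8, 1, 0)))
  expect_equal(nrow(detectLipophilic(fR2, fL2, cfg)), 4)
})

test_that("contact bits work at residue and group granularity", {
  p <- makeProbeComplex(probeSpec("Contact", 3.2))
  rec <- p$receptor
  lig <- readLigands(p$sdf)[[1]]
  ra <- residueAtoms(rec, 1)
  expect_equal(detectContact(ra, lig, cfg, "residue"), 1L)
  ## contact only through base atoms
  expect_equal(unname(detectContact(ra, lig, cfg, "group")), c(0L, 0L, 1L))
  expect_equal(names(detectContact(ra, lig, cfg, "group")), c("P", "S", "B"))
  far <- makeProbeComplex(probeSpec("Contact", 20))
  ligFar <- readLigands(far$sdf)[[1]]
  expect_equal(detectContact(ra, ligFar, cfg, "residue"), 0L)
  expect_equal(unname(detectContact(ra, ligFar, cfg, "group")), c(0L, 0L, 0L))
})

test_that("detectors agree with the brute-force oracle on random probes", {
  for (itype in siftChannels("FULL")) {
    for (seed in 1:12) {
      spec <- randomProbeSpec(itype, seed * 31 + 7)
      expect_true(probeAgreesWithOracle(spec, seed),
                  info = sprintf("%s seed %d", itype, seed))
    }
  }
})

test_that("enlarging cutoffs never removes records; shrinking never adds", {
  for (seed in 1:10) {
    itype <- sample(siftChannels("FULL"), 1)
    spec <- randomProbeSpec(itype, seed * 17 + 3)
    p <- makeProbeComplex(spec, seed)
    lig <- readLigands(p$sdf)[[1]]
    featL <- perceiveFeatures(lig)
    featR <- SIFtNA:::residueFeatures(p$receptor, spec$targetResidue)
    run <- function(cc) detectorKeys(SIFtNA:::bindRecords(list(
      detectHydrogenBonds(featR, featL, cc),
      detectCationAnion(featR, featL, cc),
      detectPiStacking(featR, featL, cc),
      detectLipophilic(featR, featL, cc))))
    base <- run(cfg)
    wide <- run(geometryConfig(hb_dist_max = 4.5, ca_dist_max = 6.5,
                               pi_stack_dist_max = 6.5,
                               lipophilic_dist_max = 5))
    narrow <- run(geometryConfig(hb_dist_max = 3.2, ca_dist_max = 4.5,
                                 pi_stack_dist_max = 4.5,
                                 lipophilic_dist_max = 3.2))
    expect_true(all(base %in% wide))
    expect_true(all(narrow %in% base))
  }
})

test_that("joint rigid motion leaves all records invariant", {
  for (seed in 1:6) {
    spec <- randomProbeSpec(sample(siftChannels("FULL"), 1), seed * 13 + 1)
    p <- makeProbeComplex(spec, seed)
    lig <- readLigands(p$sdf)[[1]]
    mo <- randomRigidMotion(seed + 100)
    rec2 <- transformReceptor(p$receptor, mo)
    lig2 <- transformLigand(lig, mo)
    k1 <- detectorKeys(detectInteractions(p$receptor, lig))
    k2 <- detectorKeys(detectInteractions(rec2, lig2))
    expect_identical(k1, k2)
    ## distances also agree to high precision
    r1 <- detectInteractions(p$receptor, lig)
    r2 <- detectInteractions(rec2, lig2)
    expect_equal(sort(r1$distance), sort(r2$distance), tolerance = 1e-6)
  }
})
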
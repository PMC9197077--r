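test_that("feature perception types the probe ligands correctly", {
  benzene <- readLigands(probeLigandText("benzene"))[[1]]
  f <- perceiveFeatures(benzene)
  expect_length(f@rings, 1)
  expect_equal(length(f@rings[[1]]$members), 6)
  expect_equal(nrow(f@lipophilic), 6)
  expect_equal(nrow(f@donors), 0)
  expect_equal(nrow(f@acceptors), 0)

  ## protonated amine: cationic nitrogen is a donor, never an acceptor
  amm <- readLigands(probeLigandText("ammonium"))[[1]]
  fa <- perceiveFeatures(amm)
  expect_equal(fa@cations$name, "N1")
  expect_equal(fa@donors$name, "N1")
  expect_equal(nrow(fa@acceptors), 0)
  expect_equal(nrow(fa@lipophilic), 0)

  ## methanol: O is donor and acceptor; its carbon is not lipophilic
  met <- readLigands(probeLigandText("methanol"))[[1]]
  fm <- perceiveFeatures(met)
  expect_equal(fm@donors$name, "O1")
  expect_equal(fm@acceptors$name, "O1")
  expect_equal(nrow(fm@lipophilic), 0)

  ## chlorobenzene: one C-Cl halogen donor whose halogen has exactly one
  ## neighbour, a carbon
  clb <- readLigands(probeLigandText("chlorobenzene"))[[1]]
  fc <- perceiveFeatures(clb)
  expect_equal(nrow(fc@halogenDonors), 1)
  nb <- SIFtNA:::bondNeighbors(ligandBonds(clb), nrow(ligandAtoms(clb)))
  xIdx <- fc@halogenDonors$idx[1]
  expect_length(nb[[xIdx]], 1)
  expect_equal(ligandAtoms(clb)$element[nb[[xIdx]]], "C")
})

test_that("charged atoms never enter the lipophilic set", {
  for (kind in c("acetate", "ammonium", "methane")) {
    lig <- readLigands(probeLigandText(kind))[[1]]
    f <- perceiveFeatures(lig)
    charged <- c(f@cations$idx, f@anions$idx)
    expect_length(intersect(f@lipophilic$idx, charged), 0)
  }
  ## methane's carbon is lipophilic
  f <- perceiveFeatures(readLigands(probeLigandText("methane"))[[1]])
  expect_equal(f@lipophilic$name, "C1")
})

test_that("feature perception is invariant to atom-order permutation", {
  orig <- probeLigandText("acetate")
  lines <- orig
  nA <- 7; nB <- 6
  atomLines <- lines[5:(4 + nA)]
  bondLines <- lines[(5 + nA):(4 + nA + nB)]
  set.seed(42)
  perm <- sample(nA)
  newAtoms <- atomLines[perm]
  remap <- order(perm)   # old index -> new index
  newBonds <- vapply(bondLines, function(b) {
    i <- as.integer(substr(b, 1, 3)); j <- as.integer(substr(b, 4, 6))
    sprintf("%3d%3d%s", remap[i], remap[j], substring(b, 7))
  }, "", USE.NAMES = FALSE)
  chg <- grep("^M  CHG", lines, value = TRUE)
  oldIdx <- as.integer(substr(chg, 11, 14))
  newChg <- sprintf("M  CHG  1 %3d  -1", remap[oldIdx])
  permuted <- c(lines[1:4], newAtoms, newBonds, newChg, "M  END", "$$$$")
  f1 <- perceiveFeatures(readLigands(orig)[[1]])
  f2 <- perceiveFeatures(readLigands(paste(permuted, collapse = "\n"))[[1]])
  coordSet <- function(df) {
    m <- round(as.matrix(df[, c("x", "y", "z")]), 6)
    m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  for (slot in c("donors", "acceptors", "cations", "anions", "lipophilic"))
    expect_equal(coordSet(methods::slot(f1, slot)),
                 coordSet(methods::slot(f2, slot)), tolerance = 1e-9)
  expect_equal(length(f1@rings), length(f2@rings))
})

test_that("SMARTS matching returns deterministic atom index tuples", {
  ethanolish <- readLigands(probeLigandText("methanol"))[[1]]
  m <- matchSmarts(ethanolish, "[OX2H]")
  expect_length(m, 1)
  expect_equal(ligandAtoms(ethanolish)$element[m[[1]][1]], "O")
  ## aromatic pattern on a saturated molecule matches nothing
  expect_length(matchSmarts(readLigands(probeLigandText("methane"))[[1]],
                            "c1ccccc1"), 0)
  expect_error(matchSmarts(ethanolish, "[#6]("),
               class = "siftna_pattern_error")
  ## benzene ring match present once (unique matches)
  bz <- readLigands(probeLigandText("benzene"))[[1]]
  expect_length(matchSmarts(bz, "c1ccccc1"), 1)
})

test_that("ring geometry gives centroid and unit normal of the best-fit plane", {
  hexagon <- hexRing(c(0, 0, 0), c(0, 0, 1))
  g <- ringGeometry(hexagon)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-9)
  ## translation equivariance
  g2 <- ringGeometry(sweep(hexagon, 2, c(-1, -2, -3)))
  expect_equal(g2$centroid, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(abs(sum(g$normal * g2$normal)), 1, tolerance = 1e-9)
  ## rotation equivariance: normals rotate with the ring
  mo <- randomRigidMotion(7)
  g3 <- ringGeometry(hexagon %*% t(mo$R))
  expect_equal(abs(sum(g3$normal * (mo$R %*% g$normal))), 1, tolerance = 1e-9)
  expect_error(ringGeometry(cbind(1:4, 1:4, 1:4)),
               class = "siftna_geometry_error")
})

test_that("receptor residues carry the expected feature tables", {
  rec <- readReceptor(probeReceptor("G")$pdb)
  f <- SIFtNA:::residueFeatures(rec, 1)
  ## phosphate oxygens are anions regardless of recorded charge
  expect_setequal(f@anions$name, c("OP1", "OP2"))
  expect_true(all(c("N1", "N2", "O2'") %in% f@donors$name))
  expect_true(all(c("N3", "N7", "O6", "OP1", "OP2") %in% f@acceptors$name))
  ## purines contribute the 6- and 5-membered rings separately
  expect_length(f@rings, 2)
  expect_setequal(vapply(f@rings, function(r) length(r$members), 0L), c(5L, 6L))
  ## pyrimidine: one ring
  recU <- readReceptor(probeReceptor("U")$pdb)
  expect_length(SIFtNA:::residueFeatures(recU, 1)@rings, 1)
  ## ribose C5' is available for lipophilic contacts
  expect_true("C5'" %in% f@lipophilic$name)
  expect_false("C1'" %in% f@lipophilic$name)
})

test_that("residue SMARTS matching agrees with the feature tables", {
  for (b in c("A", "C", "G", "U")) {
    rec <- readReceptor(probeReceptor(b)$pdb)
    atoms <- residueAtoms(rec, 1)
    f <- SIFtNA:::residueFeatures(rec, 1)
    don <- sort(atoms$name[vapply(
      matchResidueSmarts(rec, 1, RECEPTOR_HB_DONOR_SMARTS), `[`, 0L, 1)])
    acc <- sort(atoms$name[vapply(
      matchResidueSmarts(rec, 1, RECEPTOR_HB_ACCEPTOR_SMARTS), `[`, 0L, 1)])
    expect_equal(don, sort(f@donors$name), info = b)
    expect_equal(acc, sort(f@acceptors$name), info = b)
  }
})
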
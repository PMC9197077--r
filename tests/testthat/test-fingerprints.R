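## helper: build a SIFt object from a bit matrix and base letters, for
## wrapper tests that do not need a structural origin
siftFromBits <- function(bits, bases, variant = "FULL") {
  channels <- siftChannels(variant)
  manifest <- data.frame(chain = "A", number = seq_along(bases),
                         name = bases, stringsAsFactors = FALSE)
  new("SIFt", variant = variant, manifest = manifest, channels = channels,
      bits = as.integer(bits), ligandId = list(title = "x", poseIndex = 1L),
      records = SIFtNA:::emptyRecords())
}

test_that("FULL fingerprints have residue-major, channel-minor layout", {
  p <- hbComplexAtResidue(c("G", "G", "G"), target = 2, distance = 3.0)
  rec <- readReceptor(p$pdb)
  lig <- readLigands(p$sdf)[[1]]
  s <- computeSIFt(rec, lig, "FULL")
  expect_length(siftBits(s), 36)
  ## the single hydrogen bond sets exactly the HB bit of residue 2
  expect_equal(sum(siftBits(s)), 1)
  expect_equal(siftBits(s)[1 * 12 + 1], 1L)
  ## a distant ligand gives the all-zero vector in any variant
  far <- makeProbeComplex(probeSpec("Contact", 50,
                                    receptorTemplate = c("G", "G", "G")))
  ligFar <- readLigands(far$sdf)[[1]]
  for (v in c("FULL", "PBS", "SIMPLE"))
    expect_equal(sum(siftBits(computeSIFt(rec, ligFar, v))), 0)
})

test_that("fingerprint output is independent of ligand atom order", {
  p <- makeProbeComplex(probeSpec("CationAnion", 4.0))
  rec <- readReceptor(p$pdb)
  lines <- p$sdf
  nA <- 5; nB <- 4
  atomLines <- lines[5:(4 + nA)]
  bondLines <- lines[(5 + nA):(4 + nA + nB)]
  perm <- c(3, 1, 5, 2, 4)
  remap <- order(perm)
  newBonds <- vapply(bondLines, function(b) {
    i <- as.integer(substr(b, 1, 3)); j <- as.integer(substr(b, 4, 6))
    sprintf("%3d%3d%s", remap[i], remap[j], substring(b, 7))
  }, "", USE.NAMES = FALSE)
  chg <- grep("^M  CHG", lines, value = TRUE)
  oldIdx <- as.integer(substr(chg, 11, 14))
  permuted <- c(lines[1:4], atomLines[perm], newBonds,
                sprintf("M  CHG  1 %3d   1", remap[oldIdx]), "M  END", "$$$$")
  s1 <- computeSIFt(rec, readLigands(p$sdf)[[1]], "FULL")
  s2 <- computeSIFt(rec, readLigands(paste(permuted, collapse = "\n"))[[1]],
                    "FULL")
  expect_equal(siftBits(s1), siftBits(s2))
})

test_that("wrappers aggregate by nucleotide class, purine class and count", {
  bases <- c("A", "C", "A", "G", "U")
  bits <- matrix(0L, nrow = 5, ncol = 12)
  bits[1, 1] <- 1L   # HB on A1
  bits[3, 1] <- 1L   # HB on A3
  bits[4, 6] <- 1L   # PiStacking on G4
  s <- siftFromBits(t(bits)[TRUE], bases)  # residue-major flatten
  s@bits <- as.integer(as.vector(t(bits)))
  acug <- wrapSIFt(s, "ACUG")
  expect_equal(acug["A", "HB"], 1L)
  expect_equal(acug["C", "HB"], 0L)
  expect_equal(acug["G", "HB"], 0L)
  expect_equal(acug["U", "HB"], 0L)
  expect_equal(acug["G", "PiStacking"], 1L)
  pupy <- wrapSIFt(s, "PuPy")
  expect_equal(pupy["Purine", "PiStacking"], 1L)
  expect_equal(pupy["Pyrimidine", "PiStacking"], 0L)
  cnt <- wrapSIFt(s, "Counter")
  expect_equal(unname(cnt["HB"]), 2L)
  expect_error(wrapSIFt(s, "Bogus"), class = "siftna_usage_error")
  ## thymine maps onto the U row
  sT <- siftFromBits(rep(0L, 12), "T")
  sT@bits[1] <- 1L
  expect_equal(wrapSIFt(sT, "ACUG")["U", "HB"], 1L)
})

test_that("wrapper identities hold on random fingerprints", {
  pop <- makeFingerprintPopulation(25, 0.3, 48, seed = 11)
  bases <- rep(c("A", "C", "G", "U"), 1)
  for (r in seq_len(nrow(pop))) {
    s <- siftFromBits(pop[r, ], bases)
    m <- matrix(pop[r, ], ncol = 12, byrow = TRUE)
    ## Counter = per-channel Hamming weight
    expect_equal(unname(wrapSIFt(s, "Counter")), colSums(m))
    ## ACUG bit = OR over residues of the class
    acug <- wrapSIFt(s, "ACUG")
    for (b in c("A", "C", "G", "U"))
      expect_equal(unname(acug[b, ]),
                   as.integer(colSums(m[bases == b, , drop = FALSE]) > 0))
    ## all-zero cascades
    if (all(pop[r, ] == 0)) {
      expect_true(all(wrapSIFt(s, "Counter") == 0))
      expect_true(all(acug == 0))
    }
  }
})

test_that("ion-profile mode fingerprints each inorganic ion separately", {
  base <- probeReceptor("G")
  op1 <- base$atoms[base$atoms$name == "OP1", ]
  pdir <- c(op1$x, op1$y, op1$z) -
    as.numeric(base$atoms[base$atoms$name == "P", c("x", "y", "z")])
  pdir <- pdir / sqrt(sum(pdir^2))
  het <- function(serial, el, resno, pos)
    sprintf("HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, toupper(el), toupper(el), "A", resno,
            pos[1], pos[2], pos[3], toupper(el))
  at <- c(op1$x, op1$y, op1$z)
  pdb <- c(setdiff(base$pdb, "END"),
           het(900, "Mg", 201, at + 3.0 * pdir),
           het(901, "K", 202, at + 40 * pdir), "END")
  rec <- readReceptor(pdb)
  sifts <- ionProfile(rec, "FULL")
  expect_length(sifts, 2)
  ## Mg at 3.0 A from OP1: inside the cation-anion window
  ch <- sifts[[1]]@channels
  expect_equal(siftBits(sifts[[1]])[match("CationAnion", ch)], 1L)
  ## only the cation-anion channel can be set for a metal ligand
  expect_equal(sum(siftBits(sifts[[1]])[-match("CationAnion", ch)]), 0)
  ## the far potassium sees nothing
  expect_equal(sum(siftBits(sifts[[2]])), 0)
  noIons <- readReceptor(probeReceptor("G")$pdb)
  expect_error(ionProfile(noIons), class = "siftna_no_ions_error")
})

test_that("SIFt TSVs round-trip bit-identically", {
  rec <- readReceptor(probeReceptor(c("G", "A", "U"))$pdb)
  p1 <- hbComplexAtResidue(c("G", "A", "U"), 1, 3.0)
  p2 <- hbComplexAtResidue(c("G", "A", "U"), 3, 3.2)
  s1 <- computeSIFt(rec, readLigands(p1$sdf)[[1]], "FULL")
  lig2 <- readLigands(p2$sdf)[[1]]
  lig2@poseIndex <- 2L
  s2 <- computeSIFt(rec, lig2, "FULL")
  tf <- tempfile(fileext = ".tsv")
  writeSiftTSV(list(s1, s2), tf)
  tab <- readSiftTSV(tf)
  expect_equal(dim(tab), c(2, 36))
  expect_equal(unname(tab[1, ]), siftBits(s1))
  expect_equal(unname(tab[2, ]), siftBits(s2))
  ## header: 1 id column + 36 bit columns with the documented names
  header <- strsplit(readLines(tf, n = 1), "\t")[[1]]
  expect_length(header, 37)
  expect_equal(header[1], "ligand_id")
  expect_equal(header[2], "A.1.G#HB")
  ## header-only file for an empty fingerprint list
  tf2 <- tempfile(fileext = ".tsv")
  writeSiftTSV(list(), tf2, reference = s1)
  expect_length(readLines(tf2), 1)
  expect_equal(nrow(readSiftTSV(tf2)), 0)
  ## mixed variants are rejected
  sS <- computeSIFt(rec, readLigands(p1$sdf)[[1]], "SIMPLE")
  expect_error(writeSiftTSV(list(s1, sS), tempfile()),
               class = "siftna_manifest_error")
})

test_that("detail TSV lists interactions with fixed-precision geometry", {
  p <- makeProbeComplex(probeSpec("HB", 2.85))
  rec <- readReceptor(p$pdb)
  s <- computeSIFt(rec, readLigands(p$sdf)[[1]], "FULL")
  tf <- tempfile(fileext = ".tsv")
  writeDetailTSV(siftRecords(s), tf)
  tab <- read.delim(tf, colClasses = "character")
  expect_equal(names(tab)[1:4],
               c("ligand_title", "pose", "interaction_type", "subtype"))
  expect_equal(tab$distance[tab$interaction_type == "HB" &
                              tab$receptor_atoms == "N1"], "2.850")
  ## stacking rows carry ring centroids as coordinates
  ps <- makeProbeComplex(probeSpec("PiStacking", 3.5))
  sps <- computeSIFt(readReceptor(ps$pdb), readLigands(ps$sdf)[[1]], "FULL")
  tf2 <- tempfile(fileext = ".tsv")
  writeDetailTSV(siftRecords(sps), tf2)
  tab2 <- read.delim(tf2, colClasses = "character")
  stack <- tab2[tab2$interaction_type == "PiStacking", ]
  expect_equal(nrow(stack), 1)
  expect_match(stack$receptor_atoms, "\\+")
  expect_match(stack$receptor_xyz, "^-?[0-9.]+,-?[0-9.]+,-?[0-9.]+$")
  ## empty records give a header-only file
  tf3 <- tempfile(fileext = ".tsv")
  writeDetailTSV(SIFtNA:::emptyRecords(), tf3)
  expect_length(readLines(tf3), 1)
})
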
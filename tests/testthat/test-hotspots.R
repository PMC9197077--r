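## fabricate detail records with the fields the statistics consume
fakeRecord <- function(itype, resname, atom, resno = 1, chain = "A",
                       distance = 3.0, complex = "c1") {
  data.frame(itype = itype, subtype = NA_character_, chain = chain,
             resno = resno, resname = resname, receptorAtoms = atom,
             distance = distance, complex = complex, stringsAsFactors = FALSE)
}

test_that("per-atom statistics count and normalize per interaction type", {
  recs <- rbind(
    do.call(rbind, replicate(4, fakeRecord("HB", "G", "N7"), simplify = FALSE)),
    do.call(rbind, replicate(3, fakeRecord("HB", "A", "N1", resno = 2),
                             simplify = FALSE)),
    do.call(rbind, replicate(3, fakeRecord("HB", "C", "O2", resno = 3),
                             simplify = FALSE)),
    fakeRecord("Lipophilic", "G", "C5'"))
  tab <- atomInteractionStats(recs)
  g <- tab[tab$residue_name == "G" & tab$atom_name == "N7", ]
  expect_equal(g$count, 4L)
  expect_equal(g$pct_of_type, 40)
  ## percentages sum to 100 within each interaction type
  for (t in unique(tab$itype))
    expect_equal(sum(tab$pct_of_type[tab$itype == t]), 100, tolerance = 0.01)
  expect_equal(nrow(atomInteractionStats(SIFtNA:::emptyRecords())), 0)
  ## pooling across complexes adds counts
  recs2 <- rbind(recs, transform(fakeRecord("HB", "G", "N7"), complex = "c2"))
  tab2 <- atomInteractionStats(recs2)
  expect_equal(tab2$count[tab2$atom_name == "N7" & tab2$itype == "HB"], 5L)
})

test_that("group rollup splits counts into phosphate, sugar and base", {
  recs <- rbind(fakeRecord("HB", "G", "OP1"), fakeRecord("HB", "G", "O2'"),
                fakeRecord("HB", "G", "N7"), fakeRecord("HB", "G", "O6"))
  g <- groupInteractionStats(recs)
  expect_equal(g$count[g$group == "BASE"], 2L)
  expect_equal(g$pct[g$group == "PHOSPHATE"], 25)
  expect_equal(sum(g$pct), 100)
})

test_that("nucleobase faces partition the hydrogen-bonding atoms", {
  expect_equal(faceOf("A", "N1"), "WatsonCrick")
  expect_equal(faceOf("G", "N7"), "Hoogsteen")
  expect_equal(faceOf("C", "O2"), "Sugar")
  expect_error(faceOf("G", "C8"), class = "siftna_face_error")
  fm <- defaultFaceMap()
  for (b in names(fm)) {
    ## every mapped atom gets exactly one face (named vector => unique keys)
    expect_false(anyDuplicated(names(fm[[b]])) > 0)
    expect_true(all(fm[[b]] %in% c("WatsonCrick", "Hoogsteen", "Sugar")))
    ## every hydrogen-bond-capable base atom of the built-in tables is mapped
    hb <- SIFtNA:::BASE_HB[[b]]
    expect_true(all(c(hb$donors, setdiff(hb$acceptors, "")) %in%
                      names(fm[[b]])))
  }
})

test_that("unique-residue counts deduplicate by residue and complex", {
  recs <- rbind(fakeRecord("HB", "G", "N7", resno = 7),
                fakeRecord("HB", "G", "O6", resno = 7),
                fakeRecord("HB", "G", "N1", resno = 7))
  expect_equal(unname(uniqueResidueCounts(recs)["HB"]), 1L)
  recs2 <- rbind(recs, fakeRecord("HB", "A", "N1", resno = 9))
  expect_equal(unname(uniqueResidueCounts(recs2)["HB"]), 2L)
  ## the same residue number in another complex counts again
  recs3 <- rbind(recs, transform(fakeRecord("HB", "G", "N7", resno = 7),
                                 complex = "c2"))
  expect_equal(unname(uniqueResidueCounts(recs3)["HB"]), 2L)
  expect_length(uniqueResidueCounts(SIFtNA:::emptyRecords()), 0)
  ## never exceeds raw record counts
  expect_lte(uniqueResidueCounts(recs2)["HB"], sum(recs2$itype == "HB"))
})

test_that("distance histograms conserve counts over fixed-width bins", {
  d <- c(2.71, 2.74, 2.9, 3.3, 3.71)
  recs <- do.call(rbind, lapply(d, function(x)
    fakeRecord("HB", "G", "N7", distance = x)))
  h <- distanceHistogram(recs, "HB", binWidth = 0.2, range = c(0, 3.9))
  expect_equal(sum(h$count), 5)
  ## constant width except a possibly truncated final bin at the cutoff
  w <- h$upper - h$lower
  expect_equal(w[-length(w)], rep(0.2, nrow(h) - 1), tolerance = 1e-9)
  expect_lte(w[length(w)], 0.2 + 1e-9)
  ## all records at one distance occupy a single bin
  one <- do.call(rbind, replicate(7, fakeRecord("HB", "G", "N7",
                                                distance = 2.85),
                                  simplify = FALSE))
  h1 <- distanceHistogram(one, "HB", 0.2, c(0, 3.9))
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(max(h1$count), 7)
  ## empty input gives all-zero bins
  h0 <- distanceHistogram(SIFtNA:::emptyRecords(), "HB", 0.2, c(0, 3.9))
  expect_true(all(h0$count == 0))
  expect_error(distanceHistogram(recs, "HB", binWidth = 0),
               class = "siftna_usage_error")
})

test_that("surveyInteractions pools detail files into hot-spot statistics", {
  mk <- function(spec) {
    p <- makeProbeComplex(spec)
    s <- computeSIFt(readReceptor(p$pdb), readLigands(p$sdf)[[1]], "FULL")
    tf <- tempfile(fileext = ".tsv")
    writeDetailTSV(siftRecords(s), tf)
    tf
  }
  paths <- c(mk(probeSpec("HB", 3.0)), mk(probeSpec("CationAnion", 4.0)),
             mk(probeSpec("PiStacking", 3.5)))
  sv <- surveyInteractions(paths)
  expect_true(all(c("HB", "CationAnion", "PiStacking") %in%
                    names(sv$totals)))
  expect_true(all(c("records", "atoms", "groups", "uniqueResidues") %in%
                    names(sv)))
  expect_gte(sv$uniqueResidues[["CationAnion"]], 1)
  for (t in unique(sv$atoms$itype))
    expect_equal(sum(sv$atoms$pct_of_type[sv$atoms$itype == t]), 100,
                 tolerance = 0.01)
})
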
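test_that("receptor parsing orders residues and routes waters and ions", {
  pr <- probeReceptor(c("A", "C", "G"))
  het <- function(serial, name, resname, resno, x, el)
    sprintf("HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resname, "A", resno, x, x, x, toupper(el))
  extra <- c(het(900, "MG", "MG", 201, 30, "Mg"),
             het(901, "O", "HOH", 101, 33, "O"))
  pdb <- c(setdiff(pr$pdb, "END"), extra, "END")
  rec <- readReceptor(pdb)
  res <- residues(rec)
  expect_equal(res$number, 1:3)
  expect_equal(res$name, c("A", "C", "G"))
  expect_equal(nrow(rec@ions), 1)
  expect_equal(rec@ions$element, "Mg")
  expect_equal(nrow(rec@waters), 1)
  ## the ion/water routing leaves the residues untouched
  expect_equal(nrow(rec@atoms), nrow(pr$atoms))
})

test_that("duplicate residue numbers across chains are rejected", {
  one <- probeReceptor("G")$pdb
  asChain <- function(lines, ch, resno) {
    body <- grep("^ATOM", lines, value = TRUE)
    substr(body, 23, 26) <- sprintf("%4d", resno)
    substr(body, 22, 22) <- ch
    body
  }
  pdb <- c(asChain(one, "A", 5), asChain(one, "B", 5), "END")
  expect_error(readReceptor(pdb), class = "siftna_unique_numbering_error")
  ## distinct numbers on distinct chains are fine
  pdb2 <- c(asChain(one, "A", 5), asChain(one, "B", 6), "END")
  expect_equal(nrow(residues(readReceptor(pdb2))), 2)
})

test_that("unsupported inputs raise typed parse errors", {
  expect_error(readReceptor("no atoms here"), class = "siftna_parse_error")
  ## organic HETATM (a buffer molecule) must be removed beforehand
  pdb <- c(probeReceptor("G")$pdb[1:5],
           "HETATM 900  C1  GOL A 301       9.000   9.000   9.000  1.00  0.00           C",
           "HETATM 901  O1  GOL A 301       9.500   9.500   9.000  1.00  0.00           O",
           "END")
  expect_error(readReceptor(pdb), class = "siftna_parse_error")
  ## unknown residue with no nucleotide-like atoms
  pdb2 <- c("ATOM      1 XX1  LIG A   1       1.000   1.000   1.000  1.00  0.00           X",
            "END")
  expect_error(readReceptor(pdb2),
               class = "siftna_unsupported_residue_error")
})

test_that("only the first model of a multi-model PDB is read", {
  one <- probeReceptor("G")$pdb
  body <- setdiff(one, "END")
  pdb <- c("MODEL     1", body, "ENDMDL", "MODEL     2", body, "ENDMDL", "END")
  rec <- readReceptor(pdb)
  expect_equal(nrow(residues(rec)), 1)
})

test_that("ligand SDF parsing preserves order, charges and structure", {
  sdf <- c(probeLigandText("methanol"), probeLigandText("ammonium"),
           probeLigandText("acetate"))
  ligs <- readLigands(sdf)
  expect_length(ligs, 3)
  expect_equal(vapply(ligs, function(l) l@poseIndex, 0L), 1:3)
  ## CHG properties preserved exactly
  amm <- ligandAtoms(ligs[[2]])
  expect_equal(amm$charge[amm$element == "N"], 1L)
  ace <- ligandAtoms(ligs[[3]])
  expect_equal(sort(ace$charge[ace$element == "O"]), c(-1L, 0L))
  ## bonds are read with indices in range
  expect_true(all(ligandBonds(ligs[[1]])$i <= nrow(ligandAtoms(ligs[[1]]))))
})

test_that("malformed SDF records are rejected", {
  expect_error(readLigands("   \n"), class = "siftna_parse_error")
  trunc <- probeLigandText("methanol")
  trunc <- trunc[1:(length(trunc) - 4)]  # drop bonds + M END + $$$$
  expect_error(readLigands(paste(c(trunc, "$$$$"), collapse = "\n")),
               class = "siftna_parse_error")
})

test_that("atom names classify into the phosphate/sugar/base partition", {
  expect_equal(classifyAtomName(c("P", "OP1", "OP2", "OP3", "O5'", "O3'")),
               rep("PHOSPHATE", 6))
  expect_equal(classifyAtomName(c("C1'", "C5'", "O4'", "O2'")),
               rep("SUGAR", 4))
  expect_equal(classifyAtomName(c("N7", "O6", "C5M")), rep("BASE", 3))
  expect_error(classifyAtomName("QZX"),
               class = "siftna_unclassifiable_atom_error")
  ## every non-hydrogen template atom gets exactly one label, hydrogens
  ## inherit their heavy atom's group
  for (b in c("A", "C", "G", "U", "T")) {
    t <- nucleotideTemplate(b)
    t$isH <- t$element == "H"
    grp <- classifyResidueAtoms(t)
    expect_false(anyNA(grp))
    expect_true(all(grp %in% c("PHOSPHATE", "SUGAR", "BASE")))
    expect_equal(grp[t$name == "H1'"], "SUGAR")
    expect_equal(grp[t$name == "HO2'"], "SUGAR")
  }
})

test_that("receptor round-trips through PDB text", {
  p <- makeProbeComplex(probeSpec("Water_mediated", 2.8))
  rec1 <- readReceptor(p$pdb)
  rec2 <- readReceptor(writeReceptorPDB(rec1))
  expect_equal(residues(rec1), residues(rec2))
  expect_equal(rec1@atoms$name, rec2@atoms$name)
  expect_equal(rec1@atoms[, c("x", "y", "z")], rec2@atoms[, c("x", "y", "z")],
               tolerance = 1e-9)
  expect_equal(nrow(rec1@waters), nrow(rec2@waters))
})

test_that("hydrogen addition preserves heavy atoms and formal charges", {
  bare <- paste(c("methane", "  test", "",
                  "  1  0  0  0  0  0  0  0  0  0999 V2000",
                  "    0.0000    0.0000    0.0000 C   0  0",
                  "M  END", "$$$$", ""), collapse = "\n")
  lig <- readLigands(bare)[[1]]
  expect_identical(addHydrogens(lig, "none"), lig)
  for (method in c("openbabel", "rdkit")) {
    out <- addHydrogens(lig, method)
    expect_equal(sum(ligandAtoms(out)$element == "H"), 4)
    expect_equal(sum(!ligandAtoms(out)$isH), 1)
  }
  ## pentavalent neutral carbon cannot be sanitized
  penta <- paste(c("bad", "  test", "",
                   "  6  5  0  0  0  0  0  0  0  0999 V2000",
                   "    0.0000    0.0000    0.0000 C   0  0",
                   "    1.5000    0.0000    0.0000 C   0  0",
                   "   -1.5000    0.0000    0.0000 C   0  0",
                   "    0.0000    1.5000    0.0000 C   0  0",
                   "    0.0000   -1.5000    0.0000 C   0  0",
                   "    0.0000    0.0000    1.5000 C   0  0",
                   " 1  2  1  0", " 1  3  1  0", " 1  4  1  0",
                   " 1  5  1  0", " 1  6  1  0",
                   "M  END", "$$$$", ""), collapse = "\n")
  lig2 <- readLigands(penta)[[1]]
  expect_error(addHydrogens(lig2, "openbabel"),
               class = "siftna_sanitization_error")
})

test_that("a receptor of only waters and ions parses with zero residues", {
  pdb <- c(
    "HETATM    1  O   HOH A 101       1.000   1.000   1.000  1.00  0.00           O",
    "HETATM    2 MG    MG A 201       4.000   4.000   4.000  1.00  0.00          MG",
    "END")
  rec <- readReceptor(pdb)
  expect_equal(nrow(residues(rec)), 0)
  expect_equal(nrow(rec@waters), 1)
  expect_equal(nrow(rec@ions), 1)
  lig <- readLigands(probeLigandText("methanol"))[[1]]
  expect_error(computeSIFt(rec, lig, "FULL"),
               class = "siftna_empty_receptor_error")
})
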
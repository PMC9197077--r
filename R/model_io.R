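## Input parsing: receptor PDB (record parsing via bio3d; routing and
## classification here) and ligand SDF (via OpenBabel, which preserves
## M CHG formal charges).

WATER_NAMES <- c("HOH", "WAT", "H2O")

isTextInput <- function(x) length(x) > 1 || grepl("\n", x) || !file.exists(x)

asFile <- function(x, ext) {
  if (isTextInput(x)) {
    tf <- tempfile(fileext = ext)
    writeLines(paste(x, collapse = "\n"), tf)
    tf
  } else x
}

#' Read a nucleic-acid receptor from PDB
#'
#' Parses one RNA or DNA model (at most the first \code{MODEL} of a
#' multi-model file is read). Water residues (HOH/WAT/H2O) are routed to
#' the \code{waters} slot, single-atom HETATM records of metal elements to
#' \code{ions}; any other HETATM (organic ligand or buffer) is an error,
#' as such molecules must be removed before the analysis. Every
#' non-hydrogen residue atom receives a phosphate/sugar/base group label
#' and residue numbering must be unique across all chains.
#'
#' @param input Path to a PDB file, or PDB text (character vector or a
#'   single string with newlines).
#' @param metalSet Element symbols recognized as inorganic cations.
#' @return A [Receptor-class] object.
#' @examples
#' pdb <- makeProbeComplex(probeSpec("HB", distance = 3.0))$pdb
#' rec <- readReceptor(pdb)
#' residues(rec)
#' @export
readReceptor <- function(input, metalSet = DEFAULT_METAL_SET) {
  path <- asFile(input, ".pdb")
  src <- if (isTextInput(input)) "" else normalizePath(input)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec))
    siftStop("siftna_parse_error", "no ATOM/HETATM records found")
  ## first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) {
    keep <- seq_len(endm[1] - 1)
    tf <- tempfile(fileext = ".pdb")
    writeLines(lines[keep], tf)
    path <- tf
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  if (!nrow(at))
    siftStop("siftna_parse_error", "no atoms parsed from PDB input")
  element <- at$elesy
  noEl <- is.na(element) | !nzchar(trimws(element))
  element[noEl] <- guessElement(at$elety[noEl])
  element <- normalizeElementCase(trimws(element))
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, resname = trimws(at$resid),
    isH = element == "H", stringsAsFactors = FALSE)
  isWater <- atoms$resname %in% WATER_NAMES
  isHet <- at$type == "HETATM" & !isWater
  ionRows <- logical(nrow(atoms))
  if (any(isHet)) {
    for (key in unique(paste(atoms$chain, atoms$resno)[isHet])) {
      sel <- paste(atoms$chain, atoms$resno) == key & isHet
      if (sum(sel) == 1 && atoms$element[sel] %in% metalSet) {
        ionRows[sel] <- TRUE
      } else {
        siftStop("siftna_parse_error",
                 "HETATM residue '%s' (%s) is neither water nor a metal ion; remove ligands/buffer before parsing",
                 atoms$resname[sel][1], key)
      }
    }
  }
  res <- atoms[!isWater & !ionRows, , drop = FALSE]
  if (nrow(res)) {
    ## unique numbering across the whole receptor
    key <- paste(res$chain, res$resno)
    firstOfRes <- !duplicated(key)
    if (anyDuplicated(res$resno[firstOfRes]))
      siftStop("siftna_unique_numbering_error",
               "residue numbers are not unique across chains: %s",
               paste(unique(res$resno[firstOfRes][duplicated(res$resno[firstOfRes])]),
                     collapse = ", "))
    ## residue support check + group classification
    res <- res[order(match(res$chain, unique(res$chain)), res$resno), , drop = FALSE]
    grp <- rep(NA_character_, nrow(res))
    for (rn in unique(res$resno)) {
      sel <- res$resno == rn
      ra <- res[sel, , drop = FALSE]
      known <- !is.na(normalizeBaseName(ra$resname[1]))
      overlap <- any(ra$name %in% c(PHOSPHATE_NAMES, SUGAR_NAMES) |
                       grepl("^[CNO][0-9]$", ra$name))
      if (!known && !overlap)
        siftStop("siftna_unsupported_residue_error",
                 "residue %s/%d (%s) is not a recognizable nucleotide",
                 ra$chain[1], rn, ra$resname[1])
      grp[sel] <- classifyResidueAtoms(ra)
    }
    res$group <- grp
  } else {
    res$group <- character(0)
  }
  wat <- atoms[isWater & atoms$element == "O", , drop = FALSE]
  wat$group <- rep(NA_character_, nrow(wat))
  ion <- atoms[ionRows, , drop = FALSE]
  ion$group <- rep(NA_character_, nrow(ion))
  new("Receptor", atoms = res, waters = wat, ions = ion, sourcePath = src)
}

## Old-style O1P/O2P names are normalized on classification input.
guessElement <- function(elety) {
  nm <- trimws(elety)
  el <- sub("^([A-Za-z]{1,2}).*$", "\\1", nm)
  one <- substr(el, 1, 1)
  ifelse(one %in% c("H", "C", "N", "O", "P", "S"), one, el)
}

normalizeElementCase <- function(el) {
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' Group labels for the atoms of one residue
#'
#' Assigns each atom of a nucleotide residue to the PHOSPHATE, SUGAR or
#' BASE group. Heavy atoms are classified by [classifyAtomName()];
#' hydrogens inherit the group of their nearest heavy atom.
#'
#' @param atoms data.frame with columns \code{name}, \code{element} (or
#'   \code{isH}), \code{x}, \code{y}, \code{z}.
#' @return Character vector of group labels, parallel to \code{atoms} rows.
#' @export
classifyResidueAtoms <- function(atoms) {
  isH <- if ("isH" %in% names(atoms)) atoms$isH else atoms$element == "H"
  name <- sub("^O([123])P$", "OP\\1", atoms$name)
  grp <- rep(NA_character_, nrow(atoms))
  grp[!isH] <- classifyAtomName(name[!isH])
  if (any(isH)) {
    heavy <- which(!isH)
    if (!length(heavy))
      siftStop("siftna_unclassifiable_atom_error", "residue has only hydrogens")
    hm <- as.matrix(atoms[isH, c("x", "y", "z")])
    dm <- crossDist(hm, as.matrix(atoms[heavy, c("x", "y", "z")]))
    grp[isH] <- grp[heavy][apply(dm, 1, which.min)]
  }
  grp
}

#' Serialize a receptor back to PDB text
#'
#' Writes residues (chain order, then residue number), then waters, then
#' ions, in the same dialect [readReceptor()] parses; coordinates keep the
#' PDB fixed three-decimal precision.
#'
#' @param receptor A [Receptor-class] object.
#' @param path Optional output file; when NULL the text is returned.
#' @return Character vector of PDB lines (invisibly when \code{path} given).
#' @export
writeReceptorPDB <- function(receptor, path = NULL) {
  stopifnot(is(receptor, "Receptor"))
  fmtName <- function(n)
    sprintf("%-4.4s", ifelse(nchar(n) >= 4, n, paste0(" ", n)))
  line <- function(type, serial, name, resname, chain, resno, x, y, z, el)
    sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial, fmtName(name), resname, chain, resno, x, y, z,
            toupper(el))
  out <- character(0)
  serial <- 0L
  emit <- function(df, type) {
    if (!nrow(df)) return(invisible(NULL))
    ser <- serial + seq_len(nrow(df))
    serial <<- serial + nrow(df)
    out <<- c(out, line(type, ser, df$name, df$resname, df$chain,
                        df$resno, df$x, df$y, df$z, df$element))
  }
  emit(receptor@atoms, "ATOM")
  emit(receptor@waters, "HETATM")
  emit(receptor@ions, "HETATM")
  out <- c(out, "END")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

## ---------------------------------------------------------------------------
## Ligand SDF

#' Read ligand records from an SDF file
#'
#' Parses a (possibly multi-record) V2000/V3000 SDF through OpenBabel,
#' preserving formal charges from the atom block and \code{M CHG}
#' properties exactly. Records receive a 1-based \code{poseIndex} in file
#' order.
#'
#' @param input Path to an SDF file, or SDF text.
#' @return List of [Ligand-class] objects.
#' @examples
#' sdf <- makeProbeComplex(probeSpec("HB", distance = 3.0))$sdf
#' lig <- readLigands(sdf)[[1]]
#' @export
readLigands <- function(input) {
  text <- if (isTextInput(input)) paste(input, collapse = "\n")
          else paste(readLines(input, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(text)))
    siftStop("siftna_parse_error", "empty SDF input")
  blocks <- strsplit(text, "\\$\\$\\$\\$[ \t]*\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (!length(blocks))
    siftStop("siftna_parse_error", "no SDF records found")
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    block <- sub("\n+$", "", blocks[[k]])
    validateMolBlock(block)
    molBlock <- paste0(block, "\n$$$$\n")
    dat <- withOBMol(molBlock, "SDF", obMolData)
    if (is.null(dat) || !nrow(dat$atoms))
      siftStop("siftna_parse_error", "SDF record %d could not be parsed", k)
    title <- trimws(strsplit(block, "\n")[[1]][1])
    atoms <- dat$atoms
    atoms$isH <- atoms$element == "H"
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
    out[[k]] <- new("Ligand", title = title, poseIndex = k,
                    atoms = atoms, bonds = dat$bonds, molBlock = molBlock)
  }
  out
}

## Structural validation of a V2000 record (counts line vs block lengths);
## V3000 records are delegated to OpenBabel untouched.
validateMolBlock <- function(block) {
  lines <- strsplit(block, "\n")[[1]]
  if (length(lines) < 4)
    siftStop("siftna_parse_error", "truncated SDF record")
  counts <- lines[4]
  if (grepl("V3000", counts)) return(invisible(TRUE))
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nA) || is.na(nB))
    siftStop("siftna_parse_error", "malformed counts line: %s", counts)
  body <- lines[-(1:4)]
  mEnd <- grep("^M  END", body)
  nBody <- if (length(mEnd)) mEnd[1] - 1 else length(body)
  if (nBody < nA + nB)
    siftStop("siftna_parse_error",
             "atom/bond block inconsistent with counts line (%d atoms, %d bonds declared)",
             nA, nB)
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Hydrogen addition

MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 6, P = 5, F = 1, Cl = 1, Br = 1, I = 1)

checkValences <- function(ligand) {
  a <- ligand@atoms
  b <- ligand@bonds
  if (!nrow(b)) return(invisible(TRUE))
  bsum <- numeric(nrow(a))
  for (k in seq_len(nrow(b))) {
    o <- b$order[k]
    bsum[b$i[k]] <- bsum[b$i[k]] + o
    bsum[b$j[k]] <- bsum[b$j[k]] + o
  }
  for (i in seq_len(nrow(a))) {
    mv <- MAX_VALENCE[a$element[i]]
    if (is.na(mv)) next
    if (bsum[i] > mv + a$charge[i] * (if (a$element[i] %in% c("N", "C")) 1 else -1))
      siftStop("siftna_sanitization_error",
               "atom %d (%s) exceeds allowed valence (%g bonds)",
               i, a$element[i], bsum[i])
  }
  invisible(TRUE)
}

#' Add explicit hydrogens to a ligand record
#'
#' \code{method = "openbabel"} uses OpenBabel's hydrogen-adding algorithm,
#' \code{method = "rdkit"} shells out to the Python RDKit
#' (\code{Chem.AddHs} with coordinate generation), and \code{method =
#' "none"} returns the input untouched. Heavy-atom coordinates and formal
#' charges are preserved in every mode.
#'
#' @param ligand A [Ligand-class] object.
#' @param method One of \code{"openbabel"}, \code{"rdkit"}, \code{"none"}.
#' @return A [Ligand-class] object with explicit hydrogens.
#' @export
addHydrogens <- function(ligand, method = c("openbabel", "rdkit", "none")) {
  method <- match.arg(method)
  stopifnot(is(ligand, "Ligand"))
  if (method == "none") return(ligand)
  checkValences(ligand)
  outBlock <- switch(method,
    openbabel = withOBMol(ligand@molBlock, "SDF", function(m) {
      obFun("OBMol_AddHydrogens")(m)
      conv <- obFun("OBConversion")()
      on.exit(obFun("delete_OBConversion")(conv), add = TRUE)
      obFun("OBConversion_SetOutFormat")(conv, "SDF")
      obFun("OBConversion_WriteString")(conv, m)
    }),
    rdkit = {
      script <- paste(
        "import sys",
        "from rdkit import Chem",
        "m = Chem.MolFromMolBlock(sys.stdin.read(), removeHs=False)",
        "sys.exit(3) if m is None else None",
        "m = Chem.AddHs(m, addCoords=True)",
        "print(Chem.MolToMolBlock(m))",
        sep = "\n")
      res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                      input = ligand@molBlock,
                                      stdout = TRUE, stderr = FALSE))
      status <- attr(res, "status") %||% 0L
      if (status != 0)
        siftStop("siftna_sanitization_error",
                 "RDKit could not sanitize ligand '%s'", ligand@title)
      paste0(paste(res, collapse = "\n"), "\n$$$$\n")
    })
  if (is.null(outBlock) || !nzchar(outBlock))
    siftStop("siftna_sanitization_error", "hydrogen addition failed")
  newLig <- readLigands(outBlock)[[1]]
  newLig@title <- ligand@title
  newLig@poseIndex <- ligand@poseIndex
  ## formal charges survive round-trips through both toolkits, but assert
  heavyOld <- ligand@atoms[!ligand@atoms$isH, ]
  heavyNew <- newLig@atoms[!newLig@atoms$isH, ]
  if (nrow(heavyOld) != nrow(heavyNew) ||
      max(abs(as.matrix(heavyOld[, c("x", "y", "z")]) -
              as.matrix(heavyNew[, c("x", "y", "z")]))) > 1e-3)
    siftStop("siftna_sanitization_error",
             "hydrogen addition moved heavy atoms for '%s'", ligand@title)
  validObject(newLig)
  newLig
}
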
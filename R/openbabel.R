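## Bridge to the OpenBabel API shipped with ChemmineOB. The high-level
## ChemmineR wrappers discard formal charges and SMARTS atom maps, so the
## package calls the underlying SWIG bindings directly.

obFun <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <- utils::getFromNamespace(name, "ChemmineOB")
    cache[[name]]
  }
})

## Run `fn` on the first OBMol parsed from `text` in the given format
## ("SDF" or "PDB") and return fn's value.
withOBMol <- function(text, format, fn) {
  out <- NULL
  ChemmineOB::forEachMol(format, text, function(m) {
    if (is.null(out)) out <<- fn(m)
    invisible(NULL)
  })
  out
}

## Extract atoms/bonds/aromaticity from an OBMol into plain data frames.
obMolData <- function(m) {
  nA <- obFun("OBMol_NumAtoms")(m)
  nB <- obFun("OBMol_NumBonds")(m)
  getAtom <- obFun("OBMol_GetAtom")
  atomicNum <- obFun("OBAtom_GetAtomicNum")
  charge <- obFun("OBAtom_GetFormalCharge")
  isArom <- obFun("OBAtom_IsAromatic")
  gx <- obFun("OBAtom_GetX"); gy <- obFun("OBAtom_GetY"); gz <- obFun("OBAtom_GetZ")
  el <- character(nA); x <- y <- z <- numeric(nA)
  chg <- integer(nA); arom <- logical(nA)
  for (i in seq_len(nA)) {
    a <- getAtom(m, i)
    el[i] <- elementSymbol(atomicNum(a))
    x[i] <- gx(a); y[i] <- gy(a); z[i] <- gz(a)
    chg[i] <- charge(a); arom[i] <- isArom(a)
  }
  atoms <- data.frame(element = el, x = x, y = y, z = z, charge = chg,
                      aromatic = arom, stringsAsFactors = FALSE)
  getBond <- obFun("OBMol_GetBond")
  bi <- obFun("OBBond_GetBeginAtomIdx"); be <- obFun("OBBond_GetEndAtomIdx")
  bo <- obFun("OBBond_GetBondOrder"); ba <- obFun("OBBond_IsAromatic")
  i <- j <- ord <- integer(nB); barom <- logical(nB)
  for (k in seq_len(nB)) {
    b <- getBond(m, k - 1L)
    i[k] <- bi(b); j[k] <- be(b); ord[k] <- bo(b); barom[k] <- ba(b)
  }
  bonds <- data.frame(i = i, j = j, order = ord, aromatic = barom)
  list(atoms = atoms, bonds = bonds)
}

## Smallest-set-of-smallest-rings as a list of atom index vectors, with
## aromaticity flags.
obMolRings <- function(m) {
  obFun("OBMol_FindRingAtomsAndBonds")(m)
  obFun("OBMol_FindSSSR")(m)
  rv <- obFun("OBMol_GetSSSR")(m)
  n <- obFun("vectorpOBRing_size")(rv)
  getItem <- obFun("vectorpOBRing___getitem__")
  lapply(seq_len(n), function(k) {
    r <- getItem(rv, k - 1L)
    list(members = as.integer(obFun("OBRing__path_get")(r)),
         aromatic = isTRUE(obFun("OBRing_IsAromatic")(r)))
  })
}

## compiled SMARTS patterns are cached by pattern string
obSmartsCompiled <- local({
  cache <- new.env(parent = emptyenv())
  function(pattern) {
    sp <- cache[[pattern]]
    if (!is.null(sp)) return(sp)
    sp <- obFun("OBSmartsPattern")()
    ok <- suppressWarnings(tryCatch(obFun("OBSmartsPattern_Init")(sp, pattern),
                                    error = function(e) FALSE))
    if (!isTRUE(ok)) {
      obFun("delete_OBSmartsPattern")(sp)
      siftStop("siftna_pattern_error", "invalid SMARTS pattern: %s", pattern)
    }
    cache[[pattern]] <- sp
    sp
  }
})

## SMARTS match: list of integer vectors of 1-based atom indices.
obSmartsMatch <- function(m, pattern, unique = TRUE) {
  sp <- obSmartsCompiled(pattern)
  obFun("OBSmartsPattern_Match")(sp, m)
  maps <- if (unique) obFun("OBSmartsPattern_GetUMapList")(sp)
          else obFun("OBSmartsPattern_GetMapList")(sp)
  maps <- lapply(maps, as.integer)
  ## deterministic ordering by first atom index, then lexicographic
  if (length(maps) > 1) {
    key <- vapply(maps, function(mm) paste(sprintf("%06d", mm), collapse = ""), "")
    maps <- maps[order(key)]
  }
  maps
}

## Number of atoms in a SMARTS pattern (for plugin anchor validation).
obSmartsNumAtoms <- function(pattern) {
  obFun("OBSmartsPattern_NumAtoms")(obSmartsCompiled(pattern))
}

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

elementSymbol <- function(z) {
  ifelse(z >= 1 & z <= length(ELEMENT_SYMBOLS), ELEMENT_SYMBOLS[z], "X")
}
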
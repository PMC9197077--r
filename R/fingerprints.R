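## SIFt assembly: run the detectors over all residues of a receptor for
## one ligand record, set bits per (residue, channel), and write/read the
## tab-separated outputs.

#' Detect all interactions between a receptor and one ligand
#'
#' Runs the twelve built-in detection channels (plus any plugins) for
#' every residue of the receptor against one ligand record, and returns
#' the detailed interaction records annotated with residue identity and
#' ligand identity. Mediating waters and ions are taken from the receptor
#' file. For a bare metal-cation ligand only the cation-anion channel is
#' evaluated.
#'
#' @param receptor A [Receptor-class] object.
#' @param ligand A [Ligand-class] object.
#' @param cfg A [GeometryConfig-class].
#' @param hbMode Hydrogen-bond criterion, \code{"distance"} or \code{"dha"}.
#' @param plugins List of plugin definitions from [loadPluginFile()].
#' @param featL Optional precomputed ligand [FeatureSet-class].
#' @param featRList Optional precomputed per-residue feature sets
#'   (from [receptorFeatureList()]).
#' @return data.frame of interaction records.
#' @export
detectInteractions <- function(receptor, ligand, cfg = geometryConfig(),
                               hbMode = c("distance", "dha"),
                               plugins = list(), featL = NULL,
                               featRList = NULL) {
  hbMode <- match.arg(hbMode)
  stopifnot(is(receptor, "Receptor"), is(ligand, "Ligand"))
  res <- residues(receptor)
  if (!nrow(res)) return(emptyRecords())
  metalLigand <- isMetalLigand(ligand, cfg)
  if (is.null(featL)) featL <- if (metalLigand) metalLigandFeatures(ligand)
                               else perceiveFeatures(ligand, cfg)
  if (is.null(featRList)) featRList <- receptorFeatureList(receptor, cfg)
  all <- list()
  for (r in seq_len(nrow(res))) {
    featR <- featRList[[as.character(res$number[r])]]
    recs <- if (metalLigand) {
      detectCationAnion(featR, featL, cfg)
    } else bindRecords(list(
      detectHydrogenBonds(featR, featL, cfg, hbMode),
      detectHalogenBonds(featR, featL, cfg),
      detectCationAnion(featR, featL, cfg),
      detectPiIon(featR, featL, cfg, "cation"),
      detectPiIon(featR, featL, cfg, "anion"),
      detectPiStacking(featR, featL, cfg),
      detectIonMediated(featR, featL, receptor@ions, cfg),
      detectWaterMediated(featR, featL, receptor@waters, cfg),
      detectLipophilic(featR, featL, cfg)))
    if (length(plugins) && !metalLigand) {
      prec <- lapply(plugins, function(p)
        evaluatePlugin(p, receptor, res$number[r], ligand, cfg))
      recs <- bindRecords(c(list(recs), prec))
    }
    if (nrow(recs)) {
      recs$chain <- res$chain[r]
      recs$resno <- res$number[r]
      recs$resname <- res$name[r]
      all[[length(all) + 1]] <- recs
    }
  }
  out <- if (length(all)) do.call(rbind, all) else emptyRecords()
  if (nrow(out)) {
    out$ligandTitle <- ligand@title
    out$pose <- ligand@poseIndex
  } else {
    out$ligandTitle <- character(0)
    out$pose <- integer(0)
  }
  out
}

isMetalLigand <- function(ligand, cfg) {
  heavy <- ligand@atoms[!ligand@atoms$isH, , drop = FALSE]
  nrow(heavy) == 1 && heavy$element[1] %in% cfg@metal_set
}

metalLigandFeatures <- function(ligand) {
  f <- emptyFeatureSet()
  heavy <- which(!ligand@atoms$isH)
  f@cations <- featureDf(ligand@atoms, heavy)
  f
}

#' Per-residue receptor feature sets
#'
#' Perceives the interaction features of every residue once, for reuse
#' across many ligand poses.
#'
#' @param receptor A [Receptor-class] object.
#' @param cfg A [GeometryConfig-class].
#' @return Named list of [FeatureSet-class], keyed by residue number.
#' @export
receptorFeatureList <- function(receptor, cfg = geometryConfig()) {
  res <- residues(receptor)
  out <- lapply(seq_len(nrow(res)), function(r)
    residueFeatures(receptor, res$number[r], cfg))
  names(out) <- as.character(res$number)
  out
}

#' Compute a Structural Interaction Fingerprint
#'
#' Builds the SIFt of one receptor-ligand pair at the requested
#' resolution. For \code{FULL}, bit (residue r, channel c) is 1 iff at
#' least one interaction record of type c involves r; \code{SIMPLE} and
#' \code{PBS} use the any-contact criterion per residue or per
#' phosphate/sugar/base group. Bit order is residue-major (manifest
#' order), channel-minor (registry order).
#'
#' @inheritParams detectInteractions
#' @param variant \code{"FULL"}, \code{"PBS"} or \code{"SIMPLE"}.
#' @return A [SIFt-class] object.
#' @examples
#' probe <- makeProbeComplex(probeSpec("HB", distance = 3.0))
#' rec <- readReceptor(probe$pdb)
#' lig <- readLigands(probe$sdf)[[1]]
#' sift <- computeSIFt(rec, lig, "FULL")
#' sum(siftBits(sift))
#' @export
computeSIFt <- function(receptor, ligand, variant = c("FULL", "PBS", "SIMPLE"),
                        cfg = geometryConfig(), hbMode = c("distance", "dha"),
                        plugins = list(), featRList = NULL) {
  variant <- match.arg(variant)
  hbMode <- match.arg(hbMode)
  stopifnot(is(receptor, "Receptor"), is(ligand, "Ligand"))
  manifest <- residues(receptor)
  if (!nrow(manifest))
    siftStop("siftna_empty_receptor_error", "receptor has no residues")
  channels <- siftChannels(variant)
  if (variant == "FULL" && length(plugins))
    channels <- c(channels, vapply(plugins, function(p) p$name, ""))
  bits <- integer(nrow(manifest) * length(channels))
  records <- emptyRecords()
  records$ligandTitle <- character(0); records$pose <- integer(0)
  if (variant == "FULL") {
    records <- detectInteractions(receptor, ligand, cfg, hbMode, plugins,
                                  featRList = featRList)
    if (nrow(records)) {
      ri <- match(records$resno, manifest$number)
      ci <- match(records$itype, channels)
      keep <- !is.na(ri) & !is.na(ci)
      bits[(ri[keep] - 1L) * length(channels) + ci[keep]] <- 1L
    }
  } else {
    for (r in seq_len(nrow(manifest))) {
      ra <- residueAtoms(receptor, manifest$number[r])
      b <- detectContact(ra, ligand, cfg,
                         if (variant == "SIMPLE") "residue" else "group")
      bits[((r - 1L) * length(channels) + 1L):(r * length(channels))] <-
        as.integer(b)
    }
  }
  new("SIFt", variant = variant, manifest = manifest, channels = channels,
      bits = bits, ligandId = list(title = ligand@title,
                                   poseIndex = ligand@poseIndex),
      records = records)
}

#' Interaction profile of the receptor's inorganic ions
#'
#' Treats each inorganic ion in the receptor file as a ligand and computes
#' one SIFt per residue-ion pairing. For metal-cation ligands only the
#' cation-anion channel (FULL) or the contact bits (SIMPLE/PBS) can be
#' set.
#'
#' @param receptor A [Receptor-class] object containing at least one ion.
#' @param variant Fingerprint resolution.
#' @param cfg A [GeometryConfig-class].
#' @return List of [SIFt-class], one per ion, in file order.
#' @export
ionProfile <- function(receptor, variant = c("FULL", "PBS", "SIMPLE"),
                       cfg = geometryConfig()) {
  variant <- match.arg(variant)
  stopifnot(is(receptor, "Receptor"))
  ions <- receptor@ions
  if (!nrow(ions))
    siftStop("siftna_no_ions_error", "receptor contains no inorganic ions")
  lapply(seq_len(nrow(ions)), function(i) {
    lig <- ionAsLigand(ions[i, , drop = FALSE], i)
    computeSIFt(receptor, lig, variant, cfg)
  })
}

ionAsLigand <- function(ionRow, pose) {
  atoms <- data.frame(element = ionRow$element, x = ionRow$x, y = ionRow$y,
                      z = ionRow$z, charge = 1L, aromatic = FALSE,
                      isH = FALSE, name = paste0(ionRow$element, "1"),
                      stringsAsFactors = FALSE)
  block <- paste(c(ionRow$element, "  SIFtNA", "",
                   "  1  0  0  0  0  0  0  0  0  0999 V2000",
                   sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                           ionRow$x, ionRow$y, ionRow$z, ionRow$element),
                   "M  END", "$$$$", ""), collapse = "\n")
  new("Ligand", title = ionRow$element, poseIndex = as.integer(pose),
      atoms = atoms,
      bonds = emptyDf(i = integer(), j = integer(), order = integer(),
                      aromatic = logical()),
      molBlock = block)
}

## ---------------------------------------------------------------------------
## Wrappers

PURINES <- c("A", "G")

#' Post-process a fingerprint with the ACUG, PuPy or Counter wrapper
#'
#' \code{ACUG} reports, per channel, the logical OR over all residues of
#' each nucleotide type (A, C, G, and U-or-T: thymine maps to the U row
#' for DNA receptors); \code{PuPy} does the same for purines and
#' pyrimidines; \code{Counter} reports the total number of residues with
#' the channel set (the Hamming weight of the channel's residue bits).
#'
#' @param sift A [SIFt-class] object (FULL for the typed wrappers;
#'   Counter is also meaningful for SIMPLE/PBS).
#' @param wrapper One of \code{"ACUG"}, \code{"PuPy"}, \code{"Counter"}.
#' @return For ACUG/PuPy an integer matrix (classes x channels); for
#'   Counter a named integer vector per channel.
#' @export
wrapSIFt <- function(sift, wrapper = c("ACUG", "PuPy", "Counter")) {
  if (length(wrapper) == 1 && !wrapper %in% c("ACUG", "PuPy", "Counter"))
    siftStop("siftna_usage_error", "unknown wrapper: %s", wrapper)
  wrapper <- match.arg(wrapper)
  stopifnot(is(sift, "SIFt"))
  nC <- length(sift@channels)
  bitMat <- matrix(sift@bits, ncol = nC, byrow = TRUE,
                   dimnames = list(NULL, sift@channels))
  if (wrapper == "Counter")
    return(colSums(bitMat))
  base <- normalizeBaseName(sift@manifest$name)
  cls <- if (wrapper == "ACUG") {
    out <- ifelse(base == "T", "U", base)
    levels <- c("A", "C", "G", "U")
    list(values = out, levels = levels)
  } else {
    out <- ifelse(base %in% PURINES, "Purine", "Pyrimidine")
    out[is.na(base)] <- NA
    list(values = out, levels = c("Purine", "Pyrimidine"))
  }
  m <- matrix(0L, nrow = length(cls$levels), ncol = nC,
              dimnames = list(cls$levels, sift@channels))
  for (k in seq_along(cls$levels)) {
    rows <- which(!is.na(cls$values) & cls$values == cls$levels[k])
    if (length(rows))
      m[k, ] <- as.integer(colSums(bitMat[rows, , drop = FALSE]) > 0)
  }
  m
}

## ---------------------------------------------------------------------------
## TSV output

siftColumnNames <- function(sift) {
  res <- sift@manifest
  resLabel <- paste0(res$chain, ".", res$number, ".", res$name)
  as.vector(t(outer(resLabel, sift@channels, paste, sep = "#")))
}

ligandLabel <- function(sift)
  paste0(sift@ligandId$title, "#", sift@ligandId$poseIndex)

#' Write fingerprints to a tab-separated file
#'
#' One row per ligand pose; the first column is the ligand identifier
#' (\code{title#pose}), followed by one 0/1 column per (residue, channel)
#' named \code{CHAIN.NUMBER.RESNAME#CHANNEL}. All fingerprints must share
#' the variant and residue manifest.
#'
#' @param sifts List of [SIFt-class] objects (may be empty for a
#'   header-only file, in which case a reference SIFt must be given).
#' @param path Output path.
#' @param reference Optional [SIFt-class] supplying the header when
#'   \code{sifts} is empty.
#' @return \code{path}, invisibly.
#' @export
writeSiftTSV <- function(sifts, path, reference = NULL) {
  if (is(sifts, "SIFt")) sifts <- list(sifts)
  ref <- if (length(sifts)) sifts[[1]] else reference
  if (is.null(ref))
    siftStop("siftna_manifest_error", "no fingerprints and no reference header")
  for (s in sifts) {
    if (!identical(s@variant, ref@variant) ||
        !identical(s@manifest, ref@manifest) ||
        !identical(s@channels, ref@channels))
      siftStop("siftna_manifest_error",
               "fingerprints do not share variant/manifest/channels")
  }
  header <- paste(c("ligand_id", siftColumnNames(ref)), collapse = "\t")
  rows <- vapply(sifts, function(s)
    paste(c(ligandLabel(s), s@bits), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a fingerprint matrix from a tab-separated file
#'
#' Reads the TSV produced by [writeSiftTSV()] back into a 0/1 integer
#' matrix with ligand identifiers as row names and
#' \code{CHAIN.NUMBER.RESNAME#CHANNEL} column names.
#'
#' @param path Path of a SIFt TSV file.
#' @return Integer matrix (possibly 0-row).
#' @export
readSiftTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    siftStop("siftna_parse_error", "empty SIFt TSV: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!length(header) || header[1] != "ligand_id")
    siftStop("siftna_parse_error", "not a SIFt TSV: %s", path)
  cols <- header[-1]
  if (length(lines) == 1) {
    m <- matrix(integer(0), nrow = 0, ncol = length(cols),
                dimnames = list(NULL, cols))
    return(m)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- vapply(rows, length, 0L) != length(header)
  if (any(bad))
    siftStop("siftna_parse_error", "ragged SIFt TSV row in %s", path)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  colnames(m) <- cols
  rownames(m) <- vapply(rows, `[`, "", 1)
  m
}

#' Write detailed interaction records to a tab-separated file
#'
#' Human-readable listing of every detected interaction: type, subtype,
#' residue identity, interacting atoms or ring atom lists with their
#' coordinates (ring records carry centroids), mediator if any, distance
#' and angle at three decimals. Rows are ordered by pose, then residue,
#' then channel registry order.
#'
#' @param records data.frame of interaction records
#'   (from [detectInteractions()] or [siftRecords()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDetailTSV <- function(records, path) {
  cols <- c("ligand_title", "pose", "interaction_type", "subtype", "chain",
            "residue_number", "residue_name", "receptor_atoms",
            "receptor_xyz", "ligand_atoms", "ligand_xyz", "mediator",
            "distance", "angle")
  if (!nrow(records)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  ord <- order(records$pose, records$resno,
               match(records$itype, c(FULL_CHANNELS, unique(records$itype))))
  records <- records[ord, , drop = FALSE]
  xyz <- function(x, y, z) sprintf("%.3f,%.3f,%.3f", x, y, z)
  out <- data.frame(
    ligand_title = records$ligandTitle,
    pose = records$pose,
    interaction_type = records$itype,
    subtype = ifelse(is.na(records$subtype), "", records$subtype),
    chain = records$chain,
    residue_number = records$resno,
    residue_name = records$resname,
    receptor_atoms = records$receptorAtoms,
    receptor_xyz = xyz(records$rx, records$ry, records$rz),
    ligand_atoms = records$ligandAtoms,
    ligand_xyz = xyz(records$lx, records$ly, records$lz),
    mediator = ifelse(is.na(records$mediator), "", records$mediator),
    distance = sprintf("%.3f", records$distance),
    angle = ifelse(is.na(records$angle), "", sprintf("%.3f", records$angle)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
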
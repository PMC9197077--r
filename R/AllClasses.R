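#' @import methods
NULL

## ---------------------------------------------------------------------------
## Channel registry

FULL_CHANNELS <- c("HB", "HAL", "CationAnion", "PiCation", "PiAnion",
                   "PiStacking", "Mg_mediated", "K_mediated", "Na_mediated",
                   "OtherMetal_mediated", "Water_mediated", "Lipophilic")

#' Channel registry for a fingerprint variant
#'
#' Returns the ordered interaction channels encoded by each fingerprint
#' resolution: \code{SIMPLE} has a single any-contact channel, \code{PBS}
#' one contact channel per phosphate/sugar/base group, and \code{FULL} the
#' twelve typed channels (six pairwise interaction classes, four
#' metal-mediated subtypes, water-mediated, lipophilic).
#'
#' @param variant One of \code{"SIMPLE"}, \code{"PBS"}, \code{"FULL"}.
#' @return Character vector of channel names, in fingerprint bit order.
#' @examples
#' siftChannels("FULL")
#' @export
siftChannels <- function(variant = c("FULL", "PBS", "SIMPLE")) {
  variant <- match.arg(variant)
  switch(variant,
         SIMPLE = "Contact",
         PBS = c("P", "S", "B"),
         FULL = FULL_CHANNELS)
}

## ---------------------------------------------------------------------------
## GeometryConfig

#' @title Geometric criteria for interaction detection
#'
#' @description Holds every numeric criterion used by the interaction
#' detectors. The hydrogen-bond heavy-atom cutoff of 3.9 Angstrom is the
#' published default of the profiling protocol; the remaining values are
#' reconstructions following the standard interaction-profiler literature
#' (PLIP-style hydrogen-bond angle, Auffinger-style halogen windows,
#' 5.5/2.0 Angstrom + 30 degree stacking criteria, 3.5 Angstrom water
#' bridge legs, 4.0 Angstrom lipophilic contacts) and every one can be
#' overridden, programmatically or from a flat key=value configuration file.
#'
#' @slot hb_dist_max Hydrogen bond D...A heavy-atom distance cutoff (A).
#' @slot hb_dha_angle_min Minimum D-H...A angle in angle-aware mode (deg).
#' @slot hal_dist_max Halogen bond X...A distance cutoff (A).
#' @slot hal_don_angle Ideal C-X...A donor angle (deg); +/- window below.
#' @slot hal_don_angle_window Half-width of the donor angle window (deg).
#' @slot hal_acc_angle Ideal X...A-Y acceptor angle (deg).
#' @slot hal_acc_angle_window Half-width of the acceptor angle window (deg).
#' @slot ca_dist_min Cation-anion minimum distance (clash guard, A).
#' @slot ca_dist_max Cation-anion maximum distance (A).
#' @slot pi_stack_dist_max Ring centroid-centroid cutoff (A).
#' @slot pi_stack_offset_max In-plane centroid offset cutoff (A).
#' @slot pi_stack_parallel_angle_max Max interplanar angle, parallel class (deg).
#' @slot pi_stack_tshape_angle_min Lower interplanar angle, T-shaped class (deg).
#' @slot pi_stack_tshape_angle_max Upper interplanar angle, T-shaped class (deg).
#' @slot pi_ion_dist_max Ring centroid to charged atom cutoff (A).
#' @slot pi_ion_angle_max Max angle between ring normal and centroid-ion (deg).
#' @slot ion_mediated_dist_max Named numeric: coordination cutoff per metal
#'   (names \code{MG}, \code{K}, \code{NA}, \code{OTHER}), in A.
#' @slot water_mediated_dist_max Water bridge leg cutoff (A).
#' @slot lipophilic_dist_max Apolar contact cutoff (A).
#' @slot simple_contact_dist_max Any-atom contact cutoff, SIMPLE/PBS (A).
#' @slot metal_set Element symbols routed to the inorganic-ion records.
#' @slot lipophilic_smarts SMARTS override for ligand lipophilic atoms.
#' @slot hb_donor_smarts SMARTS used for ligand donor perception.
#' @slot hb_acceptor_smarts SMARTS used for ligand acceptor perception.
#' @seealso [geometryConfig()], [readGeometryConfig()]
#' @export
setClass("GeometryConfig", representation(
  hb_dist_max = "numeric",
  hb_dha_angle_min = "numeric",
  hal_dist_max = "numeric",
  hal_don_angle = "numeric",
  hal_don_angle_window = "numeric",
  hal_acc_angle = "numeric",
  hal_acc_angle_window = "numeric",
  ca_dist_min = "numeric",
  ca_dist_max = "numeric",
  pi_stack_dist_max = "numeric",
  pi_stack_offset_max = "numeric",
  pi_stack_parallel_angle_max = "numeric",
  pi_stack_tshape_angle_min = "numeric",
  pi_stack_tshape_angle_max = "numeric",
  pi_ion_dist_max = "numeric",
  pi_ion_angle_max = "numeric",
  ion_mediated_dist_max = "numeric",
  water_mediated_dist_max = "numeric",
  lipophilic_dist_max = "numeric",
  simple_contact_dist_max = "numeric",
  metal_set = "character",
  lipophilic_smarts = "character",
  hb_donor_smarts = "character",
  hb_acceptor_smarts = "character"
))

setValidity("GeometryConfig", function(object) {
  num <- c("hb_dist_max", "hal_dist_max", "ca_dist_max", "pi_stack_dist_max",
           "pi_ion_dist_max", "water_mediated_dist_max", "lipophilic_dist_max",
           "simple_contact_dist_max")
  for (s in num)
    if (length(slot(object, s)) != 1 || slot(object, s) <= 0)
      return(sprintf("%s must be a single positive number", s))
  if (object@ca_dist_min >= object@ca_dist_max)
    return("ca_dist_min must be smaller than ca_dist_max")
  need <- c("MG", "K", "NA", "OTHER")
  if (!all(need %in% names(object@ion_mediated_dist_max)))
    return("ion_mediated_dist_max must name MG, K, NA and OTHER")
  if (any(object@ion_mediated_dist_max <= 0))
    return("ion_mediated_dist_max entries must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## Receptor

#' @title Parsed nucleic-acid receptor
#'
#' @description One RNA or DNA model: ordered residue atoms with
#' phosphate/sugar/base group labels, plus separated water oxygens and
#' inorganic metal ions. Residue numbering must be unique across all chains.
#'
#' @slot atoms data.frame of residue atoms: \code{serial}, \code{name},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{chain},
#'   \code{resno}, \code{resname}, \code{group}, \code{isH}.
#' @slot waters data.frame of water oxygen atoms (same columns, no group).
#' @slot ions data.frame of inorganic metal ions.
#' @slot sourcePath Path the structure was read from ("" for text input).
#' @seealso [readReceptor()], [residues()]
#' @export
setClass("Receptor", representation(
  atoms = "data.frame",
  waters = "data.frame",
  ions = "data.frame",
  sourcePath = "character"
))

setValidity("Receptor", function(object) {
  a <- object@atoms
  if (nrow(a)) {
    if (!all(is.finite(c(a$x, a$y, a$z))))
      return("atom coordinates must be finite")
    key <- unique(a$resno)
    if (anyDuplicated(key))
      return("residue numbers must be unique")
    if (any(!a$isH & (is.na(a$group) | !a$group %in% c("PHOSPHATE", "SUGAR", "BASE"))))
      return("every non-hydrogen residue atom needs a group label")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Ligand

#' @title One ligand record from an SDF file
#'
#' @description A single SDF entry: atoms with coordinates and formal
#' charges, bonds, and the 1-based position of the record in the file
#' (the docking pose index).
#'
#' @slot title Record title (first line of the molfile header).
#' @slot poseIndex 1-based position in the SDF file.
#' @slot atoms data.frame: \code{element}, \code{x}, \code{y}, \code{z},
#'   \code{charge}, \code{aromatic}, \code{isH}.
#' @slot bonds data.frame: \code{i}, \code{j}, \code{order}, \code{aromatic}.
#' @slot molBlock The V2000 mol block used to rebuild the molecule for
#'   SMARTS matching.
#' @seealso [readLigands()], [perceiveFeatures()]
#' @export
setClass("Ligand", representation(
  title = "character",
  poseIndex = "integer",
  atoms = "data.frame",
  bonds = "data.frame",
  molBlock = "character"
))

setValidity("Ligand", function(object) {
  a <- object@atoms
  b <- object@bonds
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("ligand coordinates must be finite")
  if (nrow(a) && any(abs(a$charge) > 4))
    return("formal charges must lie in [-4, 4]")
  if (nrow(b) && (any(b$i < 1 | b$i > nrow(a)) || any(b$j < 1 | b$j > nrow(a))))
    return("bond indices out of range")
  if (length(object@poseIndex) != 1 || object@poseIndex < 1)
    return("poseIndex must be a single integer >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## FeatureSet

#' @title Interaction-capable features of one molecule side
#'
#' @description Perceived pharmacophoric features on either a receptor
#' residue or a ligand record: hydrogen-bond donors (with hydrogen
#' positions), acceptors (with one bonded heavy neighbour for halogen-bond
#' acceptor angles), halogen-bond donors (C-X pairs), charged centres,
#' aromatic rings (with centroid and best-fit plane normal), and lipophilic
#' atoms. Atom indices refer to rows of the owning atom table; names are
#' PDB atom names for receptor residues and element+index labels for
#' ligands.
#'
#' @slot donors data.frame: \code{idx}, \code{name}, \code{x}, \code{y}, \code{z}.
#' @slot donorH data.frame: \code{donorIdx}, \code{x}, \code{y}, \code{z}.
#' @slot acceptors data.frame: \code{idx}, \code{name}, \code{x}, \code{y},
#'   \code{z}, \code{nx}, \code{ny}, \code{nz}, \code{hasNbr}.
#' @slot halogenDonors data.frame: \code{idx}, \code{name} (halogen),
#'   \code{x}, \code{y}, \code{z}, \code{cx}, \code{cy}, \code{cz}.
#' @slot cations data.frame: \code{idx}, \code{name}, \code{x}, \code{y}, \code{z}.
#' @slot anions data.frame: \code{idx}, \code{name}, \code{x}, \code{y}, \code{z}.
#' @slot rings list of rings, each \code{list(members, names, centroid, normal)}.
#' @slot lipophilic data.frame: \code{idx}, \code{name}, \code{x}, \code{y}, \code{z}.
#' @export
setClass("FeatureSet", representation(
  donors = "data.frame",
  donorH = "data.frame",
  acceptors = "data.frame",
  halogenDonors = "data.frame",
  cations = "data.frame",
  anions = "data.frame",
  rings = "list",
  lipophilic = "data.frame"
))

setValidity("FeatureSet", function(object) {
  for (r in object@rings) {
    if (length(r$members) < 5)
      return("rings must have at least 5 member atoms")
    if (abs(vnorm(r$normal) - 1) > 1e-9)
      return("ring normals must be unit vectors")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## SIFt

#' @title Structural Interaction Fingerprint
#'
#' @description The binary interaction fingerprint of one receptor-ligand
#' pair: an ordered bit vector over (residue x channel), together with the
#' residue manifest, the channel registry, the resolution variant, and the
#' detailed interaction records that produced the set bits.
#'
#' @slot variant \code{"SIMPLE"}, \code{"PBS"} or \code{"FULL"}.
#' @slot manifest data.frame of residues in bit order: \code{chain},
#'   \code{number}, \code{name}.
#' @slot channels Ordered channel names (built-in registry, then plugins).
#' @slot bits Integer vector of 0/1, length \code{nrow(manifest) * length(channels)},
#'   laid out residue-major (all channels of residue 1, then residue 2, ...).
#' @slot ligandId list(title, poseIndex) identifying the ligand record.
#' @slot records data.frame of detailed interaction records.
#' @seealso [computeSIFt()], [wrapSIFt()], [writeSiftTSV()]
#' @export
setClass("SIFt", representation(
  variant = "character",
  manifest = "data.frame",
  channels = "character",
  bits = "integer",
  ligandId = "list",
  records = "data.frame"
))

setValidity("SIFt", function(object) {
  if (!object@variant %in% c("SIMPLE", "PBS", "FULL"))
    return("variant must be SIMPLE, PBS or FULL")
  if (length(object@bits) != nrow(object@manifest) * length(object@channels))
    return("bit vector length must equal residues x channels")
  if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
    return("bits must be 0/1")
  base <- siftChannels(object@variant)
  if (length(object@channels) < length(base) ||
      !identical(object@channels[seq_along(base)], base))
    return("channel registry must start with the built-in channels")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "GeometryConfig", function(object) {
  cat("GeometryConfig\n")
  cat(sprintf("  hydrogen bonds : D...A <= %.2f A, D-H...A >= %.0f deg\n",
              object@hb_dist_max, object@hb_dha_angle_min))
  cat(sprintf("  halogen bonds  : X...A <= %.2f A, donor %0.f+/-%.0f, acceptor %.0f+/-%.0f deg\n",
              object@hal_dist_max, object@hal_don_angle, object@hal_don_angle_window,
              object@hal_acc_angle, object@hal_acc_angle_window))
  cat(sprintf("  cation-anion   : (%.2f, %.2f] A\n", object@ca_dist_min, object@ca_dist_max))
  cat(sprintf("  Pi-stacking    : d <= %.2f A, offset <= %.2f A, parallel <= %.0f deg, T in [%.0f, %.0f]\n",
              object@pi_stack_dist_max, object@pi_stack_offset_max,
              object@pi_stack_parallel_angle_max, object@pi_stack_tshape_angle_min,
              object@pi_stack_tshape_angle_max))
  cat(sprintf("  Pi-ion         : d <= %.2f A, angle <= %.0f deg\n",
              object@pi_ion_dist_max, object@pi_ion_angle_max))
  im <- object@ion_mediated_dist_max
  cat(sprintf("  ion-mediated   : Mg %.2f, K %.2f, Na %.2f, other %.2f A\n",
              im[["MG"]], im[["K"]], im[["NA"]], im[["OTHER"]]))
  cat(sprintf("  water-mediated : legs <= %.2f A; lipophilic <= %.2f A; contact <= %.2f A\n",
              object@water_mediated_dist_max, object@lipophilic_dist_max,
              object@simple_contact_dist_max))
})

setMethod("show", "Receptor", function(object) {
  res <- residues(object)
  cat(sprintf("Receptor with %d residue(s), %d atom(s), %d water(s), %d ion(s)\n",
              nrow(res), nrow(object@atoms), nrow(object@waters), nrow(object@ions)))
  if (nrow(res))
    cat("  residues:", paste(utils::head(paste0(res$chain, "/", res$number, ":", res$name), 8),
                             collapse = " "),
        if (nrow(res) > 8) "..." else "", "\n")
})

setMethod("show", "Ligand", function(object) {
  cat(sprintf("Ligand '%s' (pose %d): %d atom(s) (%d heavy), %d bond(s)\n",
              object@title, object@poseIndex, nrow(object@atoms),
              sum(!object@atoms$isH), nrow(object@bonds)))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf(paste0("FeatureSet: %d donor(s), %d acceptor(s), %d halogen donor(s), ",
                     "%d cation(s), %d anion(s), %d ring(s), %d lipophilic atom(s)\n"),
              nrow(object@donors), nrow(object@acceptors), nrow(object@halogenDonors),
              nrow(object@cations), nrow(object@anions), length(object@rings),
              nrow(object@lipophilic)))
})

setMethod("show", "SIFt", function(object) {
  cat(sprintf("SIFt [%s] for '%s' (pose %d): %d residues x %d channels, %d bit(s) set\n",
              object@variant, object@ligandId$title, object@ligandId$poseIndex,
              nrow(object@manifest), length(object@channels), sum(object@bits)))
})

## ---------------------------------------------------------------------------
## Accessors

#' Residue manifest of a receptor
#'
#' @param x A [Receptor-class] object.
#' @return data.frame with columns \code{chain}, \code{number}, \code{name},
#'   one row per residue in fingerprint order.
#' @export
residues <- function(x) {
  stopifnot(is(x, "Receptor"))
  a <- x@atoms
  if (!nrow(a))
    return(emptyDf(chain = character(), number = integer(), name = character()))
  u <- !duplicated(a$resno)
  data.frame(chain = a$chain[u], number = a$resno[u], name = a$resname[u],
             stringsAsFactors = FALSE)
}

#' Atoms of one receptor residue
#'
#' @param x A [Receptor-class] object.
#' @param number Residue number (unique across the receptor).
#' @return data.frame of that residue's atoms.
#' @export
residueAtoms <- function(x, number) {
  stopifnot(is(x, "Receptor"))
  a <- x@atoms[x@atoms$resno == number, , drop = FALSE]
  if (!nrow(a))
    siftStop("siftna_parse_error", "no residue numbered %s", number)
  a
}

#' Fingerprint bit vector
#' @param x A [SIFt-class] object.
#' @return Integer 0/1 vector in (residue-major, channel-minor) order.
#' @export
siftBits <- function(x) { stopifnot(is(x, "SIFt")); x@bits }

#' Fingerprint variant
#' @param x A [SIFt-class] object.
#' @return "SIMPLE", "PBS" or "FULL".
#' @export
siftVariant <- function(x) { stopifnot(is(x, "SIFt")); x@variant }

#' Residue manifest of a fingerprint
#' @param x A [SIFt-class] object.
#' @return data.frame with \code{chain}, \code{number}, \code{name}.
#' @export
siftManifest <- function(x) { stopifnot(is(x, "SIFt")); x@manifest }

#' Detailed interaction records behind a fingerprint
#' @param x A [SIFt-class] object.
#' @return data.frame of interaction records.
#' @export
siftRecords <- function(x) { stopifnot(is(x, "SIFt")); x@records }

#' Ligand identity of a fingerprint
#' @param x A [SIFt-class] object.
#' @return list(title, poseIndex).
#' @export
siftLigandId <- function(x) { stopifnot(is(x, "SIFt")); x@ligandId }

#' Atom table of a ligand record
#' @param x A [Ligand-class] object.
#' @return data.frame of atoms.
#' @export
ligandAtoms <- function(x) { stopifnot(is(x, "Ligand")); x@atoms }

#' Bond table of a ligand record
#' @param x A [Ligand-class] object.
#' @return data.frame of bonds.
#' @export
ligandBonds <- function(x) { stopifnot(is(x, "Ligand")); x@bonds }
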
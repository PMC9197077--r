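## User-defined interaction types: SMARTS patterns for the receptor and
## ligand sides plus a geometric criterion (distance; distance + angle;
## distance + dihedral), loaded from a YAML file and evaluated as
## additional fingerprint channels after the twelve built-in ones.
##
## Schema (one list under the top-level key `plugins`):
##   - name: polar                      # unique within the file
##     receptor_smarts: "[#7,#8]"
##     ligand_smarts: "[#7,#8,#16]"
##     criterion:
##       type: distance                 # distance | distance_angle |
##       dmin: 0.0                      #   distance_dihedral
##       dmax: 3.9
##       # distance_angle adds:   amin, amax, anchors: [R1, L1, L2]
##       # distance_dihedral adds: amin, amax, anchors: [R1, R2, L1, L2]
## Anchors are side-qualified 1-based positions in the SMARTS match tuple
## ("R2" = second atom of the receptor match). The distance itself is
## always measured between R1 and L1.

## Receptor-side SMARTS equivalent to the built-in nucleotide
## donor/acceptor tables (on residues with explicit polar hydrogens).

#' @rdname loadPluginFile
#' @export
RECEPTOR_HB_DONOR_SMARTS <- "[#7,#8;!H0]"

#' @rdname loadPluginFile
#' @export
RECEPTOR_HB_ACCEPTOR_SMARTS <-
  "[$([#8;!$([#8+])]),$([#7;X1,X2;!$([#7+])])]"

#' Load plugin definitions from a YAML file
#'
#' Parses and validates user-defined interaction types. Definitions keep
#' file order; their fingerprint channels are registered after the twelve
#' built-in channels, in declaration order. The exported constants
#' \code{RECEPTOR_HB_DONOR_SMARTS} and \code{RECEPTOR_HB_ACCEPTOR_SMARTS}
#' express the built-in receptor hydrogen-bonding tables as SMARTS for use
#' in plugins.
#'
#' @param input Path to a YAML file, or YAML text.
#' @return List of plugin definitions (lists with \code{name},
#'   \code{receptor_smarts}, \code{ligand_smarts}, \code{criterion}).
#' @examples
#' defs <- loadPluginFile(samplePluginFile())
#' vapply(defs, function(d) d$name, "")
#' @export
loadPluginFile <- function(input) {
  doc <- tryCatch(
    if (isTextInput(input)) yaml::yaml.load(paste(input, collapse = "\n"))
    else yaml::read_yaml(input),
    error = function(e)
      siftStop("siftna_plugin_schema_error", "YAML parse failure: %s",
               conditionMessage(e)))
  defs <- doc$plugins
  if (is.null(defs) || !is.list(defs) || !length(defs))
    siftStop("siftna_plugin_schema_error",
             "plugin file must contain a non-empty `plugins` list")
  nm <- vapply(defs, function(d) d$name %||% NA_character_, "")
  if (anyNA(nm) || any(!nzchar(nm)))
    siftStop("siftna_plugin_schema_error", "every plugin needs a name")
  if (anyDuplicated(nm))
    siftStop("siftna_plugin_schema_error", "duplicate plugin name: %s",
             nm[duplicated(nm)][1])
  lapply(defs, validatePlugin)
}

validatePlugin <- function(d) {
  for (fld in c("receptor_smarts", "ligand_smarts", "criterion"))
    if (is.null(d[[fld]]))
      siftStop("siftna_plugin_schema_error", "plugin '%s' lacks %s",
               d$name, fld)
  nR <- obSmartsNumAtoms(d$receptor_smarts)
  nL <- obSmartsNumAtoms(d$ligand_smarts)
  cr <- d$criterion
  if (is.null(cr$type) ||
      !cr$type %in% c("distance", "distance_angle", "distance_dihedral"))
    siftStop("siftna_plugin_schema_error",
             "plugin '%s': criterion type must be distance, distance_angle or distance_dihedral",
             d$name)
  if (is.null(cr$dmax))
    siftStop("siftna_plugin_schema_error", "plugin '%s': dmax required", d$name)
  cr$dmin <- cr$dmin %||% 0
  if (cr$type != "distance") {
    need <- if (cr$type == "distance_angle") 3L else 4L
    if (is.null(cr$amin) || is.null(cr$amax))
      siftStop("siftna_plugin_schema_error",
               "plugin '%s': amin/amax required for %s", d$name, cr$type)
    anchors <- cr$anchors
    if (is.null(anchors) || length(anchors) != need)
      siftStop("siftna_plugin_schema_error",
               "plugin '%s': %d anchors required for %s", d$name, need, cr$type)
    for (a in anchors) {
      if (!grepl("^[RL][0-9]+$", a))
        siftStop("siftna_plugin_schema_error",
                 "plugin '%s': bad anchor '%s' (use R<i>/L<i>)", d$name, a)
      pos <- as.integer(substring(a, 2))
      lim <- if (startsWith(a, "R")) nR else nL
      if (pos < 1 || pos > lim)
        siftStop("siftna_plugin_schema_error",
                 "plugin '%s': anchor %s exceeds SMARTS atom count (%d)",
                 d$name, a, lim)
    }
  }
  d$criterion <- cr
  d
}

#' Evaluate one plugin on a residue-ligand pair
#'
#' Matches the plugin's SMARTS on the receptor residue and the ligand, and
#' emits one interaction record per (receptor match, ligand match) pair
#' that satisfies the geometric criterion. The distance is measured
#' between the first atoms of the two matches; angle and dihedral
#' criteria evaluate their anchor atoms (side-qualified match positions).
#'
#' @param defn One plugin definition from [loadPluginFile()].
#' @param receptor A [Receptor-class] object.
#' @param number Residue number.
#' @param ligand A [Ligand-class] object.
#' @param cfg A [GeometryConfig-class] (unused by the built-in criteria,
#'   accepted for interface uniformity).
#' @return data.frame of interaction records with \code{itype} equal to
#'   the plugin name.
#' @export
evaluatePlugin <- function(defn, receptor, number, ligand,
                           cfg = geometryConfig()) {
  resA <- residueAtoms(receptor, number)
  rownames(resA) <- NULL
  mR <- matchResidueSmarts(receptor, number, defn$receptor_smarts)
  if (!length(mR)) return(emptyRecords())
  mL <- matchSmarts(ligand, defn$ligand_smarts)
  if (!length(mL)) return(emptyRecords())
  cr <- defn$criterion
  ligA <- ligand@atoms
  coordR <- function(i) as.numeric(resA[i, c("x", "y", "z")])
  coordL <- function(i) as.numeric(ligA[i, c("x", "y", "z")])
  anchorCoord <- function(a, rTuple, lTuple) {
    pos <- as.integer(substring(a, 2))
    if (startsWith(a, "R")) coordR(rTuple[pos]) else coordL(lTuple[pos])
  }
  recs <- list()
  for (rt in mR) for (lt in mL) {
    p1 <- coordR(rt[1]); p2 <- coordL(lt[1])
    ## same distance primitive as the built-in detectors, so that shared
    ## cutoffs break ties identically at the boundary
    d <- crossDist(matrix(p1, ncol = 3), matrix(p2, ncol = 3))[1, 1]
    if (d < cr$dmin || d > cr$dmax) next
    ang <- NA_real_
    if (cr$type == "distance_angle") {
      pts <- lapply(cr$anchors, anchorCoord, rTuple = rt, lTuple = lt)
      ang <- angle3(pts[[1]], pts[[2]], pts[[3]])
      if (ang < cr$amin || ang > cr$amax) next
    } else if (cr$type == "distance_dihedral") {
      pts <- lapply(cr$anchors, anchorCoord, rTuple = rt, lTuple = lt)
      ang <- dihedral4(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      if (ang < cr$amin || ang > cr$amax) next
    }
    recs[[length(recs) + 1]] <-
      makeRecord(defn$name, paste(resA$name[rt], collapse = "+"), p1,
                 paste(ligA$name[lt], collapse = "+"), p2, d, ang)
  }
  recordsFromList(recs)
}

#' Path of the shipped sample plugin file
#'
#' Six reconstructed sample interaction types: any contact, polar, weak
#' polar, n->pi*, weak hydrogen bonds, and halogen multipolar. The SMARTS
#' and thresholds are documented reconstructions, not published values.
#'
#' @return Path of the YAML file installed with the package.
#' @export
samplePluginFile <- function() {
  system.file("extdata", "sample_plugins.yaml", package = "SIFtNA",
              mustWork = TRUE)
}
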
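## GeometryConfig construction and flat key=value round-tripping.

DEFAULT_METAL_SET <- c("Na", "K", "Mg", "Ca", "Mn", "Fe", "Zn", "Co", "Ni",
                       "Cu", "Sr", "Ba", "Cd", "Pb")

## Ligand-side perception patterns; user-overridable through the config.
## Donors are N/O/S carrying at least one hydrogen (implicit or explicit);
## acceptors are O (not positively charged) and N with a free lone pair
## (excluding positively charged, quaternary, amide and pyrrole-type N);
## lipophilic atoms are C/S bonded only to C, H, S or halogens, uncharged.
DEFAULT_HB_DONOR_SMARTS <- "[#7,#8,#16;!H0]"
DEFAULT_HB_ACCEPTOR_SMARTS <- paste0(
  "[$([#8;!$([#8+])]),",
  "$([#7;!$([#7+]);!$([NX4]);!$([nX3H1]);!$([NX3][CX3]=[OX1])])]")
DEFAULT_LIPOPHILIC_SMARTS <-
  "[#6,#16;+0;!$([#6,#16]~[!#6;!#1;!#16;!#9;!#17;!#35;!#53])]"

#' Construct a geometry configuration
#'
#' Returns a [GeometryConfig-class] with the package defaults, overriding
#' any field passed by name. The 3.9 Angstrom hydrogen-bond heavy-atom
#' cutoff is the published default; the other values are documented
#' reconstructions from the interaction-profiler literature and are all
#' overridable here or via [readGeometryConfig()].
#'
#' @param ... Named fields to override, using the slot names of
#'   [GeometryConfig-class] (e.g. \code{hb_dist_max = 3.5}).
#' @return A [GeometryConfig-class] object.
#' @examples
#' cfg <- geometryConfig(hb_dist_max = 3.5)
#' @export
geometryConfig <- function(...) {
  defaults <- list(
    hb_dist_max = 3.9,
    hb_dha_angle_min = 100,
    hal_dist_max = 4.0,
    hal_don_angle = 165,
    hal_don_angle_window = 30,
    hal_acc_angle = 120,
    hal_acc_angle_window = 30,
    ca_dist_min = 0.5,
    ca_dist_max = 5.5,
    pi_stack_dist_max = 5.5,
    pi_stack_offset_max = 2.0,
    pi_stack_parallel_angle_max = 30,
    pi_stack_tshape_angle_min = 60,
    pi_stack_tshape_angle_max = 90,
    pi_ion_dist_max = 6.0,
    pi_ion_angle_max = 30,
    ion_mediated_dist_max = c(MG = 3.0, K = 3.5, "NA" = 3.1, OTHER = 3.0),
    water_mediated_dist_max = 3.5,
    lipophilic_dist_max = 4.0,
    simple_contact_dist_max = 4.0,
    metal_set = DEFAULT_METAL_SET,
    lipophilic_smarts = DEFAULT_LIPOPHILIC_SMARTS,
    hb_donor_smarts = DEFAULT_HB_DONOR_SMARTS,
    hb_acceptor_smarts = DEFAULT_HB_ACCEPTOR_SMARTS
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    siftStop("siftna_usage_error", "unknown GeometryConfig field(s): %s",
             paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (nm == "ion_mediated_dist_max") {
      v <- defaults[[nm]]
      o <- over[[nm]]
      v[toupper(names(o))] <- o
      defaults[[nm]] <- v
    } else defaults[[nm]] <- over[[nm]]
  }
  do.call(new, c(list("GeometryConfig"), defaults))
}

#' Read geometry criteria from a flat key=value file
#'
#' Keys are the [GeometryConfig-class] slot names; the per-metal
#' coordination cutoffs use keys \code{ion_mediated_dist_max_mg},
#' \code{_k}, \code{_na} and \code{_other}; \code{metal_set} is a
#' comma-separated element list. Lines starting with \code{#} are ignored.
#'
#' @param path Path to the configuration file.
#' @param base Configuration supplying the values not present in the file.
#' @return A [GeometryConfig-class] object.
#' @export
readGeometryConfig <- function(path, base = geometryConfig()) {
  if (!file.exists(path))
    siftStop("siftna_usage_error", "config file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- base
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      siftStop("siftna_usage_error", "malformed config line: %s", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (grepl("^ion_mediated_dist_max_", key)) {
      el <- toupper(sub("^ion_mediated_dist_max_", "", key))
      v <- cfg@ion_mediated_dist_max
      v[el] <- as.numeric(val)
      cfg@ion_mediated_dist_max <- v
    } else if (key == "metal_set") {
      cfg@metal_set <- trimws(strsplit(val, ",")[[1]])
    } else if (key %in% c("lipophilic_smarts", "hb_donor_smarts",
                          "hb_acceptor_smarts")) {
      slot(cfg, key) <- val
    } else if (key %in% slotNames("GeometryConfig")) {
      slot(cfg, key) <- as.numeric(val)
    } else {
      siftStop("siftna_usage_error", "unknown config key: %s", key)
    }
  }
  validObject(cfg)
  cfg
}

#' Write geometry criteria to a flat key=value file
#'
#' @param cfg A [GeometryConfig-class] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeometryConfig <- function(cfg, path) {
  stopifnot(is(cfg, "GeometryConfig"))
  scalars <- setdiff(slotNames("GeometryConfig"),
                     c("ion_mediated_dist_max", "metal_set",
                       "lipophilic_smarts", "hb_donor_smarts",
                       "hb_acceptor_smarts"))
  lines <- vapply(scalars, function(s)
    sprintf("%s=%s", s, format(slot(cfg, s), digits = 12)), "")
  im <- cfg@ion_mediated_dist_max
  lines <- c(lines,
             sprintf("ion_mediated_dist_max_%s=%s",
                     tolower(names(im)), format(unname(im), digits = 12)),
             sprintf("metal_set=%s", paste(cfg@metal_set, collapse = ",")),
             sprintf("lipophilic_smarts=%s", cfg@lipophilic_smarts),
             sprintf("hb_donor_smarts=%s", cfg@hb_donor_smarts),
             sprintf("hb_acceptor_smarts=%s", cfg@hb_acceptor_smarts))
  writeLines(lines, path)
  invisible(path)
}
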
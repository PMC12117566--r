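# Domain types and the declarative system specification shared by all build
# stages. Internal units are nm and elementary charges throughout; unit
# conversion happens only in the file writers.

#' Simulation box
#' @param x,y,z box edge lengths in nm, all strictly positive
#' @return object of class `cg_box`
#' @export
cg_box <- function(x, y, z) {
  b <- structure(list(x = x, y = y, z = z), class = "cg_box")
  for (f in c("x", "y", "z"))
    if (!is.numeric(b[[f]]) || length(b[[f]]) != 1 || !is.finite(b[[f]]) || b[[f]] <= 0)
      stop_cg("invalid_parameter", sprintf("box %s must be a positive length (nm)", f))
  b
}

bead_frame <- function(name, resname, x, y, z, charge, tail = FALSE) {
  data.frame(name = as.character(name), resname = as.character(resname),
             x = x, y = y, z = z, charge = charge, tail = tail,
             stringsAsFactors = FALSE)
}

# default packing radius: half the maximal xy bead-pair distance + 0.1 nm pad
default_radius <- function(beads) {
  n <- nrow(beads)
  if (n == 1) return(0.1 + 0.05)
  d <- as.matrix(stats::dist(beads[, c("x", "y")]))
  max(d) / 2 + 0.1
}

#' Lipid template
#'
#' A named lipid: ordered beads with local coordinates (head-side anchor at
#' the origin, tails extending toward -z, the upper-leaflet orientation),
#' per-bead charges, a 2D packing radius and a size class used by the
#' placement engine.
#'
#' @param name lipid identifier
#' @param beads data.frame with columns name, resname, x, y, z, charge and
#'   optionally tail (logical; marks hydrophobic tail beads)
#' @param radius packing radius in nm; default half the maximal xy bead-pair
#'   distance plus 0.1 nm padding
#' @param size_class `"large"`, `"small"`, or NA to classify relative to the
#'   other lipid types of the leaflet (median radius split)
#' @return object of class `lipid_type`
#' @export
lipid_type <- function(name, beads, radius = NULL, size_class = NA_character_) {
  stopifnot(is.data.frame(beads), nrow(beads) >= 1)
  if (is.null(beads$tail)) beads$tail <- FALSE
  if (any(!is.finite(beads$charge)))
    stop_cg("invalid_parameter", sprintf("lipid %s: non-finite bead charge", name))
  radius <- radius %||% default_radius(beads)
  if (radius <= 0) stop_cg("invalid_parameter", "packing radius must be > 0")
  structure(list(name = name, beads = beads, radius = radius,
                 charge = sum(beads$charge), size_class = size_class),
            class = "lipid_type")
}

#' Solvent / ion / solute template
#'
#' @param name molecule identifier
#' @param beads data.frame as in [lipid_type()]
#' @param molarity default molarity in mol/L (>= 0)
#' @param mapping_factor atoms represented per molecule, used by the
#'   mapping-aware mixed-solvent ratio mode (>= 1)
#' @param role one of solvent, positive-ion, negative-ion, solute
#' @return object of class `solvent_spec`
#' @export
solvent_spec <- function(name, beads, molarity = 0, mapping_factor = 1,
                         role = c("solvent", "positive-ion", "negative-ion", "solute")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(beads), nrow(beads) >= 1)
  if (molarity < 0) stop_cg("invalid_parameter", "molarity must be >= 0")
  if (mapping_factor < 1) stop_cg("invalid_parameter", "mapping_factor must be >= 1")
  structure(list(name = name, beads = beads, molarity = molarity,
                 mapping_factor = mapping_factor, role = role,
                 charge = sum(beads$charge)),
            class = "solvent_spec")
}

#' One leaflet of a membrane
#'
#' @param side `"upper"` or `"lower"`
#' @param z_anchor z position of the head-anchor plane, nm
#' @param composition named positive weights, lipid name -> ratio, in
#'   declaration order
#' @param apl requested area per lipid, nm^2
#' @param boundary leaflet boundary polygon (n x 2 matrix); NULL = full box xy
#' @param holes list of pore polygons
#' @return object of class `leaflet_spec`
#' @export
leaflet_spec <- function(side = c("upper", "lower"), z_anchor, composition,
                         apl, boundary = NULL, holes = list()) {
  side <- match.arg(side)
  if (length(composition) == 0 || any(composition <= 0) || is.null(names(composition)))
    stop_cg("invalid_parameter", "composition must be named positive weights")
  if (apl <= 0) stop_cg("invalid_parameter", "apl must be > 0")
  structure(list(side = side, z_anchor = z_anchor, composition = composition,
                 apl = apl, boundary = boundary, holes = holes),
            class = "leaflet_spec")
}

#' One (possibly monolayer) membrane of the system
#'
#' @param composition named weights for the upper leaflet (and the lower one
#'   unless `composition_lower` is given)
#' @param apl upper-leaflet APL in nm^2; `apl_lower` defaults to it
#' @param zc membrane center z in nm; NULL = box center, resolved at build
#' @param thickness distance between the two leaflet anchor planes, nm (default 4, matching the ~2 nm fixture lipid length)
#' @param composition_lower,apl_lower lower-leaflet overrides
#' @param leaflets `"both"`, `"upper"` or `"lower"` (monolayers)
#' @param boundary patch boundary polygon or NULL for the full box
#' @param pores list of pore polygons
#' @return object of class `membrane_spec`
#' @export
membrane_spec <- function(composition, apl = 0.6, zc = NULL, thickness = 4,
                          composition_lower = composition, apl_lower = apl,
                          leaflets = c("both", "upper", "lower"),
                          boundary = NULL, pores = list()) {
  leaflets <- match.arg(leaflets)
  if (length(composition) == 0 || is.null(names(composition)))
    stop_cg("invalid_parameter", "membrane composition must be a named weight vector")
  structure(list(composition = composition, apl = apl, zc = zc,
                 thickness = thickness, composition_lower = composition_lower,
                 apl_lower = apl_lower, leaflets = leaflets,
                 boundary = boundary, pores = pores),
            class = "membrane_spec")
}

#' Protein placement request
#' @param file coordinate file (GRO or PDB)
#' @param cx,cy,cz translation applied to the file coordinates, nm
#' @param rotz rotation about z in degrees, applied before translation
#' @export
protein_spec <- function(file, cx = 0, cy = 0, cz = 0, rotz = 0) {
  structure(list(file = file, cx = cx, cy = cy, cz = cz, rotz = rotz),
            class = "protein_spec")
}

#' Solvation request
#' @param solvents named numeric vector, solvent name -> molarity (mol/L),
#'   in declaration order
#' @param salt NULL or list(pos =, neg =, molarity =) naming ion species
#' @param neutralization `"add"`, `"remove"` or `"combined"`
#' @param ratio_mode `"beads"` or `"mapping"`
#' @export
solvation_spec <- function(solvents, salt = NULL,
                           neutralization = c("add", "remove", "combined"),
                           ratio_mode = c("beads", "mapping")) {
  if (length(solvents) == 0 || is.null(names(solvents)) || any(solvents < 0))
    stop_cg("invalid_parameter", "solvents must be a named non-negative molarity vector")
  structure(list(solvents = solvents, salt = salt,
                 neutralization = match.arg(neutralization),
                 ratio_mode = match.arg(ratio_mode)),
            class = "solvation_spec")
}

#' Flooding request (many copies of a solute in the solvent space)
#' @param solute solute molecule name
#' @param count absolute copy number, or NULL to use `molarity`
#' @param molarity molarity to convert to a count from the free volume
#' @export
flood_spec <- function(solute, count = NULL, molarity = NULL) {
  if (is.null(count) && is.null(molarity))
    stop_cg("invalid_parameter", "flooding needs a count or a molarity")
  structure(list(solute = solute, count = count, molarity = molarity),
            class = "flood_spec")
}

#' Declarative system specification
#'
#' The single document from which an entire system is built: box, membranes,
#' proteins, solvation, flooding, output paths and the master random seed.
#'
#' @param box a [cg_box()]
#' @param membranes list of [membrane_spec()]
#' @param proteins list of [protein_spec()]
#' @param solvation a [solvation_spec()] or NULL
#' @param flooding list of [flood_spec()]
#' @param output list with optional elements gro, top, pdb (paths)
#' @param seed master integer seed; stage seeds derive via [child_seed()]
#' @return object of class `system_spec`
#' @export
system_spec <- function(box, membranes = list(), proteins = list(),
                        solvation = NULL, flooding = list(),
                        output = list(), seed = 1L) {
  structure(list(box = box, membranes = membranes, proteins = proteins,
                 solvation = solvation, flooding = flooding,
                 output = output, seed = as.integer(seed)),
            class = "system_spec")
}

#' Validate a system specification
#'
#' @param spec a [system_spec()]
#' @return list of diagnostics, each `list(level, field, message)` with level
#'   `"fatal"` or `"warning"`; an empty list means the spec is buildable
#' @export
validate_spec <- function(spec) {
  diags <- list()
  add <- function(d) diags[[length(diags) + 1L]] <<- d
  if (!inherits(spec, "system_spec")) {
    return(list(diagnostic("fatal", "spec", "not a system_spec object")))
  }
  for (f in c("x", "y", "z")) {
    v <- spec$box[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      add(diagnostic("fatal", paste0("box.", f),
                     sprintf("box %s must be strictly positive, got %s", f, format(v))))
  }
  if (length(spec$membranes) == 0 && length(spec$proteins) == 0 &&
      is.null(spec$solvation) && length(spec$flooding) == 0)
    add(diagnostic("fatal", "spec",
                   "nothing to build: need at least one membrane, protein, solvent or solute"))
  if (length(spec$membranes) > 1) {
    zc <- vapply(spec$membranes, function(m) m$zc %||% NA_real_, numeric(1))
    th <- vapply(spec$membranes, function(m) m$thickness, numeric(1))
    if (any(is.na(zc))) {
      add(diagnostic("fatal", "membranes",
                     "stacked membranes must all set an explicit center z"))
    } else {
      o <- order(zc)
      zs <- zc[o]; ts <- th[o]
      if (any(diff(zs) <= 0))
        add(diagnostic("fatal", "membranes",
                       "overlapping membranes: center z values must be strictly increasing"))
      else if (any(zs[-length(zs)] + ts[-length(ts)] / 2 >
                   zs[-1] - ts[-1] / 2))
        add(diagnostic("fatal", "membranes",
                       "overlapping membranes: leaflet slabs intersect"))
    }
  }
  for (i in seq_along(spec$membranes)) {
    m <- spec$membranes[[i]]
    if (any(m$apl <= 0) || any(m$apl_lower <= 0))
      add(diagnostic("fatal", sprintf("membranes[%d].apl", i), "apl must be > 0"))
    if (any(m$composition <= 0) || any(m$composition_lower <= 0))
      add(diagnostic("fatal", sprintf("membranes[%d].composition", i),
                     "lipid ratio weights must be positive"))
  }
  diags
}

#' Stage order of a build
#'
#' Stages run serially in a fixed order: proteins, membranes leaflet by
#' leaflet (membranes sorted by ascending center z), flooding solutes,
#' solvent, ions/neutralization, then the writers. The order is a pure
#' function of the spec, so identical specs build identically.
#'
#' @param spec a valid [system_spec()]
#' @return character vector of stage labels
#' @export
build_order <- function(spec) {
  stages <- character(0)
  for (i in seq_along(spec$proteins)) stages <- c(stages, sprintf("protein:%d", i))
  if (length(spec$membranes) > 0) {
    zc <- vapply(spec$membranes, function(m) m$zc %||% spec$box$z / 2, numeric(1))
    for (i in order(zc)) {
      m <- spec$membranes[[i]]
      if (m$leaflets %in% c("both", "upper"))
        stages <- c(stages, sprintf("membrane:%d:upper", i))
      if (m$leaflets %in% c("both", "lower"))
        stages <- c(stages, sprintf("membrane:%d:lower", i))
    }
  }
  for (i in seq_along(spec$flooding)) stages <- c(stages, sprintf("flood:%d", i))
  if (!is.null(spec$solvation)) stages <- c(stages, "solvent", "ions")
  c(stages, "write")
}
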
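# Parameter libraries, fragment-based lipid assembly, molecule import, and
# structure-only output (crafting).
#
# Fragment geometry convention: the head-side anchor of every fragment sits
# at its local origin and the molecule's principal axis runs along -z, so a
# built lipid is in the upper-leaflet orientation and the lower leaflet is a
# plain z-negation.

#' Create an empty molecule/fragment library
#'
#' Libraries are searched in user-declared priority order; several libraries
#' of the same kind may coexist, and an earlier library shadows a later one
#' for duplicate names.
#'
#' @param name library name
#' @param kind free-form kind tag (lipid, solvent, ion, fragment, protein, mixed)
#' @return object of class `molecule_library`
#' @export
molecule_library <- function(name, kind = "mixed") {
  structure(list(name = name, kind = kind, entries = list()),
            class = "molecule_library")
}

#' Add an entry to a library
#' @param lib a [molecule_library()]
#' @param entry a fragment, [lipid_type()], [solvent_spec()] or `cg_molecule`
#' @export
lib_add <- function(lib, entry) {
  lib$entries[[entry$name]] <- entry
  lib
}

entry_kind <- function(e) {
  if (inherits(e, "cg_fragment")) e$kind
  else if (inherits(e, "lipid_type")) "lipid"
  else if (inherits(e, "solvent_spec")) e$role
  else "molecule"
}

#' Resolve a name across libraries in priority order
#' @param name entry name
#' @param libraries list of [molecule_library()] in priority order
#' @export
resolve_name <- function(name, libraries) {
  for (lib in libraries) {
    e <- lib$entries[[name]]
    if (!is.null(e)) return(e)
  }
  stop_cg("lookup_error",
          sprintf("'%s' not found in libraries: %s", name,
                  paste(vapply(libraries, function(l) l$name, character(1)),
                        collapse = " > ")))
}

new_fragment <- function(name, kind, beads, anchors) {
  kind <- match.arg(kind, c("head", "linker", "tail"))
  need <- switch(kind, head = "down", linker = "up", tail = "up")
  if (!need %in% names(anchors))
    stop_cg("invalid_parameter",
            sprintf("fragment %s (%s) lacks required anchor '%s'", name, kind, need))
  if (kind == "linker" && !any(grepl("^tail", names(anchors))))
    stop_cg("invalid_parameter",
            sprintf("linker fragment %s needs at least one tail-side anchor", name))
  structure(list(name = name, kind = kind, beads = beads, anchors = anchors),
            class = "cg_fragment")
}

#' Parse a fragment/molecule library file
#'
#' Plain text format, one block per entry:
#' \preformatted{
#' fragment NAME head|linker|tail
#' bead  NAME RESNAME X Y Z CHARGE [tail]
#' anchor NAME X Y Z
#' end
#'
#' molecule NAME solvent|positive-ion|negative-ion|solute|lipid
#' bead ... ; mapping N
#' end
#' }
#' Coordinates in nm, charges in elementary charges.
#'
#' @param path library file path
#' @param name library name (defaults to the file name)
#' @return a [molecule_library()]
#' @export
parse_fragment_library <- function(path, name = basename(path)) {
  lib <- molecule_library(name)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  while (i <= length(lines)) {
    toks <- strsplit(trimws(sub("#.*$", "", lines[i])), "\\s+")[[1]]
    if (length(toks) == 0 || toks[1] == "") { i <- i + 1L; next }
    if (!toks[1] %in% c("fragment", "molecule"))
      stop_cg("parse_error", sprintf("%s:%d: expected 'fragment' or 'molecule'", path, i))
    hdr <- toks
    beads <- list(); anchors <- list(); mapping <- 1
    i <- i + 1L
    repeat {
      if (i > length(lines))
        stop_cg("parse_error", sprintf("%s: unterminated block '%s'", path, hdr[2]))
      t2 <- strsplit(trimws(sub("#.*$", "", lines[i])), "\\s+")[[1]]
      i <- i + 1L
      if (length(t2) == 0 || t2[1] == "") next
      if (t2[1] == "end") break
      if (t2[1] == "bead") {
        beads[[length(beads) + 1L]] <- bead_frame(
          t2[2], t2[3], as.numeric(t2[4]), as.numeric(t2[5]), as.numeric(t2[6]),
          as.numeric(t2[7]), tail = length(t2) >= 8 && t2[8] == "tail")
      } else if (t2[1] == "anchor") {
        anchors[[t2[2]]] <- as.numeric(t2[3:5])
      } else if (t2[1] == "mapping") {
        mapping <- as.numeric(t2[2])
      } else {
        stop_cg("parse_error", sprintf("%s: unknown directive '%s'", path, t2[1]))
      }
    }
    bdf <- do.call(rbind, beads)
    entry <- if (hdr[1] == "fragment") {
      new_fragment(hdr[2], hdr[3], bdf, anchors)
    } else if (hdr[3] == "lipid") {
      lipid_type(hdr[2], bdf)
    } else {
      solvent_spec(hdr[2], bdf, molarity = 0, mapping_factor = mapping,
                   role = hdr[3])
    }
    lib <- lib_add(lib, entry)
  }
  lib
}

translate_beads <- function(beads, v) {
  beads$x <- beads$x + v[1]; beads$y <- beads$y + v[2]; beads$z <- beads$z + v[3]
  beads
}

#' Assemble a lipid from head, linker and tail fragments
#'
#' Fragments are joined by translation only: the linker's head-side anchor is
#' moved onto the head's down anchor, and each tail's head-side anchor onto
#' the corresponding linker tail anchor (tail1, tail2, ... in order). Internal
#' fragment geometry is preserved exactly; the total charge is the sum of the
#' fragment charges; tail-fragment beads are flagged as hydrophobic.
#'
#' @param head,linker head and linker fragment names
#' @param tails character vector of tail fragment names (at most as many as
#'   the linker has tail anchors)
#' @param libraries list of [molecule_library()] in priority order
#' @param name lipid name; default concatenates the fragment names
#' @return a [lipid_type()]
#' @export
build_lipid <- function(head, linker, tails, libraries, name = NULL) {
  hf <- resolve_name(head, libraries)
  lf <- resolve_name(linker, libraries)
  tfs <- lapply(tails, resolve_name, libraries = libraries)
  for (f in c(list(hf, lf), tfs))
    if (!inherits(f, "cg_fragment"))
      stop_cg("lookup_error", sprintf("'%s' is not a fragment", f$name))
  tail_anchors <- grep("^tail", names(lf$anchors), value = TRUE)
  tail_anchors <- tail_anchors[order(tail_anchors)]
  if (length(tails) > length(tail_anchors))
    stop_cg("assembly_error",
            sprintf("%d tails requested but linker %s has %d tail anchors",
                    length(tails), linker, length(tail_anchors)))
  beads <- hf$beads
  t_link <- hf$anchors$down - lf$anchors$up
  lb <- translate_beads(lf$beads, t_link)
  beads <- rbind(beads, lb)
  for (k in seq_along(tfs)) {
    anchor_pos <- lf$anchors[[tail_anchors[k]]] + t_link
    tb <- translate_beads(tfs[[k]]$beads, anchor_pos - tfs[[k]]$anchors$up)
    tb$tail <- TRUE
    beads <- rbind(beads, tb)
  }
  rownames(beads) <- NULL
  lipid_type(name %||% paste(c(head, linker, tails), collapse = "-"), beads)
}

#' Import a molecule from a structure file
#'
#' Coordinates come from a GRO or PDB file; charges come from a topology
#' entry named by `top_name` when a parsed topology is supplied, and default
#' to zero (with a warning) otherwise. The molecule is recentered so its
#' geometric center sits at the local origin.
#'
#' @param structure_file GRO or PDB path
#' @param name entry name (default: topology name or file base name)
#' @param topology a [parse_topology()] result or NULL
#' @param top_name `[moleculetype]` name linking the structure to its charges
#' @return object of class `cg_molecule`: name, beads, charge
#' @export
import_molecule <- function(structure_file, name = NULL, topology = NULL,
                            top_name = NULL) {
  st <- read_structure(structure_file)
  a <- st$atoms
  charges <- rep(0, nrow(a))
  if (!is.null(topology) && !is.null(top_name)) {
    q <- topology$molecules[[top_name]]
    if (is.null(q))
      stop_cg("lookup_error", sprintf("no [moleculetype] '%s' in topology", top_name))
    if (length(q) != nrow(a))
      stop_cg("import_error",
              sprintf("bead count mismatch: structure %s has %d beads, topology %s has %d atoms",
                      structure_file, nrow(a), top_name, length(q)))
    charges <- q
  } else {
    warning(sprintf("no topology linked for %s; all charges set to 0",
                    basename(structure_file)))
  }
  beads <- bead_frame(a$name, a$resname,
                      a$x - mean(a$x), a$y - mean(a$y), a$z - mean(a$z),
                      charges)
  structure(list(name = name %||% top_name %||%
                   toupper(tools::file_path_sans_ext(basename(structure_file))),
                 beads = beads, charge = sum(charges)),
            class = "cg_molecule")
}

#' List library entries matching a glob pattern
#'
#' @param pattern glob pattern (e.g. `"*"`, `"PO*"`)
#' @param libraries list of [molecule_library()] in priority order
#' @return data.frame: name, kind, library, priority, n_beads, charge; entries
#'   of higher-priority libraries come first
#' @export
query_library <- function(pattern, libraries) {
  rows <- list()
  rx <- utils::glob2rx(pattern)
  for (pri in seq_along(libraries)) {
    lib <- libraries[[pri]]
    for (e in lib$entries) {
      if (!grepl(rx, e$name)) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = e$name, kind = entry_kind(e), library = lib$name,
        priority = pri, n_beads = nrow(e$beads),
        charge = sum(e$beads$charge), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(name = character(0), kind = character(0),
                      library = character(0), priority = integer(0),
                      n_beads = integer(0), charge = numeric(0)))
  do.call(rbind, rows)
}

#' Write a single molecule's structure without building a system
#'
#' The crafting path: resolve (or accept) a molecule and write only its
#' coordinate file, for force-field development workflows that need structure
#' files of individual species.
#'
#' @param molecule an entry name (resolved against `libraries`) or a built
#'   [lipid_type()] / `cg_molecule` object
#' @param path output file; format chosen by extension (.gro or .pdb)
#' @param libraries list of [molecule_library()] used for name resolution
#' @return `path`, invisibly
#' @export
craft <- function(molecule, path, libraries = list()) {
  e <- if (is.character(molecule)) resolve_name(molecule, libraries) else molecule
  if (inherits(e, "cg_fragment"))
    stop_cg("lookup_error", sprintf("'%s' is a fragment, not a molecule", e$name))
  b <- e$beads
  atoms <- data.frame(resnr = 1L, resname = b$resname, name = b$name,
                      x = b$x - min(b$x) + 1, y = b$y - min(b$y) + 1,
                      z = b$z - min(b$z) + 1, stringsAsFactors = FALSE)
  span <- c(diff(range(b$x)), diff(range(b$y)), diff(range(b$z))) + 2
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") write_pdb(atoms, span, path, title = e$name)
  else write_gro(atoms, span, path, title = e$name)
  invisible(path)
}
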
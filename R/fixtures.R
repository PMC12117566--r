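# Synthetic templates and toy systems: a minimal fragment set, generic
# solvents/ions, idealized bead-stack proteins and matching topology files,
# so every build stage is testable without external downloads. Geometry is
# idealized (beads on lattices); no physical realism is claimed.

fixture_fragments <- function() {
  list(
    new_fragment("PHEAD", "head",
                 rbind(bead_frame("NC3", "LIP", 0, 0, 0, 1),
                       bead_frame("PO4", "LIP", 0, 0, -0.3, -1)),
                 list(down = c(0, 0, -0.55))),
    new_fragment("SHEAD", "head",
                 bead_frame("GL0", "LIP", 0, 0, 0, 0),
                 list(down = c(0, 0, -0.25))),
    new_fragment("NHEAD", "head",
                 bead_frame("COO", "LIP", 0, 0, 0, -1),
                 list(down = c(0, 0, -0.3))),
    new_fragment("GLYC", "linker",
                 bead_frame("GL1", "LIP", 0, 0, 0, 0),
                 list(up = c(0, 0, 0.2),
                      tail1 = c(-0.15, 0, -0.2), tail2 = c(0.15, 0, -0.2))),
    new_fragment("MONO", "linker",
                 bead_frame("GL1", "LIP", 0, 0, 0, 0),
                 list(up = c(0, 0, 0.2), tail1 = c(0, 0, -0.2))),
    new_fragment("TL4", "tail",
                 rbind(bead_frame("C1", "LIP", 0, 0, 0, 0, tail = TRUE),
                       bead_frame("C2", "LIP", 0, 0, -0.3, 0, tail = TRUE),
                       bead_frame("C3", "LIP", 0, 0, -0.6, 0, tail = TRUE),
                       bead_frame("C4", "LIP", 0, 0, -0.9, 0, tail = TRUE)),
                 list(up = c(0, 0, 0.15))),
    new_fragment("TL2", "tail",
                 rbind(bead_frame("C1", "LIP", 0, 0, 0, 0, tail = TRUE),
                       bead_frame("C2", "LIP", 0, 0, -0.3, 0, tail = TRUE)),
                 list(up = c(0, 0, 0.15)))
  )
}

fixture_molecules <- function() {
  list(
    solvent_spec("W", bead_frame("W", "W", 0, 0, 0, 0),
                 mapping_factor = 4, role = "solvent"),
    solvent_spec("SW", bead_frame("SW", "SW", 0, 0, 0, 0),
                 mapping_factor = 1, role = "solvent"),
    solvent_spec("NA", bead_frame("NA", "NA", 0, 0, 0, 1),
                 role = "positive-ion"),
    solvent_spec("CL", bead_frame("CL", "CL", 0, 0, 0, -1),
                 role = "negative-ion"),
    solvent_spec("CA", bead_frame("CA", "CA", 0, 0, 0, 2),
                 role = "positive-ion"),
    solvent_spec("SO4", bead_frame("SO4", "SO4", 0, 0, 0, -2),
                 role = "negative-ion"),
    solvent_spec("SOLU",
                 rbind(bead_frame("S1", "SOLU", 0, 0, 0, 0),
                       bead_frame("S2", "SOLU", 0.25, 0, 0, 0)),
                 role = "solute")
  )
}

#' The in-built fixture library
#'
#' A minimal fragment set (two heads, two linkers, two tail lengths), generic
#' single-bead solvents/ions (mono- and divalent), a two-bead solute, and
#' three assembled lipid templates: LLIP (neutral two-tail, large), SLIP
#' (neutral one-tail, small) and CLIP (anionic one-tail, small).
#'
#' @return a [molecule_library()] named `"fixtures"`
#' @export
fixture_library <- function() {
  lib <- molecule_library("fixtures", kind = "mixed")
  for (f in fixture_fragments()) lib <- lib_add(lib, f)
  for (m in fixture_molecules()) lib <- lib_add(lib, m)
  frg <- list(lib)
  lib <- lib_add(lib, build_lipid("PHEAD", "GLYC", c("TL4", "TL4"), frg, name = "LLIP"))
  lib <- lib_add(lib, build_lipid("SHEAD", "MONO", "TL2", frg, name = "SLIP"))
  lib <- lib_add(lib, build_lipid("NHEAD", "MONO", "TL2", frg, name = "CLIP"))
  lib
}

format_entry_block <- function(e) {
  hdr <- if (inherits(e, "cg_fragment"))
    sprintf("fragment %s %s", e$name, e$kind)
  else sprintf("molecule %s %s",
               e$name, if (inherits(e, "lipid_type")) "lipid" else e$role)
  b <- e$beads
  lines <- sprintf("bead %s %s %s %s %s %s%s",
                   b$name, b$resname, fmt_num(b$x), fmt_num(b$y), fmt_num(b$z),
                   fmt_num(b$charge), ifelse(b$tail, " tail", ""))
  if (inherits(e, "cg_fragment"))
    lines <- c(lines, vapply(names(e$anchors), function(a)
      sprintf("anchor %s %s", a, paste(fmt_num(e$anchors[[a]]), collapse = " ")),
      character(1)))
  if (inherits(e, "solvent_spec") && e$mapping_factor != 1)
    lines <- c(lines, sprintf("mapping %s", fmt_num(e$mapping_factor)))
  c(hdr, lines, "end", "")
}

#' Write a library to its plain-text file format
#' @param lib a [molecule_library()]
#' @param path output path
#' @export
write_fragment_library <- function(lib, path) {
  out <- unlist(lapply(lib$entries, format_entry_block))
  writeLines(out, path)
  invisible(path)
}

ring_beads <- function(z, radius, n = 6L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  data.frame(x = radius * cos(th), y = radius * sin(th), z = z)
}

# toy proteins: a straight cylinder and a z-asymmetric hourglass bead stack
# (waist below the midplane, so the two leaflets see different footprints)
fixture_protein_beads <- function(shape = c("cylinder", "hourglass"), seed = 1L) {
  shape <- match.arg(shape)
  set.seed(seed)
  zs <- seq(3, 7, by = 0.4)
  pieces <- lapply(zs, function(z) {
    r <- if (shape == "cylinder") 0.8 else 0.2 + 0.3 * abs(z - 4.4)
    ring_beads(z, r)
  })
  b <- do.call(rbind, pieces)
  b$x <- b$x + stats::runif(nrow(b), -0.01, 0.01)
  b$y <- b$y + stats::runif(nrow(b), -0.01, 0.01)
  b
}

itp_atoms_block <- function(name, beads) {
  c(sprintf("[ moleculetype ]"),
    sprintf("%s  1", name),
    "",
    "[ atoms ]",
    ";  nr type resnr residue atom cgnr charge",
    sprintf("%5d %5s %5d %5s %5s %5d %8.3f",
            seq_len(nrow(beads)), beads$name, 1L, name,
            beads$name, seq_len(nrow(beads)), beads$charge),
    "")
}

#' Generate the fixture file set on disk
#'
#' Writes the fragment library, single-molecule GRO files for every fixture
#' molecule, toy protein coordinates (GRO and PDB), and a three-level
#' GROMACS topology tree (topol.top -> molecules.itp -> ions.itp) whose
#' per-bead charges match the templates exactly. Deterministic for a given
#' seed.
#'
#' @param dir output directory (created if missing)
#' @param seed integer seed (protein-bead jitter)
#' @return named list of written paths
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- fixture_library()
  paths <- list(library = file.path(dir, "fragments.lib"))
  write_fragment_library(lib, paths$library)

  for (m in fixture_molecules()) {
    p <- file.path(dir, paste0(m$name, ".gro"))
    craft(m, p)
    paths[[m$name]] <- p
  }
  for (l in c("LLIP", "SLIP", "CLIP")) {
    p <- file.path(dir, paste0(l, ".gro"))
    craft(l, p, list(lib))
    paths[[l]] <- p
  }

  prot <- list()
  for (shape in c("cylinder", "hourglass")) {
    b <- fixture_protein_beads(shape, seed = seed)
    nm <- toupper(substr(shape, 1, 3))
    atoms <- data.frame(resnr = 1L, resname = nm, name = "BB",
                        x = b$x + 2, y = b$y + 2, z = b$z,
                        stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(shape, ".gro"))
    write_gro(atoms, c(4, 4, 10), p, title = shape)
    paths[[shape]] <- p
    prot[[nm]] <- nrow(b)
  }
  write_pdb(read_gro(paths$cylinder)$atoms, c(4, 4, 10),
            file.path(dir, "cylinder.pdb"))
  paths$cylinder_pdb <- file.path(dir, "cylinder.pdb")

  ions <- c("NA", "CL", "CA", "SO4")
  mols <- setdiff(vapply(fixture_molecules(), function(m) m$name, character(1)), ions)
  ion_lines <- unlist(lapply(ions, function(n)
    itp_atoms_block(n, resolve_name(n, list(lib))$beads)))
  writeLines(ion_lines, file.path(dir, "ions.itp"))
  mol_lines <- unlist(lapply(c(mols, "LLIP", "SLIP", "CLIP"), function(n)
    itp_atoms_block(n, resolve_name(n, list(lib))$beads)))
  prot_lines <- unlist(lapply(names(prot), function(n)
    itp_atoms_block(n, data.frame(name = rep("BB", prot[[n]]),
                                  charge = rep(0, prot[[n]])))))
  writeLines(c("#include \"ions.itp\"", "", mol_lines, prot_lines),
             file.path(dir, "molecules.itp"))
  writeLines(c("; fixture topology", "#include \"molecules.itp\"", "",
               "[ system ]", "fixture", "", "[ molecules ]"),
             file.path(dir, "topol.top"))
  paths$ions_itp <- file.path(dir, "ions.itp")
  paths$molecules_itp <- file.path(dir, "molecules.itp")
  paths$top <- file.path(dir, "topol.top")
  paths
}
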
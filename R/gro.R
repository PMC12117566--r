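# Fixed-width GRO coordinate I/O (nm, 3 decimals) and a secondary PDB writer.

#' Write a GRO coordinate file
#'
#' Fixed-width GRO dialect: title, atom count, one line per atom
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f` = residue number, residue name, atom name,
#' atom number, x/y/z in nm), then the box vector line. Residue and atom
#' numbers wrap at 100000.
#'
#' @param atoms data.frame with columns resnr, resname, name, x, y, z
#' @param box a [cg_box()] or numeric length-3
#' @param path output path
#' @param title title line
#' @return `path`, invisibly
#' @export
write_gro <- function(atoms, box, path, title = "built by cgbuildr") {
  if (inherits(box, "cg_box")) box <- c(box$x, box$y, box$z)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_cg("write_error",
            sprintf("non-finite coordinate for bead %s/%s (atom %d)",
                    atoms$resname[i], atoms$name[i], i))
  }
  n <- nrow(atoms)
  lines <- c(title, sprintf("%d", n))
  if (n > 0) {
    lines <- c(lines, sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      atoms$resnr %% 100000L,
      substr(atoms$resname, 1, 5),
      substr(atoms$name, 1, 5),
      seq_len(n) %% 100000L,
      atoms$x, atoms$y, atoms$z))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#' @param path GRO file path
#' @return list: `title`, `atoms` data.frame (resnr, resname, name, atomnr,
#'   x, y, z), `box` numeric length-3 (nm)
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop_cg("parse_error", sprintf("truncated GRO file %s", path))
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < 2 + n + 1)
    stop_cg("parse_error", sprintf("bad atom count in %s", path))
  al <- lines[3:(2 + n)]
  atoms <- data.frame(
    resnr = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    atomnr = as.integer(substr(al, 16, 20)),
    x = as.numeric(substr(al, 21, 28)),
    y = as.numeric(substr(al, 29, 36)),
    z = as.numeric(substr(al, 37, 44)),
    stringsAsFactors = FALSE)
  box <- as.numeric(strsplit(trimws(lines[2 + n + 1]), "\\s+")[[1]])[1:3]
  list(title = lines[1], atoms = atoms, box = box)
}

#' Write a PDB coordinate file (secondary writer; Angstrom units)
#' @inheritParams write_gro
#' @export
write_pdb <- function(atoms, box, path, title = "built by cgbuildr") {
  if (inherits(box, "cg_box")) box <- c(box$x, box$y, box$z)
  n <- nrow(atoms)
  lines <- c(sprintf("TITLE     %s", title),
             sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     box[1] * 10, box[2] * 10, box[3] * 10))
  if (n > 0) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(n) %% 100000L,
      substr(atoms$name, 1, 4),
      substr(atoms$resname, 1, 4),
      atoms$resnr %% 100000L,
      atoms$x * 10, atoms$y * 10, atoms$z * 10))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB coordinate file (coordinates converted to nm)
#' @param path PDB file path
#' @return list as in [read_gro()] (box NA if no CRYST1 record)
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  al <- lines[grepl("^(ATOM|HETATM)", lines)]
  atoms <- data.frame(
    resnr = as.integer(substr(al, 23, 26)),
    resname = trimws(substr(al, 18, 21)),
    name = trimws(substr(al, 13, 16)),
    atomnr = as.integer(substr(al, 7, 11)),
    x = as.numeric(substr(al, 31, 38)) / 10,
    y = as.numeric(substr(al, 39, 46)) / 10,
    z = as.numeric(substr(al, 47, 54)) / 10,
    stringsAsFactors = FALSE)
  cr <- lines[grepl("^CRYST1", lines)]
  box <- if (length(cr) > 0)
    c(as.numeric(substr(cr[1], 7, 15)), as.numeric(substr(cr[1], 16, 24)),
      as.numeric(substr(cr[1], 25, 33))) / 10
  else rep(NA_real_, 3)
  list(title = "", atoms = atoms, box = box)
}

read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") read_gro(path)
  else if (ext == "pdb") read_pdb(path)
  else stop_cg("parse_error", sprintf("unsupported structure format '%s'", ext))
}
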
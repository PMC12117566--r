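# GROMACS topology handling: the builder only needs per-bead charges (from
# [moleculetype]/[atoms] blocks) and the output [system]/[molecules] ledger;
# everything else is passed through verbatim.

section_name <- function(line) {
  m <- regmatches(line, regexec("^\\s*\\[\\s*([A-Za-z_]+)\\s*\\]", line))[[1]]
  if (length(m) == 2) tolower(m[2]) else NA_character_
}

strip_comment <- function(line) sub(";.*$", "", line)

parse_top_file <- function(path, chain, acc) {
  if (!file.exists(path))
    stop_cg("parse_error",
            sprintf("missing include target '%s' (include chain: %s)",
                    path, paste(chain, collapse = " -> ")))
  lines <- readLines(path, warn = FALSE)
  sec <- NA_character_
  cur_mol <- NULL
  ifdef_depth <- 0L
  ifdef_warned <- FALSE
  flush_mol <- function() {
    if (!is.null(cur_mol)) {
      if (cur_mol$name %in% names(acc$molecules))
        stop_cg("parse_error",
                sprintf("duplicate [moleculetype] definition '%s' (%s and %s)",
                        cur_mol$name, acc$sources[[cur_mol$name]], path))
      acc$molecules[[cur_mol$name]] <<- cur_mol$charges
      acc$sources[[cur_mol$name]] <<- path
    }
    cur_mol <<- NULL
  }
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    trimmed <- trimws(strip_comment(raw))
    if (grepl("^#ifdef|^#ifndef", trimmed)) {
      ifdef_depth <- ifdef_depth + 1L
      if (!ifdef_warned) {
        warning(sprintf("%s:%d: #ifdef block passed through unevaluated; charges inside are ignored",
                        path, ln))
        ifdef_warned <- TRUE
      }
      next
    }
    if (grepl("^#endif", trimmed)) {
      ifdef_depth <- max(0L, ifdef_depth - 1L)
      next
    }
    if (ifdef_depth > 0L) next
    inc <- regmatches(trimmed, regexec("^#include\\s+\"([^\"]+)\"", trimmed))[[1]]
    if (length(inc) == 2) {
      flush_mol()
      target <- file.path(dirname(path), inc[2])
      if (!file.exists(target) && file.exists(inc[2])) target <- inc[2]
      acc <- parse_top_file(target, c(chain, target), acc)
      sec <- NA_character_
      next
    }
    s <- section_name(raw)
    if (!is.na(s)) {
      if (s == "moleculetype") flush_mol()
      sec <- s
      next
    }
    if (trimmed == "") next
    if (is.na(sec)) next
    if (sec == "moleculetype") {
      flush_mol()
      toks <- strsplit(trimmed, "\\s+")[[1]]
      cur_mol <- list(name = toks[1], charges = numeric(0))
    } else if (sec == "atoms") {
      if (is.null(cur_mol))
        stop_cg("parse_error", sprintf("%s:%d: [atoms] outside [moleculetype]", path, ln))
      toks <- strsplit(trimmed, "\\s+")[[1]]
      # nr type resnr residue atom cgnr charge [mass]
      if (length(toks) < 6)
        stop_cg("parse_error", sprintf("%s:%d: malformed atoms line '%s'", path, ln, raw))
      q <- if (length(toks) >= 7) suppressWarnings(as.numeric(toks[7])) else 0
      if (is.na(q))
        stop_cg("parse_error", sprintf("%s:%d: non-numeric charge in atoms line '%s'",
                                       path, ln, raw))
      cur_mol$charges <- c(cur_mol$charges, q)
    }
  }
  flush_mol()
  acc
}

#' Parse a GROMACS topology tree
#'
#' Collects every `[moleculetype]`'s per-atom charges across the whole
#' `#include` tree (depth-first; includes resolve relative to the including
#' file). `#ifdef` blocks are passed through unevaluated with a warning.
#'
#' @param root path to the root .top/.itp file
#' @return object of class `topology_set`: `molecules` (name -> numeric
#'   charge vector), `sources` (name -> defining file), `root`
#' @export
parse_topology <- function(root) {
  acc <- new.env()
  acc$molecules <- list()
  acc$sources <- list()
  acc <- parse_top_file(root, root, acc)
  structure(list(molecules = as.list(acc$molecules),
                 sources = as.list(acc$sources), root = root),
            class = "topology_set")
}

#' Net charge of a topology molecule
#' @param topset a [parse_topology()] result
#' @param name moleculetype name
#' @export
molecule_charge <- function(topset, name) {
  q <- topset$molecules[[name]]
  if (is.null(q)) stop_cg("lookup_error", sprintf("no topology entry '%s'", name))
  sum(q)
}

# run-length merge of consecutive identical molecule names
merge_ledger <- function(names, counts) {
  if (length(names) == 0) return(data.frame(name = character(0), count = integer(0)))
  keep <- c(TRUE, names[-1] != names[-length(names)])
  grp <- cumsum(keep)
  data.frame(name = names[keep],
             count = as.integer(tapply(counts, grp, sum)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the output topology of a built system
#'
#' Copies the root topology verbatim (preserving `#include` lines), drops any
#' existing `[system]`/`[molecules]` sections, and appends the built system's
#' sections, with consecutive identical molecules merged into one counted
#' line.
#'
#' @param topset a [parse_topology()] result (or NULL to emit only the
#'   include-less ledger)
#' @param ledger data.frame with columns name, count in build order
#' @param path output .top path
#' @param title `[system]` title line
#' @return the merged ledger, invisibly
#' @export
write_topology <- function(topset, ledger, path, title = "built system") {
  merged <- merge_ledger(ledger$name, ledger$count)
  if (!is.null(topset)) {
    missing <- setdiff(unique(merged$name), names(topset$molecules))
    if (length(missing) > 0)
      stop_cg("topology_error",
              sprintf("built molecules lack topology entries: %s",
                      paste(missing, collapse = ", ")))
  }
  out <- character(0)
  if (!is.null(topset)) {
    lines <- readLines(topset$root, warn = FALSE)
    sec <- NA_character_
    for (raw in lines) {
      s <- section_name(raw)
      if (!is.na(s)) sec <- s
      if (!is.na(sec) && sec %in% c("system", "molecules")) next
      out <- c(out, raw)
    }
  }
  out <- c(out, "", "[ system ]", title, "", "[ molecules ]",
           "; name  count")
  if (nrow(merged) > 0)
    out <- c(out, sprintf("%-8s %d", merged$name, merged$count))
  writeLines(out, path)
  invisible(merged)
}
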
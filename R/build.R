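# The serial build pipeline: proteins -> membranes (leaflet by leaflet) ->
# flooding -> solvent -> ions/neutralization -> writers, and the command-line
# entry point over it.

resolve_lipid <- function(name, libraries) {
  e <- resolve_name(name, libraries)
  if (inherits(e, "lipid_type")) e
  else if (!is.null(e$beads)) lipid_type(name, e$beads)
  else stop_cg("lookup_error", sprintf("'%s' is not usable as a lipid", name))
}

resolve_solvent <- function(name, libraries, molarity = 0) {
  e <- resolve_name(name, libraries)
  if (inherits(e, "solvent_spec"))
    solvent_spec(name, e$beads, molarity = molarity,
                 mapping_factor = e$mapping_factor, role = e$role)
  else if (!is.null(e$beads))
    solvent_spec(name, e$beads, molarity = molarity)
  else stop_cg("lookup_error", sprintf("'%s' is not usable as a solvent", name))
}

center_template <- function(beads) {
  beads$x <- beads$x - mean(beads$x)
  beads$y <- beads$y - mean(beads$y)
  beads$z <- beads$z - mean(beads$z)
  beads
}

# expand cell-center placements into bead records
realize_placements <- function(placements, templates) {
  if (nrow(placements) == 0) return(NULL)
  pieces <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    tpl <- center_template(templates[[placements$molname[i]]])
    pieces[[i]] <- data.frame(
      molname = placements$molname[i], molid = i, resname = placements$molname[i],
      name = tpl$name, x = tpl$x + placements$x[i], y = tpl$y + placements$y[i],
      z = tpl$z + placements$z[i], charge = tpl$charge, tail = FALSE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}

#' Build a system from its declarative specification
#'
#' Runs validation, then the serial stage order of [build_order()]: proteins
#' are read and placed, each leaflet is allocated
#' ([plan_leaflet()]), placed ([initial_placement()]) and relaxed
#' ([relax()]), flooding solutes and solvent molecules are inserted on the
#' occupancy grid ([rasterize()], [place_solvent()]), salt is added at its
#' target molarity and the system neutralized exactly ([neutralize()]), and
#' the requested coordinate/topology files are written. The whole build is a
#' pure function of (spec, seed).
#'
#' @param spec a [system_spec()]
#' @param libraries list of [molecule_library()] in priority order; the
#'   in-built [fixture_library()] is always appended as the final fallback
#' @param topology a [parse_topology()] result used for imported-molecule
#'   charges and for the output .top, or NULL
#' @param protein_bead_radius footprint radius assigned to protein beads, nm
#' @param debug_dir if set, write per-leaflet CSVs of disc centers/radii
#'   before and after relaxation into this directory
#' @param verbose emit per-stage log messages
#' @return object of class `cg_system`: `atoms` (bead table with charges),
#'   `ledger` (molecule name/count in build order), `ion_plan`, `log`,
#'   `stages`, `spec`
#' @export
build_system <- function(spec, libraries = list(), topology = NULL,
                         protein_bead_radius = 0.3, debug_dir = NULL,
                         verbose = FALSE) {
  libraries <- c(libraries, list(fixture_library()))
  diags <- validate_spec(spec)
  if (is_fatal(diags)) {
    msgs <- vapply(diags, function(d) sprintf("[%s] %s: %s", d$level, d$field, d$message),
                   character(1))
    stop_cg("invalid_spec", paste(msgs, collapse = "\n"))
  }
  for (d in diags) warning(sprintf("%s: %s", d$field, d$message))

  stages <- build_order(spec)
  box <- spec$box
  logv <- character(0)
  say <- function(...) {
    m <- sprintf(...)
    logv <<- c(logv, m)
    if (verbose) message(m)
  }

  atoms <- NULL
  ledger_name <- character(0); ledger_count <- integer(0)
  add_ledger <- function(name, count) {
    ledger_name <<- c(ledger_name, name)
    ledger_count <<- c(ledger_count, as.integer(count))
  }
  append_atoms <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    atoms <<- if (is.null(atoms)) df else rbind(atoms, df)
  }

  protein_xyz <- NULL            # with footprint radii
  mem_tail_z <- list()           # per membrane: realized tail bead z range
  grid <- NULL
  solv_volume <- NULL            # solvent-accessible volume used for molarities
  ion_plan <- NULL

  ensure_grid <- function(extra_specs) {
    if (!is.null(grid)) return(invisible())
    slabs <- list()
    for (i in seq_along(spec$membranes)) {
      tz <- mem_tail_z[[as.character(i)]]
      if (is.null(tz)) next
      m <- spec$membranes[[i]]
      slabs[[length(slabs) + 1L]] <- list(
        zlo = tz[1] - 0.15, zhi = tz[2] + 0.15,
        boundary = m$boundary %||% rect_polygon(0, box$x, 0, box$y),
        holes = m$pores)
    }
    grid <<- rasterize(box, extra_specs, beads = atoms, slabs = slabs)
    say("raster: cell %.3f nm, %d free cells, %.1f nm^3 free volume",
        grid$cell, grid$n_free, grid$free_volume)
  }

  solv_specs <- list()
  if (!is.null(spec$solvation)) {
    sv <- spec$solvation
    solv_specs <- lapply(seq_along(sv$solvents), function(i)
      resolve_solvent(names(sv$solvents)[i], libraries, sv$solvents[[i]]))
  }
  flood_specs <- lapply(spec$flooding, function(fl)
    resolve_solvent(fl$solute, libraries))
  all_cell_specs <- c(solv_specs, flood_specs)

  for (label in stages) {
    part <- strsplit(label, ":")[[1]]
    kind <- part[1]
    if (kind == "protein") {
      i <- as.integer(part[2])
      p <- spec$proteins[[i]]
      st <- read_structure(p$file)
      a <- st$atoms
      if (p$rotz != 0) {
        th <- p$rotz * pi / 180
        cx <- mean(a$x); cy <- mean(a$y)
        xr <- cx + (a$x - cx) * cos(th) - (a$y - cy) * sin(th)
        yr <- cy + (a$x - cx) * sin(th) + (a$y - cy) * cos(th)
        a$x <- xr; a$y <- yr
      }
      a$x <- a$x + p$cx; a$y <- a$y + p$cy; a$z <- a$z + p$cz
      molname <- a$resname[1]
      charges <- rep(0, nrow(a))
      if (!is.null(topology) && !is.null(topology$molecules[[molname]])) {
        q <- topology$molecules[[molname]]
        if (length(q) == nrow(a))
          charges <- q
        else
          warning(sprintf("topology %s has %d atoms, structure has %d; protein charges set to 0",
                          molname, length(q), nrow(a)))
      }
      append_atoms(data.frame(molname = molname, molid = 1L, resname = a$resname,
                              name = a$name, x = a$x, y = a$y, z = a$z,
                              charge = charges, tail = FALSE,
                              stringsAsFactors = FALSE))
      add_ledger(molname, 1L)
      protein_xyz <- rbind(protein_xyz,
                           data.frame(x = a$x, y = a$y, z = a$z,
                                      radius = protein_bead_radius))
      say("protein %s: %d beads at (%.2f, %.2f, %.2f)", molname, nrow(a),
          p$cx, p$cy, p$cz)
    } else if (kind == "membrane") {
      i <- as.integer(part[2]); side <- part[3]
      m <- spec$membranes[[i]]
      zc <- m$zc %||% (box$z / 2)
      z_anchor <- if (side == "upper") zc + m$thickness / 2 else zc - m$thickness / 2
      slab <- if (side == "upper") c(zc, z_anchor + 0.3) else c(z_anchor - 0.3, zc)
      comp <- if (side == "upper") m$composition else m$composition_lower
      apl <- if (side == "upper") m$apl else m$apl_lower
      boundary <- m$boundary %||% rect_polygon(0, box$x, 0, box$y)
      holes <- m$pores
      if (!is.null(protein_xyz))
        holes <- c(holes, protein_footprint(protein_xyz, slab[1], slab[2]))
      region <- leaflet_region(boundary, holes)
      a_free <- free_area(region)
      types <- stats::setNames(
        lapply(names(comp), resolve_lipid, libraries = libraries), names(comp))
      plan <- plan_leaflet(a_free, apl, comp)
      discs <- initial_placement(plan, region, types,
                                 seed = child_seed(spec$seed, paste0(label, ":place")))
      rx <- relax(discs, region,
                  seed = child_seed(spec$seed, paste0(label, ":relax")))
      if (!is.null(debug_dir)) {
        dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
        tag <- gsub(":", "_", label)
        utils::write.csv(discs, file.path(debug_dir, paste0(tag, "_initial.csv")),
                         row.names = FALSE)
        utils::write.csv(rx$discs, file.path(debug_dir, paste0(tag, "_relaxed.csv")),
                         row.names = FALSE)
      }
      bd <- realize_leaflet(rx$discs, types, z_anchor, side,
                            seed = child_seed(spec$seed, paste0(label, ":rot")))
      append_atoms(bd)
      for (nm in names(plan$counts))
        if (plan$counts[[nm]] > 0) add_ledger(nm, plan$counts[[nm]])
      if (nrow(bd) > 0 && any(bd$tail)) {
        key <- as.character(i)
        tz <- range(bd$z[bd$tail])
        mem_tail_z[[key]] <- if (is.null(mem_tail_z[[key]])) tz
          else range(c(mem_tail_z[[key]], tz))
      }
      say("membrane %d %s leaflet: A_free %.2f nm^2, %d lipids (%s)%s", i, side,
          a_free, plan$n_max,
          paste(sprintf("%s %d", names(plan$counts), plan$counts), collapse = ", "),
          if (rx$converged) "" else " [relaxation hit step budget]")
    } else if (kind == "flood") {
      i <- as.integer(part[2])
      fl <- spec$flooding[[i]]
      ensure_grid(all_cell_specs)
      cnt <- fl$count %||%
        as.integer(round_half_away(fl$molarity * AVOGADRO_NM3 * grid$free_volume))
      pl <- place_solvent(grid, stats::setNames(cnt, fl$solute),
                          seed = child_seed(spec$seed, label))
      grid <- pl$grid
      tmpl <- stats::setNames(list(flood_specs[[i]]$beads), fl$solute)
      append_atoms(realize_placements(pl$placements, tmpl))
      if (cnt > 0) add_ledger(fl$solute, cnt)
      say("flooding: %d %s solutes", cnt, fl$solute)
    } else if (kind == "solvent") {
      sv <- spec$solvation
      ensure_grid(all_cell_specs)
      # molarity conversions for solvent and salt share this volume
      solv_volume <- grid$free_volume
      counts <- solvent_counts(solv_volume, solv_specs, sv$ratio_mode)
      pl <- place_solvent(grid, counts, seed = child_seed(spec$seed, "solvent"))
      grid <- pl$grid
      tmpl <- stats::setNames(lapply(solv_specs, function(s) s$beads),
                              vapply(solv_specs, function(s) s$name, character(1)))
      append_atoms(realize_placements(pl$placements, tmpl))
      for (nm in names(counts)) if (counts[[nm]] > 0) add_ledger(nm, counts[[nm]])
      say("solvent: %s", paste(sprintf("%s %d", names(counts), counts), collapse = ", "))
    } else if (kind == "ions") {
      sv <- spec$solvation
      if (is.null(sv$salt)) {
        q <- round(sum(atoms$charge %||% 0))
        if (q != 0)
          warning(sprintf("system carries net charge %+d but no ion species were given", q))
        next
      }
      ensure_grid(all_cell_specs)
      if (is.null(solv_volume)) solv_volume <- grid$free_volume
      n_salt <- as.integer(round_half_away(sv$salt$molarity * AVOGADRO_NM3 *
                                           solv_volume))
      pos <- resolve_solvent(sv$salt$pos, libraries)
      neg <- resolve_solvent(sv$salt$neg, libraries)
      q_pre <- round(sum(atoms$charge %||% 0)) +
        n_salt * round(pos$charge) + n_salt * round(neg$charge)
      ion_plan <- neutralize(q_pre, pos, neg,
                             placed_counts = stats::setNames(c(n_salt, n_salt),
                                                             c(pos$name, neg$name)),
                             algorithm = sv$neutralization)
      final <- stats::setNames(c(n_salt, n_salt), c(pos$name, neg$name)) +
        ion_plan$add - ion_plan$remove
      pl <- place_solvent(grid, final, seed = child_seed(spec$seed, "ions"))
      grid <- pl$grid
      tmpl <- stats::setNames(list(pos$beads, neg$beads), c(pos$name, neg$name))
      append_atoms(realize_placements(pl$placements, tmpl))
      for (nm in names(final)) if (final[[nm]] > 0) add_ledger(nm, final[[nm]])
      say("ions: %s (salt %d+%d, add %s, remove %s); net charge %d",
          paste(sprintf("%s %d", names(final), final), collapse = ", "),
          n_salt, n_salt,
          paste(ion_plan$add, collapse = "/"), paste(ion_plan$remove, collapse = "/"),
          round(sum(atoms$charge)))
    }
    # the "write" stage runs after the loop once numbering is final
  }

  ledger <- data.frame(name = ledger_name, count = ledger_count,
                       stringsAsFactors = FALSE)
  if (is.null(atoms))
    atoms <- data.frame(molname = character(0), molid = integer(0),
                        resname = character(0), name = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        charge = numeric(0), tail = logical(0))
  # assign one residue number per molecule instance, in build order
  brk <- c(TRUE, atoms$molname[-1] != atoms$molname[-nrow(atoms)] |
                 atoms$molid[-1] != atoms$molid[-nrow(atoms)])
  if (nrow(atoms) == 0) brk <- logical(0)
  atoms$resnr <- cumsum(brk)

  sys <- structure(list(spec = spec, atoms = atoms, ledger = ledger,
                        ion_plan = ion_plan, log = logv, stages = stages,
                        grid = if (!is.null(grid))
                          list(cell = grid$cell, n_free = grid$n_free,
                               free_volume = grid$free_volume,
                               solvation_volume = solv_volume)),
                   class = "cg_system")

  out <- spec$output
  if (!is.null(out$gro)) write_gro(atoms, box, out$gro)
  if (!is.null(out$pdb)) write_pdb(atoms, box, out$pdb)
  if (!is.null(out$top)) write_topology(topology, ledger, out$top)
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$atoms), "beads,",
      sum(x$ledger$count), "molecules\n")
  lg <- merge_ledger(x$ledger$name, x$ledger$count)
  for (i in seq_len(nrow(lg))) cat(sprintf("  %-8s %d\n", lg$name[i], lg$count[i]))
  invisible(x)
}

parse_cli <- function(argv) {
  spec_args <- list(box = NULL, membrane = character(0), protein = character(0),
                    solvation = NULL, flood = character(0), seed = 1L,
                    out = list(), config = NULL)
  libs <- character(0); itps <- character(0)
  i <- 1L
  need <- function(n = 1L) {
    if (i + n > length(argv)) stop_cg("cli_error", sprintf("flag %s needs a value", argv[i]))
    v <- argv[(i + 1L):(i + n)]
    i <<- i + n
    v
  }
  while (i <= length(argv)) {
    a <- argv[i]
    switch(a,
      "--config" = { spec_args$config <- need() },
      "--box" = { spec_args$box <- as.numeric(need(3L)) },
      "--membrane" = { spec_args$membrane <- c(spec_args$membrane, need()) },
      "--protein" = { spec_args$protein <- c(spec_args$protein, need()) },
      "--solvation" = { spec_args$solvation <- need() },
      "--flood" = { spec_args$flood <- c(spec_args$flood, need()) },
      "--itp" = { itps <- c(itps, need()) },
      "--library" = { libs <- c(libs, need()) },
      "--out-gro" = { spec_args$out$gro <- need() },
      "--out-top" = { spec_args$out$top <- need() },
      "--out-pdb" = { spec_args$out$pdb <- need() },
      "--seed" = { spec_args$seed <- as.integer(need()) },
      stop_cg("cli_error", sprintf("unknown flag '%s'", a))
    )
    i <- i + 1L
  }
  spec <- if (!is.null(spec_args$config)) {
    read_config(spec_args$config)
  } else {
    if (is.null(spec_args$box)) stop_cg("cli_error", "--box X Y Z is required")
    system_spec(
      box = cg_box(spec_args$box[1], spec_args$box[2], spec_args$box[3]),
      membranes = lapply(spec_args$membrane, parse_membrane_arg),
      proteins = lapply(spec_args$protein, parse_protein_arg),
      solvation = if (!is.null(spec_args$solvation))
        parse_solvation_arg(spec_args$solvation),
      flooding = lapply(spec_args$flood, parse_flood_arg),
      output = spec_args$out,
      seed = spec_args$seed)
  }
  topology <- NULL
  if (length(itps) > 0) {
    topology <- parse_topology(itps[1])
    for (f in itps[-1]) {
      t2 <- parse_topology(f)
      dup <- intersect(names(topology$molecules), names(t2$molecules))
      if (length(dup) > 0)
        stop_cg("parse_error", sprintf("duplicate moleculetypes across topologies: %s",
                                       paste(dup, collapse = ", ")))
      topology$molecules <- c(topology$molecules, t2$molecules)
      topology$sources <- c(topology$sources, t2$sources)
    }
  }
  list(spec = spec, libraries = lapply(libs, parse_fragment_library),
       topology = topology)
}

#' Command-line entry point
#'
#' Builds a system from CLI flags (`--box X Y Z`, repeatable `--membrane`,
#' `--protein`, `--flood`, plus `--solvation`, `--itp`, `--library`,
#' `--out-gro/--out-top/--out-pdb`, `--seed`, or `--config FILE`), logging
#' each stage. The first positional argument may select the `fixtures`
#' subcommand (`cli_build(c("fixtures", dir, seed))`), which writes the
#' synthetic fixture set instead of building a system.
#'
#' @param argv character vector of arguments (default: the process arguments)
#' @return integer exit status, invisibly: 0 on success, 1 on any diagnosed
#'   failure (message on stderr)
#' @export
cli_build <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) >= 1 && argv[1] == "fixtures") {
      dir <- if (length(argv) >= 2) argv[2] else "fixtures"
      seed <- if (length(argv) >= 3) as.integer(argv[3]) else 1L
      make_fixtures(dir, seed)
      message(sprintf("fixtures written to %s", dir))
      0L
    } else {
      parsed <- parse_cli(argv)
      build_system(parsed$spec, parsed$libraries, parsed$topology, verbose = TRUE)
      0L
    }
  }, cgbuildr_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
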
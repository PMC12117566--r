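# Rasterized solvation: mark occupied box cells, convert molarity to counts,
# place solvent/ions into free cells, neutralize the system charge.

#' Avogadro factor in molecules per nm^3 per mol/L
#'
#' 1 M corresponds to 0.6022140857 molecules per nm^3.
#' @export
AVOGADRO_NM3 <- 0.6022140857

molecule_extent <- function(beads) {
  if (nrow(beads) < 2) return(0)
  max(stats::dist(beads[, c("x", "y", "z")]))
}

#' Rasterize the box for solvent insertion
#'
#' The cell size equals the maximal intra-molecular bead distance over all
#' requested solvent molecules, with a floor of 0.5 nm. A cell is marked
#' occupied when an existing bead center falls in it, or when the cell's
#' z-extent overlaps a membrane hydrophobic slab and the cell center's xy
#' position lies inside that membrane's footprint (boundary minus pores).
#'
#' @param box a [cg_box()]
#' @param solvents list of [solvent_spec()] to be inserted
#' @param beads NULL or data.frame of existing bead coordinates (x, y, z)
#' @param slabs list of hydrophobic slabs, each
#'   `list(zlo, zhi, boundary = polygon or NULL, holes = list())`
#' @return object of class `occupancy_grid`: cell size, dims, free (logical
#'   3D array), free cell count, free volume nm^3
#' @export
rasterize <- function(box, solvents, beads = NULL, slabs = list()) {
  if (length(solvents) == 0)
    stop_cg("invalid_parameter", "rasterize needs at least one solvent")
  cell <- max(0.5, max(vapply(solvents, function(s) molecule_extent(s$beads),
                              numeric(1))))
  dims <- c(floor(box$x / cell), floor(box$y / cell), floor(box$z / cell))
  if (any(dims < 1))
    stop_cg("solvation_infeasible", "box smaller than one solvent cell")
  free <- array(TRUE, dim = dims)

  if (!is.null(beads) && nrow(beads) > 0) {
    ix <- pmin(dims[1], pmax(1, floor(beads$x / cell) + 1L))
    iy <- pmin(dims[2], pmax(1, floor(beads$y / cell) + 1L))
    iz <- pmin(dims[3], pmax(1, floor(beads$z / cell) + 1L))
    free[cbind(ix, iy, iz)] <- FALSE
  }

  if (length(slabs) > 0) {
    cx <- (seq_len(dims[1]) - 0.5) * cell
    cy <- (seq_len(dims[2]) - 0.5) * cell
    zlo_cell <- (seq_len(dims[3]) - 1) * cell
    zhi_cell <- zlo_cell + cell
    xy <- as.matrix(expand.grid(x = cx, y = cy))
    for (sl in slabs) {
      zhit <- which(zlo_cell < sl$zhi & zhi_cell > sl$zlo)
      if (length(zhit) == 0) next
      inxy <- if (is.null(sl$boundary)) rep(TRUE, nrow(xy)) else {
        reg <- leaflet_region(sl$boundary, sl$holes %||% list())
        points_in_region(xy, reg)
      }
      if (!any(inxy)) next
      m <- matrix(inxy, dims[1], dims[2])
      for (k in zhit) free[, , k] <- free[, , k] & !m
    }
  }

  n_free <- sum(free)
  if (n_free == 0)
    stop_cg("solvation_infeasible", "no free cells left for solvent insertion")
  structure(list(cell = cell, dims = dims, free = free,
                 n_free = n_free, free_volume = n_free * cell^3, box = box),
            class = "occupancy_grid")
}

#' Solvent molecule counts from molarity and free volume
#'
#' A single solvent gets `round(molarity x 0.6022 x V_free)` molecules. For
#' mixtures, the total count (from the summed molarity) is split by the
#' requested ratios: in `"beads"` mode the weights are the molarities as
#' given; in `"mapping"` mode each weight is multiplied by the solvent's
#' atom-to-bead mapping factor before normalization, so a 50:50 request with
#' mapping factors 4:1 yields an 80:20 molecule split. The split uses floor
#' allocation plus largest-relative-deficit fill, so counts sum exactly to
#' the total.
#'
#' @param free_volume free volume in nm^3 (> 0)
#' @param specs list of [solvent_spec()] with molarities in declaration order
#' @param ratio_mode `"beads"` or `"mapping"`
#' @return named integer counts
#' @export
solvent_counts <- function(free_volume, specs, ratio_mode = c("beads", "mapping")) {
  ratio_mode <- match.arg(ratio_mode)
  if (free_volume <= 0) stop_cg("invalid_parameter", "free_volume must be > 0")
  mol <- vapply(specs, function(s) s$molarity, numeric(1))
  if (any(mol < 0)) stop_cg("invalid_parameter", "negative molarity")
  nm <- vapply(specs, function(s) s$name, character(1))
  names(mol) <- nm
  total <- as.integer(round_half_away(sum(mol) * AVOGADRO_NM3 * free_volume))
  if (length(specs) == 1) return(stats::setNames(total, nm))
  w <- if (ratio_mode == "mapping")
    mol * vapply(specs, function(s) s$mapping_factor, numeric(1)) else mol
  if (total == 0) return(stats::setNames(integer(length(w)), nm))
  keep <- w > 0
  counts <- stats::setNames(integer(length(w)), nm)
  if (any(keep)) {
    fl <- floor_allocation(w[keep], total)
    counts[keep] <- fill_to_max(fl$counts, w[keep], total)
  }
  counts
}

#' Place molecules into free grid cells
#'
#' Each molecule occupies one free cell chosen by seeded sampling without
#' replacement and is centered in it; chosen cells become occupied.
#'
#' @param grid an [rasterize()] occupancy grid
#' @param counts named integer counts (molecule name -> copies)
#' @param seed RNG seed
#' @return list: `placements` data.frame (molname, x, y, z of molecule
#'   centers, in placement order grouped by name), `grid` updated grid
#' @export
place_solvent <- function(grid, counts, seed = 1L) {
  counts <- counts[counts > 0]
  n_tot <- sum(counts)
  if (n_tot == 0)
    return(list(placements = data.frame(molname = character(0), x = numeric(0),
                                        y = numeric(0), z = numeric(0)),
                grid = grid))
  free_idx <- which(grid$free)
  if (n_tot > length(free_idx))
    stop_cg("solvation_infeasible",
            sprintf("need %d cells but only %d are free (short by %d)",
                    n_tot, length(free_idx), n_tot - length(free_idx)))
  set.seed(seed)
  pick <- sample(free_idx, n_tot)
  ai <- arrayInd(pick, grid$dims)
  placements <- data.frame(
    molname = rep(names(counts), counts),
    x = (ai[, 1] - 0.5) * grid$cell,
    y = (ai[, 2] - 0.5) * grid$cell,
    z = (ai[, 3] - 0.5) * grid$cell,
    stringsAsFactors = FALSE)
  grid$free[pick] <- FALSE
  grid$n_free <- sum(grid$free)
  grid$free_volume <- grid$n_free * grid$cell^3
  list(placements = placements, grid = grid)
}

#' Neutralize the system charge
#'
#' Three algorithms: `"add"` inserts counterions (topping off with co-ions
#' when the counterion valence does not divide the excess, so only additions
#' occur); `"remove"` deletes already-placed co-ions; `"combined"` splits the
#' required charge correction as evenly as possible between counterion
#' additions and co-ion removals, assigning an odd remainder to the addition
#' side. All paths end at exactly zero net charge or raise a
#' neutralization-infeasible error.
#'
#' @param system_charge signed integer total charge before neutralization
#'   (salt ions at the target molarity already included)
#' @param pos,neg [solvent_spec()] of the positive and negative ion species
#' @param placed_counts named counts of already-placed ions (removal pool)
#' @param algorithm `"add"`, `"remove"` or `"combined"`
#' @return object of class `ion_plan`: named `add` and `remove` integer
#'   counts and `net_after` (always 0)
#' @export
neutralize <- function(system_charge, pos, neg, placed_counts = integer(0),
                       algorithm = c("add", "remove", "combined")) {
  algorithm <- match.arg(algorithm)
  q <- as.integer(round(system_charge))
  vpos <- as.integer(round(pos$charge))
  vneg <- as.integer(round(abs(neg$charge)))
  if (vpos < 1 || vneg < 1)
    stop_cg("invalid_parameter", "ion species must carry nonzero charge")
  add <- stats::setNames(integer(2), c(pos$name, neg$name))
  rem <- stats::setNames(integer(2), c(pos$name, neg$name))
  if (q != 0) {
    counter <- if (q < 0) pos else neg        # opposite sign of the excess
    co <- if (q < 0) neg else pos
    v_counter <- if (q < 0) vpos else vneg
    v_co <- if (q < 0) vneg else vpos
    need <- abs(q)
    if (algorithm == "add") {
      # fewest additions: a counterions plus (only if needed for exactness)
      # b co-ions, with a*v_counter - b*v_co == |q|
      ab <- NULL
      for (tot in 0:(need * 2 + 4)) {
        for (a in 0:tot) {
          b <- tot - a
          if (a * v_counter - b * v_co == need) { ab <- c(a, b); break }
        }
        if (!is.null(ab)) break
      }
      if (is.null(ab))
        stop_cg("neutralization_infeasible",
                sprintf("cannot cancel charge %+d by additions of %+d/%-d ions",
                        q, vpos, -vneg))
      add[counter$name] <- add[counter$name] + ab[1]
      add[co$name] <- add[co$name] + ab[2]
    } else if (algorithm == "remove") {
      pool <- placed_counts[co$name]
      if (is.na(pool)) pool <- 0L
      if (need %% v_co != 0)
        stop_cg("neutralization_infeasible",
                sprintf("charge %+d is not a multiple of the co-ion valence %d",
                        q, v_co))
      k <- need %/% v_co
      if (k > pool)
        stop_cg("neutralization_infeasible",
                sprintf("need to remove %d %s ions but only %d are placed",
                        k, co$name, pool))
      rem[co$name] <- k
    } else {
      # split the charge correction evenly; odd remainder goes to addition.
      # scan outward from the even split for a pair divisible by the valences
      # and covered by the removal pool
      pool <- placed_counts[co$name]
      if (is.na(pool)) pool <- 0L
      base_add <- ceiling(need / 2)
      found <- FALSE
      for (delta in 0:need) {
        for (qa in unique(c(base_add + delta, base_add - delta))) {
          qr <- need - qa
          if (qa < 0 || qr < 0) next
          if (qa %% v_counter != 0 || qr %% v_co != 0) next
          if (qr %/% v_co > pool) next
          add[counter$name] <- qa %/% v_counter
          rem[co$name] <- qr %/% v_co
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found)
        stop_cg("neutralization_infeasible",
                sprintf("cannot split charge %+d between additions and removals", q))
    }
  }
  net <- q +
    add[pos$name] * vpos - add[neg$name] * vneg -
    rem[pos$name] * vpos + rem[neg$name] * vneg
  stopifnot(net == 0)
  structure(list(add = add, remove = rem, net_after = 0L), class = "ion_plan")
}
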
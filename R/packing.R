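# Leaflet packing: protein footprints, grid/line initial placement of lipid
# discs, and push-force overlap relaxation in the membrane plane.

#' Protein footprint on one leaflet
#'
#' Beads whose z-interval (z +- radius) intersects the leaflet slab are
#' projected onto the xy plane; each contributes its disc, polygonized as a
#' 32-gon, to the leaflet's hole list. Beads outside the slab contribute
#' nothing, so an hourglass-shaped protein yields different footprints on the
#' two leaflets.
#'
#' @param beads data.frame with columns x, y, z (nm) and radius (nm)
#' @param zlo,zhi leaflet slab z-range, nm
#' @return list of hole polygons (possibly empty)
#' @export
protein_footprint <- function(beads, zlo, zhi) {
  if (is.null(beads) || nrow(beads) == 0) return(list())
  hit <- (beads$z - beads$radius) < zhi & (beads$z + beads$radius) > zlo
  lapply(which(hit), function(i)
    disc_polygon(beads$x[i], beads$y[i], beads$radius[i]))
}

# resolve large/small classes: explicit size_class wins, NA classes split at
# the median radius of the lipid types present (>= median -> large)
classify_sizes <- function(types) {
  radii <- vapply(types, function(t) t$radius, numeric(1))
  med <- stats::median(radii)
  vapply(seq_along(types), function(i) {
    sc <- types[[i]]$size_class
    if (!is.na(sc)) sc else if (radii[i] >= med) "large" else "small"
  }, character(1))
}

new_discs <- function(type = character(0), x = numeric(0), y = numeric(0),
                      r = numeric(0)) {
  data.frame(type = type, x = x, y = y, r = r, stringsAsFactors = FALSE)
}

#' Initial lipid disc placement
#'
#' Large-class lipids are placed semirandomly on a 2D grid whose pitch starts
#' at twice the largest large-lipid radius; small-class lipids fill
#' y-directional lines through the area not occupied by large lipids. Both
#' stages iteratively tighten their spacing (factor 0.92, up to 25 rounds)
#' until every requested lipid fits, and fail with a placement-infeasible
#' error otherwise.
#'
#' @param plan a [plan_leaflet()] result (named integer counts)
#' @param region a [leaflet_region()]
#' @param types named list of [lipid_type()] for every name in the plan
#' @param seed integer RNG seed for the semirandom cell/slot choice
#' @return data.frame of discs: type, x, y, r
#' @export
initial_placement <- function(plan, region, types, seed = 1L) {
  counts <- plan$counts
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(new_discs())
  types <- types[names(counts)]
  cls <- classify_sizes(types)
  radii <- vapply(types, function(t) t$radius, numeric(1))
  set.seed(seed)

  inst_type <- rep(names(counts), counts)          # declaration order
  inst_r <- radii[inst_type]
  inst_large <- cls[match(inst_type, names(counts))] == "large"
  bb <- apply(region$boundary, 2, range)

  lattice <- function(pitch) {
    xs <- seq(bb[1, 1] + pitch / 2, bb[2, 1], by = pitch)
    ys <- seq(bb[1, 2] + pitch / 2, bb[2, 2], by = pitch)
    as.matrix(expand.grid(x = xs, y = ys))
  }

  large_xy <- matrix(numeric(0), 0, 2); large_r <- numeric(0)
  n_large <- sum(inst_large)
  if (n_large > 0) {
    pitch <- 2 * max(radii[cls == "large"])
    placed <- FALSE
    for (round in 1:25) {
      cells <- lattice(pitch)
      ok <- points_in_region(cells, region)
      if (sum(ok) >= n_large) {
        pick <- sample(which(ok), n_large)
        large_xy <- cells[pick, , drop = FALSE]
        placed <- TRUE
        break
      }
      pitch <- pitch * 0.92
    }
    if (!placed)
      stop_cg("placement_infeasible",
              sprintf("cannot fit %d large lipids in the leaflet region", n_large))
    large_r <- inst_r[inst_large]
  }

  small_xy <- matrix(numeric(0), 0, 2)
  n_small <- sum(!inst_large)
  if (n_small > 0) {
    s <- 2 * max(radii[cls == "small"])
    placed <- FALSE
    for (round in 1:25) {
      # y-directional lines spaced s in x; slots spaced s along each line
      cand <- lattice(s)
      ok <- points_in_region(cand, region)
      cand <- cand[ok, , drop = FALSE]
      if (nrow(large_xy) > 0 && nrow(cand) > 0) {
        # keep only slots clear of already-placed large discs
        rmax_small <- max(inst_r[!inst_large])
        keep <- rep(TRUE, nrow(cand))
        for (k in seq_len(nrow(large_xy))) {
          d2 <- (cand[, 1] - large_xy[k, 1])^2 + (cand[, 2] - large_xy[k, 2])^2
          keep <- keep & d2 >= (large_r[k] + rmax_small)^2 * 0.8
        }
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand) >= n_small) {
        pick <- sample(nrow(cand), n_small)
        small_xy <- cand[pick, , drop = FALSE]
        placed <- TRUE
        break
      }
      s <- s * 0.92
    }
    if (!placed)
      stop_cg("placement_infeasible",
              sprintf("cannot fit %d small lipids in the leaflet region", n_small))
  }

  xy <- matrix(NA_real_, length(inst_type), 2)
  if (n_large > 0) xy[inst_large, ] <- large_xy
  if (n_small > 0) xy[!inst_large, ] <- small_xy
  new_discs(inst_type, xy[, 1], xy[, 2], inst_r)
}

#' Total pairwise overlap depth of a disc set
#' @param discs data.frame with x, y, r
#' @return sum over pairs of `max(0, r_i + r_j - d_ij)` in nm
#' @export
total_overlap <- function(discs) {
  n <- nrow(discs)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(discs[, c("x", "y")]))
  rs <- outer(discs$r, discs$r, "+")
  o <- pmax(rs - d, 0)
  diag(o) <- 0
  sum(o) / 2
}

# penetration depth of each disc into the boundary / holes and the unit push
# direction resolving it
edge_push <- function(P, r, region) {
  n <- nrow(P)
  fx <- numeric(n); fy <- numeric(n); pen_tot <- numeric(n)
  nb <- polygon_nearest(P, region$boundary)
  inb <- points_in_polygon(P, region$boundary)
  sd <- ifelse(inb, nb$dist, -nb$dist)
  pen <- pmax(0, r - sd)
  dirx <- ifelse(inb, nb$ux, -nb$ux)
  diry <- ifelse(inb, nb$uy, -nb$uy)
  fx <- fx + pen * dirx; fy <- fy + pen * diry; pen_tot <- pen_tot + pen
  for (h in region$holes) {
    hb <- apply(h, 2, range)
    margin <- max(r)
    cand <- which(P[, 1] >= hb[1, 1] - margin & P[, 1] <= hb[2, 1] + margin &
                  P[, 2] >= hb[1, 2] - margin & P[, 2] <= hb[2, 2] + margin)
    if (length(cand) == 0) next
    Pc <- P[cand, , drop = FALSE]
    nh <- polygon_nearest(Pc, h)
    inh <- points_in_polygon(Pc, h)
    sdh <- ifelse(inh, -nh$dist, nh$dist)      # signed distance, + outside
    penh <- pmax(0, r[cand] - sdh)
    dxh <- ifelse(inh, -nh$ux, nh$ux)
    dyh <- ifelse(inh, -nh$uy, nh$uy)
    fx[cand] <- fx[cand] + penh * dxh
    fy[cand] <- fy[cand] + penh * dyh
    pen_tot[cand] <- pen_tot[cand] + penh
  }
  list(fx = fx, fy = fy, pen = pen_tot)
}

project_into_region <- function(P, region, eps = 1e-3) {
  inb <- points_in_polygon(P, region$boundary)
  if (any(!inb)) {
    nb <- polygon_nearest(P[!inb, , drop = FALSE], region$boundary)
    ctr <- colMeans(region$boundary)
    dirx <- ctr[1] - nb$px; diry <- ctr[2] - nb$py
    len <- sqrt(dirx^2 + diry^2); len[len < 1e-12] <- 1
    P[!inb, 1] <- nb$px + eps * dirx / len
    P[!inb, 2] <- nb$py + eps * diry / len
  }
  for (h in region$holes) {
    inh <- points_in_polygon(P, h)
    if (!any(inh)) next
    nh <- polygon_nearest(P[inh, , drop = FALSE], h)
    dirx <- P[inh, 1] - nh$px; diry <- P[inh, 2] - nh$py
    len <- sqrt(dirx^2 + diry^2)
    zero <- len < 1e-12
    if (any(zero)) { dirx[zero] <- 1; diry[zero] <- 0; len[zero] <- 1 }
    # move just past the hole edge, away from the interior
    P[inh, 1] <- nh$px - eps * dirx / len
    P[inh, 2] <- nh$py - eps * diry / len
  }
  P
}

#' Relax disc overlaps with the push-force scheme
#'
#' Discs within a cutoff of 1.2 (r_i + r_j) exert a pairwise push along the
#' center-center vector; the displacement magnitude is overlap depth times
#' (r_i + r_j)/2 times a step factor that decreases linearly from 0.5 to 0.05
#' over the step budget, so early steps take large corrective moves and late
#' steps fine-tune. The boundary and every hole push the same way on discs
#' that penetrate them. Iteration stops when the largest per-disc displacement
#' falls below `tolerance` or the step budget is exhausted; every
#' `record_every` steps the configuration is checkpointed and a step that
#' worsened the total overlap is rolled back to the best checkpoint before
#' continuing, which keeps the sampled overlap trace non-increasing.
#'
#' @param discs data.frame from [initial_placement()]
#' @param region a [leaflet_region()]
#' @param tolerance convergence threshold on the max per-disc displacement, nm
#' @param max_steps step budget
#' @param seed RNG seed (used only to break exactly-coincident centers)
#' @param record_every sampling interval of the overlap trace
#' @return list: `discs` (relaxed), `converged` (logical), `steps`,
#'   `overlap_trace` (numeric, sampled totals including start and end)
#' @export
relax <- function(discs, region, tolerance = 0.005, max_steps = 100L,
                  seed = 1L, record_every = 10L) {
  n <- nrow(discs)
  if (n == 0)
    return(list(discs = discs, converged = TRUE, steps = 0L, overlap_trace = 0))
  set.seed(seed)
  P <- as.matrix(discs[, c("x", "y")])
  r <- discs$r
  if (n == 1) {
    return(list(discs = discs, converged = TRUE, steps = 1L,
                overlap_trace = 0))
  }

  energy <- function(P) {
    d <- as.matrix(stats::dist(P))
    rs <- outer(r, r, "+")
    o <- pmax(rs - d, 0); diag(o) <- 0
    sum(o) / 2
  }

  trace <- energy(P)
  best_P <- P; best_e <- trace[1]
  converged <- FALSE
  lam0 <- 0.5; lam1 <- 0.05
  steps_done <- 0L

  for (s in seq_len(max_steps)) {
    lam <- if (max_steps > 1) lam0 + (lam1 - lam0) * (s - 1) / (max_steps - 1) else lam0
    dx <- outer(P[, 1], P[, 1], "-")
    dy <- outer(P[, 2], P[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    rs <- outer(r, r, "+")
    o <- pmax(rs - d, 0)
    diag(o) <- 0
    act <- o > 0
    if (any(act & d < 1e-9)) {
      # coincident centers: seeded jitter to define a push direction
      idx <- which(act & d < 1e-9 & upper.tri(d), arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        th <- stats::runif(1, 0, 2 * pi)
        dx[idx[k, 1], idx[k, 2]] <- cos(th) * 1e-6
        dy[idx[k, 1], idx[k, 2]] <- sin(th) * 1e-6
        dx[idx[k, 2], idx[k, 1]] <- -cos(th) * 1e-6
        dy[idx[k, 2], idx[k, 1]] <- -sin(th) * 1e-6
      }
      d <- pmax(d, 1e-6)
    }
    dsafe <- ifelse(d > 0, d, 1)
    w <- o * (rs / 2) * lam / dsafe
    mx <- rowSums(w * dx)
    my <- rowSums(w * dy)

    ep <- edge_push(P, r, region)
    mx <- mx + ep$fx * r * lam
    my <- my + ep$fy * r * lam

    # cap each move at the disc radius to keep the scheme stable
    mlen <- sqrt(mx^2 + my^2)
    over <- mlen > r
    if (any(over)) {
      sc <- r[over] / mlen[over]
      mx[over] <- mx[over] * sc; my[over] <- my[over] * sc
      mlen[over] <- r[over]
    }
    P[, 1] <- P[, 1] + mx
    P[, 2] <- P[, 2] + my
    P <- project_into_region(P, region)
    steps_done <- s

    if (s %% record_every == 0L || s == max_steps) {
      e <- energy(P)
      if (e > best_e) {
        P <- best_P           # monotone safeguard: roll back to best state
        e <- best_e
      } else {
        best_P <- P; best_e <- e
      }
      trace <- c(trace, e)
    }
    if (max(mlen) < tolerance) { converged <- TRUE; break }
  }
  e_fin <- energy(P)
  if (e_fin > best_e) { P <- best_P; e_fin <- best_e }
  if (trace[length(trace)] != e_fin) trace <- c(trace, e_fin)
  out <- discs
  out$x <- P[, 1]; out$y <- P[, 2]
  list(discs = out, converged = converged, steps = steps_done,
       overlap_trace = trace)
}

#' Realize a leaflet in 3D from relaxed discs
#'
#' Each disc is replaced by its lipid template translated to (x, y, z_anchor),
#' mirrored in z for the lower leaflet (templates point their tails toward -z,
#' the upper-leaflet orientation), and rotated about z by a seeded random
#' angle per lipid.
#'
#' @param discs relaxed disc data.frame
#' @param types named list of [lipid_type()]
#' @param z_anchor head-anchor plane z, nm
#' @param side `"upper"` or `"lower"`
#' @param seed RNG seed for the rotations
#' @return bead data.frame: molname, molid, resname, name, x, y, z, charge, tail
#' @export
realize_leaflet <- function(discs, types, z_anchor, side = c("upper", "lower"),
                            seed = 1L) {
  side <- match.arg(side)
  set.seed(seed)
  if (nrow(discs) == 0)
    return(data.frame(molname = character(0), molid = integer(0),
                      resname = character(0), name = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = numeric(0), tail = logical(0)))
  pieces <- vector("list", nrow(discs))
  for (i in seq_len(nrow(discs))) {
    tpl <- types[[discs$type[i]]]$beads
    th <- stats::runif(1, 0, 2 * pi)
    xr <- tpl$x * cos(th) - tpl$y * sin(th)
    yr <- tpl$x * sin(th) + tpl$y * cos(th)
    zz <- if (side == "lower") -tpl$z else tpl$z
    pieces[[i]] <- data.frame(
      molname = discs$type[i], molid = i, resname = discs$type[i],
      name = tpl$name, x = xr + discs$x[i], y = yr + discs$y[i],
      z = zz + z_anchor, charge = tpl$charge, tail = tpl$tail,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}
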
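# Integer lipid allocation: from free leaflet area, area per lipid (APL) and
# ratio weights to exact per-type integer counts, plus the reference counting
# rules used in the accuracy comparison.

#' Ideal (real-valued) lipid count of a leaflet
#'
#' The unconstrained count A_free / APL, kept as a real number. This is the
#' yardstick against which integer builds are scored.
#'
#' @param a_free free leaflet area, nm^2 (>= 0)
#' @param apl area per lipid, nm^2 (> 0)
#' @return real count
#' @export
ideal_count <- function(a_free, apl) {
  if (any(apl <= 0)) stop_cg("invalid_parameter", "apl must be > 0")
  if (any(a_free < 0)) stop_cg("invalid_parameter", "a_free must be >= 0")
  a_free / apl
}

#' Maximum integer lipid count of a leaflet
#'
#' A_free / APL rounded to the nearest integer (half away from zero). The
#' result is always within 0.5 of the ideal count, so the relative deviation
#' falls below 1% as soon as the ideal count reaches 50 lipids.
#'
#' @inheritParams ideal_count
#' @return integer count
#' @export
max_count <- function(a_free, apl) {
  as.integer(round_half_away(ideal_count(a_free, apl)))
}

#' Row-times-column reference count
#'
#' The counting rule of the widely used grid-based bilayer setup tool
#' (insane): lipids are laid on a 2D grid whose row and column counts are
#' each rounded independently, `round(x/APL) * round(y/APL)`, implemented
#' here exactly as that formula is printed. Note the formula divides a side
#' length by an area; it is reproduced verbatim as the comparison reference,
#' not endorsed dimensionally.
#'
#' @param x,y membrane side lengths, nm (> 0)
#' @param apl area per lipid, nm^2 (> 0)
#' @return integer count
#' @export
insane_count <- function(x, y, apl) {
  if (any(apl <= 0) || any(x <= 0) || any(y <= 0))
    stop_cg("invalid_parameter", "x, y and apl must be > 0")
  as.integer(round_half_away(x / apl) * round_half_away(y / apl))
}

norm_shares <- function(weights, n_max) {
  if (length(weights) == 0) stop_cg("invalid_parameter", "empty weight vector")
  w <- as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop_cg("invalid_parameter", "weights must be positive and finite")
  w / sum(w) * n_max
}

#' Floor allocation of lipid counts across types
#'
#' Each type receives `floor(w_i / sum(w) * n_max)` lipids; the sum of these
#' floors is the minimum allowed leaflet count.
#'
#' @param weights named positive ratio weights, one per lipid type, in
#'   declaration order
#' @param n_max total integer lipid count of the leaflet
#' @return list with `counts` (named integer vector) and `n_min`
#' @export
floor_allocation <- function(weights, n_max) {
  if (length(weights) == 0 && n_max > 0)
    stop_cg("invalid_parameter", "no lipid types given for a non-empty leaflet")
  if (length(weights) == 0) return(list(counts = integer(0), n_min = 0L))
  shares <- norm_shares(weights, n_max)
  counts <- as.integer(floor_snap(shares))
  names(counts) <- names(weights)
  list(counts = counts, n_min = sum(counts))
}

#' Fill a floor allocation up to the leaflet total
#'
#' Starting from the floor counts, lipids are added one at a time to the most
#' underrepresented type relative to its requested share: the type maximizing
#' the relative deficit `(share_i - count_i) / share_i`. Ties go to the
#' earliest-declared type. The alternative `priority = "absolute"` scheme
#' ranks by the raw shortfall `share_i - count_i` instead.
#'
#' @param counts integer counts from [floor_allocation()]
#' @param weights the same ratio weights
#' @param n_max target total
#' @param priority `"relative"` (default) or `"absolute"` deficit ranking
#' @return named integer counts summing to `n_max`
#' @export
fill_to_max <- function(counts, weights, n_max,
                        priority = c("relative", "absolute")) {
  priority <- match.arg(priority)
  stopifnot(length(counts) == length(weights), sum(counts) <= n_max)
  shares <- norm_shares(weights, n_max)
  counts <- as.numeric(counts)
  while (sum(counts) < n_max) {
    d <- if (priority == "relative") (shares - counts) / shares
         else shares - counts
    i <- which.max(d)  # which.max returns the first maximum: declaration order
    counts[i] <- counts[i] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- names(weights)
  counts
}

#' Plan a leaflet: area + APL + ratios to integer counts per type
#'
#' @param a_free free leaflet area, nm^2
#' @param apl area per lipid, nm^2
#' @param composition named positive ratio weights in declaration order
#' @inheritParams fill_to_max
#' @return list of class `leaflet_plan`: `counts`, `n_min`, `n_max`, `a_free`
#' @export
plan_leaflet <- function(a_free, apl, composition,
                         priority = c("relative", "absolute")) {
  n_max <- max_count(a_free, apl)
  fl <- floor_allocation(composition, n_max)
  counts <- fill_to_max(fl$counts, composition, n_max, priority = match.arg(priority))
  structure(list(counts = counts, n_min = fl$n_min, n_max = n_max,
                 a_free = a_free),
            class = "leaflet_plan")
}

#' Lipid-count accuracy sweep over square membrane patches
#'
#' For square patches with side lengths from `x_min` to `x_max` in steps of
#' `step`, computes per-leaflet counts by the nearest-integer area rule
#' ([max_count()]) and by the row-times-column reference rule
#' ([insane_count()]), and their deviations from the ideal real count. When
#' the two leaflet APLs differ, the interleaflet ratio deviation
#' `(N_upper,built : N_lower,built) / (N_upper,ideal : N_lower,ideal)` is
#' reported per rule as well.
#'
#' @param x_min,x_max,step sweep bounds and increment, nm
#' @param apl_upper,apl_lower per-leaflet APL, nm^2
#' @return data.frame with columns side, n_ideal, n_area, n_insane, dev_area,
#'   dev_insane, ratio_dev_area, ratio_dev_insane (count columns refer to the
#'   upper leaflet; deviations are built/ideal ratios)
#' @export
accuracy_sweep <- function(x_min = 4, x_max = 51, step = 0.05,
                           apl_upper = 0.6, apl_lower = apl_upper) {
  if (step <= 0 || x_max < x_min)
    stop_cg("invalid_parameter", "invalid sweep range")
  side <- seq(x_min, x_max, by = step)
  a <- side^2
  n_ideal_u <- ideal_count(a, apl_upper)
  n_ideal_l <- ideal_count(a, apl_lower)
  n_area_u <- round_half_away(n_ideal_u)
  n_area_l <- round_half_away(n_ideal_l)
  n_ins_u <- round_half_away(side / apl_upper)^2
  n_ins_l <- round_half_away(side / apl_lower)^2
  out <- data.frame(
    side = side,
    n_ideal = n_ideal_u,
    n_area = n_area_u,
    n_insane = n_ins_u,
    dev_area = n_area_u / n_ideal_u,
    dev_insane = n_ins_u / n_ideal_u
  )
  if (!isTRUE(all.equal(apl_upper, apl_lower))) {
    ratio_ideal <- n_ideal_u / n_ideal_l
    out$ratio_dev_area <- (n_area_u / n_area_l) / ratio_ideal
    out$ratio_dev_insane <- (n_ins_u / n_ins_l) / ratio_ideal
  } else {
    out$ratio_dev_area <- 1
    out$ratio_dev_insane <- 1
  }
  out
}
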
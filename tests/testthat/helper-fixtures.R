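# shared fixtures, generated once per test run

.fx_cache <- new.env()

fixture_paths <- function() {
  if (is.null(.fx_cache$paths)) {
    d <- file.path(tempdir(), "cgbuildr-fixtures")
    .fx_cache$paths <- make_fixtures(d, seed = 7L)
  }
  .fx_cache$paths
}

fx_libs <- function() {
  if (is.null(.fx_cache$lib)) .fx_cache$lib <- fixture_library()
  list(.fx_cache$lib)
}

fx_type <- function(name) resolve_name(name, fx_libs())

square_region <- function(side, holes = list()) {
  leaflet_region(rect_polygon(0, side, 0, side), holes)
}

# independent overlap oracle: plain double loop over pairs
overlap_bruteforce <- function(discs) {
  tot <- 0
  n <- nrow(discs)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((discs$x[i] - discs$x[j])^2 + (discs$y[i] - discs$y[j])^2)
    tot <- tot + max(0, discs$r[i] + discs$r[j] - d)
  }
  tot
}

# independent union-of-circles area oracle by Monte Carlo on exact circles
circle_union_area_mc <- function(centers, radii, n = 2e5, seed = 99) {
  set.seed(seed)
  x0 <- min(centers[, 1] - radii); x1 <- max(centers[, 1] + radii)
  y0 <- min(centers[, 2] - radii); y1 <- max(centers[, 2] + radii)
  px <- stats::runif(n, x0, x1); py <- stats::runif(n, y0, y1)
  hit <- rep(FALSE, n)
  for (k in seq_len(nrow(centers)))
    hit <- hit | ((px - centers[k, 1])^2 + (py - centers[k, 2])^2 <= radii[k]^2)
  mean(hit) * (x1 - x0) * (y1 - y0)
}
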
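test_that("free area subtracts hole unions, not hole sums", {
  expect_equal(free_area(square_region(6)), 36)
  expect_equal(free_area(square_region(10, list(rect_polygon(0, 2, 0, 2)))), 96,
               tolerance = 1e-6)
  # two 2x2 pores offset by 1 nm: union = 4 + 4 - 2 = 6 (inclusion-exclusion)
  r <- square_region(10, list(rect_polygon(0, 2, 0, 2), rect_polygon(1, 3, 0, 2)))
  expect_equal(free_area(r), 94, tolerance = 1e-4)
  # hole clipped to the boundary only counts its inside part
  r2 <- square_region(10, list(rect_polygon(-1, 1, 0, 2)))
  expect_equal(free_area(r2), 98, tolerance = 1e-4)
  expect_warning(a0 <- free_area(square_region(2, list(rect_polygon(-1, 3, -1, 3)))))
  expect_equal(a0, 0)
})

test_that("a single-bead footprint removes the bead disc area within 1%", {
  holes <- protein_footprint(data.frame(x = 5, y = 5, z = 5, radius = 0.3), 4, 6)
  expect_length(holes, 1)
  a <- free_area(square_region(10, holes))
  expect_equal(100 - a, pi * 0.3^2, tolerance = 0.01)
})

test_that("footprints are leaflet-selective in z", {
  beads <- data.frame(x = 5, y = 5, z = c(2, 5, 8), radius = 0.3)
  expect_length(protein_footprint(beads, 4, 6), 1)   # only the z = 5 bead
  expect_length(protein_footprint(beads, 11, 12), 0)
})

test_that("an hourglass bead stack gives the two leaflets different free areas", {
  b <- cgbuildr:::fixture_protein_beads("hourglass", seed = 3)
  b$x <- b$x + 5; b$y <- b$y + 5
  prot <- data.frame(x = b$x, y = b$y, z = b$z, radius = 0.3)
  a_up <- free_area(square_region(10, protein_footprint(prot, 5, 6.3)))
  a_lo <- free_area(square_region(10, protein_footprint(prot, 3.7, 5)))
  expect_gt(abs(a_up - a_lo), 0.5)
  # cross-check one footprint against an independent circle-union oracle
  hit <- prot[(prot$z + prot$radius) > 5 & (prot$z - prot$radius) < 6.3, ]
  mc <- circle_union_area_mc(as.matrix(hit[, c("x", "y")]), hit$radius)
  expect_equal(100 - a_up, mc, tolerance = 0.03)
})

test_that("identical lipids go on a grid with centers at least a pitch apart", {
  ty <- list(L = lipid_type("L", bead_frame("B", "L", 0, 0, 0, 0), radius = 0.5))
  plan <- structure(list(counts = c(L = 4L)), class = "leaflet_plan")
  d <- initial_placement(plan, square_region(4), ty, seed = 5)
  expect_equal(nrow(d), 4)
  dm <- as.matrix(dist(d[, c("x", "y")]))
  expect_true(all(dm[upper.tri(dm)] >= 1 - 1e-9))  # pitch = 2 r = 1
  expect_true(all(points_in_region(as.matrix(d[, c("x", "y")]), square_region(4))))

  empty <- initial_placement(structure(list(counts = integer(0)),
                                       class = "leaflet_plan"),
                             square_region(4), ty, seed = 5)
  expect_equal(nrow(empty), 0)
})

test_that("large/small mixtures place every requested lipid inside the region", {
  ty <- list(BIG = lipid_type("BIG", bead_frame("B", "B", 0, 0, 0, 0), radius = 0.5),
             SML = lipid_type("SML", bead_frame("S", "S", 0, 0, 0, 0), radius = 0.25))
  plan <- structure(list(counts = c(BIG = 4L, SML = 12L)), class = "leaflet_plan")
  reg <- square_region(6)
  d <- initial_placement(plan, reg, ty, seed = 8)
  expect_equal(table(d$type)[["BIG"]], 4)
  expect_equal(table(d$type)[["SML"]], 12)
  expect_true(all(points_in_region(as.matrix(d[, c("x", "y")]), reg)))
})

test_that("two overlapping discs separate symmetrically", {
  d <- new_d <- data.frame(type = "L", x = c(5, 5.4), y = c(5, 5), r = 0.5)
  rx <- relax(d, square_region(10), seed = 1)
  fin <- rx$discs
  sep <- abs(fin$x[2] - fin$x[1])
  expect_gte(sep, 1 - 0.05)
  expect_equal(fin$y, c(5, 5), tolerance = 1e-9)           # push along the axis
  expect_equal(mean(fin$x), 5.2, tolerance = 1e-9)         # symmetric moves
  expect_lt(total_overlap(fin), total_overlap(d))
})

test_that("a lone disc is already converged", {
  d <- data.frame(type = "L", x = 3, y = 3, r = 0.5)
  rx <- relax(d, square_region(10), seed = 1)
  expect_true(rx$converged)
  expect_equal(rx$discs$x, 3)
  expect_equal(rx$discs$y, 3)
})

test_that("dense packings lose overlap and stay contained", {
  set.seed(21)
  reg <- square_region(10)
  n <- 100
  d <- data.frame(type = "L", x = runif(n, 0.6, 9.4), y = runif(n, 0.6, 9.4),
                  r = 0.53)  # ~90% packing density
  e0 <- total_overlap(d)
  rx <- relax(d, reg, seed = 4)
  expect_lt(total_overlap(rx$discs), e0)
  expect_equal(total_overlap(rx$discs), overlap_bruteforce(rx$discs),
               tolerance = 1e-9)
  expect_true(all(points_in_region(as.matrix(rx$discs[, c("x", "y")]), reg)))
  expect_true(all(diff(rx$overlap_trace) <= 1e-9))
})

test_that("relaxation conserves discs and is deterministic under a seed", {
  ty <- list(BIG = lipid_type("BIG", bead_frame("B", "B", 0, 0, 0, 0), radius = 0.4),
             SML = lipid_type("SML", bead_frame("S", "S", 0, 0, 0, 0), radius = 0.2))
  plan <- structure(list(counts = c(BIG = 20L, SML = 30L)), class = "leaflet_plan")
  reg <- square_region(8, list(rect_polygon(3, 5, 3, 5)))
  d <- initial_placement(plan, reg, ty, seed = 13)
  r1 <- relax(d, reg, seed = 14)
  r2 <- relax(d, reg, seed = 14)
  expect_identical(r1$discs, r2$discs)
  expect_identical(r1$discs$type, d$type)
  expect_identical(r1$discs$r, d$r)
})

test_that("a converged homogeneous leaflet realizes the requested APL", {
  apl <- 0.6; side <- 6
  plan <- plan_leaflet(side^2, apl, c(LLIP = 1))
  ty <- list(LLIP = fx_type("LLIP"))
  reg <- square_region(side)
  rx <- relax(initial_placement(plan, reg, ty, seed = 3), reg, seed = 3)
  realized <- side^2 / nrow(rx$discs)
  n_ideal <- side^2 / apl
  expect_lte(abs(side^2 / realized - n_ideal), 0.5)
})

test_that("leaflet realization mirrors the lower leaflet and keeps charges", {
  ty <- list(CLIP = fx_type("CLIP"))
  d <- data.frame(type = "CLIP", x = 2, y = 2, r = 0.15)
  up <- realize_leaflet(d, ty, z_anchor = 7, side = "upper", seed = 1)
  lo <- realize_leaflet(d, ty, z_anchor = 3, side = "lower", seed = 1)
  expect_true(all(up$z <= 7 + 1e-9))
  expect_true(all(lo$z >= 3 - 1e-9))
  expect_equal(sum(up$charge), -1)
  expect_equal(nrow(up), 4)
  # mirrored z offsets match exactly
  expect_equal(up$z - 7, -(lo$z - 3), tolerance = 1e-12)
})
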
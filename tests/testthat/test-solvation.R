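w_spec <- function(molarity = 0)
  solvent_spec("W", data.frame(name = "W", resname = "W", x = 0, y = 0, z = 0,
                               charge = 0), molarity = molarity)

test_that("an empty box rasterizes to the full free volume", {
  g <- rasterize(cg_box(10, 10, 10), list(w_spec()))
  expect_equal(g$cell, 0.5)
  expect_equal(g$n_free, 8000)
  expect_equal(g$free_volume, 1000)
})

test_that("a hydrophobic slab removes its z-band from the free volume", {
  g <- rasterize(cg_box(10, 10, 10), list(w_spec()),
                 slabs = list(list(zlo = 4, zhi = 6, boundary = NULL)))
  expect_equal(g$free_volume, 800)
})

test_that("bead occupancy marks exactly the containing cells", {
  beads <- data.frame(x = c(0.1, 3.26, 9.99), y = c(0.1, 3.26, 9.99),
                      z = c(0.1, 3.26, 9.99))
  g <- rasterize(cg_box(10, 10, 10), list(w_spec()), beads = beads)
  expect_equal(g$n_free, 8000 - 3)
  # brute-force: a cell is occupied iff some bead falls inside it
  for (k in seq_len(nrow(beads))) {
    idx <- floor(c(beads$x[k], beads$y[k], beads$z[k]) / g$cell) + 1
    expect_false(g$free[idx[1], idx[2], idx[3]])
  }
})

test_that("solvent counts follow molarity and ratio modes", {
  expect_equal(solvent_counts(1000, list(w_spec(0.15))), c(W = 90L))
  a <- solvent_spec("A", w_spec()$beads, molarity = 1, mapping_factor = 4)
  b <- solvent_spec("B", w_spec()$beads, molarity = 1, mapping_factor = 1)
  tot <- solvent_counts(1000, list(a, b), ratio_mode = "beads")
  expect_equal(unname(tot["A"] - tot["B"]) <= 1, TRUE)
  expect_equal(sum(tot), as.integer(round(2 * 0.6022140857 * 1000)))
  # mapping mode on an exact total of 100
  a2 <- solvent_spec("A", w_spec()$beads, molarity = 100 / (0.6022140857 * 1000) / 2,
                     mapping_factor = 4)
  b2 <- solvent_spec("B", w_spec()$beads, molarity = a2$molarity, mapping_factor = 1)
  m <- solvent_counts(1000, list(a2, b2), ratio_mode = "mapping")
  expect_equal(unname(m), c(80L, 20L))
  expect_equal(solvent_counts(1000, list(a2, b2), ratio_mode = "beads"),
               c(A = 50L, B = 50L))
  expect_error(solvent_counts(-5, list(w_spec(1))), class = "invalid_parameter")
})

test_that("placement uses distinct free cells and books volume", {
  g <- rasterize(cg_box(10, 10, 10), list(w_spec()))
  pl <- place_solvent(g, c(W = 90L), seed = 2)
  expect_equal(nrow(pl$placements), 90)
  expect_equal(nrow(unique(pl$placements[, c("x", "y", "z")])), 90)
  expect_equal(pl$grid$free_volume, g$free_volume - 90 * g$cell^3)

  pl0 <- place_solvent(g, c(W = 0L), seed = 2)
  expect_equal(nrow(pl0$placements), 0)
  expect_equal(pl0$grid$n_free, g$n_free)

  expect_error(place_solvent(g, c(W = g$n_free + 1L), seed = 2),
               class = "solvation_infeasible")
})

test_that("realized counts recover the requested molarity within one molecule", {
  g <- rasterize(cg_box(8, 8, 8), list(w_spec()))
  for (mol in c(0.05, 0.15, 1, 10)) {
    cnt <- solvent_counts(g$free_volume, list(w_spec(mol)))
    expect_lte(abs(cnt / (0.6022140857 * g$free_volume) - mol),
               1 / (0.6022140857 * g$free_volume))
  }
})

test_that("solvent placement avoids the hydrophobic slab", {
  g <- rasterize(cg_box(10, 10, 10), list(w_spec()),
                 slabs = list(list(zlo = 4, zhi = 6, boundary = NULL)))
  pl <- place_solvent(g, c(W = 500L), seed = 9)
  expect_true(all(pl$placements$z < 4 | pl$placements$z > 6))
})

ion <- function(name, q) solvent_spec(name, data.frame(
  name = name, resname = name, x = 0, y = 0, z = 0, charge = q),
  role = if (q > 0) "positive-ion" else "negative-ion")

test_that("the three neutralization algorithms cancel the charge exactly", {
  na <- ion("NA", 1); cl <- ion("CL", -1)
  p <- neutralize(-5, na, cl, algorithm = "add")
  expect_equal(unname(p$add["NA"]), 5)
  expect_equal(sum(p$remove), 0)

  p0 <- neutralize(0, na, cl, algorithm = "add")
  expect_equal(sum(p0$add) + sum(p0$remove), 0)

  pc <- neutralize(-5, na, cl, placed_counts = c(NA. = 0, CL = 10),
                   algorithm = "combined")
  expect_equal(unname(pc$add["NA"]), 3)   # odd remainder goes to addition
  expect_equal(unname(pc$remove["CL"]), 2)
})

test_that("neutralization reaches zero for all charges and valence pairings", {
  na <- ion("NA", 1); cl <- ion("CL", -1)
  ca <- ion("CA", 2); so4 <- ion("SO4", -2)
  pool <- c(20L, 20L)
  for (q in -10:10) {
    for (pair in list(list(na, cl), list(ca, cl), list(na, so4))) {
      pos <- pair[[1]]; neg <- pair[[2]]
      pc <- stats::setNames(pool, c(pos$name, neg$name))
      for (alg in c("add", "combined")) {
        p <- neutralize(q, pos, neg, placed_counts = pc, algorithm = alg)
        net <- q + p$add[pos$name] * pos$charge + p$add[neg$name] * neg$charge -
          p$remove[pos$name] * pos$charge - p$remove[neg$name] * neg$charge
        expect_equal(unname(net), 0)
      }
      # removal changes charge in co-ion valence steps; only exact cases pass
      v_co <- abs(if (q < 0) neg$charge else pos$charge)
      if (q == 0 || abs(q) %% v_co == 0) {
        p <- neutralize(q, pos, neg, placed_counts = pc, algorithm = "remove")
        net <- q - p$remove[pos$name] * pos$charge - p$remove[neg$name] * neg$charge
        expect_equal(unname(net), 0)
      } else {
        expect_error(neutralize(q, pos, neg, placed_counts = pc,
                                algorithm = "remove"),
                     class = "neutralization_infeasible")
      }
    }
  }
})

test_that("removal fails loudly when the co-ion pool is too small", {
  na <- ion("NA", 1); cl <- ion("CL", -1)
  expect_error(neutralize(4, na, cl, placed_counts = c(2L, 2L) |>
                            stats::setNames(c("NA", "CL")),
                          algorithm = "remove"),
               class = "neutralization_infeasible")
})
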
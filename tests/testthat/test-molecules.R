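test_that("fragment assembly joins anchors by translation and counts beads", {
  libs <- fx_libs()
  lip <- build_lipid("SHEAD", "GLYC", c("TL4", "TL4"), libs, name = "TEST")
  expect_equal(nrow(lip$beads), 10)   # 1 head + 1 linker + 2 x 4 tail beads
  # anchor coincidence: each tail's up-anchor lands on its linker tail anchor
  head <- resolve_name("SHEAD", libs); link <- resolve_name("GLYC", libs)
  tail <- resolve_name("TL4", libs)
  t_link <- head$anchors$down - link$anchors$up
  for (k in 1:2) {
    anchor_global <- link$anchors[[paste0("tail", k)]] + t_link
    first_tail_bead <- as.numeric(lip$beads[2 + (k - 1) * 4 + 1, c("x", "y", "z")])
    expect_equal(first_tail_bead,
                 anchor_global - tail$anchors$up + as.numeric(tail$beads[1, c("x", "y", "z")]),
                 tolerance = 1e-6)
  }
  expect_true(all(lip$beads$tail[3:10]))
})

test_that("assembly preserves fragment-internal geometry and adds charges", {
  libs <- fx_libs()
  lip <- build_lipid("PHEAD", "GLYC", c("TL4", "TL4"), libs)
  frag <- resolve_name("TL4", libs)
  built_tail <- lip$beads[4:7, c("x", "y", "z")]
  expect_equal(as.matrix(dist(built_tail)), as.matrix(dist(frag$beads[, c("x", "y", "z")])),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(lip$charge, 0)      # +1 - 1 head
  expect_equal(build_lipid("NHEAD", "MONO", "TL2", libs)$charge, -1)
})

test_that("too many tails for the linker is an assembly error", {
  expect_error(build_lipid("SHEAD", "GLYC", c("TL4", "TL4", "TL2"), fx_libs()),
               class = "assembly_error")
  expect_error(build_lipid("SHEAD", "MONO", c("TL2", "TL2"), fx_libs()),
               class = "assembly_error")
  expect_error(build_lipid("NOPE", "GLYC", "TL4", fx_libs()),
               class = "lookup_error")
})

test_that("imported molecules take charges from the linked topology", {
  fx <- fixture_paths()
  top <- parse_topology(fx$top)
  m <- import_molecule(fx$CLIP, topology = top, top_name = "CLIP")
  expect_equal(nrow(m$beads), 4)
  expect_equal(m$charge, -1)
  expect_equal(m$beads$charge, top$molecules$CLIP)

  expect_warning(m0 <- import_molecule(fx$SLIP), "charges set to 0")
  expect_equal(m0$charge, 0)

  expect_error(import_molecule(fx$SLIP, topology = top, top_name = "LLIP"),
               class = "import_error", regexp = "4 beads.*11 atoms")
})

test_that("library queries honor priority order and shadowing", {
  all <- query_library("*", fx_libs())
  expect_gt(nrow(all), 10)
  expect_equal(nrow(query_library("ZZZ*", fx_libs())), 0)

  lib_a <- lib_add(molecule_library("devA"),
                   lipid_type("DUP", bead_frame("A", "A", 0, 0, 0, 0)))
  lib_b <- lib_add(molecule_library("devB"),
                   lipid_type("DUP", rbind(bead_frame("B1", "B", 0, 0, 0, 0),
                                           bead_frame("B2", "B", 0.2, 0, 0, 0))))
  q <- query_library("DUP", list(lib_a, lib_b))
  expect_equal(q$library, c("devA", "devB"))
  expect_equal(q$priority, c(1L, 2L))
  expect_equal(nrow(resolve_name("DUP", list(lib_a, lib_b))$beads), 1)
  expect_equal(nrow(resolve_name("DUP", list(lib_b, lib_a))$beads), 2)
})

test_that("crafting writes a structure-only file that round-trips", {
  libs <- fx_libs()
  d <- withr::local_tempdir()
  p <- file.path(d, "lip.gro")
  craft(build_lipid("SHEAD", "GLYC", c("TL4", "TL4"), libs, name = "TEN"), p)
  g <- read_gro(p)
  expect_equal(nrow(g$atoms), 10)

  p2 <- file.path(d, "w.gro")
  craft("W", p2, libs)
  expect_equal(nrow(read_gro(p2)$atoms), 1)

  # craft -> import round-trip reproduces coordinates to 3 decimals
  expect_warning(m <- import_molecule(p), "charges")
  re <- file.path(d, "again.gro")
  craft(m, re)
  a1 <- read_gro(p)$atoms; a2 <- read_gro(re)$atoms
  expect_equal(a1$x - mean(a1$x), a2$x - mean(a2$x), tolerance = 2e-3)
  expect_equal(a1$z - mean(a1$z), a2$z - mean(a2$z), tolerance = 2e-3)
})

test_that("the library text format round-trips every fixture entry", {
  lib <- fixture_library()
  d <- withr::local_tempdir()
  p <- file.path(d, "lib.txt")
  write_fragment_library(lib, p)
  back <- parse_fragment_library(p)
  expect_setequal(names(back$entries), names(lib$entries))
  for (n in names(lib$entries)) {
    expect_equal(back$entries[[n]]$beads$charge, lib$entries[[n]]$beads$charge)
    expect_equal(back$entries[[n]]$beads$x, lib$entries[[n]]$beads$x,
                 tolerance = 1e-9)
  }
})
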
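test_that("a membrane-only build plans 60 lipids per leaflet at 36 nm2 / 0.6", {
  spec <- system_spec(cg_box(6, 6, 10),
                      membranes = list(membrane_spec(c(LLIP = 1), apl = 0.6)),
                      seed = 3L)
  sys <- build_system(spec)
  lg <- sys$ledger
  expect_equal(lg$name, c("LLIP", "LLIP"))
  expect_equal(lg$count, c(60L, 60L))
  expect_true(any(grepl("60 lipids", sys$log)))
  # upper and lower leaflets sit on opposite sides of the midplane
  expect_gt(max(sys$atoms$z), 6.9)
  expect_lt(min(sys$atoms$z), 3.1)
})

test_that("the molecules ledger bead total equals the GRO atom count", {
  fx <- fixture_paths()
  top <- parse_topology(fx$top)
  d <- withr::local_tempdir()
  out_gro <- file.path(d, "sys.gro"); out_top <- file.path(d, "sys.top")
  spec <- system_spec(
    cg_box(6, 6, 12),
    membranes = list(membrane_spec(c(LLIP = 4, CLIP = 1), apl = 0.6)),
    proteins = list(protein_spec(fx$cylinder, cx = 1, cy = 1, cz = 1)),
    solvation = solvation_spec(c(W = 8),
                               salt = list(pos = "NA", neg = "CL", molarity = 0.15)),
    flooding = list(flood_spec("SOLU", count = 10L)),
    output = list(gro = out_gro, top = out_top), seed = 5L)
  sys <- build_system(spec, topology = top)
  g <- read_gro(out_gro)
  beads_per <- vapply(top$molecules, length, integer(1))
  expect_equal(sum(sys$ledger$count * beads_per[sys$ledger$name]),
               nrow(g$atoms))
  # and the net charge is exactly zero after neutralization
  expect_equal(round(sum(sys$atoms$charge)), 0)
  expect_true(file.exists(out_top))
})

test_that("charged leaflets are neutralized by counterion addition", {
  spec <- system_spec(
    cg_box(5, 5, 10),
    membranes = list(membrane_spec(c(CLIP = 1), apl = 0.5)),
    solvation = solvation_spec(c(W = 8),
                               salt = list(pos = "NA", neg = "CL", molarity = 0)),
    seed = 11L)
  sys <- build_system(spec)
  n_lip <- sum(sys$ledger$count[sys$ledger$name == "CLIP"])
  expect_equal(sum(sys$ledger$count[sys$ledger$name == "NA"]), n_lip)
  expect_equal(round(sum(sys$atoms$charge)), 0)
})

test_that("protein footprints shrink the leaflet allocation", {
  fx <- fixture_paths()
  with_prot <- system_spec(
    cg_box(6, 6, 10),
    membranes = list(membrane_spec(c(LLIP = 1), apl = 0.6)),
    proteins = list(protein_spec(fx$cylinder, cx = 1, cy = 1)),
    seed = 2L)
  sys <- build_system(with_prot)
  n_with <- sys$ledger$count[sys$ledger$name == "LLIP"][1]
  expect_lt(n_with, 60)   # footprint area has been subtracted
  # the footprint area is roughly the cylinder cross-section
  a_lost <- (60 - n_with) * 0.6
  expect_gt(a_lost, 1)
})

test_that("the CLI builds from flags and reports failures", {
  d <- withr::local_tempdir()
  out_gro <- file.path(d, "cli.gro"); out_top <- file.path(d, "cli.top")
  st <- suppressMessages(cli_build(c(
    "--box", "5", "5", "5",
    "--solvation", "solvent:W:12",
    "--out-gro", out_gro, "--out-top", out_top, "--seed", "4")))
  expect_identical(st, 0L)
  expect_true(file.exists(out_gro))
  g <- read_gro(out_gro)
  expect_equal(nrow(g$atoms),
               as.integer(round(12 * 0.6022140857 * 125)))

  expect_identical(suppressMessages(cli_build(c("--box", "5", "5", "5"))), 1L)
  expect_identical(suppressMessages(cli_build(c("--frobnicate"))), 1L)
})

test_that("the CLI logs per-leaflet lipid counts for a membrane build", {
  d <- withr::local_tempdir()
  msgs <- capture_messages(
    st <- cli_build(c("--box", "6", "6", "10",
                      "--membrane", "lipid:LLIP:1 apl:0.6",
                      "--out-gro", file.path(d, "m.gro"), "--seed", "1")))
  expect_identical(st, 0L)
  expect_true(any(grepl("60 lipids", msgs)))
})

test_that("the fixtures subcommand writes the fixture set", {
  d <- withr::local_tempdir()
  st <- suppressMessages(cli_build(c("fixtures", file.path(d, "fx"), "3")))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(d, "fx", "topol.top")))
  expect_true(file.exists(file.path(d, "fx", "fragments.lib")))
})

test_that("config files drive the same build as flags", {
  d <- withr::local_tempdir()
  out1 <- file.path(d, "flag.gro"); out2 <- file.path(d, "cfg.gro")
  spec <- system_spec(cg_box(5, 5, 8),
                      membranes = list(membrane_spec(c(SLIP = 1), apl = 0.45)),
                      output = list(gro = out1), seed = 6L)
  build_system(spec)
  cfgp <- file.path(d, "c.yaml")
  spec2 <- spec; spec2$output$gro <- out2
  write_config(spec2, cfgp)
  st <- suppressMessages(cli_build(c("--config", cfgp)))
  expect_identical(st, 0L)
  expect_identical(readLines(out1)[-1], readLines(out2)[-1])
})
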
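minimal_spec <- function(...) {
  system_spec(cg_box(10, 10, 10),
              membranes = list(membrane_spec(c(LLIP = 1), apl = 0.6)), ...)
}

test_that("validation accepts a minimal spec and flags broken ones", {
  expect_length(validate_spec(minimal_spec()), 0)

  expect_error(cg_box(10, 10, 0), class = "invalid_parameter")
  bad_box <- minimal_spec()
  bad_box$box$z <- 0                      # corrupt after construction
  d <- validate_spec(bad_box)
  expect_length(d, 1)
  expect_equal(d[[1]]$level, "fatal")
  expect_match(d[[1]]$field, "box.z")

  stacked <- system_spec(cg_box(10, 10, 30), membranes = list(
    membrane_spec(c(LLIP = 1), zc = 10), membrane_spec(c(SLIP = 1), zc = 10)))
  d2 <- validate_spec(stacked)
  expect_true(any(vapply(d2, function(x)
    grepl("overlapping membranes", x$message), logical(1))))

  empty <- system_spec(cg_box(10, 10, 10))
  d3 <- validate_spec(empty)
  expect_true(any(vapply(d3, function(x)
    grepl("nothing to build", x$message), logical(1))))
})

test_that("the stage order is protein, membranes by z, flood, solvent, ions, write", {
  fx <- fixture_paths()
  spec <- system_spec(cg_box(10, 10, 10),
                      membranes = list(membrane_spec(c(LLIP = 1))),
                      proteins = list(protein_spec(fx$cylinder)),
                      solvation = solvation_spec(c(W = 10)))
  expect_equal(build_order(spec),
               c("protein:1", "membrane:1:upper", "membrane:1:lower",
                 "solvent", "ions", "write"))

  solv_only <- system_spec(cg_box(5, 5, 5), solvation = solvation_spec(c(W = 10)))
  expect_equal(build_order(solv_only), c("solvent", "ions", "write"))

  stacked <- system_spec(cg_box(10, 10, 30), membranes = list(
    membrane_spec(c(LLIP = 1), zc = 20), membrane_spec(c(SLIP = 1), zc = 8)))
  ord <- build_order(stacked)
  expect_equal(ord[1:2], c("membrane:2:upper", "membrane:2:lower"))
  expect_equal(ord[3:4], c("membrane:1:upper", "membrane:1:lower"))
})

test_that("specs round-trip through the flat config document", {
  fx <- fixture_paths()
  spec <- system_spec(
    cg_box(12, 8.5, 20),
    membranes = list(
      membrane_spec(c(LLIP = 5, SLIP = 3), apl = 0.55, zc = 6,
                    pores = list(rect_polygon(2, 4, 2, 4))),
      membrane_spec(c(SLIP = 1), apl = 0.62, zc = 14, thickness = 3.5,
                    composition_lower = c(LLIP = 2, CLIP = 1),
                    apl_lower = 0.48)),
    proteins = list(protein_spec(fx$cylinder, cx = 1.5, cz = -2, rotz = 45)),
    solvation = solvation_spec(c(W = 40, SW = 10),
                               salt = list(pos = "NA", neg = "CL", molarity = 0.15),
                               neutralization = "combined", ratio_mode = "mapping"),
    flooding = list(flood_spec("SOLU", count = 25L)),
    output = list(gro = "sys.gro", top = "sys.top"),
    seed = 77L)
  cfg <- spec_to_config(spec)
  back <- config_to_spec(cfg)
  expect_equal(back, spec, tolerance = 1e-9)

  # and through an actual YAML file
  d <- withr::local_tempdir()
  p <- file.path(d, "spec.yaml")
  write_config(spec, p)
  expect_equal(read_config(p), spec, tolerance = 1e-9)
})

test_that("circular pores parse from the cx,cy,r shorthand", {
  m <- parse_membrane_arg("lipid:LLIP:1 apl:0.6 pore:5,5,1.5")
  expect_length(m$pores, 1)
  expect_equal(polygon_area(m$pores[[1]]), pi * 1.5^2, tolerance = 0.01)
  expect_error(parse_membrane_arg("lipid:LLIP:1 nonsense:1"),
               class = "parse_error")
})

test_that("stage seeds are stable and distinct per stage", {
  expect_identical(child_seed(42L, "solvent"), child_seed(42L, "solvent"))
  expect_false(child_seed(42L, "solvent") == child_seed(42L, "ions"))
  expect_false(child_seed(42L, "solvent") == child_seed(43L, "solvent"))
  expect_true(child_seed(2147483646L, "membrane:1:upper:relax") >= 0)
})

test_that("identical spec and seed build byte-identical coordinates", {
  d <- withr::local_tempdir()
  run <- function(tag) {
    out <- file.path(d, paste0(tag, ".gro"))
    spec <- system_spec(cg_box(5, 5, 8),
                        membranes = list(membrane_spec(c(LLIP = 3, SLIP = 1))),
                        solvation = solvation_spec(c(W = 6)),
                        output = list(gro = out), seed = 9L)
    build_system(spec)
    readLines(out)
  }
  expect_identical(run("a"), run("b"))
})
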
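test_that("guard-cell pair area follows the half-ellipse geometry", {
  # hand evaluation of (pi/2) * l * w
  expect_equal(guard_cell_pair_area(20e-6, 7.2e-6), 2.261946710584651e-10,
               tolerance = 1e-12)
  # homogeneity of degree 2
  l <- runif(20, 5e-6, 40e-6)
  w <- runif(20, 2e-6, 15e-6)
  expect_equal(guard_cell_pair_area(2 * l, 2 * w),
               4 * guard_cell_pair_area(l, w))
  expect_error(guard_cell_pair_area(0, 7e-6), "positive")
  expect_error(guard_cell_pair_area(20e-6, -1e-6), "positive")
})

test_that("maximum pore area is the f_lw fraction of the pore-length circle", {
  expect_equal(max_pore_area(10e-6, 1), 7.853981633974483e-11,
               tolerance = 1e-12)
  expect_equal(max_pore_area(10e-6, 0.4), 3.141592653589793e-11,
               tolerance = 1e-12)
  # vanishes continuously with pore length
  expect_lt(max_pore_area(1e-12, 0.5), 1e-24)
  expect_error(max_pore_area(10e-6, 0.3), "0.4")
  expect_error(max_pore_area(10e-6, 1.2), "0.4")
  expect_error(max_pore_area(0, 0.5), "positive")
})

test_that("pore depth recovers the guard-cell width (round trip)", {
  # w_gc = r_wl * l_gc makes the implied depth equal w_gc exactly
  set.seed(11)
  for (i in 1:25) {
    r_wl <- runif(1, 0.2, 0.6)
    l <- runif(1, 5e-6, 60e-6)
    w <- r_wl * l
    expect_equal(pore_depth_from_agc(guard_cell_pair_area(l, w), r_wl), w,
                 tolerance = 1e-12)
  }
  # square-root homogeneity: quadrupling area doubles depth
  a <- 2.262e-10
  expect_equal(pore_depth_from_agc(4 * a, 0.36),
               2 * pore_depth_from_agc(a, 0.36), tolerance = 1e-12)
  expect_error(pore_depth_from_agc(0, 0.36), "positive")
})

test_that("epidermal cover is the density-size product and flags impossible covers", {
  expect_equal(f_gc(1e8, 1e-10), 0.01)
  expect_equal(f_gc(0, 1e-10), 0)
  expect_warning(f_gc(1e9, 2e-9), "f_gc > 1")
  # area-preserving trajectory a_gc = b_s / D leaves cover constant
  b_s <- 0.07
  d <- 10^runif(100, 7, 9)
  expect_equal(f_gc(d, b_s / d), rep(b_s, 100), tolerance = 1e-12)
})

test_that("anatomical maximum conductance matches the frozen diffusion fixture and is linear in density", {
  # independent hand evaluation of the diffusion quotient, frozen
  expect_equal(g_smax(2e8, 2.7e-11, 7.2e-6), 0.464902763746639,
               tolerance = 1e-10)
  expect_equal(g_smax(0, 2.7e-11, 7.2e-6), 0)
  set.seed(21)
  for (i in 1:20) {
    d <- 10^runif(1, 7, 9)
    amax <- 10^runif(1, -12, -10)
    dp <- runif(1, 2e-6, 2e-5)
    c_mult <- runif(1, 0.1, 10)
    expect_equal(g_smax(c_mult * d, amax, dp), c_mult * g_smax(d, amax, dp),
                 tolerance = 1e-12)
  }
  expect_error(g_smax(1e8, -1e-11, 7e-6), "positive")
})

test_that("ingest averages within and across sources and applies the compilation rules", {
  tr <- suppressMessages(suppressWarnings(ingest_traits(
    raw_rows(), density_unit = "per_mm2", length_unit = "um",
    area_unit = "um2")))

  # grand mean across two sources: (100 + 200)/2 mm^-2 in SI
  hypo <- tr[tr$species == "Hypo una", ]
  expect_equal(hypo$d_s, 1.5e8)
  expect_false(hypo$amphistomatous)
  expect_equal(hypo$n_sources, 2L)

  # adaxial:abaxial ratio 0.2 > 0.05: amphistomatous, mean of surfaces
  amphi <- tr[tr$species == "Amphi duo", ]
  expect_true(amphi$amphistomatous)
  expect_equal(amphi$d_s, 6e7)

  # a_gc computed from guard-cell dimensions when not reported
  eqn6 <- tr[tr$species == "Eqn six", ]
  expect_equal(eqn6$a_gc, (pi / 2) * 20e-6 * 7.2e-6, tolerance = 1e-12)

  # missing density row rejected with a reason
  rej <- attr(tr, "rejected")
  expect_equal(rej$species, "Badrow tres")
  expect_match(rej$reason, "density")
  expect_false("Badrow tres" %in% tr$species)
})

test_that("ingest drops unrealistic a_max (>= a_gc) with a warning naming the species", {
  expect_warning(
    tr <- suppressMessages(ingest_traits(raw_rows(), density_unit = "per_mm2",
                                         length_unit = "um",
                                         area_unit = "um2")),
    "Bigpore quat"
  )
  big <- tr[tr$species == "Bigpore quat", ]
  expect_true(is.na(big$a_max))       # value excluded
  expect_true(big$species %in% tr$species)  # record retained
  expect_equal(attr(tr, "dropped_amax"), "Bigpore quat")
})

test_that("ingest is deterministic under row reordering", {
  raw <- raw_rows()
  t1 <- suppressMessages(suppressWarnings(ingest_traits(
    raw, density_unit = "per_mm2", length_unit = "um", area_unit = "um2")))
  t2 <- suppressMessages(suppressWarnings(ingest_traits(
    raw[rev(seq_len(nrow(raw))), ], density_unit = "per_mm2",
    length_unit = "um", area_unit = "um2")))
  attr(t1, "rejected") <- attr(t2, "rejected") <- NULL
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("unknown morphology classes fall back to mid-range f_lw with a warning", {
  expect_warning(v <- flw_for_class(c("kidney_shaped", "mystery")),
                 "mystery")
  expect_equal(v, c(0.5, 0.5))
  expect_equal(flw_for_class("circular_pore"), 1.0)
  expect_equal(flw_for_class("elliptical_pore"), 0.4)
})
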
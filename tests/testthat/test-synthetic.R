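test_that("zero-shift wells reproduce the baseline distribution", {
  panel <- tiny_panel()
  tab <- generate_well_events(panel, effect_signature(), 20000, seed = 11)
  sc <- arcsinh_scale(tab)
  med <- apply(sc$values[, panel$markers], 2, median)
  # Monte-Carlo error of a median at n = 20000, spread <= 0.5: ~0.004
  expect_true(all(abs(med - panel$baseline_location) < 0.02))
  expect_equal(sum(tab$values[, "truth_island"]), 0)
})

test_that("signature shifts move scaled medians by the stated delta", {
  panel <- tiny_panel()
  sig <- effect_signature(c(mA = 0.8, mC = -0.5))
  tab <- arcsinh_scale(generate_well_events(panel, sig, 20000, seed = 12))
  med <- apply(tab$values[, panel$markers], 2, median)
  expect_equal(unname(med["mA"] - panel$baseline_location["mA"]), 0.8,
               tolerance = 0.03)
  expect_equal(unname(med["mC"] - panel$baseline_location["mC"]), -0.5,
               tolerance = 0.03)
  expect_equal(unname(med["mB"] - panel$baseline_location["mB"]), 0,
               tolerance = 0.03)
})

test_that("island fraction is recovered within its binomial 99% CI", {
  panel <- tiny_panel()
  sig <- effect_signature(island_fraction = 0.03,
                          island_shift = c(mA = 2.5))
  n <- 100000
  tab <- generate_well_events(panel, sig, n, seed = 13)
  k <- sum(tab$values[, "truth_island"])
  ci <- qbinom(c(0.005, 0.995), n, 0.03)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("generation is bit-identical under a fixed seed and leaves RNG state alone", {
  panel <- tiny_panel()
  set.seed(99); before <- .Random.seed
  sig <- effect_signature(c(mA = 1), island_fraction = 0.02,
                          island_shift = c(mA = 3))
  a <- generate_well_events(panel, sig, 500, seed = 5)
  expect_identical(.Random.seed, before)
  b <- generate_well_events(panel, sig, 500, seed = 5)
  expect_identical(a, b)
})

test_that("generator rejects invalid signatures and sizes", {
  panel <- tiny_panel()
  expect_error(generate_well_events(panel, effect_signature(c(nope = 1)), 10),
               "not in panel")
  expect_error(generate_well_events(panel, effect_signature(), 0), "n_cells")
  expect_error(effect_signature(island_fraction = 1), "island_fraction")
  expect_error(effect_signature(c(mA = Inf)), "finite")
})

test_that("raw intensities are finite and floored", {
  panel <- marker_panel(markers = "low", cofactors = 100,
                        baseline_location = 0.05, baseline_spread = 1)
  tab <- generate_well_events(panel, effect_signature(), 5000, seed = 3)
  expect_true(all(is.finite(tab$values)))
  expect_true(all(tab$values[, "low"] >= 0))
})

test_that("pooling conserves counts and carries distinct ground-truth labels", {
  panel <- tiny_panel()
  plate <- rocaglate_plate_map()
  wells <- lapply(seq_len(nrow(plate)), function(w) {
    generate_well_events(panel, effect_signature(), 50, seed = w)
  })
  pool <- generate_barcoded_pool(plate, barcode_scheme(), wells, seed = 2)
  expect_equal(n_events(pool), 50 * nrow(plate))
  expect_setequal(unique(pool$annotations$well_id), plate$well_id)
  expect_error(
    generate_barcoded_pool(plate, barcode_scheme(), wells[-1], seed = 2),
    "one event table per plate well")
  big <- plate[rep(1, 49), ]; big$well_id <- sprintf("X%02d", 1:49)
  expect_error(
    generate_barcoded_pool(big, barcode_scheme(),
                           rep(wells[1], 49), seed = 2),
    "capacity")
})

test_that("zero level spread puts every event exactly at its level centers", {
  panel <- tiny_panel()
  scheme <- barcode_scheme(level_spread = 0)
  plate <- rocaglate_plate_map()[1:4, ]
  wells <- lapply(1:4, function(w) {
    generate_well_events(panel, effect_signature(), 20, seed = w)
  })
  pool <- generate_barcoded_pool(plate, scheme, wells, seed = 1)
  for (w in 1:4) {
    lev <- scheme$well_assignment[w, ]
    idx <- pool$annotations$well_id == plate$well_id[w]
    expect_equal(
      unique(asinh(pool$values[idx, scheme$dyes[1]] /
                     scheme$dye_cofactors[1])),
      scheme$level_centers[[1]][lev$level_1], tolerance = 1e-12)
  }
})

test_that("identity spillover leaves dye channels independent of functional channels", {
  panel <- tiny_panel()
  plate <- rocaglate_plate_map()[1:2, ]
  wells <- lapply(1:2, function(w) {
    generate_well_events(panel, effect_signature(), 20000, seed = w)
  })
  pool <- generate_barcoded_pool(plate, barcode_scheme(), wells, seed = 9)
  for (w in plate$well_id) {
    idx <- pool$annotations$well_id == w
    cors <- cor(pool$values[idx, "Pacific_Blue"],
                pool$values[idx, c("mA", "mB", "mC")])
    expect_true(all(abs(cors) < 0.03))
  }
})

test_that("dose-response wells hit the 4PL response at the anchor doses", {
  panel <- tiny_panel()
  truth <- list(b = -1.5, c = 2, d = 80, e = 0.3)
  tabs <- generate_dose_response(panel, truth, n_cells = 20000, seed = 21,
                                 marker = "mA")
  frac0 <- mean(tabs[["0"]]$values[, "truth_positive"])
  expect_equal(100 * frac0, truth$c, tolerance = 3 * sqrt(2 * 80 / 20000) * 100)
  tabs_e <- generate_dose_response(panel, truth, doses = truth$e,
                                   n_cells = 20000, seed = 22, marker = "mA")
  frac_e <- mean(tabs_e[[1]]$values[, "truth_positive"])
  expect_equal(100 * frac_e, (truth$c + truth$d) / 2, tolerance = 2)
  expect_error(generate_dose_response(panel, truth, doses = -1, marker = "mA"),
               "nonnegative")
})
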
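test_that("fold change is zero against itself, recovers shifts, and is antisymmetric", {
  panel <- tiny_panel()
  veh <- arcsinh_scale(generate_well_events(panel, effect_signature(), 5000,
                                            seed = 41))
  expect_identical(unname(fold_change(veh, veh, panel$markers)),
                   rep(0, 3))
  treated <- arcsinh_scale(generate_well_events(
    panel, effect_signature(c(mB = 0.5)), 5000, seed = 42))
  d <- fold_change(treated, veh, panel$markers)
  expect_equal(unname(d["mB"]), 0.5, tolerance = 0.05)
  expect_equal(fold_change(veh, treated, panel$markers), -d)
  expect_error(fold_change(subset_events(veh, integer(0)), veh,
                           panel$markers), "nonempty")
})

test_that("the hit threshold is vehicle median + 3 x interpolated IQR", {
  # vehicle deltas {0.00, 0.01, 0.02}: median 0.01, IQR 0.01 -> 0.04
  vdelta <- matrix(c(0.00, 0.01, 0.02), ncol = 1,
                   dimnames = list(paste0("v", 1:3), "m"))
  delta <- matrix(c(0.03, 0.05), ncol = 1,
                  dimnames = list(c("c1", "c2"), "m"))
  res <- select_hits(delta, vdelta)
  expect_equal(res$threshold, 0.04)
  expect_identical(unname(res$hits), c(FALSE, TRUE))
  # all below threshold -> zero hits
  low <- matrix(c(0.01, 0.02), ncol = 1, dimnames = list(c("c1", "c2"), "m"))
  expect_false(any(select_hits(low, vdelta)$hits))
  expect_error(select_hits(delta, vdelta[0, , drop = FALSE]), "no vehicle")
  expect_warning(select_hits(delta, vdelta[1, , drop = FALSE]), "single")
})

test_that("per-readout mode thresholds each marker separately", {
  vdelta <- cbind(m1 = c(0, 0.01, 0.02), m2 = c(0, 0.1, 0.2))
  delta <- rbind(c1 = c(m1 = 0.05, m2 = 0.05))
  res <- select_hits(delta, vdelta, mode = "per_readout")
  expect_equal(unname(res$threshold), c(0.04, 0.4))
  expect_true(res$hit_matrix["c1", "m1"])
  expect_false(res$hit_matrix["c1", "m2"])
})

test_that("a held-out vehicle is not a hit against its peers", {
  panel <- marker_panel()
  markers <- panel$markers
  vehicles <- lapply(1:6, function(i) {
    arcsinh_scale(generate_well_events(panel, effect_signature(), 800,
                                       seed = 100 + i))
  })
  deltas <- t(vapply(2:6, function(i) {
    fold_change(vehicles[[i]], vehicles[[1]], markers)
  }, setNames(numeric(length(markers)), markers)))
  for (i in seq_len(nrow(deltas))) {
    res <- select_hits(deltas[i, , drop = FALSE],
                       deltas[-i, , drop = FALSE])
    expect_false(any(res$hits))
  }
})

test_that("chemotype composition reports library and hit-set percentages", {
  chem <- c(rep("rocaglate", 19), rep("other", 581))
  hits <- c(rep(TRUE, 9), rep(FALSE, 10),   # 9 of 19 rocaglates bioactive
            rep(TRUE, 56), rep(FALSE, 525)) # 65 hits total
  comp <- chemotype_composition(chem, hits)
  roc <- comp[comp$chemotype == "rocaglate", ]
  expect_equal(roc$pct_library, 3.2)   # 19 / 600
  expect_equal(roc$pct_hits, 13.8)     # 9 / 65
  expect_equal(sum(comp$n_hits), 65)
  one <- chemotype_composition(rep("solo", 4), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(one$pct_library, 100)
  expect_equal(one$pct_hits, 100)
  none <- chemotype_composition(chem, rep(FALSE, 600))
  expect_true(is.na(none$pct_hits[1]))
})

test_that("percent positive gates against explicit and vehicle-referenced cutoffs", {
  panel <- tiny_panel()
  veh <- arcsinh_scale(generate_well_events(panel, effect_signature(), 20000,
                                            seed = 51))
  # cutoff below every event -> 100%
  expect_equal(as.numeric(percent_positive(veh, "mA", cutoff = -Inf)), 100)
  # vehicle against its own 99th percentile -> ~1%
  self_pct <- percent_positive(veh, "mA", vehicle = veh, q = 99)
  expect_equal(as.numeric(self_pct), 1, tolerance = 0.1)
  # generator truth: 20% of cells shifted far above the cutoff
  sig <- effect_signature(island_fraction = 0.2,
                          island_shift = c(mA = 4))
  shifted <- arcsinh_scale(generate_well_events(panel, sig, 20000, seed = 52))
  cutoff <- attr(self_pct, "cutoff")
  pct <- as.numeric(percent_positive(shifted, "mA", cutoff = cutoff))
  expect_equal(pct, 20 + 1, tolerance = 0.1)  # shifted cells + baseline tail
  expect_error(percent_positive(subset_events(veh, integer(0)), "mA",
                                cutoff = 0), "empty")
})

test_that("specificity ratio is a guarded log2 ratio", {
  expect_equal(as.numeric(specificity_ratio(30, 30)), 0)
  expect_equal(as.numeric(specificity_ratio(40, 10, eps = 0)), 2)
  guarded <- specificity_ratio(40, 0)
  expect_true(is.finite(guarded))
  expect_true(attr(guarded, "guarded"))
  expect_equal(as.numeric(guarded), log2(40.1 / 0.1))
})

test_that("clustering merges identical profiles first and recovers blocks", {
  delta <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(-1, 0, 1),
                 d = c(-1.1, 0.1, 1.1))
  ch <- cluster_heatmap(delta)
  expect_equal(ch$row_hclust$height[1], 0)  # identical rows merge at 0
  cut <- cutree(ch$row_hclust, 2)
  expect_equal(unname(cut), c(1, 1, 2, 2))
  # permuting rows leaves the dendrogram leaf set order-consistent
  perm <- c(3, 1, 4, 2)
  ch2 <- cluster_heatmap(delta[perm, ])
  expect_identical(rownames(ch2$matrix)[ch2$row_order],
                   rownames(ch$matrix)[ch$row_order])
  expect_warning(cluster_heatmap(rbind(a = c(1, NA), b = c(0, 1))),
                 "imputed")
})

test_that("rank-sum exact path matches hand enumeration and handles degeneracy", {
  res <- rank_sum_test(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3)   # 2 of C(4,2)=6 splits as extreme
  same <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$p_value, 1)
  ab <- rank_sum_test(c(1, 3, 5), c(1, 3, 5))
  expect_equal(ab$p_value, 1, tolerance = 1e-9)
})

test_that("rank-sum exact path equals the permutation oracle", {
  set.seed(61)
  for (i in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    vals <- sample(seq_len(50), m + n)   # distinct -> no ties
    a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
    res <- rank_sum_test(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_rank_sum_p(a, b), tolerance = 1e-12)
  }
})

test_that("4PL fits recover noiseless curves and the EC50 midpoint property", {
  doses <- c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 0)
  truth <- list(b = -1.5, c = 2, d = 80, e = 0.3)
  resp <- fourpl(doses, truth$b, truth$c, truth$d, truth$e)
  fit <- fit_4pl(doses, resp)
  expect_true(fit$converged)
  expect_equal(fit$e, truth$e, tolerance = 0.01)
  expect_equal(fit$b, truth$b, tolerance = 0.01)
  expect_lte(fit$c, fit$d)
  # response at dose e is the midpoint of the asymptotes
  expect_equal(fourpl(truth$e, fit$b, fit$c, fit$d, fit$e),
               (fit$c + fit$d) / 2, tolerance = 1e-6)
  expect_error(fit_4pl(doses, rep(50, 8)), "no dose effect")
  expect_error(fit_4pl(c(0, 1, 2), c(1, 2, 3)), "5 dose levels")
})

test_that("4PL fits are invariant to dose unit rescaling", {
  doses <- c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 0)
  set.seed(71)
  resp <- pmin(100, pmax(0, fourpl(doses, -1.2, 5, 90, 0.4) + rnorm(8, 0, 1)))
  f1 <- fit_4pl(doses, resp)
  f2 <- fit_4pl(doses * 1000, resp)
  expect_equal(f2$e, f1$e * 1000, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  expect_equal(f2$c, f1$c, tolerance = 1e-6)
  expect_equal(f2$d, f1$d, tolerance = 1e-6)
})

test_that("a decreasing (inhibition-style) curve fits with positive hill in this form", {
  doses <- c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 0)
  resp <- fourpl(doses, 1.5, 2, 80, 0.3)   # b > 0: response falls with dose
  fit <- fit_4pl(doses, resp)
  expect_equal(fit$e, 0.3, tolerance = 0.01)
  expect_gt(fit$b, 0)
})
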
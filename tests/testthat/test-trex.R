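test_that("equal subsampling yields exactly equal groups, deterministically", {
  panel <- tiny_panel()
  a <- generate_well_events(panel, effect_signature(), 1500, seed = 1)
  b <- generate_well_events(panel, effect_signature(), 2500, seed = 2)
  c <- generate_well_events(panel, effect_signature(), 4000, seed = 3)
  sub <- equal_subsample(list(g1 = a, g2 = b, g3 = c), per_group_n = 1000,
                         seed = 7)
  expect_equal(n_events(sub), 3000)
  expect_equal(unname(table(sub$annotations$group)), rep(1000L, 3),
               ignore_attr = TRUE)
  sub2 <- equal_subsample(list(g1 = a, g2 = b, g3 = c), per_group_n = 1000,
                          seed = 7)
  expect_identical(sub$values, sub2$values)
  # a short group lowers everyone to its size, with a message
  expect_message(
    sub3 <- equal_subsample(list(g1 = a, g2 = b), per_group_n = 2000,
                            seed = 1),
    "lowered")
  expect_equal(unname(table(sub3$annotations$group)), rep(1500L, 2),
               ignore_attr = TRUE)
  expect_error(equal_subsample(list(g1 = subset_events(a, integer(0)),
                                    g2 = b)), "empty group")
})

test_that("embedding separates well-separated populations", {
  skip_if_not_installed("cluster")
  panel <- tiny_panel()
  near <- arcsinh_scale(generate_well_events(panel, effect_signature(), 300,
                                             seed = 1))
  far <- arcsinh_scale(generate_well_events(
    panel, effect_signature(c(mA = 6, mB = 6, mC = 6)), 300, seed = 2))
  both <- bind_events(list(near, far))
  emb <- embed_cells(both, method = "tsne", perplexity = 30, max_iter = 400,
                     seed = 3)
  sil <- cluster::silhouette(rep(1:2, each = 300),
                             dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("embedding is reproducible under a fixed seed and tolerates duplicates", {
  panel <- tiny_panel()
  tab <- arcsinh_scale(generate_well_events(panel, effect_signature(), 200,
                                            seed = 4))
  dup <- bind_events(list(tab, tab))   # exact duplicate rows
  e1 <- embed_cells(dup, method = "tsne", perplexity = 20, max_iter = 250,
                    seed = 5)
  expect_true(all(is.finite(e1$coords)))
  e2 <- embed_cells(dup, method = "tsne", perplexity = 20, max_iter = 250,
                    seed = 5)
  expect_identical(e1$coords, e2$coords)
  expect_error(embed_cells(subset_events(tab, 1:50), perplexity = 60),
               "perplexity")
})

test_that("knn fractions at the hotspot boundary label correctly", {
  # geometry: one query cell at origin; 57 test cells on a tight inner
  # ring, 3 reference cells slightly further, everything else far away
  set.seed(10)
  inner <- cbind(cos(1:57), sin(1:57)) * 1
  mid <- cbind(cos(1:3), sin(1:3)) * 1.5
  far_t <- matrix(rnorm(200, 60, 1), ncol = 2)
  far_r <- matrix(rnorm(200, -60, 1), ncol = 2)
  coords <- rbind(c(0, 0), inner, mid, far_t, far_r)
  labels <- c("reference", rep("test", 57), rep("reference", 3),
              rep("test", 100), rep("reference", 100))
  res <- knn_enrichment(coords, labels, k = 60)
  expect_equal(res$fraction_from_test[1], 57 / 60)
  expect_equal(as.character(res$hotspot[1]), "red")  # 0.95 cutoff inclusive
})

test_that("an interleaved lattice is null: fractions near 0.5 and D = 0", {
  g <- expand.grid(x = 1:30, y = 1:30)
  labels <- ifelse((g$x + g$y) %% 2 == 0, "test", "reference")
  res <- knn_enrichment(as.matrix(g), labels, k = 60)
  expect_true(all(abs(res$fraction_from_test - 0.5) < 0.2))
  expect_equal(degree_of_difference(res), 0)
})

test_that("knn enrichment equals the brute-force all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(50:200, 1)
    coords <- matrix(rnorm(2 * n), ncol = 2)
    labels <- sample(c("test", "reference"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    k <- sample(5:20, 1)
    res <- knn_enrichment(coords, labels, k = k)
    expect_identical(res$fraction_from_test,
                     oracle_knn_fraction(coords, labels, k))
  }
})

test_that("label swap maps fractions to their complement and preserves D", {
  set.seed(20)
  coords <- matrix(rnorm(600), ncol = 2)
  labels <- rep(c("test", "reference"), length.out = 300)
  res <- knn_enrichment(coords, labels, k = 15)
  swapped <- ifelse(labels == "test", "reference", "test")
  res2 <- knn_enrichment(coords, swapped, k = 15)
  expect_equal(res2$fraction_from_test, 1 - res$fraction_from_test)
  expect_equal(degree_of_difference(res2), degree_of_difference(res))
})

test_that("degree of difference is the printed ratio", {
  expect_equal(degree_of_difference(fake_trex_result(150, 50, 1000)), 0.20)
  expect_equal(degree_of_difference(fake_trex_result(0, 0, 500)), 0)
  expect_equal(degree_of_difference(fake_trex_result(300, 200, 500)), 1)
})

test_that("single-label input is rejected", {
  coords <- matrix(rnorm(200), ncol = 2)
  expect_error(knn_enrichment(coords, rep("test", 100), k = 5),
               "both")
})

test_that("island quantification counts points in polygons per group", {
  # unit square gate; hand-constructed points
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  pts <- rbind(c(0.5, 0.5), c(0.2, 0.8), c(1.5, 0.5), c(-0.1, 0.2),
               c(0.9, 0.1), c(2, 2))
  groups <- c("a", "a", "a", "b", "b", "b")
  pct <- island_quantify(pts, sq, groups)
  expect_equal(unname(pct["a"]), 100 * 2 / 3)
  expect_equal(unname(pct["b"]), 100 * 1 / 3)
  # gate containing everything
  big <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10))
  expect_equal(unname(island_quantify(pts, big, groups)), c(100, 100))
  # empty factor level reported missing, not 0
  pct3 <- island_quantify(pts, sq, factor(groups, levels = c("a", "b", "c")))
  expect_true(is.na(pct3["c"]))
  expect_error(point_in_polygon(pts, sq[1:2, ]), "degenerate")
})

test_that("the half-open edge convention tiles without double counting", {
  left <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  right <- cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))
  on_edge <- cbind(rep(1, 5), seq(0.1, 0.9, length.out = 5))
  in_left <- point_in_polygon(on_edge, left)
  in_right <- point_in_polygon(on_edge, right)
  expect_true(all(xor(in_left, in_right)))
})
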
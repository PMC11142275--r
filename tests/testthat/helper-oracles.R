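# Shared fixtures and independent oracles used across test files.

tiny_panel <- function() {
  marker_panel(markers = c("mA", "mB", "mC"), cofactors = c(6000, 150, 12000),
               baseline_location = c(1.0, 1.5, 2.0),
               baseline_spread = c(0.3, 0.4, 0.5))
}

# scaled event table built directly from a matrix of arcsinh-scale values
scaled_table <- function(mat) {
  tab <- event_table(mat, roles = rep("functional", ncol(mat)),
                     cofactors = rep(6000, ncol(mat)))
  tab$channel_meta$scaled <- TRUE
  tab
}

# brute-force KNN test-fraction: all-pairs distances, self excluded
oracle_knn_fraction <- function(coords, labels, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(labels[nb] == "test")
  }, 0)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_rank_sum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# direct-formula MEM oracle with its own sort-based order statistics
oracle_mem_raw <- function(mat, mag_ref, iqr_ref, iqr_floor = 0.5) {
  q_type7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    mag <- q_type7(x, 0.5)
    iqr <- max(q_type7(x, 0.75) - q_type7(x, 0.25), iqr_floor)
    if (abs(mag) <= 1e-12) return(0)
    raw <- abs(mag - mag_ref[j]) + iqr_ref[j] / iqr - 1
    if (mag < mag_ref[j]) -raw else raw
  }, 0)
}

# construct a trex_result by hand (for formula-only tests)
fake_trex_result <- function(n_red, n_blue, n_total) {
  hotspot <- factor(c(rep("red", n_red), rep("blue", n_blue),
                      rep("none", n_total - n_red - n_blue)),
                    levels = c("red", "blue", "none"))
  structure(list(fraction_from_test = rep(0.5, n_total), hotspot = hotspot,
                 k = 60, hotspot_hi = 0.95, hotspot_lo = 0.05,
                 n_test = n_total, n_reference = n_total,
                 degree_of_difference = mean(hotspot != "none")),
            class = "trex_result")
}
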
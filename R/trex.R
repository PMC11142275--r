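#' Equal-representation subsampling
#'
#' Uniform sampling without replacement so that every group (well,
#' subclass, or condition) contributes exactly the same number of events
#' before a comparison — the equal-representation step preceding the
#' KNN-enrichment analysis. If any group has fewer events than requested
#' (or `per_group_n` is NULL), all groups are downsampled to the smallest
#' group size, with a message.
#'
#' @param tables named list of `event_table`s, one per group.
#' @param per_group_n events to take per group, or NULL for the minimum
#'   group size.
#' @param seed integer seed.
#' @return A single `event_table` with a `group` annotation column.
#' @export
equal_subsample <- function(tables, per_group_n = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("`tables` must be a named list (group names)")
  }
  sizes <- vapply(tables, n_events, 0L)
  if (any(sizes == 0)) {
    stop("empty group(s): ", paste(names(tables)[sizes == 0], collapse = ", "))
  }
  n <- if (is.null(per_group_n)) min(sizes) else min(per_group_n, min(sizes))
  if (!is.null(per_group_n) && n < per_group_n) {
    message("per_group_n lowered to smallest group size (", n, ")")
  }
  .with_seed(seed, {
    picked <- lapply(names(tables), function(g) {
      tab <- subset_events(tables[[g]], sort(sample.int(n_events(tables[[g]]), n)))
      if (is.null(tab$annotations)) {
        tab$annotations <- data.frame(group = rep(g, n),
                                      stringsAsFactors = FALSE)
      } else {
        tab$annotations$group <- g
      }
      tab
    })
    bind_events(picked)
  })
}

#' 2-D embedding of the functional marker space
#'
#' Nonlinear dimensionality reduction of the arcsinh-scaled marker matrix
#' for visual and KNN-enrichment analysis. The default backend is
#' Barnes-Hut t-SNE (perplexity 60); a UMAP backend is selectable. Only
#' the neighbourhood structure of the embedding is consumed downstream.
#'
#' @param table an `event_table` with scaled functional channels.
#' @param markers channels to embed (default: all functional channels).
#' @param method `"tsne"` or `"umap"`.
#' @param perplexity t-SNE perplexity (requires at least
#'   `3 * perplexity + 1` events).
#' @param max_iter t-SNE iterations.
#' @param n_neighbors UMAP neighbourhood size.
#' @param seed integer seed (fixed seed gives identical coordinates).
#' @return An `embedding_coords` object: `coords` (events x 2) plus
#'   provenance (backend, parameters, seed, markers).
#' @export
embed_cells <- function(table, markers = channels(table, "functional"),
                        method = c("tsne", "umap"), perplexity = 60,
                        max_iter = 1000, n_neighbors = 15, seed = 1) {
  stopifnot(inherits(table, "event_table"))
  method <- match.arg(method)
  x <- .channel_matrix(table, markers, require_scaled = TRUE)
  if (method == "tsne") {
    if (nrow(x) < 3 * perplexity + 1) {
      stop("t-SNE needs at least 3 * perplexity + 1 = ", 3 * perplexity + 1,
           " events (got ", nrow(x), ")")
    }
    coords <- .with_seed(seed, {
      Rtsne::Rtsne(x, perplexity = perplexity, max_iter = max_iter,
                   check_duplicates = FALSE, pca = TRUE, verbose = FALSE,
                   num_threads = 1)$Y
    })
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("the umap backend requires the 'uwot' package")
    }
    coords <- .with_seed(seed, {
      uwot::umap(x, n_neighbors = n_neighbors, n_threads = 1,
                 n_sgd_threads = 1)
    })
  }
  colnames(coords) <- c("dim1", "dim2")
  structure(
    list(coords = coords,
         provenance = list(method = method, perplexity = perplexity,
                           max_iter = max_iter, n_neighbors = n_neighbors,
                           seed = seed, markers = markers)),
    class = "embedding_coords"
  )
}

#' KNN enrichment of test vs reference cells (T-REX)
#'
#' For every cell, the fraction of its `k` nearest neighbours in
#' embedding space (the cell itself excluded) that carry the `test`
#' label. Cells in neighbourhoods at or above `hotspot_hi` test fraction
#' are "red" (enriched in the test condition); at or below `hotspot_lo`,
#' "blue" (enriched in the reference); otherwise unlabelled. The degree
#' of difference is `(red + blue) / total`. Neighbour searches are exact
#' (kd-tree, eps = 0) and deterministic for a given input, with ties at
#' equal distance resolved by the backend's fixed scan order.
#'
#' @param coords an [embed_cells()] result, or an events x 2 coordinate
#'   matrix.
#' @param labels character/factor with values `"test"` and `"reference"`,
#'   one per embedded event; both labels must be present.
#' @param k neighbour count (default 60).
#' @param hotspot_hi,hotspot_lo enrichment cutoffs (defaults 0.95, 0.05).
#' @return A `trex_result`: `fraction_from_test`, `hotspot` (factor
#'   red/blue/none), `degree_of_difference`, and group sizes.
#' @export
knn_enrichment <- function(coords, labels, k = 60,
                           hotspot_hi = 0.95, hotspot_lo = 0.05) {
  if (inherits(coords, "embedding_coords")) coords <- coords$coords
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(coords))
  if (!all(c("test", "reference") %in% labels)) {
    stop("both 'test' and 'reference' labels must be present")
  }
  if (!all(labels %in% c("test", "reference"))) {
    stop("labels must be 'test' or 'reference'")
  }
  if (!(hotspot_lo >= 0 && hotspot_lo < hotspot_hi && hotspot_hi <= 1)) {
    stop("need 0 <= hotspot_lo < hotspot_hi <= 1")
  }
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must be in [1, n_events - 1]")
  nn <- RANN::nn2(coords, coords, k = k + 1)
  idx <- nn$nn.idx
  # drop one occurrence of self per row (first column in the generic case;
  # under exact duplicates self can land elsewhere in the tied block)
  neigh <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- idx[i, ]
    self <- match(i, row)
    if (is.na(self)) row <- row[seq_len(k)] else row <- row[-self]
    neigh[i, ] <- row[seq_len(k)]
  }
  is_test <- labels == "test"
  fraction <- rowMeans(matrix(is_test[neigh], n, k))
  hotspot <- factor(
    ifelse(fraction >= hotspot_hi, "red",
           ifelse(fraction <= hotspot_lo, "blue", "none")),
    levels = c("red", "blue", "none")
  )
  structure(
    list(fraction_from_test = fraction, hotspot = hotspot,
         k = k, hotspot_hi = hotspot_hi, hotspot_lo = hotspot_lo,
         n_test = sum(is_test), n_reference = sum(!is_test),
         degree_of_difference = mean(hotspot != "none")),
    class = "trex_result"
  )
}

#' @export
print.trex_result <- function(x, ...) {
  cat("<trex_result> ", length(x$fraction_from_test), " cells (test ",
      x$n_test, ", reference ", x$n_reference, "), k = ", x$k, "\n", sep = "")
  cat(sprintf("  red %d, blue %d; degree of difference %.4f\n",
              sum(x$hotspot == "red"), sum(x$hotspot == "blue"),
              x$degree_of_difference))
  invisible(x)
}

#' Degree of difference
#'
#' `(number of red cells + number of blue cells) / total number of
#' cells`: the fraction of cells sitting in strongly enriched or strongly
#' depleted KNN neighbourhoods; 0 when the two conditions are
#' indistinguishable.
#'
#' @param result a `trex_result`.
#' @return a number in `[0, 1]`.
#' @export
degree_of_difference <- function(result) {
  stopifnot(inherits(result, "trex_result"))
  (sum(result$hotspot == "red") + sum(result$hotspot == "blue")) /
    length(result$hotspot)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting with a half-open edge convention: a point on an edge
#' counts as inside exactly when the edge is "below-left" of the ray —
#' points on the lower/left boundary are inside, on the upper/right
#' boundary outside — so tiling polygons count every point exactly once.
#'
#' @param points n x 2 matrix.
#' @param polygon m x 2 vertex matrix (m >= 3, implicitly closed, simple).
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(points, polygon) {
  points <- as.matrix(points)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("degenerate polygon: need at least 3 vertices")
  n <- nrow(points)
  inside <- rep(FALSE, n)
  m <- nrow(polygon)
  j <- m
  for (i in seq_len(m)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > points[, 2]) != (yj > points[, 2])) &
      (points[, 1] < (xj - xi) * (points[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Percentage of each group's cells inside a gate polygon
#'
#' Quantifies an "island" gate drawn on the embedding: for each group,
#' 100 x (cells inside the polygon) / (cells in the group). Groups with
#' no cells are reported as NA (missing), not 0.
#'
#' @param coords an [embed_cells()] result or n x 2 matrix.
#' @param polygon gate vertices (m x 2, m >= 3).
#' @param groups grouping labels, one per embedded event; may contain
#'   levels with zero events (factor) which are reported NA.
#' @return named numeric vector: percent in gate per group.
#' @export
island_quantify <- function(coords, polygon, groups) {
  if (inherits(coords, "embedding_coords")) coords <- coords$coords
  stopifnot(nrow(coords) == length(groups))
  inside <- point_in_polygon(coords, polygon)
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  out <- vapply(lev, function(g) {
    n <- sum(groups == g)
    if (n == 0) NA_real_ else 100 * sum(inside & groups == g) / n
  }, 0)
  out
}

#' Auto-gate the hotspot island richest in a marker
#'
#' Convenience alternative to a hand-drawn polygon: selects "red" hotspot
#' cells, clusters them into connected regions by single-linkage at a
#' distance threshold, picks the region with the highest mean of the
#' named marker, and returns its bounding convex hull as the gate
#' polygon.
#'
#' @param coords an [embed_cells()] result or n x 2 matrix.
#' @param result a `trex_result` aligned with `coords`.
#' @param marker_values per-event values of the marker to maximise.
#' @param link_dist single-linkage merge distance (embedding units);
#'   default 1/30 of the embedding's larger axis range.
#' @return polygon vertex matrix (convex hull of the chosen region),
#'   or NULL when there are no red cells.
#' @export
auto_island_gate <- function(coords, result, marker_values, link_dist = NULL) {
  if (inherits(coords, "embedding_coords")) coords <- coords$coords
  red <- which(result$hotspot == "red")
  if (length(red) == 0) return(NULL)
  pts <- coords[red, , drop = FALSE]
  if (is.null(link_dist)) {
    link_dist <- max(apply(coords, 2, function(v) diff(range(v)))) / 30
  }
  comp <- if (length(red) == 1) 1L else {
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = link_dist)
  }
  means <- tapply(marker_values[red], comp, mean)
  best <- as.integer(names(means)[which.max(means)])
  sel <- pts[comp == best, , drop = FALSE]
  if (nrow(sel) < 3) {
    # pad a tiny region to a valid triangle around its centroid
    cx <- mean(sel[, 1]); cy <- mean(sel[, 2])
    r <- max(link_dist / 2, 1e-6)
    return(cbind(cx + r * cos(c(0, 2, 4) * pi / 3),
                 cy + r * sin(c(0, 2, 4) * pi / 3)))
  }
  hull <- grDevices::chull(sel)
  sel[hull, , drop = FALSE]
}
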
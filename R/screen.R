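#' Arcsinh fold change of a treated well vs vehicle
#'
#' The screen's effect statistic: for each marker, the difference of
#' arcsinh-scaled medians, `delta = median_scaled(treated) -
#' median_scaled(vehicle)`. On this scale 0 means no change and +1 about
#' an e-fold raw increase in the logarithmic regime, which is how the
#' heatmap values from roughly -1.5 to +1 read. A literal
#' ratio-inside-arcsinh variant, `asinh(MFI_treated / MFI_vehicle)` on
#' raw medians, is available for comparison via `mode`.
#'
#' @param treated,vehicle `event_table`s with scaled functional channels
#'   (raw channels for `mode = "arcsinh_ratio"`).
#' @param markers markers to compare.
#' @param mode `"difference"` (default) or `"arcsinh_ratio"`.
#' @return named numeric vector of per-marker deltas.
#' @export
fold_change <- function(treated, vehicle, markers,
                        mode = c("difference", "arcsinh_ratio")) {
  mode <- match.arg(mode)
  if (n_events(treated) == 0 || n_events(vehicle) == 0) {
    stop("fold_change requires nonempty wells")
  }
  if (mode == "difference") {
    mt <- apply(.channel_matrix(treated, markers, require_scaled = TRUE),
                2, stats::median)
    mv <- apply(.channel_matrix(vehicle, markers, require_scaled = TRUE),
                2, stats::median)
    mt - mv
  } else {
    mt <- apply(.channel_matrix(treated, markers), 2, stats::median)
    mv <- apply(.channel_matrix(vehicle, markers), 2, stats::median)
    asinh(mt / mv)
  }
}

#' Hit selection with a vehicle-derived threshold
#'
#' The bioactivity threshold is the vehicle median + 3 x IQR of the
#' vehicle fold-change values, computed either pooled across readouts
#' (default, one line for the whole screen) or per readout. A compound is
#' a hit on a readout when its fold change exceeds the threshold, and an
#' overall hit when it is a hit on any readout.
#'
#' @param delta compounds x markers matrix of fold changes (rownames =
#'   compound ids).
#' @param vehicle_delta vehicle wells x markers matrix of fold changes
#'   (each vehicle scored like a compound). At least 2 vehicle wells are
#'   required for a meaningful IQR; with exactly 1 the IQR is 0 and the
#'   result is flagged.
#' @param mode `"pooled"` or `"per_readout"`.
#' @return list with `hits` (logical per compound), `hit_matrix`
#'   (per readout), `threshold` (scalar or per readout), and
#'   `degenerate` flag.
#' @export
select_hits <- function(delta, vehicle_delta, mode = c("pooled", "per_readout")) {
  mode <- match.arg(mode)
  delta <- as.matrix(delta)
  vehicle_delta <- as.matrix(vehicle_delta)
  if (nrow(vehicle_delta) == 0) stop("no vehicle wells")
  degenerate <- nrow(vehicle_delta) < 2
  if (degenerate) warning("single vehicle well: IQR is 0, threshold fragile")
  if (mode == "pooled") {
    v <- as.numeric(vehicle_delta)
    threshold <- stats::median(v) + 3 * stats::IQR(v, type = 7)
    hit_matrix <- delta > threshold
  } else {
    threshold <- apply(vehicle_delta, 2, function(v) {
      stats::median(v) + 3 * stats::IQR(v, type = 7)
    })
    hit_matrix <- sweep(delta, 2, threshold, ">")
  }
  list(hits = apply(hit_matrix, 1, any), hit_matrix = hit_matrix,
       threshold = threshold, mode = mode, degenerate = degenerate)
}

#' Chemotype composition of a library and of its hit set
#'
#' Per-chemotype counts and percentages (to one decimal) among all
#' library compounds and among the hits — e.g. a chemotype at 3.2% of a
#' 600-compound library rising to 13.8% of 65 hits marks a strong
#' over-representation.
#'
#' @param chemotypes character vector, one chemotype per compound.
#' @param hits logical vector aligned with `chemotypes`.
#' @return data.frame: `chemotype`, `n_library`, `pct_library`, `n_hits`,
#'   `pct_hits` (NA when there are no hits).
#' @export
chemotype_composition <- function(chemotypes, hits) {
  stopifnot(length(chemotypes) == length(hits))
  lev <- sort(unique(chemotypes))
  n_lib <- as.integer(table(factor(chemotypes, levels = lev)))
  n_hit <- as.integer(table(factor(chemotypes[hits], levels = lev)))
  total_hits <- sum(hits)
  data.frame(
    chemotype = lev,
    n_library = n_lib,
    pct_library = round(100 * n_lib / length(chemotypes), 1),
    n_hits = n_hit,
    pct_hits = if (total_hits == 0) NA_real_ else
      round(100 * n_hit / total_hits, 1),
    stringsAsFactors = FALSE
  )
}

#' Percent of events above a positivity cutoff
#'
#' Marker-positive gating on one channel: the percentage of a well's
#' events above an intensity cutoff. The cutoff is either explicit (on
#' the channel's current scale) or vehicle-referenced: the q-th
#' percentile (default 99) of the vehicle well's values, so that by
#' construction the vehicle itself sits near `100 - q` percent positive.
#'
#' @param well an `event_table`.
#' @param marker channel name.
#' @param cutoff explicit cutoff, or NULL to derive from `vehicle`.
#' @param vehicle vehicle `event_table` (required when `cutoff` is NULL).
#' @param q vehicle percentile defining the cutoff.
#' @return percentage in `[0, 100]`, with the cutoff as attribute.
#' @export
percent_positive <- function(well, marker, cutoff = NULL, vehicle = NULL,
                             q = 99) {
  if (n_events(well) == 0) stop("empty well")
  if (is.null(cutoff)) {
    if (is.null(vehicle)) stop("need an explicit cutoff or a vehicle well")
    cutoff <- percentile(.channel_matrix(vehicle, marker)[, 1], q)
  }
  x <- .channel_matrix(well, marker)[, 1]
  structure(100 * mean(x > cutoff), cutoff = cutoff)
}

#' Cell-type specificity ratio
#'
#' `log2((pct_a + eps) / (pct_b + eps))` comparing the percent-positive
#' readout between two cell types (e.g. leukemia vs healthy blood), with
#' a pseudo-count `eps` (default 0.1 percentage point) guarding zero
#' denominators. Positive values mean activity specific to the first
#' cell type.
#'
#' @param pct_a,pct_b percentages (>= 0).
#' @param eps pseudo-count in percentage points; `eps = 0` gives the
#'   plain ratio (infinite when `pct_b = 0`).
#' @return the log2 ratio, with `eps` and a `guarded` flag (TRUE when
#'   either percentage was 0) as attributes.
#' @export
specificity_ratio <- function(pct_a, pct_b, eps = 0.1) {
  stopifnot(pct_a >= 0, pct_b >= 0, eps >= 0)
  structure(log2((pct_a + eps) / (pct_b + eps)),
            eps = eps, guarded = (pct_a == 0 || pct_b == 0))
}

#' Hierarchical clustering of a fold-change matrix
#'
#' Agglomerative clustering of compounds (rows) and readouts (columns)
#' of the fold-change matrix, as used to order bioactivity heatmaps.
#' Missing values are imputed as 0 (no change) and flagged. Leaf order is
#' deterministic for a given matrix.
#'
#' @param delta compounds x markers numeric matrix.
#' @param method linkage (default `"average"`).
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return list with `row_hclust`, `col_hclust`, `row_order`,
#'   `col_order`, the (imputed) `matrix`, and `imputed` count.
#' @export
cluster_heatmap <- function(delta, method = "average", metric = "euclidean") {
  delta <- as.matrix(delta)
  imputed <- sum(is.na(delta))
  if (imputed > 0) {
    warning(imputed, " missing value(s) imputed as 0 (no change)")
    delta[is.na(delta)] <- 0
  }
  row_h <- if (nrow(delta) > 1) {
    stats::hclust(stats::dist(delta, method = metric), method = method)
  } else NULL
  col_h <- if (ncol(delta) > 1) {
    stats::hclust(stats::dist(t(delta), method = metric), method = method)
  } else NULL
  list(row_hclust = row_h, col_hclust = col_h,
       row_order = if (is.null(row_h)) seq_len(nrow(delta)) else row_h$order,
       col_order = if (is.null(col_h)) seq_len(ncol(delta)) else col_h$order,
       matrix = delta, imputed = imputed)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midrank ties: exact enumeration when the
#' combined sample size is at most 12 and there are no ties, otherwise
#' the normal approximation with tie correction and continuity
#' correction. When every value in both groups is identical the test is
#' uninformative and p = 1 is returned.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with `statistic` (Mann-Whitney U of the first group),
#'   `p_value`, and `exact` (logical).
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                exact = FALSE))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = c + (d - c) / (1 + (x / e)^b)` (see
#' [fourpl()]) with all four parameters free: hill slope `b`, the two
#' asymptotes `c` and `d`, and the EC50 `e`. Dose 0 is evaluated as the
#' asymptote limit, so the zero-dose control enters the fit without a
#' log singularity. The fit is parameterised internally on `log(e)` to
#' keep the EC50 positive, started from the response range and the dose
#' bracketing half-response, and canonicalised so that `c <= d` (the
#' sign of `b` flips accordingly; the curve is unchanged).
#'
#' @param doses nonnegative dose vector (>= 5 distinct levels including
#'   dose 0).
#' @param responses percent responses in `[0, 100]`, same length.
#' @return A `dose_response_fit`: `b`, `c`, `d`, `e`, `fitted`,
#'   `residual_sd`, `converged`.
#' @export
fit_4pl <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), all(doses >= 0),
            all(responses >= 0), all(responses <= 100))
  if (length(unique(doses)) < 5 || !any(doses == 0)) {
    stop("need at least 5 dose levels including dose 0")
  }
  if (diff(range(responses)) == 0) stop("no dose effect: constant responses")

  c0 <- min(responses); d0 <- max(responses)
  # e0: dose whose response is nearest the half-way point, among x > 0
  half <- (c0 + d0) / 2
  pos <- doses > 0
  e0 <- doses[pos][which.min(abs(responses[pos] - half))]
  # rising curve (higher response at higher dose) needs b < 0 in this form
  rising <- stats::cor(doses, responses) >= 0
  b0 <- if (rising) -1 else 1

  fit <- minpack.lm::nlsLM(
    responses ~ fourpl(doses, b, c, d, exp(loge)),
    start = list(b = b0, c = c0, d = d0, loge = log(e0)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  b <- cf[["b"]]; cc <- cf[["c"]]; dd <- cf[["d"]]; e <- exp(cf[["loge"]])
  if (cc > dd) { tmp <- cc; cc <- dd; dd <- tmp; b <- -b }
  conv <- fit$convInfo$isConv
  structure(
    list(b = b, c = cc, d = dd, e = e,
         fitted = fourpl(doses, b, cc, dd, e),
         residual_sd = stats::sd(stats::residuals(fit)),
         converged = isTRUE(conv), doses = doses, responses = responses),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> EC50 = %.4g, asymptotes [%.3g, %.3g], hill %.3g%s\n",
    x$e, x$c, x$d, x$b, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
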
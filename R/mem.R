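#' MEM reference
#'
#' Marker Enrichment Modeling scores a population against a reference.
#' Two reference kinds are supported:
#' \describe{
#'   \item{population}{a comparison population: per-marker reference
#'     magnitude (median on arcsinh scale) and IQR are taken from it.}
#'   \item{statistical_null}{a null-hypothesis reference: magnitude 0 for
#'     every marker, and a common reference IQR equal to the median of
#'     the candidate population's per-marker IQRs — useful when no
#'     natural comparison population exists.}
#' }
#'
#' @param population an `event_table` with scaled functional channels;
#'   for the statistical null it is the candidate population whose
#'   per-marker IQRs define the common reference IQR.
#' @param markers markers entering the analysis.
#' @param kind `"population"` or `"statistical_null"`.
#' @return A `mem_reference`: per-marker `mag_ref` and `iqr_ref`.
#' @export
mem_reference <- function(population, markers,
                          kind = c("statistical_null", "population")) {
  kind <- match.arg(kind)
  x <- .channel_matrix(population, markers, require_scaled = TRUE)
  if (nrow(x) == 0) stop("reference population is empty")
  iqrs <- apply(x, 2, stats::IQR, type = 7)
  if (kind == "population") {
    mag <- apply(x, 2, stats::median)
    iqr_ref <- iqrs
  } else {
    mag <- stats::setNames(rep(0, length(markers)), markers)
    iqr_ref <- stats::setNames(rep(stats::median(iqrs), length(markers)),
                               markers)
  }
  structure(list(mag_ref = mag, iqr_ref = iqr_ref, kind = kind,
                 markers = markers),
            class = "mem_reference")
}

#' Raw MEM enrichment scores
#'
#' Per marker, with population magnitude `MAG_pop` (median, arcsinh
#' scale) and spread `IQR_pop`:
#' \deqn{raw = |MAG_{pop} - MAG_{ref}| + IQR_{ref}/IQR_{pop} - 1}
#' negated when `MAG_pop < MAG_ref`. The IQR contribution is zeroed out
#' for markers whose population magnitude is 0 (raw score 0): a marker
#' with null signal is not enriched, whatever its spread. Degenerate
#' `IQR_pop = 0` is floored at `iqr_floor` and flagged.
#'
#' @param population an `event_table` with scaled functional channels.
#' @param markers markers to score (default: the reference's marker set).
#' @param reference a [mem_reference()].
#' @param iqr_floor floor for degenerate population IQRs (arcsinh units).
#' @param mag_tol absolute tolerance for the `MAG_pop = 0` comparison.
#' @return A `mem_scores` object: `raw` (named numeric), `mag_pop`,
#'   `iqr_pop`, and `iqr_floored` (logical flags).
#' @export
mem_scores <- function(population, markers = reference$markers, reference,
                       iqr_floor = 0.5, mag_tol = 1e-12) {
  stopifnot(inherits(reference, "mem_reference"))
  x <- .channel_matrix(population, markers, require_scaled = TRUE)
  if (nrow(x) == 0) stop("population is empty")
  missing_ref <- setdiff(markers, names(reference$mag_ref))
  if (length(missing_ref)) {
    stop("reference lacks marker(s): ", paste(missing_ref, collapse = ", "))
  }
  mag_pop <- apply(x, 2, stats::median)
  iqr_pop <- apply(x, 2, stats::IQR, type = 7)
  floored <- iqr_pop < iqr_floor
  iqr_pop_use <- pmax(iqr_pop, iqr_floor)
  mag_ref <- reference$mag_ref[markers]
  iqr_ref <- reference$iqr_ref[markers]
  raw <- abs(mag_pop - mag_ref) + iqr_ref / iqr_pop_use - 1
  raw <- ifelse(mag_pop < mag_ref, -raw, raw)
  raw[abs(mag_pop) <= mag_tol] <- 0
  structure(list(raw = raw, mag_pop = mag_pop, iqr_pop = iqr_pop,
                 iqr_floored = floored, reference_kind = reference$kind),
            class = "mem_scores")
}

#' Scale raw MEM scores to the -10..+10 range
#'
#' `scaled = 10 * raw / max(|raw|)` over the marker set, so the most
#' enriched marker in an analysis maps to +10 (or -10 when depletion
#' dominates) and relative enrichment is preserved. All-zero raw scores
#' scale to all zeros. Scaling is idempotent up to the common factor:
#' multiplying all raw scores by any c > 0 leaves the scaled scores
#' unchanged.
#'
#' @param scores a `mem_scores` object or named numeric vector of raw
#'   scores.
#' @return named numeric vector of scaled scores in `[-10, 10]`.
#' @export
scale_mem <- function(scores) {
  raw <- if (inherits(scores, "mem_scores")) scores$raw else scores
  stopifnot(is.numeric(raw), length(raw) >= 1)
  m <- max(abs(raw))
  if (m == 0) return(raw * 0)
  10 * (raw / m)   # normalise first: the extreme marker maps to exactly 10
}

#' Render a MEM label
#'
#' Text such as `"gH2AX+10, p-4EBP1+7"`: markers whose scaled score has
#' absolute value at or above `threshold`, each rendered as the marker
#' name followed by the signed score rounded to the nearest integer,
#' sorted by descending scaled score; markers tied at the same rounded
#' value are ordered alphabetically.
#'
#' @param scaled named numeric vector from [scale_mem()].
#' @param threshold minimum absolute scaled score to display (default 5).
#' @return a single string (empty when nothing reaches the threshold).
#' @export
render_label <- function(scaled, threshold = 5) {
  stopifnot(!is.null(names(scaled)))
  keep <- abs(scaled) >= threshold
  if (!any(keep)) return("")
  s <- scaled[keep]
  v <- round(s)
  ord <- order(-v, names(s))
  paste0(names(s)[ord], ifelse(v[ord] >= 0, "+", "-"), abs(v[ord]),
         collapse = ", ")
}

#' One-call MEM label for a population
#'
#' Scores, scales and renders in one step.
#'
#' @inheritParams mem_scores
#' @param threshold label display threshold (see [render_label()]).
#' @return list with `raw`, `scaled`, and `label`.
#' @export
mem_label <- function(population, markers = reference$markers, reference,
                      threshold = 5, iqr_floor = 0.5) {
  sc <- mem_scores(population, markers, reference, iqr_floor = iqr_floor)
  scaled <- scale_mem(sc)
  list(raw = sc$raw, scaled = scaled,
       label = render_label(scaled, threshold))
}
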
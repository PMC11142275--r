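#' Arcsinh-scale functional channels
#'
#' Replaces each functional channel `x` by `asinh(x / cofactor)`, the
#' standard cytometry scaling (linear near zero, logarithmic for large
#' intensities; the cofactor sets the transition). Other roles are left
#' untouched. The transform is recorded per channel so downstream stages
#' can require scaled input; scaling an already-scaled channel errors.
#'
#' @param table an `event_table` with raw intensities.
#' @param cofactors a [cofactor_map()], or NULL to use the cofactors
#'   already attached to the table's channel metadata.
#' @return the table with functional channels scaled.
#' @seealso [inverse_arcsinh()] for the exact inverse.
#' @export
arcsinh_scale <- function(table, cofactors = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (!is.null(cofactors)) table <- set_cofactors(table, cofactors)
  fun <- which(table$channel_meta$role == "functional")
  if (any(table$channel_meta$scaled[fun])) {
    stop("channel(s) already arcsinh-scaled: ",
         paste(table$channel_meta$name[fun][table$channel_meta$scaled[fun]],
               collapse = ", "))
  }
  co <- table$channel_meta$cofactor[fun]
  if (anyNA(co)) {
    stop("missing cofactor for functional channel(s): ",
         paste(table$channel_meta$name[fun][is.na(co)], collapse = ", "))
  }
  table$values[, fun] <- asinh(sweep(table$values[, fun, drop = FALSE],
                                     2, co, "/"))
  table$channel_meta$scaled[fun] <- TRUE
  table
}

#' Invert the arcsinh scaling
#'
#' `sinh(x) * cofactor`, recovering raw intensities exactly.
#'
#' @param table an `event_table` with scaled functional channels.
#' @return the table with functional channels back on raw scale.
#' @export
inverse_arcsinh <- function(table) {
  stopifnot(inherits(table, "event_table"))
  fun <- which(table$channel_meta$role == "functional" &
                 table$channel_meta$scaled)
  co <- table$channel_meta$cofactor[fun]
  table$values[, fun] <- sweep(sinh(table$values[, fun, drop = FALSE]),
                               2, co, "*")
  table$channel_meta$scaled[fun] <- FALSE
  table
}

#' Quality-control gate specification
#'
#' An ordered list of rule-based gates, applied sequentially. Three rule
#' types cover the standard QC sequence (singlets, intact cells, uptake,
#' viability):
#' \describe{
#'   \item{ratio}{keep events with `y / x` within `bounds` — singlet
#'     gating on FSC-A vs FSC-H (doublets have doubled area at unchanged
#'     height, halving the ratio).}
#'   \item{rectangle}{keep events with `x` and `y` inside the rectangle
#'     `c(xmin, xmax, ymin, ymax)` — intact-cell gating on FSC-A vs SSC-A.}
#'   \item{threshold}{keep events with `x` above (`side = "above"`) or
#'     below (`side = "below"`) `bounds[1]` — uptake and viability gates.}
#' }
#'
#' @param ... gates created by [qc_gate()], in application order.
#' @return A `qc_gate_spec` object.
#' @export
qc_gate_spec <- function(...) {
  gates <- list(...)
  for (g in gates) stopifnot(inherits(g, "qc_gate"))
  structure(gates, class = "qc_gate_spec")
}

#' @rdname qc_gate_spec
#' @param name gate label used in the retention report.
#' @param x_channel,y_channel channel names (y unused for thresholds).
#' @param rule one of `"ratio"`, `"rectangle"`, `"threshold"`.
#' @param bounds numeric bounds (see rule descriptions).
#' @param side for threshold rules, `"above"` or `"below"`.
#' @export
qc_gate <- function(name, x_channel, y_channel = NULL,
                    rule = c("ratio", "rectangle", "threshold"),
                    bounds, side = "above") {
  rule <- match.arg(rule)
  if (rule == "ratio" && length(bounds) != 2) stop("ratio rule needs 2 bounds")
  if (rule == "rectangle" && length(bounds) != 4) {
    stop("rectangle rule needs 4 bounds")
  }
  if (rule == "threshold" && length(bounds) != 1) {
    stop("threshold rule needs 1 bound")
  }
  structure(list(name = name, x_channel = x_channel, y_channel = y_channel,
                 rule = rule, bounds = bounds, side = side),
            class = "qc_gate")
}

#' Default QC gate sequence for generated data
#'
#' QC1 singlets (FSC-A vs FSC-H height/area ratio within a tolerance band
#' around the singlet ratio), QC2 intact cells (FSC-A vs SSC-A
#' rectangle), QC3 barcode uptake (Ax750 above threshold), QC4 viability
#' (Ax700 below threshold). Bounds default to values matched to the
#' synthetic generator's distributions.
#'
#' @param singlet_bounds ratio band for FSC-H / FSC-A.
#' @param intact_bounds rectangle `c(xmin, xmax, ymin, ymax)` on
#'   FSC-A x SSC-A.
#' @param uptake_min minimum Ax750 intensity.
#' @param viability_max maximum Ax700 intensity (dead cells stain high).
#' @return A `qc_gate_spec`.
#' @export
default_qc_spec <- function(singlet_bounds = c(0.70, 1.30),
                            intact_bounds = c(2e4, 2.4e5, 1e4, 2.4e5),
                            uptake_min = 1200, viability_max = 4000) {
  qc_gate_spec(
    qc_gate("QC1_singlets", "FSC-A", "FSC-H", "ratio", singlet_bounds),
    qc_gate("QC2_intact", "FSC-A", "SSC-A", "rectangle", intact_bounds),
    qc_gate("QC3_uptake", "Ax750", rule = "threshold", bounds = uptake_min,
            side = "above"),
    qc_gate("QC4_viable", "Ax700", rule = "threshold", bounds = viability_max,
            side = "below")
  )
}

#' Apply QC gates in order
#'
#' @param table an `event_table`.
#' @param spec a [qc_gate_spec()].
#' @return list with `table` (events passing all gates) and `report`
#'   (data.frame: gate, events_in, events_kept, events_removed). A gate
#'   removing all remaining events raises a warning, not an error.
#' @export
apply_qc_gates <- function(table, spec) {
  stopifnot(inherits(table, "event_table"), inherits(spec, "qc_gate_spec"))
  report <- data.frame(gate = character(0), events_in = integer(0),
                       events_kept = integer(0), events_removed = integer(0))
  for (g in spec) {
    n_in <- n_events(table)
    keep <- if (n_in == 0) logical(0) else {
      x <- .channel_matrix(table, g$x_channel)[, 1]
      switch(g$rule,
        ratio = {
          y <- .channel_matrix(table, g$y_channel)[, 1]
          r <- y / x
          r >= g$bounds[1] & r <= g$bounds[2]
        },
        rectangle = {
          y <- .channel_matrix(table, g$y_channel)[, 1]
          x >= g$bounds[1] & x <= g$bounds[2] &
            y >= g$bounds[3] & y <= g$bounds[4]
        },
        threshold = if (g$side == "above") x > g$bounds[1] else x < g$bounds[1]
      )
    }
    table <- subset_events(table, keep)
    report <- rbind(report, data.frame(
      gate = g$name, events_in = n_in, events_kept = sum(keep),
      events_removed = n_in - sum(keep)))
    if (n_in > 0 && sum(keep) == 0) {
      warning("gate '", g$name, "' removed all events")
    }
  }
  list(table = table, report = report)
}

#' Percentile by linear interpolation between closest ranks
#'
#' The convention pinned for all summary statistics (identical to
#' `quantile(type = 7)`), so order-statistic tests are exact.
#'
#' @param x numeric vector.
#' @param p percentile in `[0, 100]`.
#' @return the interpolated order statistic.
#' @export
percentile <- function(x, p) {
  unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
}

#' Per-well per-marker summary statistics
#'
#' Exact order statistics (median, IQR, arbitrary percentiles) on the
#' channel values as currently scaled. Events must carry well
#' annotations. Empty wells yield NA with a warning.
#'
#' @param table an `event_table` annotated with `well_id`.
#' @param markers channels to summarise.
#' @param statistics character vector drawn from `"median"`, `"IQR"`,
#'   and `"p<q>"` percentile specs (e.g. `"p98"`).
#' @return data.frame with columns `well_id`, `marker`, one column per
#'   statistic.
#' @export
well_summary <- function(table, markers,
                         statistics = c("median", "IQR")) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(table$annotations) || is.null(table$annotations$well_id)) {
    stop("events must be annotated with well_id")
  }
  vals <- .channel_matrix(table, markers)
  wells <- unique(table$annotations$well_id)
  stat_fun <- function(x, s) {
    if (length(x) == 0) return(NA_real_)
    if (s == "median") return(stats::median(x))
    if (s == "IQR") return(stats::IQR(x, type = 7))
    if (grepl("^p[0-9.]+$", s)) {
      return(percentile(x, as.numeric(sub("^p", "", s))))
    }
    stop("unknown statistic: ", s)
  }
  rows <- expand.grid(well_id = wells, marker = markers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (s in statistics) {
    rows[[s]] <- mapply(function(w, m) {
      stat_fun(vals[table$annotations$well_id == w, m], s)
    }, rows$well_id, rows$marker)
  }
  if (anyNA(rows[statistics])) warning("empty well(s): statistics are NA")
  rows
}
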
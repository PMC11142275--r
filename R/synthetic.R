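#' Marker panel definition
#'
#' Describes the functional (phospho-protein) channels of a screen: names,
#' per-marker arcsinh cofactors, and the vehicle (baseline) intensity
#' distribution on arcsinh scale. The default panel is the 11-readout
#' signaling panel used for deep rocaglate characterisation, with the
#' standard cofactor of 6000 except where higher-range channels need
#' 12000/25000.
#'
#' @param markers character vector of unique marker names.
#' @param cofactors numeric, length 1 or `length(markers)`; arcsinh
#'   cofactors (> 0).
#' @param baseline_location,baseline_spread numeric, length 1 or
#'   `length(markers)`; location and spread (> 0) of the vehicle intensity
#'   distribution on arcsinh scale.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(markers = rocaglate_panel_markers(),
                         cofactors = rocaglate_panel_cofactors(markers),
                         baseline_location = 1.5,
                         baseline_spread = 0.4) {
  stopifnot(is.character(markers), length(markers) >= 1)
  if (anyDuplicated(markers)) stop("marker names must be unique")
  cofactors <- rep_len(as.numeric(cofactors), length(markers))
  if (any(!is.finite(cofactors)) || any(cofactors <= 0)) {
    stop("cofactors must be positive and finite")
  }
  baseline_location <- rep_len(as.numeric(baseline_location), length(markers))
  baseline_spread <- rep_len(as.numeric(baseline_spread), length(markers))
  if (any(baseline_spread <= 0)) stop("baseline_spread must be > 0")
  structure(
    list(markers = markers,
         cofactors = stats::setNames(cofactors, markers),
         baseline_location = stats::setNames(baseline_location, markers),
         baseline_spread = stats::setNames(baseline_spread, markers)),
    class = "marker_panel"
  )
}

#' @rdname marker_panel
#' @export
rocaglate_panel_markers <- function() {
  c("Ki67", "p-S6_S240244", "gH2AX", "p-STAT3", "p-STAT5",
    "p-S6_S235236", "p-ERK", "p-HH3", "p-4EBP1", "p-LCK", "p-AKT")
}

#' @rdname marker_panel
#' @export
rocaglate_panel_cofactors <- function(markers = rocaglate_panel_markers()) {
  overrides <- c("Ki67" = 25000, "p-STAT5" = 25000,
                 "p-S6_S240244" = 12000, "p-S6_S235236" = 12000,
                 "p-LCK" = 12000, "p-STAT3" = 12000,
                 "p-HH3" = 12000, "p-4EBP1" = 12000)
  co <- stats::setNames(rep(6000, length(markers)), markers)
  hit <- intersect(names(overrides), markers)
  co[hit] <- overrides[hit]
  co
}

#' Effect signature of a treatment
#'
#' A per-marker signed shift (arcsinh units) applied to treated cells,
#' plus an optional rare "island" subpopulation receiving its own shifts
#' (emulating hyper-activated cells such as the gH2AX-high / p-4EBP1-high
#' island induced by specific rocaglate pyrimidinones).
#'
#' @param shift named numeric vector of per-marker arcsinh-scale deltas;
#'   markers not named are unshifted.
#' @param island_fraction proportion of cells in `[0, 1)` routed to the
#'   island subpopulation.
#' @param island_shift named numeric vector of per-marker deltas for
#'   island cells (replacing `shift` for those cells).
#' @return An `effect_signature` object.
#' @export
effect_signature <- function(shift = numeric(0), island_fraction = 0,
                             island_shift = numeric(0)) {
  stopifnot(is.numeric(shift), is.numeric(island_shift))
  if (length(shift) && is.null(names(shift))) stop("`shift` must be named")
  if (length(island_shift) && is.null(names(island_shift))) {
    stop("`island_shift` must be named")
  }
  if (any(!is.finite(shift)) || any(!is.finite(island_shift))) {
    stop("shifts must be finite")
  }
  if (island_fraction < 0 || island_fraction >= 1) {
    stop("island_fraction must be in [0, 1)")
  }
  structure(
    list(shift = shift, island_fraction = island_fraction,
         island_shift = island_shift),
    class = "effect_signature"
  )
}

#' Built-in subclass effect signatures
#'
#' Canonical per-subclass signatures used by the demo pipeline and tests:
#' rocaglate pyrimidinones (RP) strongly induce gH2AX with retained
#' p-4EBP1 and inhibited p-ERK, and route a rare (< 3%) fraction of cells
#' to a hyper-activated island; amidino-rocaglates (ADR) reduce gH2AX and
#' p-4EBP1 while activating p-AKT and p-STAT5; regular rocaglates (RR)
#' carry a milder mixed signature. Vehicle is the null signature.
#'
#' @param subclass one of `"RP"`, `"ADR"`, `"RR"`, `"vehicle"`.
#' @return An `effect_signature`.
#' @export
subclass_signature <- function(subclass = c("RP", "ADR", "RR", "vehicle")) {
  subclass <- match.arg(subclass)
  switch(subclass,
    RP = effect_signature(
      shift = c("gH2AX" = 1.0, "p-4EBP1" = 0.4, "p-ERK" = -0.8,
                "p-HH3" = 0.3, "p-S6_S240244" = 0.4, "Ki67" = 0.3),
      island_fraction = 0.03,
      island_shift = c("gH2AX" = 2.5, "p-4EBP1" = 1.5, "Ki67" = 0.8,
                       "p-ERK" = 0.7, "p-S6_S240244" = 0.7)
    ),
    ADR = effect_signature(
      shift = c("gH2AX" = -0.4, "p-4EBP1" = -0.4, "p-AKT" = 0.6,
                "p-STAT5" = 0.6)
    ),
    RR = effect_signature(
      shift = c("gH2AX" = 0.5, "p-ERK" = -0.3, "p-S6_S235236" = 0.3)
    ),
    vehicle = effect_signature()
  )
}

#' Two-dye fluorescent-cell-barcoding scheme
#'
#' A grid of dye intensity levels: by default eight levels of the first
#' dye crossed with six of the second, covering 48 barcoded wells. Level
#' centers are on arcsinh scale and must be strictly increasing per dye;
#' the default spacing is wide relative to the level spread so that
#' deconvolution is near-perfect by design.
#'
#' @param dyes character(2), dye channel names.
#' @param levels_per_dye integer(2), number of levels per dye.
#' @param level_centers list of two strictly increasing numeric vectors
#'   (arcsinh scale), lengths matching `levels_per_dye`.
#' @param level_spread numeric, per-level Gaussian spread on arcsinh scale
#'   (scalar or list of two per-level vectors).
#' @param dye_cofactors numeric(2), arcsinh cofactors of the dye channels.
#' @param well_ids optional character vector of well ids to map onto the
#'   grid (row-major over levels of dye 1 then dye 2); defaults to
#'   `W01..Wnn`.
#' @return A `barcode_scheme` object with a `well_assignment` table
#'   mapping each well to its `(level_1, level_2)` pair.
#' @export
barcode_scheme <- function(dyes = c("Pacific_Blue", "Pacific_Orange"),
                           levels_per_dye = c(8L, 6L),
                           level_centers = list(
                             seq(0.8, by = 0.55, length.out = levels_per_dye[1]),
                             seq(0.8, by = 0.55, length.out = levels_per_dye[2])),
                           level_spread = 0.08,
                           dye_cofactors = c(150, 150),
                           well_ids = NULL) {
  stopifnot(length(dyes) == 2, length(levels_per_dye) == 2,
            length(level_centers) == 2, length(dye_cofactors) == 2)
  levels_per_dye <- as.integer(levels_per_dye)
  if (any(levels_per_dye < 1)) stop("levels_per_dye must be >= 1")
  for (d in 1:2) {
    if (length(level_centers[[d]]) != levels_per_dye[d]) {
      stop("level_centers[[", d, "]] must have ", levels_per_dye[d], " entries")
    }
    if (levels_per_dye[d] > 1 && any(diff(level_centers[[d]]) <= 0)) {
      stop("level_centers must be strictly increasing")
    }
  }
  if (is.numeric(level_spread) && length(level_spread) == 1) {
    level_spread <- list(rep(level_spread, levels_per_dye[1]),
                         rep(level_spread, levels_per_dye[2]))
  }
  if (any(unlist(level_spread) < 0)) stop("level_spread must be >= 0")
  n_wells <- prod(levels_per_dye)
  if (is.null(well_ids)) well_ids <- sprintf("W%02d", seq_len(n_wells))
  if (length(well_ids) != n_wells || anyDuplicated(well_ids)) {
    stop("well_ids must be ", n_wells, " unique ids")
  }
  grid <- expand.grid(level_1 = seq_len(levels_per_dye[1]),
                      level_2 = seq_len(levels_per_dye[2]))
  structure(
    list(dyes = dyes, levels_per_dye = levels_per_dye,
         level_centers = level_centers, level_spread = level_spread,
         dye_cofactors = stats::setNames(as.numeric(dye_cofactors), dyes),
         well_assignment = data.frame(well_id = well_ids,
                                      level_1 = grid$level_1,
                                      level_2 = grid$level_2,
                                      stringsAsFactors = FALSE)),
    class = "barcode_scheme"
  )
}

#' Default rocaglate-style plate map
#'
#' A 45-condition layout emulating the deep-characterisation experiment:
#' 37 rocaglates (20 regular rocaglates, 8 amidino-rocaglates, 9 rocaglate
#' pyrimidinones), 3 vehicle (DMSO) wells and 5 control wells, for one
#' cell type. The layout fits inside the default 48-slot 8x6 barcode grid.
#'
#' @param cell_type `"MV411"` or `"PBMC"`.
#' @param dose_uM treatment concentration for compound wells (micromolar).
#' @return data.frame with columns `well_id`, `compound_id`, `chemotype`,
#'   `subclass`, `dose_uM`, `cell_type`, `is_vehicle`.
#' @export
rocaglate_plate_map <- function(cell_type = c("MV411", "PBMC"), dose_uM = 10) {
  cell_type <- match.arg(cell_type)
  subclass <- c(rep("RR", 20), rep("ADR", 8), rep("RP", 9),
                rep("vehicle", 3), rep("control", 5))
  compound <- c(sprintf("RR-%02d", 1:20), sprintf("ADR-%02d", 1:8),
                sprintf("RP-%02d", 1:9), sprintf("DMSO-%d", 1:3),
                c("staurosporine", "etoposide", "CMLD010335",
                  "rapamycin", "nocodazole"))
  n <- length(compound)
  data.frame(
    well_id = sprintf("W%02d", seq_len(n)),
    compound_id = compound,
    chemotype = ifelse(subclass %in% c("RR", "ADR", "RP"), "rocaglate",
                       subclass),
    subclass = subclass,
    dose_uM = ifelse(subclass %in% c("vehicle"), 0, dose_uM),
    cell_type = cell_type,
    is_vehicle = subclass == "vehicle",
    stringsAsFactors = FALSE
  )
}

# internal: non-functional channel layout shared by generated tables
.aux_channels <- function() {
  data.frame(
    name = c("FSC-A", "FSC-H", "SSC-A", "Ax750", "Ax700"),
    role = c("scatter", "scatter", "scatter", "uptake", "viability"),
    stringsAsFactors = FALSE
  )
}

#' Generate one well of synthetic events
#'
#' Draws `n_cells` events for a single well. Functional channels are
#' arcsinh-normal: each marker's scaled value is Gaussian around the
#' panel baseline location plus the signature shift, then mapped back to
#' raw intensity via the inverse arcsinh with the marker's cofactor.
#' A fraction of cells (`signature$island_fraction`) instead receives the
#' island shifts and is flagged in a ground-truth column. Scatter channels
#' are correlated log-normals with a configurable doublet fraction
#' (doublets have doubled area at unchanged height, exercising the singlet
#' gate); uptake and viability dyes are drawn from fixed unimodal
#' distributions with the configured positive/dead fractions.
#'
#' @param panel a [marker_panel()].
#' @param signature an [effect_signature()]; all its markers must be in
#'   the panel.
#' @param n_cells positive integer.
#' @param seed integer seed (bit-identical output under a fixed seed).
#' @param doublet_fraction proportion of scatter doublets.
#' @param dead_fraction proportion of non-viable cells.
#' @param floor lower bound applied to raw intensities.
#' @return An `event_table` with scatter, uptake, viability, functional
#'   and `truth_island` channels, all raw (linear) intensities.
#' @export
generate_well_events <- function(panel, signature = effect_signature(),
                                 n_cells, seed = NULL,
                                 doublet_fraction = 0.05,
                                 dead_fraction = 0.05, floor = 0) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(signature, "effect_signature"))
  if (length(n_cells) != 1 || n_cells < 1) stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  unknown <- setdiff(c(names(signature$shift), names(signature$island_shift)),
                     panel$markers)
  if (length(unknown)) {
    stop("signature marker(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  .with_seed(seed, {
    m <- length(panel$markers)
    island <- stats::runif(n_cells) < signature$island_fraction

    shift <- stats::setNames(rep(0, m), panel$markers)
    shift[names(signature$shift)] <- signature$shift
    ishift <- stats::setNames(rep(0, m), panel$markers)
    ishift[names(signature$island_shift)] <- signature$island_shift

    scaled <- matrix(stats::rnorm(n_cells * m), n_cells, m)
    scaled <- sweep(scaled, 2, panel$baseline_spread, "*")
    centers <- outer(!island, shift, "*") + outer(island, ishift, "*")
    scaled <- scaled + centers +
      matrix(panel$baseline_location, n_cells, m, byrow = TRUE)
    raw_fun <- sweep(sinh(scaled), 2, panel$cofactors, "*")

    # scatter: correlated log-normals; doublets double the area channels
    z1 <- stats::rnorm(n_cells); z2 <- stats::rnorm(n_cells)
    z3 <- 0.8 * z1 + sqrt(1 - 0.8^2) * stats::rnorm(n_cells)
    fsc_h <- exp(11 + 0.18 * z1)
    fsc_a <- exp(11.05 + 0.18 * z1 + 0.03 * z2)
    ssc_a <- exp(10.5 + 0.30 * z3)
    doublet <- stats::runif(n_cells) < doublet_fraction
    fsc_a[doublet] <- 2 * fsc_a[doublet]
    ssc_a[doublet] <- 2 * ssc_a[doublet]

    uptake <- exp(8 + 0.25 * stats::rnorm(n_cells))      # Ax750, all stained
    dead <- stats::runif(n_cells) < dead_fraction
    viab <- exp(ifelse(dead, 9.5, 6.5) + 0.35 * stats::rnorm(n_cells))  # Ax700

    values <- cbind(`FSC-A` = fsc_a, `FSC-H` = fsc_h, `SSC-A` = ssc_a,
                    Ax750 = uptake, Ax700 = viab, raw_fun,
                    truth_island = as.numeric(island))
    colnames(values) <- c(.aux_channels()$name, panel$markers, "truth_island")
    values[, seq_len(ncol(values) - 1)] <-
      pmax(values[, seq_len(ncol(values) - 1)], floor)
    event_table(
      values,
      roles = c(.aux_channels()$role, rep("functional", m), "ground_truth"),
      cofactors = c(rep(NA, 5), panel$cofactors, NA)
    )
  })
}

#' Pool barcoded wells into one synthetic tube
#'
#' Appends the two barcode-dye channels to each well's events, drawing dye
#' intensities (arcsinh scale) around the well's level centers and mapping
#' back to raw scale, optionally mixes the dye channels with a known
#' linear spillover matrix, attaches ground-truth well labels, and
#' row-binds everything into a single pooled event table — the synthetic
#' equivalent of pooling stained wells into one cytometry tube.
#'
#' @param plate plate-map data.frame (see [rocaglate_plate_map()]); one
#'   row per well, `well_id` unique.
#' @param scheme a [barcode_scheme()]; its capacity must be at least the
#'   number of plate wells (wells use the first assignments in order).
#' @param per_well_events list of `event_table`s, one per plate row.
#' @param seed integer seed.
#' @param spillover 2x2 mixing matrix applied to the raw dye channels
#'   (default identity = no spillover).
#' @return A pooled `event_table` with barcode-dye channels and
#'   annotations (`well_id`, `compound_id`, `subclass`, ...) carried as
#'   ground truth.
#' @export
generate_barcoded_pool <- function(plate, scheme, per_well_events,
                                   seed = NULL, spillover = diag(2)) {
  stopifnot(inherits(scheme, "barcode_scheme"), is.list(per_well_events))
  if (anyDuplicated(plate$well_id)) stop("plate well_ids must be unique")
  n_wells <- nrow(plate)
  if (length(per_well_events) != n_wells) {
    stop("need one event table per plate well (", n_wells, ")")
  }
  capacity <- nrow(scheme$well_assignment)
  if (n_wells > capacity) {
    stop("plate has ", n_wells, " wells but scheme capacity is ", capacity)
  }
  stopifnot(is.matrix(spillover), all(dim(spillover) == c(2, 2)))
  .with_seed(seed, {
    pooled <- vector("list", n_wells)
    for (w in seq_len(n_wells)) {
      tab <- per_well_events[[w]]
      stopifnot(inherits(tab, "event_table"))
      n <- n_events(tab)
      lev <- scheme$well_assignment[w, ]
      scaled <- cbind(
        stats::rnorm(n, scheme$level_centers[[1]][lev$level_1],
                     scheme$level_spread[[1]][lev$level_1]),
        stats::rnorm(n, scheme$level_centers[[2]][lev$level_2],
                     scheme$level_spread[[2]][lev$level_2])
      )
      raw_dye <- sweep(sinh(scaled), 2, scheme$dye_cofactors, "*")
      raw_dye <- raw_dye %*% t(spillover)
      colnames(raw_dye) <- scheme$dyes
      values <- cbind(tab$values, raw_dye)
      ann <- data.frame(
        well_id = rep(plate$well_id[w], n),
        compound_id = rep(plate$compound_id[w], n),
        chemotype = rep(plate$chemotype[w], n),
        subclass = rep(plate$subclass[w], n),
        dose_uM = rep(plate$dose_uM[w], n),
        cell_type = rep(plate$cell_type[w], n),
        stringsAsFactors = FALSE
      )
      pooled[[w]] <- event_table(
        values,
        roles = c(tab$channel_meta$role, rep("barcode_dye", 2)),
        cofactors = c(tab$channel_meta$cofactor, scheme$dye_cofactors),
        annotations = ann
      )
    }
    bind_events(pooled)
  })
}

#' Four-parameter log-logistic response curve
#'
#' Mean response at dose `x`:
#' `f(x) = c + (d - c) / (1 + (x / e)^b)`.
#' With hill slope `b < 0` the curve rises from the lower asymptote `c`
#' at dose 0 to the upper asymptote `d` at saturating dose; `e` is the
#' EC50. Dose 0 is evaluated as the asymptotic limit, so there is no log
#' singularity.
#'
#' @param x nonnegative dose vector.
#' @param b hill slope; @param c lower/left asymptote; @param d opposite
#'   asymptote; @param e EC50 (> 0), in the dose units.
#' @return response vector, same length as `x`.
#' @export
fourpl <- function(x, b, c, d, e) {
  stopifnot(e > 0, all(x >= 0))
  out <- numeric(length(x))
  zero <- x == 0
  out[!zero] <- c + (d - c) / (1 + (x[!zero] / e)^b)
  out[zero] <- if (b > 0) d else c   # limit x -> 0+
  out
}

#' Generate dose-response wells
#'
#' For each dose, draws `n_cells` events in which the fraction of cells
#' shifted into the positive (high-marker) region equals the 4PL response
#' at that dose (responses are percentages; fraction = response / 100).
#' Positive cells have the marker's arcsinh location raised by
#' `positive_shift`, far above the vehicle distribution, so downstream
#' percent-positive gating recovers the curve.
#'
#' @param panel a [marker_panel()].
#' @param true_params list with elements `b`, `c`, `d`, `e` (percent-scale
#'   asymptotes, EC50 in the dose units).
#' @param doses nonnegative dose vector; default is the eight-point design
#'   0.01, 0.05, 0.1, 0.5, 1, 5, 10 and 0 uM.
#' @param n_cells events per dose.
#' @param seed integer seed.
#' @param marker responding marker (default `"gH2AX"`).
#' @param positive_shift arcsinh-scale shift of positive cells.
#' @return Named list of `event_table`s, one per dose (names = doses);
#'   each carries a `truth_positive` ground-truth channel.
#' @export
generate_dose_response <- function(panel, true_params,
                                   doses = c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 0),
                                   n_cells = 5000, seed = NULL,
                                   marker = "gH2AX", positive_shift = 3.0) {
  stopifnot(inherits(panel, "marker_panel"), marker %in% panel$markers)
  if (any(doses < 0)) stop("doses must be nonnegative")
  p <- true_params
  stopifnot(all(c("b", "c", "d", "e") %in% names(p)))
  .with_seed(seed, {
    out <- vector("list", length(doses))
    for (i in seq_along(doses)) {
      frac <- fourpl(doses[i], p$b, p$c, p$d, p$e) / 100
      stopifnot(frac >= 0, frac <= 1)
      tab <- generate_well_events(panel, effect_signature(), n_cells)
      pos <- stats::runif(n_cells) < frac
      sc <- asinh(tab$values[pos, marker] / panel$cofactors[marker]) +
        positive_shift
      tab$values[pos, marker] <- sinh(sc) * panel$cofactors[marker]
      tab$values <- cbind(tab$values, truth_positive = as.numeric(pos))
      tab <- event_table(tab$values,
                         roles = c(tab$channel_meta$role, "ground_truth"),
                         cofactors = c(tab$channel_meta$cofactor, NA))
      out[[i]] <- tab
    }
    names(out) <- as.character(doses)
    out
  })
}
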
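#' Event table: events x channels with channel roles
#'
#' The central container of the package: a numeric matrix of per-event
#' (per-cell) channel intensities, a per-channel metadata table assigning
#' each channel a role, and optional per-event annotations (well, compound,
#' subclass, ...). Intensities are stored linear (untransformed); the
#' arcsinh transform is an explicit stage ([arcsinh_scale()]) and its state
#' is tracked per channel in `channel_meta$scaled`.
#'
#' Channel roles:
#' \describe{
#'   \item{scatter}{forward/side scatter (FSC-A, FSC-H, SSC-A)}
#'   \item{barcode_dye}{fluorescent-cell-barcoding dye channels}
#'   \item{viability}{viability dye (dead-cell exclusion)}
#'   \item{uptake}{barcode uptake control dye}
#'   \item{functional}{phospho-protein / functional readouts}
#'   \item{ground_truth}{simulator truth columns (well index, island flag);
#'     never consumed by analysis stages}
#' }
#'
#' @param values numeric matrix, events in rows, channels in columns;
#'   column names are the channel names.
#' @param roles character vector of channel roles, one per column of
#'   `values`.
#' @param cofactors optional numeric vector of per-channel arcsinh
#'   cofactors (NA where not applicable).
#' @param annotations optional data.frame of per-event annotations with
#'   `nrow(values)` rows.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, roles, cofactors = NULL, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(colnames(values))) stop("`values` must have channel (column) names")
  if (anyDuplicated(colnames(values))) stop("channel names must be unique")
  if (anyNA(values)) stop("event values must not contain NA/NaN")
  roles <- match.arg(roles, .channel_roles, several.ok = TRUE)
  if (length(roles) != ncol(values)) {
    stop("one role per channel required (", ncol(values), " channels, ",
         length(roles), " roles)")
  }
  if (is.null(cofactors)) cofactors <- rep(NA_real_, ncol(values))
  stopifnot(length(cofactors) == ncol(values))
  if (any(!is.na(cofactors) & cofactors <= 0)) stop("cofactors must be > 0")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != nrow(values)) {
      stop("annotations must have one row per event")
    }
  }
  structure(
    list(
      values = values,
      channel_meta = data.frame(
        name = colnames(values),
        role = roles,
        cofactor = as.numeric(cofactors),
        scaled = FALSE,
        stringsAsFactors = FALSE
      ),
      annotations = annotations
    ),
    class = "event_table"
  )
}

.channel_roles <- c("scatter", "barcode_dye", "viability", "uptake",
                    "functional", "ground_truth")

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", n_events(x), " events x ", ncol(x$values),
      " channels\n", sep = "")
  tab <- table(x$channel_meta$role)
  cat("  roles: ", paste(names(tab), tab, sep = ":", collapse = ", "), "\n",
      sep = "")
  if (any(x$channel_meta$scaled)) {
    cat("  arcsinh-scaled: ",
        paste(x$channel_meta$name[x$channel_meta$scaled], collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$annotations)) {
    cat("  annotations: ", paste(names(x$annotations), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of events in an event table
#' @param table an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "event_table"))
  nrow(table$values)
}

#' Channel names by role
#' @param table an `event_table`.
#' @param role one of the channel roles, or NULL for all channels.
#' @return character vector of channel names.
#' @export
channels <- function(table, role = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(role)) return(table$channel_meta$name)
  role <- match.arg(role, .channel_roles)
  table$channel_meta$name[table$channel_meta$role == role]
}

#' Subset events
#' @param table an `event_table`.
#' @param idx logical or integer index over events.
#' @return an `event_table` with the selected events.
#' @export
subset_events <- function(table, idx) {
  stopifnot(inherits(table, "event_table"))
  table$values <- table$values[idx, , drop = FALSE]
  if (!is.null(table$annotations)) {
    table$annotations <- table$annotations[idx, , drop = FALSE]
    rownames(table$annotations) <- NULL
  }
  rownames(table$values) <- NULL
  table
}

#' Row-bind event tables with identical channel layout
#' @param tables list of `event_table` objects sharing channel names,
#'   roles and scaling state.
#' @return a single combined `event_table`.
#' @export
bind_events <- function(tables) {
  stopifnot(length(tables) >= 1)
  meta <- tables[[1]]$channel_meta
  for (t in tables) {
    stopifnot(inherits(t, "event_table"))
    if (!identical(t$channel_meta$name, meta$name) ||
        !identical(t$channel_meta$scaled, meta$scaled)) {
      stop("event tables have incompatible channel layout or scaling state")
    }
  }
  values <- do.call(rbind, lapply(tables, function(t) t$values))
  rownames(values) <- NULL
  ann <- NULL
  if (!is.null(tables[[1]]$annotations)) {
    ann <- do.call(rbind, lapply(tables, function(t) t$annotations))
    rownames(ann) <- NULL
  }
  out <- tables[[1]]
  out$values <- values
  out$annotations <- ann
  out
}

# internal: matrix of the named channels, with checks
.channel_matrix <- function(table, markers, require_scaled = FALSE) {
  missing <- setdiff(markers, table$channel_meta$name)
  if (length(missing)) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  if (require_scaled) {
    sc <- table$channel_meta$scaled[match(markers, table$channel_meta$name)]
    if (!all(sc)) {
      stop("channel(s) not arcsinh-scaled: ",
           paste(markers[!sc], collapse = ", "))
    }
  }
  table$values[, markers, drop = FALSE]
}

# internal: run code under a fixed RNG seed, restoring global RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
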
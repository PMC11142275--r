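#' Fit per-dye barcode level models
#'
#' For each barcode dye independently, fits a one-dimensional Gaussian
#' mixture with as many components as the scheme has levels, on the
#' arcsinh-scaled dye intensity (using the scheme's dye cofactors). The
#' EM is initialised deterministically from evenly spaced sample
#' quantiles (component `i` of `L` at the `(i - 0.5)/L` quantile, equal
#' weights, common spread), so fits are reproducible and invariant to
#' event order. Components are returned sorted by center.
#'
#' @param table pooled `event_table` containing both dye channels.
#' @param scheme a [barcode_scheme()].
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param weight_floor minimum admissible component weight; a fitted
#'   weight below it marks the fit degenerate and errors, naming the dye.
#' @return A `barcode_levels` object: per dye, `mean`, `sd`, `weight`
#'   (each length = number of levels), plus log-likelihood and iteration
#'   diagnostics.
#' @export
fit_levels <- function(table, scheme, max_iter = 200, tol = 1e-8,
                       weight_floor = NULL) {
  stopifnot(inherits(table, "event_table"), inherits(scheme, "barcode_scheme"))
  total_levels <- sum(scheme$levels_per_dye)
  if (n_events(table) < 10 * total_levels) {
    stop("need at least ", 10 * total_levels, " events to fit ",
         total_levels, " levels")
  }
  models <- vector("list", 2)
  for (d in 1:2) {
    dye <- scheme$dyes[d]
    x <- asinh(.channel_matrix(table, dye)[, 1] / scheme$dye_cofactors[d])
    L <- scheme$levels_per_dye[d]
    floor_d <- if (is.null(weight_floor)) 0.1 / L else weight_floor
    fit <- .em_gmm_1d(x, L, max_iter = max_iter, tol = tol)
    if (min(fit$weight) < floor_d) {
      stop("degenerate mixture fit for dye '", dye, "': component weight ",
           format(min(fit$weight), digits = 3), " below floor ",
           format(floor_d, digits = 3))
    }
    models[[d]] <- fit
  }
  names(models) <- scheme$dyes
  structure(list(models = models, scheme = scheme), class = "barcode_levels")
}

# internal: 1-D Gaussian mixture EM, deterministic quantile initialisation
.em_gmm_1d <- function(x, L, max_iter = 200, tol = 1e-8, sd_floor = 1e-4) {
  n <- length(x)
  if (L == 1) {
    return(list(mean = mean(x), sd = max(stats::sd(x), sd_floor),
                weight = 1, loglik = NA_real_, iter = 0L))
  }
  mu <- as.numeric(stats::quantile(x, (seq_len(L) - 0.5) / L, type = 7))
  sigma <- rep(max(stats::sd(x) / L, sd_floor), L)
  w <- rep(1 / L, L)
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(L),
                   function(k) w[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sigma <- pmax(sigma, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mean = mu[ord], sd = sigma[ord], weight = w[ord],
       loglik = ll, iter = iter)
}

#' Assign pooled events to wells
#'
#' Each event is assigned to the `(level_1, level_2)` pair maximising the
#' product of per-dye posterior responsibilities; the confidence is that
#' product. Events below `min_confidence`, or whose best level pair is
#' not an occupied barcode slot, are left unassigned and are excluded
#' from all downstream statistics.
#'
#' @param table pooled `event_table`.
#' @param levels a [fit_levels()] result.
#' @param min_confidence confidence threshold in `[0, 1]` (default 0.9).
#' @param wells_in_use optional character vector of well ids actually
#'   occupied (defaults to all scheme wells); events mapping to unused
#'   slots are unassigned.
#' @return A `barcode_assignment` object: data.frame `assignment`
#'   (`well_id`, NA when unassigned, and `confidence`), plus the level
#'   models.
#' @export
assign_wells <- function(table, levels, min_confidence = 0.9,
                         wells_in_use = NULL) {
  stopifnot(inherits(table, "event_table"), inherits(levels, "barcode_levels"))
  scheme <- levels$scheme
  post <- vector("list", 2)
  best_level <- matrix(0L, n_events(table), 2)
  best_post <- matrix(0, n_events(table), 2)
  for (d in 1:2) {
    dye <- scheme$dyes[d]
    x <- asinh(.channel_matrix(table, dye)[, 1] / scheme$dye_cofactors[d])
    m <- levels$models[[d]]
    L <- length(m$mean)
    dens <- vapply(seq_len(L),
                   function(k) m$weight[k] * stats::dnorm(x, m$mean[k], m$sd[k]),
                   numeric(length(x)))
    dens <- matrix(dens, ncol = L)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    best_level[, d] <- max.col(resp, ties.method = "first")
    best_post[, d] <- resp[cbind(seq_len(nrow(resp)), best_level[, d])]
  }
  confidence <- best_post[, 1] * best_post[, 2]
  wa <- scheme$well_assignment
  slot <- match(paste(best_level[, 1], best_level[, 2]),
                paste(wa$level_1, wa$level_2))
  well <- wa$well_id[slot]
  if (!is.null(wells_in_use)) well[!(well %in% wells_in_use)] <- NA
  well[confidence < min_confidence] <- NA
  structure(
    list(assignment = data.frame(well_id = well, confidence = confidence,
                                 stringsAsFactors = FALSE),
         levels = levels, min_confidence = min_confidence),
    class = "barcode_assignment"
  )
}

#' Deconvolute a pooled tube into per-well tables
#'
#' Convenience wrapper: fits level models, assigns events, and splits the
#' pooled table into one `event_table` per assigned well (the assigned
#' well id is written into the annotations). Unassigned events are
#' dropped.
#'
#' @param table pooled `event_table`.
#' @param scheme a [barcode_scheme()].
#' @param min_confidence assignment confidence threshold.
#' @param wells_in_use optional occupied wells (see [assign_wells()]).
#' @return list with `wells` (named list of per-well tables),
#'   `assignment` (the `barcode_assignment`), and `unassigned_fraction`.
#' @export
debarcode <- function(table, scheme, min_confidence = 0.9,
                      wells_in_use = NULL) {
  levels <- fit_levels(table, scheme)
  asg <- assign_wells(table, levels, min_confidence, wells_in_use)
  well <- asg$assignment$well_id
  keep_wells <- unique(well[!is.na(well)])
  keep_wells <- keep_wells[order(match(keep_wells,
                                       scheme$well_assignment$well_id))]
  out <- lapply(keep_wells, function(w) {
    tab <- subset_events(table, which(!is.na(well) & well == w))
    if (is.null(tab$annotations)) {
      tab$annotations <- data.frame(well_id = rep(w, n_events(tab)),
                                    stringsAsFactors = FALSE)
    } else {
      tab$annotations$assigned_well <- w
    }
    tab
  })
  names(out) <- keep_wells
  list(wells = out, assignment = asg,
       unassigned_fraction = mean(is.na(well)))
}
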
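#' Assemble and validate a run configuration
#'
#' A single configuration object driving [run_pipeline()]: simulation
#' sizes, panel, plate map, barcode scheme, QC bounds, KNN-enrichment
#' settings, MEM settings, screen thresholds and seeds. Can be built
#' from a YAML file (scalar settings only) or programmatically; defaults
#' reproduce the package's standard study conditions (45-condition
#' rocaglate-style plate, 8x6 barcodes, k = 60, hotspot cutoffs
#' 0.95/0.05, 15% positivity threshold, 5% island threshold).
#'
#' @param config named list (or path to a YAML file) overriding defaults;
#'   nested lists are merged shallowly per section.
#' @return A validated `run_config` object.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    n_cells_per_well = 400L,
    panel = marker_panel(),
    plate = rocaglate_plate_map(),
    scheme = barcode_scheme(),
    qc = default_qc_spec(),
    input_fcs = NULL,
    debarcode = list(min_confidence = 0.9),
    trex = list(k = 60, hotspot_hi = 0.95, hotspot_lo = 0.05,
                perplexity = 60, max_iter = 1000, per_group_n = NULL),
    mem = list(threshold = 5, iqr_floor = 0.5),
    screen = list(hit_mode = "pooled", pct_positive_threshold = 15,
                  island_threshold = 5, q = 99, marker = "gH2AX",
                  vehicle_well = NULL)
  )
  cfg <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !inherits(defaults[[nm]], c(
        "marker_panel", "barcode_scheme", "qc_gate_spec")) &&
        is.list(config[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  # fail-fast validation before any compute
  stopifnot(inherits(cfg$panel, "marker_panel"),
            inherits(cfg$scheme, "barcode_scheme"),
            inherits(cfg$qc, "qc_gate_spec"))
  if (anyNA(cfg$panel$cofactors) || any(cfg$panel$cofactors <= 0)) {
    stop("config validation: every panel marker needs a positive cofactor")
  }
  if (!cfg$screen$marker %in% cfg$panel$markers) {
    stop("config validation: screen marker '", cfg$screen$marker,
         "' not in panel")
  }
  if (!is.null(cfg$input_fcs) && !file.exists(cfg$input_fcs)) {
    stop("config validation: input_fcs not found: ", cfg$input_fcs)
  }
  with(cfg$trex, stopifnot(k >= 1, hotspot_lo >= 0,
                           hotspot_lo < hotspot_hi, hotspot_hi <= 1))
  structure(cfg, class = "run_config")
}

#' Run the screening pipeline end-to-end
#'
#' Stages: (1) simulate a pooled barcoded tube from the plate map (or
#' read `input_fcs`); (2) deconvolute barcodes into wells; (3) QC-gate
#' and arcsinh-scale; (4) per-compound fold changes and hit selection
#' against the vehicle-derived threshold; (5) percent-positive gating of
#' the screen marker against the vehicle percentile cutoff; (6)
#' KNN-enrichment comparison of each rocaglate subclass vs pooled
#' vehicles with degree-of-difference; (7) island auto-gating on the
#' "RP vs others" comparison, percent-in-island per compound, and the
#' island's MEM label against the statistical-null reference. All
#' randomness derives from `config$seed`; rerunning with the same config
#' reproduces every number.
#'
#' @param config a [run_config()] (or list/path coerced through it).
#' @param out_dir output directory (created); receives per-stage CSV/JSON
#'   outputs and `manifest.json`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  plate <- config$plate
  panel <- config$panel

  # stage 1: input events
  if (is.null(config$input_fcs)) {
    wells <- lapply(seq_len(nrow(plate)), function(w) {
      sig <- if (plate$subclass[w] %in% c("RP", "ADR", "RR")) {
        subclass_signature(plate$subclass[w])
      } else {
        effect_signature()
      }
      generate_well_events(panel, sig, config$n_cells_per_well,
                           seed = seed + w)
    })
    pooled <- generate_barcoded_pool(plate, config$scheme, wells,
                                     seed = seed + 1000L)
    truth <- pooled$annotations$well_id
    pooled$annotations <- NULL  # analysis must not see ground truth
  } else {
    pooled <- read_events(config$input_fcs)
    truth <- NULL
  }

  # stage 2: debarcode
  deb <- debarcode(pooled, config$scheme,
                   min_confidence = config$debarcode$min_confidence,
                   wells_in_use = plate$well_id)
  utils::write.csv(
    data.frame(event = seq_len(nrow(deb$assignment$assignment)),
               deb$assignment$assignment),
    file.path(out_dir, "assignment.csv"), row.names = FALSE)

  # stage 3: QC + scaling, per well
  qc_reports <- list()
  processed <- lapply(names(deb$wells), function(w) {
    qc <- apply_qc_gates(deb$wells[[w]], config$qc)
    qc_reports[[w]] <<- qc$report
    arcsinh_scale(qc$table)
  })
  names(processed) <- names(deb$wells)

  # stage 4: fold changes + hits (vs first vehicle well)
  vehicle_wells <- plate$well_id[plate$is_vehicle]
  vehicle1 <- if (!is.null(config$screen$vehicle_well)) {
    config$screen$vehicle_well
  } else {
    vehicle_wells[1]
  }
  if (!vehicle1 %in% names(processed)) stop("vehicle well '", vehicle1,
                                            "' missing after debarcoding")
  markers <- panel$markers
  compound_wells <- plate$well_id[!plate$is_vehicle &
                                    plate$subclass != "control"]
  compound_wells <- intersect(compound_wells, names(processed))
  delta <- t(vapply(compound_wells, function(w) {
    fold_change(processed[[w]], processed[[vehicle1]], markers)
  }, stats::setNames(numeric(length(markers)), markers)))
  vdelta <- t(vapply(intersect(vehicle_wells, names(processed)), function(w) {
    fold_change(processed[[w]], processed[[vehicle1]], markers)
  }, stats::setNames(numeric(length(markers)), markers)))
  hits <- select_hits(delta, vdelta, mode = config$screen$hit_mode)

  # stage 5: percent positive on the screen marker
  marker <- config$screen$marker
  cutoff <- percentile(
    .channel_matrix(processed[[vehicle1]], marker)[, 1], config$screen$q)
  pct_pos <- vapply(names(processed), function(w) {
    as.numeric(percent_positive(processed[[w]], marker, cutoff = cutoff))
  }, 0)

  # stage 6: subclass vs vehicle comparisons
  subclasses <- intersect(c("RR", "ADR", "RP"), unique(plate$subclass))
  veh_tab <- bind_events(processed[intersect(vehicle_wells, names(processed))])
  trex_out <- list()
  for (sc in subclasses) {
    sc_wells <- intersect(plate$well_id[plate$subclass == sc],
                          names(processed))
    test_tab <- bind_events(processed[sc_wells])
    sub <- equal_subsample(list(test = test_tab, reference = veh_tab),
                           per_group_n = config$trex$per_group_n,
                           seed = seed + 2000L)
    emb <- embed_cells(sub, markers, method = "tsne",
                       perplexity = config$trex$perplexity,
                       max_iter = config$trex$max_iter, seed = seed + 3000L)
    res <- knn_enrichment(emb, sub$annotations$group, k = config$trex$k,
                          hotspot_hi = config$trex$hotspot_hi,
                          hotspot_lo = config$trex$hotspot_lo)
    trex_out[[sc]] <- list(embedding = emb, subsample = sub, result = res,
                           degree_of_difference = degree_of_difference(res))
  }

  # stage 7: island on "RP vs others"
  island <- NULL
  if ("RP" %in% subclasses) {
    rp_wells <- intersect(plate$well_id[plate$subclass == "RP"],
                          names(processed))
    other_wells <- setdiff(names(processed), rp_wells)
    sub <- equal_subsample(
      list(test = bind_events(processed[rp_wells]),
           reference = bind_events(processed[other_wells])),
      per_group_n = config$trex$per_group_n, seed = seed + 4000L)
    emb <- embed_cells(sub, markers, method = "tsne",
                       perplexity = config$trex$perplexity,
                       max_iter = config$trex$max_iter, seed = seed + 5000L)
    res <- knn_enrichment(emb, sub$annotations$group, k = config$trex$k,
                          hotspot_hi = config$trex$hotspot_hi,
                          hotspot_lo = config$trex$hotspot_lo)
    gate <- auto_island_gate(emb, res,
                             .channel_matrix(sub, marker)[, 1])
    if (!is.null(gate)) {
      pct_island <- island_quantify(emb, gate, sub$annotations$well_id)
      in_gate <- point_in_polygon(emb$coords, gate)
      ref <- mem_reference(sub, markers, kind = "statistical_null")
      lab <- mem_label(subset_events(sub, in_gate), markers, ref,
                       threshold = config$mem$threshold,
                       iqr_floor = config$mem$iqr_floor)
      island <- list(gate = gate, pct_island = pct_island,
                     mem = lab,
                     flagged = names(pct_island)[
                       !is.na(pct_island) &
                         pct_island > config$screen$island_threshold])
    }
  }

  # outputs + manifest
  summary_df <- data.frame(
    well_id = compound_wells,
    compound_id = plate$compound_id[match(compound_wells, plate$well_id)],
    subclass = plate$subclass[match(compound_wells, plate$well_id)],
    hit = unname(hits$hits[compound_wells]),
    pct_positive = unname(pct_pos[compound_wells]),
    pct_positive_flag = unname(pct_pos[compound_wells]) >
      config$screen$pct_positive_threshold,
    stringsAsFactors = FALSE
  )
  summary_df <- cbind(summary_df, delta[compound_wells, , drop = FALSE])
  utils::write.csv(summary_df, file.path(out_dir, "screen_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(trex_out, function(t) t$degree_of_difference),
    file.path(out_dir, "trex.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(island)) {
    jsonlite::write_json(
      list(label = island$mem$label, scaled = as.list(island$mem$scaled),
           pct_island = as.list(island$pct_island),
           flagged = island$flagged),
      file.path(out_dir, "mem.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cytosar")),
    seed = seed,
    n_cells_per_well = config$n_cells_per_well,
    hit_threshold = hits$threshold,
    hit_mode = config$screen$hit_mode,
    pct_positive_cutoff = cutoff,
    pct_positive_threshold = config$screen$pct_positive_threshold,
    island_threshold = config$screen$island_threshold,
    trex = config$trex[c("k", "hotspot_hi", "hotspot_lo", "perplexity",
                         "max_iter")],
    unassigned_fraction = deb$unassigned_fraction
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary_df, hits = hits, trex = trex_out,
                 island = island, debarcode = deb, manifest = manifest,
                 qc_reports = qc_reports, truth = truth))
}

#' Build a human-readable report from a completed run directory
#'
#' Assembles the per-compound table (fold changes, hit flags, percent
#' positive), the per-subclass degree-of-difference values, and the
#' island MEM label into a markdown report; regeneration is idempotent.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file output file (default `report.md` inside `run_dir`).
#' @return invisibly, the report lines.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  needed <- file.path(run_dir, c("screen_summary.csv", "trex.json",
                                 "manifest.json"))
  if (!all(file.exists(needed))) {
    stop("incomplete run directory: missing ",
         paste(basename(needed)[!file.exists(needed)], collapse = ", "))
  }
  summary_df <- utils::read.csv(file.path(run_dir, "screen_summary.csv"))
  trex <- jsonlite::read_json(file.path(run_dir, "trex.json"))
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  lines <- c(
    "# Screen report",
    "",
    sprintf("Seed %s; hit threshold %.4g (%s); %d compounds, %d hits.",
            manifest$seed, manifest$hit_threshold, manifest$hit_mode,
            nrow(summary_df), sum(summary_df$hit)),
    "",
    "## Degree of difference (subclass vs vehicle)",
    vapply(names(trex), function(sc) {
      sprintf("- %s: %.4f", sc, trex[[sc]])
    }, ""),
    "",
    "## Compounds",
    sprintf("- %s (%s): %s, %.1f%% positive%s",
            summary_df$compound_id, summary_df$subclass,
            ifelse(summary_df$hit, "hit", "not a hit"),
            summary_df$pct_positive,
            ifelse(summary_df$pct_positive_flag, " [above threshold]", ""))
  )
  mem_path <- file.path(run_dir, "mem.json")
  if (file.exists(mem_path)) {
    mem <- jsonlite::read_json(mem_path)
    lines <- c(lines, "", "## Island",
               sprintf("MEM label: %s", mem$label),
               if (length(mem$flagged)) {
                 sprintf("Wells above island threshold: %s",
                         paste(unlist(mem$flagged), collapse = ", "))
               } else "No wells above the island threshold.")
  } else {
    lines <- c(lines, "", "## Island", "No island stage output (omitted).")
  }
  writeLines(lines, file)
  invisible(lines)
}
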
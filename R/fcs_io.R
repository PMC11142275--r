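#' Channel-role configuration
#'
#' Maps channel names to roles. Each element is a character vector of
#' exact channel names and/or regular expressions (entries starting with
#' `"^"` or containing `"|"` are treated as patterns). Exact matches win
#' over patterns. The default matches the synthetic generator's layout.
#'
#' @param ... named character vectors, one per role.
#' @return A named list usable as `role_config` in [read_events()].
#' @export
role_config <- function(...) {
  cfg <- list(...)
  bad <- setdiff(names(cfg), .channel_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  cfg
}

#' @rdname role_config
#' @export
default_role_config <- function() {
  role_config(
    scatter = c("FSC-A", "FSC-H", "SSC-A"),
    uptake = "Ax750",
    viability = "Ax700",
    barcode_dye = c("Pacific_Blue", "Pacific_Orange"),
    ground_truth = "^truth_",
    functional = "^(p-|gH2AX|Ki67|c-CAS3|p-HH3)"
  )
}

# internal: resolve per-channel roles from a role_config
.resolve_roles <- function(channel_names, config) {
  roles <- rep(NA_character_, length(channel_names))
  is_pattern <- function(x) grepl("^\\^", x) | grepl("[|\\\\]", x)
  for (role in names(config)) {         # exact names first
    spec <- config[[role]]
    roles[channel_names %in% spec[!is_pattern(spec)]] <- role
  }
  for (role in names(config)) {
    for (pat in config[[role]][is_pattern(config[[role]])]) {
      hit <- grepl(pat, channel_names) & is.na(roles)
      roles[hit] <- role
    }
  }
  if (anyNA(roles)) {
    stop("unresolved channel role(s): ",
         paste(channel_names[is.na(roles)], collapse = ", "))
  }
  for (mandatory in c("scatter", "functional")) {
    if (!any(roles == mandatory)) {
      stop("role resolution found no '", mandatory, "' channel")
    }
  }
  roles
}

#' Read events from FCS 3.1 or CSV
#'
#' Reads an event file written by [write_events()] (FCS 3.1, float data)
#' or the package's CSV dialect (header = channel names, one row per
#' event). Intensities are returned raw (linear); channel roles are
#' resolved from `role_config` unless the file itself carries role
#' metadata (FCS files written by this package do).
#'
#' @param path file path; format chosen by extension (`.fcs` vs `.csv`).
#' @param role_config a [role_config()]; used when the file has no
#'   embedded role metadata.
#' @param cofactors optional [cofactor_map()] attached to functional
#'   channels.
#' @return An `event_table`.
#' @export
read_events <- function(path, role_config = default_role_config(),
                        cofactors = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    .read_fcs(path, role_config)
  } else {
    .read_events_csv(path, role_config)
  }
  if (!is.null(cofactors)) tab <- set_cofactors(tab, cofactors)
  tab
}

#' Write events to FCS 3.1 or CSV
#'
#' FCS 3.1 files carry single-precision float data, channel roles,
#' cofactors and scaling state as custom TEXT keywords, and annotation
#' columns as integer-coded extra parameters (decoded on read), so a
#' write/read round trip preserves the table up to float precision.
#' CSV files hold channel columns plus annotation columns.
#'
#' @param table an `event_table`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    .write_fcs(table, path)
  } else {
    df <- as.data.frame(table$values)
    if (!is.null(table$annotations)) df <- cbind(df, table$annotations)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# ---- minimal FCS 3.1 implementation (list-mode, $DATATYPE F) ----------------

.write_fcs <- function(table, path) {
  values <- table$values
  meta <- table$channel_meta
  ann <- table$annotations
  ann_keys <- character(0)
  if (!is.null(ann) && ncol(ann) > 0) {
    # annotation columns become integer-coded extra parameters
    for (nm in names(ann)) {
      col <- ann[[nm]]
      if (is.numeric(col)) {
        values <- cbind(values, as.numeric(col))
        ann_keys <- c(ann_keys, sprintf("CYTOSARann%s/num", nm))
      } else {
        f <- factor(col)
        values <- cbind(values, as.numeric(as.integer(f)))
        ann_keys <- c(ann_keys,
                      sprintf("CYTOSARann%s/%s", nm,
                              paste(levels(f), collapse = "\t")))
      }
      colnames(values)[ncol(values)] <- paste0("ann_", nm)
    }
  }
  n <- nrow(values); p <- ncol(values)
  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p)
  )
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dN", j), colnames(values)[j],
            sprintf("$P%dR", j), "262144")
    if (j <= nrow(meta)) {
      kw <- c(kw, sprintf("CYTOSARP%dROLE", j), meta$role[j],
              sprintf("CYTOSARP%dSCALED", j),
              if (meta$scaled[j]) "1" else "0")
      if (!is.na(meta$cofactor[j])) {
        kw <- c(kw, sprintf("CYTOSARP%dCOFACTOR", j),
                format(meta$cofactor[j], digits = 17))
      }
    }
  }
  for (i in seq_along(ann_keys)) {
    kw <- c(kw, sprintf("CYTOSARANN%d", i), ann_keys[i])
  }
  delim <- "\x0c"  # form feed: cannot occur in our keys/values
  text_body <- paste0(delim, paste(kw, collapse = delim), delim)
  header_len <- 58L  # "FCS3.1" + 4 spaces + 6 x 8-char offsets
  text_start <- header_len
  # placeholders are fixed-width, so text length is stable on substitution
  text_len <- nchar(text_body, type = "bytes") + 2 * (10 - 4)
  data_start <- text_start + text_len
  n_bytes <- 4L * n * p
  data_end <- if (n_bytes > 0) data_start + n_bytes - 1 else 0L
  text_body <- sub("%BD%", sprintf("%010d", data_start), text_body, fixed = TRUE)
  text_body <- sub("%ED%", sprintf("%010d", data_end), text_body, fixed = TRUE)
  text_end <- text_start + nchar(text_body, type = "bytes") - 1
  hdr_num <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ", hdr_num(text_start), hdr_num(text_end),
                   hdr_num(if (n_bytes > 0) data_start else 0),
                   hdr_num(if (n_bytes > 0 && data_end <= 99999999) data_end else 0),
                   sprintf("%8d", 0), sprintf("%8d", 0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  if (n_bytes > 0) {
    writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_fcs <- function(path, role_config) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:6]) != "FCS3.1") stop("not an FCS 3.1 file: ", path)
  off <- function(i) {
    as.integer(trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)])))
  }
  text <- rawToChar(raw[(off(1) + 1):(off(2) + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, keys)
  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L") {
    stop("only list-mode float FCS supported")
  }
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  ch_names <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]], "")
  if (n > 0) {
    bd <- as.integer(kw[["$BEGINDATA"]])
    vec <- readBin(raw[(bd + 1):length(raw)], "numeric", n * p,
                   size = 4, endian = "little")
    values <- matrix(vec, nrow = n, ncol = p, byrow = TRUE)
  } else {
    values <- matrix(numeric(0), 0, p)
  }
  colnames(values) <- ch_names

  is_ann <- grepl("^ann_", ch_names)
  ann <- NULL
  ann_specs <- kw[grepl("^CYTOSARANN[0-9]+$", names(kw))]
  if (length(ann_specs)) {
    ann <- data.frame(row.names = seq_len(n))
    for (spec in ann_specs) {
      sep <- regexpr("/", spec, fixed = TRUE)
      nm <- substr(spec, nchar("CYTOSARann") + 1, sep - 1)
      enc <- substr(spec, sep + 1, nchar(spec))
      col <- values[, paste0("ann_", nm)]
      ann[[nm]] <- if (identical(enc, "num")) col else {
        strsplit(enc, "\t", fixed = TRUE)[[1]][as.integer(col)]
      }
    }
  }
  values <- values[, !is_ann, drop = FALSE]
  p_data <- ncol(values)

  role_key <- sprintf("CYTOSARP%dROLE", seq_len(p_data))
  if (all(role_key %in% names(kw))) {
    roles <- unname(vals[match(role_key, keys)])
    cof <- vapply(seq_len(p_data), function(j) {
      k <- sprintf("CYTOSARP%dCOFACTOR", j)
      if (k %in% names(kw)) as.numeric(kw[[k]]) else NA_real_
    }, 0)
    scaled <- vapply(seq_len(p_data), function(j) {
      identical(kw[[sprintf("CYTOSARP%dSCALED", j)]], "1")
    }, TRUE)
  } else {
    roles <- .resolve_roles(colnames(values), role_config)
    cof <- rep(NA_real_, p_data)
    scaled <- rep(FALSE, p_data)
  }
  out <- event_table(values, roles, cof, annotations = ann)
  out$channel_meta$scaled <- scaled
  out
}

.read_events_csv <- function(path, role_config) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  numeric_cols <- vapply(df, is.numeric, TRUE)
  # try to resolve roles over the numeric columns; non-matching character
  # columns become annotations
  ann_cols <- names(df)[!numeric_cols]
  values <- as.matrix(df[numeric_cols])
  if (anyNA(values)) stop("event values must not contain NA/NaN")
  roles <- .resolve_roles(colnames(values), role_config)
  ann <- if (length(ann_cols)) df[ann_cols] else NULL
  event_table(values, roles, annotations = ann)
}

# ---- plate-map and cofactor I/O ---------------------------------------------

#' Read / write a plate-map CSV
#'
#' Columns: `well_id`, `compound_id`, `chemotype`, `subclass`, `dose_uM`,
#' `cell_type`, `is_vehicle`.
#'
#' @param path CSV path.
#' @return data.frame (read) or `path` invisibly (write).
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well_id", "compound_id", "chemotype", "subclass", "dose_uM",
              "cell_type", "is_vehicle")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("plate map missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$well_id)) stop("plate map well_ids must be unique")
  if (any(df$is_vehicle & df$dose_uM != 0)) {
    stop("vehicle wells must have dose 0")
  }
  df
}

#' @rdname read_plate_map
#' @param plate plate-map data.frame.
#' @export
write_plate_map <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Cofactor map
#'
#' Per-marker arcsinh cofactors with a default for unlisted markers.
#'
#' @param ... named cofactor values (all > 0).
#' @param default default cofactor for markers not named (default 6000,
#'   the standard panel setting).
#' @return A `cofactor_map` object.
#' @export
cofactor_map <- function(..., default = 6000) {
  co <- c(...)
  if (length(co) && (is.null(names(co)) || any(names(co) == ""))) {
    stop("cofactors must be named")
  }
  if (any(c(co, default) <= 0)) stop("cofactors must be > 0")
  structure(list(cofactors = co, default = default), class = "cofactor_map")
}

#' @rdname cofactor_map
#' @param map a `cofactor_map`.
#' @param markers marker names to look up.
#' @export
lookup_cofactor <- function(map, markers) {
  stopifnot(inherits(map, "cofactor_map"))
  out <- stats::setNames(rep(map$default, length(markers)), markers)
  hit <- intersect(names(map$cofactors), markers)
  out[hit] <- map$cofactors[hit]
  out
}

#' Attach cofactors to a table's functional channels
#' @param table an `event_table`.
#' @param map a [cofactor_map()].
#' @return the table with `channel_meta$cofactor` filled for functional
#'   channels.
#' @export
set_cofactors <- function(table, map) {
  stopifnot(inherits(table, "event_table"))
  fun <- table$channel_meta$role == "functional"
  table$channel_meta$cofactor[fun] <-
    lookup_cofactor(map, table$channel_meta$name[fun])
  table
}
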
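#' Recognized retinal layer names
#'
#' The closed vocabulary of segmented layers and composite zones used
#' throughout the package: the composites RETINA (full retinal thickness),
#' INNER (RNFL + GCL + IPL + INL) and OUTER (photoreceptor elements), the
#' individual layers RNFL, GCL, IPL, INL, OPL, ONL, RPE, and CMT (central
#' macular thickness, the 1-mm ETDRS disc). Unknown layer names are rejected
#' at parse time.
#'
#' @return Character vector of valid layer names.
#' @export
layer_names <- function() {
  c("RETINA", "INNER", "RNFL", "GCL", "IPL", "INL",
    "CMT", "OPL", "ONL", "OUTER", "RPE")
}

#' The four 3-mm-ring ETDRS quadrants
#' @return Character vector of quadrant names.
#' @export
ring_quadrants <- function() c("superior", "nasal", "inferior", "temporal")

#' Column-role schema for cohort tables
#'
#' Maps the roles the reader needs (patient, eye, group, day, layer,
#' thickness, and optionally sector and qc) onto the column names of a
#' delimited file. With `sector = NULL` the file is expected to hold one row
#' per (scan, layer) carrying the middle-ring mean thickness directly; with a
#' sector column the file holds one row per (scan, layer, quadrant) and the
#' reader aggregates the four 3-mm-ring quadrants via [middle_ring_mean()].
#'
#' @param patient,eye,group,day,layer,thickness Column names for the
#'   mandatory roles.
#' @param sector Optional column name holding quadrant labels
#'   (`r paste(ring_quadrants(), collapse = ", ")`).
#' @param qc Optional column name for a logical segmentation-QC flag;
#'   when absent all records are assumed to have passed QC.
#' @return A named list of class `cohort_schema`.
#' @export
cohort_schema <- function(patient = "patient_id", eye = "eye",
                          group = "group", day = "days_since_onset",
                          layer = "layer", thickness = "thickness_um",
                          sector = NULL, qc = "qc_pass") {
  structure(list(patient = patient, eye = eye, group = group, day = day,
                 layer = layer, thickness = thickness, sector = sector,
                 qc = qc),
            class = "cohort_schema")
}

new_cohort <- function(df, provenance = "") {
  structure(df, class = c("crao_cohort", "data.frame"),
            provenance = provenance)
}

#' Construct a validated cohort from a data.frame
#'
#' A cohort is a tidy table with one row per observed (patient, eye, day,
#' layer) thickness. Validation enforces the closed layer vocabulary,
#' positive thicknesses below 1000 um, non-negative days, eye in OD/OS,
#' group in CRAO/CONTROL, and uniqueness of (patient, eye, day, layer).
#'
#' @param df data.frame with columns `patient_id`, `eye`, `group`, `day`,
#'   `layer`, `thickness_um` and optionally `qc_pass` (default `TRUE`).
#' @param provenance Free-text source note stored as an attribute.
#' @return An object of class `crao_cohort` (a data.frame).
#' @export
as_cohort <- function(df, provenance = "") {
  required <- c("patient_id", "eye", "group", "day", "layer", "thickness_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("cohort is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  df <- df[, c(required, "qc_pass")]
  df$patient_id <- as.character(df$patient_id)
  df$eye <- as.character(df$eye)
  df$group <- as.character(df$group)
  df$layer <- as.character(df$layer)
  validate_cohort_rows(df)
  new_cohort(df, provenance)
}

# Row-level validation shared by as_cohort() and read_cohort(). `line` maps
# data rows to source line numbers for error reporting (NULL -> row index).
validate_cohort_rows <- function(df, line = NULL) {
  line <- line %||% seq_len(nrow(df))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stopf("invalid cohort rows (%s) at line(s) %s", what,
            paste(utils::head(line[i], 10), collapse = ", "))
  }
  bad(!df$layer %in% layer_names(), "unknown layer name")
  bad(!df$eye %in% c("OD", "OS"), "eye must be OD or OS")
  bad(!df$group %in% c("CRAO", "CONTROL"), "group must be CRAO or CONTROL")
  bad(!is.finite(df$day) | df$day < 0, "non-numeric or negative day")
  bad(!is.finite(df$thickness_um) | df$thickness_um <= 0 |
        df$thickness_um >= 1000, "thickness must be in (0, 1000) um")
  key <- paste(df$patient_id, df$eye, df$day, df$layer,
               df$sector %||% "", sep = "\r")
  bad(duplicated(key), "duplicate (patient, eye, day, layer) observation")
  invisible(df)
}

#' Read a longitudinal thickness cohort from a delimited text file
#'
#' Reads a comma-separated UTF-8 file with a header row, maps its columns
#' through `schema`, validates every row (malformed rows are reported with
#' their source line numbers), and returns a [as_cohort()] object. When the
#' schema names a sector column, per-quadrant rows are collapsed to the
#' 3-mm-ring mean with [middle_ring_mean()]; rows for the central 1-mm or
#' 6-mm sectors are ignored in that aggregation.
#'
#' @param file Path to a CSV file.
#' @param schema A [cohort_schema()].
#' @param sep Field separator (default comma).
#' @return A `crao_cohort`.
#' @export
read_cohort <- function(file, schema = cohort_schema(), sep = ",") {
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  roles <- c("patient", "eye", "group", "day", "layer", "thickness")
  for (r in roles) {
    if (!schema[[r]] %in% names(raw))
      stopf("schema error: required column '%s' (role '%s') not found in %s",
            schema[[r]], r, file)
  }
  df <- data.frame(
    patient_id = as.character(raw[[schema$patient]]),
    eye = as.character(raw[[schema$eye]]),
    group = as.character(raw[[schema$group]]),
    day = suppressWarnings(as.numeric(raw[[schema$day]])),
    layer = as.character(raw[[schema$layer]]),
    thickness_um = suppressWarnings(as.numeric(raw[[schema$thickness]])),
    stringsAsFactors = FALSE
  )
  df$qc_pass <- if (!is.null(schema$qc) && schema$qc %in% names(raw))
    as.logical(raw[[schema$qc]]) else TRUE
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (!is.null(schema$sector) && schema$sector %in% names(raw)) {
    df$sector <- tolower(as.character(raw[[schema$sector]]))
    df <- collapse_ring_sectors(df, line)
  } else {
    validate_cohort_rows(df, line)
  }
  new_cohort(df[, c("patient_id", "eye", "group", "day", "layer",
                    "thickness_um", "qc_pass")],
             provenance = file)
}

# Collapse quadrant-level rows to the middle-ring mean per (scan, layer).
collapse_ring_sectors <- function(df, line) {
  keep <- df$sector %in% ring_quadrants()
  df <- df[keep, , drop = FALSE]
  line <- line[keep]
  validate_cohort_rows(df, line)
  key <- interaction(df$patient_id, df$eye, df$day, df$layer, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(i) {
    g <- df[i, , drop = FALSE]
    q <- stats::setNames(g$thickness_um, g$sector)
    data.frame(patient_id = g$patient_id[1], eye = g$eye[1],
               group = g$group[1], day = g$day[1], layer = g$layer[1],
               thickness_um = middle_ring_mean(q),
               qc_pass = all(g$qc_pass), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a cohort to CSV
#'
#' Writes the tidy per-(scan, layer) representation; `read_cohort()` on the
#' result is the identity.
#'
#' @param cohort A `crao_cohort`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  df <- as.data.frame(cohort)
  names(df)[names(df) == "day"] <- "days_since_onset"
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Mean thickness of the four 3-mm-ring ETDRS quadrants
#'
#' The analysis unit for every layer is the arithmetic mean of the superior,
#' nasal, inferior and temporal quadrants of the 3-mm ("middle") ETDRS ring.
#'
#' @param quadrants Named numeric vector with entries `superior`, `nasal`,
#'   `inferior`, `temporal` (um). Order is irrelevant.
#' @return The mean thickness (um).
#' @export
#' @examples
#' middle_ring_mean(c(superior = 10, nasal = 20, inferior = 30, temporal = 40))
middle_ring_mean <- function(quadrants) {
  need <- ring_quadrants()
  missing_q <- setdiff(need, names(quadrants))
  if (length(missing_q))
    stopf("missing quadrant(s): %s", paste(missing_q, collapse = ", "))
  vals <- as.numeric(quadrants[need])
  if (any(!is.finite(vals) | vals <= 0 | vals >= 1000))
    stopf("quadrant thicknesses must be finite and in (0, 1000) um")
  mean(vals)
}

#' Remove scans that failed segmentation QC
#'
#' Eyes/scans flagged as poor segmentations (`qc_pass = FALSE`) are dropped;
#' nothing else is altered. The exclusion log lists every removed
#' (patient, eye, day). Idempotent.
#'
#' @param cohort A `crao_cohort`.
#' @return A list with elements `cohort` (the filtered cohort) and
#'   `excluded` (data.frame of removed patient/eye/day rows).
#' @export
apply_exclusions <- function(cohort) {
  df <- as.data.frame(cohort)
  drop <- !df$qc_pass
  log <- unique(df[drop, c("patient_id", "eye", "day")])
  rownames(log) <- NULL
  kept <- df[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0 && nrow(df) > 0)
    warnf("all records were excluded by segmentation QC; cohort is empty")
  list(cohort = new_cohort(kept, attr(cohort, "provenance") %||% ""),
       excluded = log)
}

#' Day-0 baseline points from control eyes
#'
#' Non-affected (contralateral or otherwise control) eyes are taken as the
#' day-0 time point of the decay trajectory: each control eye contributes one
#' (day = 0, thickness) point for the requested layer, to be pooled with the
#' CRAO-eye points before fitting.
#'
#' @param cohort A `crao_cohort`.
#' @param layer A layer name from [layer_names()].
#' @return data.frame with columns `day` (all 0) and `thickness_um`, one row
#'   per control eye carrying the layer. Control eyes without a value for the
#'   layer are skipped. Warns and returns zero rows when no control eyes
#'   exist.
#' @export
baseline_from_controls <- function(cohort, layer) {
  if (!layer %in% layer_names()) stopf("unknown layer '%s'", layer)
  df <- as.data.frame(cohort)
  ctl <- df[df$group == "CONTROL" & df$layer == layer, , drop = FALSE]
  if (!any(df$group == "CONTROL")) {
    warnf("cohort has no control eyes; baseline is empty and fits will rely on CRAO points alone")
    return(data.frame(day = numeric(0), thickness_um = numeric(0)))
  }
  # one point per control eye (first record if several)
  key <- paste(ctl$patient_id, ctl$eye)
  ctl <- ctl[!duplicated(key), , drop = FALSE]
  data.frame(day = rep(0, nrow(ctl)), thickness_um = ctl$thickness_um)
}

#' Per-layer summary of control-eye thicknesses
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' control-eye thickness per layer, with the number of contributing eyes.
#' Layers with a single control observation report `NA` for the SD.
#'
#' @param cohort A `crao_cohort`.
#' @return data.frame with columns `layer`, `mean_um`, `sd_um`, `n`.
#' @export
control_summary <- function(cohort) {
  df <- as.data.frame(cohort)
  ctl <- df[df$group == "CONTROL", , drop = FALSE]
  if (nrow(ctl) == 0) stopf("cohort has no control records to summarize")
  out <- do.call(rbind, lapply(split(ctl, ctl$layer), function(g) {
    data.frame(layer = g$layer[1],
               mean_um = mean(g$thickness_um),
               sd_um = if (nrow(g) > 1) stats::sd(g$thickness_um) else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$layer, layer_names())), , drop = FALSE]
}

#' @export
print.crao_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  n_eyes <- length(unique(paste(df$patient_id, df$eye)))
  cat(sprintf("CRAO thickness cohort: %d observations, %d eyes, %d layers\n",
              nrow(df), n_eyes, length(unique(df$layer))))
  if (nrow(df))
    cat(sprintf("  days %g-%g; groups: %s\n", min(df$day), max(df$day),
                paste(sort(unique(df$group)), collapse = ", ")))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  source:", prov, "\n")
  invisible(x)
}
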
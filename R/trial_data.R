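# Canonical long-format schema: one row per animal per measurement day.
.trial_required <- c("tumor_id", "arm", "animal_id", "day", "volume")
.trial_canonical <- c("tumor_id", "tumor_type", "arm", "animal_id", "day",
                      "volume", "body_weight")

#' Built-in column-name dialects
#'
#' Named presets mapping the canonical fields (`tumor_id`, `tumor_type`,
#' `arm`, `animal_id`, `day`, `volume`, `body_weight`) to the column names
#' used by known public data releases. The `"nibr-pdxe"` preset matches the
#' Novartis PDX encyclopedia export, which carries one animal per
#' model-by-treatment cell and therefore has no animal-id column; a synthetic
#' animal id is derived from the model and treatment labels on read.
#'
#' @return A named list of named character vectors (canonical field ->
#'   source column name).
#' @export
trial_dialects <- function() {
  list(
    "nibr-pdxe" = c(
      tumor_id   = "Model",
      tumor_type = "Tumor Type",
      arm        = "Treatment",
      day        = "Days Post T0",
      volume     = "Volume"
    )
  )
}

# Case-insensitive match of an arm label against conventional control names.
detect_control_arm <- function(arms) {
  hit <- arms[tolower(arms) %in% c("vehicle", "control", "untreated")]
  if (length(hit) >= 1) hit[[1]] else NULL
}

#' Construct a validated PDX trial dataset
#'
#' Wraps a long-format table of repeated tumor-volume measurements (one row
#' per animal per day) as a `trial_dataset`: a tibble with the canonical
#' columns `tumor_id`, `arm`, `animal_id`, `day`, `volume` and the optional
#' `tumor_type` and `body_weight`, plus a `control_arm` attribute naming the
#' vehicle arm and a `meta` attribute recording provenance.
#'
#' @param records A data frame with at least the five required columns.
#'   `day` (days post treatment start) and `volume` (mm^3) must be numeric
#'   or coercible; identifier columns are coerced to character.
#' @param control_arm Label of the vehicle/control arm. When `NULL`, an arm
#'   whose name case-insensitively matches "vehicle", "control" or
#'   "untreated" is used if present.
#' @param meta Named list of provenance information (source path, column
#'   mapping, and the like).
#' @return A `trial_dataset` tibble.
#' @export
trial_dataset <- function(records, control_arm = NULL, meta = list()) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.trial_required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tumor_id", "arm", "animal_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in c("day", "volume", intersect("body_weight", names(records)))) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric '%s' at row(s) %s", col,
                     paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
      }
      records[[col]] <- vn
    }
  }
  if ("tumor_type" %in% names(records)) {
    records$tumor_type <- as.character(records$tumor_type)
  }
  records <- records[, intersect(.trial_canonical, names(records)), drop = FALSE]
  key <- paste(records$tumor_id, records$arm, records$animal_id, records$day,
               sep = "\r")
  if (anyDuplicated(key) > 0L) {
    dup <- which(duplicated(key))
    stop(sprintf("duplicate (tumor, arm, animal, day) measurement at row(s) %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  arms <- unique(records$arm)
  if (is.null(control_arm) && length(arms) > 0L) {
    control_arm <- detect_control_arm(arms)
  }
  if (!is.null(control_arm) && nrow(records) > 0L && !control_arm %in% arms) {
    stop(sprintf("control arm '%s' not present in data", control_arm),
         call. = FALSE)
  }
  structure(records,
            control_arm = control_arm,
            meta = meta,
            class = c("trial_dataset", class(tibble::tibble())))
}

# Rebuild a trial_dataset after dplyr verbs stripped its class/attributes.
as_trial <- function(records, template) {
  trial_dataset(records,
                control_arm = intersect_control(records, template),
                meta = attr(template, "meta"))
}

intersect_control <- function(records, template) {
  ctrl <- attr(template, "control_arm")
  if (!is.null(ctrl) && ctrl %in% unique(records$arm)) ctrl else NULL
}

#' Get or set the control (vehicle) arm of a trial dataset
#'
#' @param ds A [trial_dataset()].
#' @param value Arm label to set.
#' @return The control-arm label (or `NULL`).
#' @export
control_arm <- function(ds) attr(ds, "control_arm")

#' @rdname control_arm
#' @export
`control_arm<-` <- function(ds, value) {
  if (!is.null(value) && !value %in% unique(ds$arm)) {
    stop(sprintf("control arm '%s' not present in data", value), call. = FALSE)
  }
  attr(ds, "control_arm") <- value
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  n_animal <- nrow(unique(as_tbl(x)[, c("tumor_id", "arm", "animal_id")]))
  cat(sprintf(
    "<trial_dataset> %d measurements | %d tumor(s), %d arm(s), %d animal(s)\n",
    nrow(x), length(unique(x$tumor_id)), length(unique(x$arm)), n_animal))
  ctrl <- control_arm(x)
  cat(sprintf("control arm: %s\n", if (is.null(ctrl)) "<unset>" else ctrl))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

as_tbl <- function(ds) {
  out <- tibble::as_tibble(ds)
  attr(out, "control_arm") <- NULL
  attr(out, "meta") <- NULL
  out
}

#' Read a PDX trial table from delimited text
#'
#' Reads a CSV or TSV file of long-format repeated measurements and returns
#' a validated [trial_dataset()]. Columns can be mapped to the canonical
#' schema either explicitly via `column_map` or through a named `dialect`
#' preset (see [trial_dialects()]); by default, canonical column names are
#' taken as-is from the header. When the mapping carries no animal id (as in
#' the `"nibr-pdxe"` dialect, one animal per model-by-treatment cell), an id
#' is synthesized as `<tumor_id>:<arm>`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector, canonical field -> source column
#'   name. Overrides (and extends) the dialect mapping.
#' @param dialect Name of a built-in preset, e.g. `"nibr-pdxe"`.
#' @param control_arm Optional control-arm label (auto-detected otherwise).
#' @param delim Field delimiter; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab`/`.txt` are tab-delimited, anything else comma).
#' @return A [trial_dataset()].
#' @export
read_trial <- function(path, column_map = NULL, dialect = NULL,
                       control_arm = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  map <- character(0)
  if (!is.null(dialect)) {
    presets <- trial_dialects()
    if (!dialect %in% names(presets)) {
      stop(sprintf("unknown dialect '%s'; available: %s", dialect,
                   paste(names(presets), collapse = ", ")), call. = FALSE)
    }
    map <- presets[[dialect]]
  }
  if (!is.null(column_map)) {
    map <- unlist(modifyList(as.list(map), as.list(column_map)))
  }
  if (length(map) == 0L) {
    present <- intersect(.trial_canonical, names(raw))
    map <- setNames(present, present)
  }
  bad_fields <- setdiff(names(map), .trial_canonical)
  if (length(bad_fields) > 0L) {
    stop("unknown canonical field(s) in column_map: ",
         paste(bad_fields, collapse = ", "), call. = FALSE)
  }
  absent <- map[!map %in% names(raw)]
  if (length(absent) > 0L) {
    stop("mapped column(s) not found in file: ",
         paste(sprintf("'%s' (for %s)", absent, names(absent)), collapse = ", "),
         call. = FALSE)
  }
  needed <- setdiff(.trial_required, c(names(map), "animal_id"))
  if (length(needed) > 0L) {
    stop("no mapping for required field(s): ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(setNames(raw[, map, drop = FALSE], names(map)))
  if (!"animal_id" %in% names(out)) {
    out$animal_id <- paste(out$tumor_id, out$arm, sep = ":")
  }
  ds <- trial_dataset(out, control_arm = control_arm,
                      meta = list(source = path, column_map = map, delim = delim))
  if (nrow(ds) == 0L) warning("no records in '", path, "'", call. = FALSE)
  ds
}

#' Write a trial dataset to delimited text
#'
#' Writes the canonical columns (RFC-4180 quoting for CSV). Reading the file
#' back with [read_trial()] reproduces the dataset exactly.
#'
#' @param ds A [trial_dataset()].
#' @param path Output path; `.tsv` writes tab-delimited, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_trial <- function(ds, path) {
  tab <- as_tbl(ds)
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    readr::write_csv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate a trial dataset
#'
#' Screens a dataset for conditions that block or degrade downstream
#' analyses. Fatal issues (negative volumes or days) make the dataset
#' unusable; warnings flag animals without a day-0 baseline, zero baseline
#' volumes, animals with fewer than two timepoints (no growth metrics), and
#' single-animal arms (no within-arm variance).
#'
#' @param ds A [trial_dataset()].
#' @return A `validation_report`: a list with an `issues` tibble
#'   (`severity`, `tumor_id`, `arm`, `animal_id`, `day`, `message`) and the
#'   counts `n_animals`, `n_tumors`, `n_arms`, `n_timepoints`.
#' @export
validate_trial <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  tab <- as_tbl(ds)
  issue <- function(severity, tumor_id = NA_character_, arm = NA_character_,
                    animal_id = NA_character_, day = NA_real_, message) {
    tibble::tibble(severity = severity, tumor_id = tumor_id, arm = arm,
                   animal_id = animal_id, day = day, message = message)
  }
  issues <- list()
  if (nrow(tab) == 0L) {
    issues[[length(issues) + 1L]] <- issue("warning", message = "no records")
  } else {
    bad_vol <- tab[!is.na(tab$volume) & tab$volume < 0, ]
    if (nrow(bad_vol) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("fatal", bad_vol$tumor_id, bad_vol$arm, bad_vol$animal_id,
              bad_vol$day, "negative volume")
    }
    bad_day <- tab[!is.na(tab$day) & tab$day < 0, ]
    if (nrow(bad_day) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("fatal", bad_day$tumor_id, bad_day$arm, bad_day$animal_id,
              bad_day$day, "negative day")
    }
    if ("body_weight" %in% names(tab)) {
      bad_bw <- tab[!is.na(tab$body_weight) & tab$body_weight <= 0, ]
      if (nrow(bad_bw) > 0L) {
        issues[[length(issues) + 1L]] <-
          issue("warning", bad_bw$tumor_id, bad_bw$arm, bad_bw$animal_id,
                bad_bw$day, "non-positive body weight")
      }
    }
    per_animal <- tab |>
      dplyr::group_by(.data$tumor_id, .data$arm, .data$animal_id) |>
      dplyr::summarise(
        min_day = min(.data$day),
        n_days = dplyr::n_distinct(.data$day),
        baseline_volume = if (any(.data$day == 0)) {
          .data$volume[which(.data$day == 0)[1L]]
        } else NA_real_,
        .groups = "drop")
    nb <- per_animal[per_animal$min_day != 0, ]
    if (nrow(nb) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("warning", nb$tumor_id, nb$arm, nb$animal_id, nb$min_day,
              "missing baseline (no day-0 measurement)")
    }
    zb <- per_animal[!is.na(per_animal$baseline_volume) &
                       per_animal$baseline_volume == 0, ]
    if (nrow(zb) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("warning", zb$tumor_id, zb$arm, zb$animal_id, 0,
              "zero baseline volume (relative metrics undefined)")
    }
    ft <- per_animal[per_animal$n_days < 2L, ]
    if (nrow(ft) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("warning", ft$tumor_id, ft$arm, ft$animal_id, NA_real_,
              "fewer than 2 timepoints (cannot compute growth)")
    }
    per_cell <- per_animal |>
      dplyr::count(.data$tumor_id, .data$arm, name = "n_animals")
    single <- per_cell[per_cell$n_animals == 1L, ]
    if (nrow(single) > 0L) {
      issues[[length(issues) + 1L]] <-
        issue("warning", single$tumor_id, single$arm, NA_character_, NA_real_,
              "single animal in arm (no within-arm variance)")
    }
  }
  issues <- if (length(issues) > 0L) {
    dplyr::bind_rows(issues)
  } else {
    issue("warning", message = character(0))[0, ]
  }
  structure(
    list(issues = issues,
         n_animals = if (nrow(tab)) nrow(unique(tab[, c("tumor_id", "arm", "animal_id")])) else 0L,
         n_tumors = length(unique(tab$tumor_id)),
         n_arms = length(unique(tab$arm)),
         n_timepoints = length(unique(tab$day))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  n_fatal <- sum(x$issues$severity == "fatal")
  n_warn <- sum(x$issues$severity == "warning")
  cat(sprintf("<validation_report> %d fatal, %d warning(s)\n", n_fatal, n_warn))
  cat(sprintf("  %d animal(s), %d tumor(s), %d arm(s), %d timepoint(s)\n",
              x$n_animals, x$n_tumors, x$n_arms, x$n_timepoints))
  if (nrow(x$issues) > 0L) print(x$issues, ...)
  invisible(x)
}

#' Does a validation report contain no fatal issues?
#' @param report A report from [validate_trial()].
#' @return `TRUE` when downstream analysis is not blocked.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  !any(report$issues$severity == "fatal")
}

#' Infer the trial-design pattern
#'
#' Classifies a trial into one of the four common PDX designs, coded by
#' (number of tumors, arms, animals per arm) with `1` for single and a
#' letter for multiple: `1AN` (one tumor, several arms, several animals per
#' arm), `T1N` (a tumor panel, one treatment arm), `TA1` (tumor panel,
#' several arms, one animal per arm) and `TAN` (several of everything).
#' Combinations outside the four canonical designs are assigned the nearest
#' code with `degenerate = TRUE`.
#'
#' @param ds A [trial_dataset()] with at least one record.
#' @return A `pattern_code` list: `code`, `n_tumors`, `n_arms_per_tumor`
#'   (max non-control arms over tumors), `n_animals_per_cell` (median
#'   animals per tumor-by-arm cell), `degenerate`.
#' @export
infer_pattern <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (nrow(ds) == 0L) stop("cannot infer a pattern from an empty dataset",
                           call. = FALSE)
  tab <- as_tbl(ds)
  ctrl <- control_arm(ds)
  cells <- tab |>
    dplyr::distinct(.data$tumor_id, .data$arm, .data$animal_id) |>
    dplyr::count(.data$tumor_id, .data$arm, name = "n_animals")
  n_tumors <- length(unique(cells$tumor_id))
  arms_per_tumor <- cells |>
    dplyr::count(.data$tumor_id, name = "n_arms")
  a_max <- max(arms_per_tumor$n_arms)
  noncontrol <- cells[is.null(ctrl) | cells$arm != (ctrl %||% ""), ] |>
    dplyr::count(.data$tumor_id, name = "n_arms")
  nc_max <- if (nrow(noncontrol) > 0L) max(noncontrol$n_arms) else 0L
  med_animals <- median(cells$n_animals)
  multi <- med_animals > 1
  code <- NULL
  degenerate <- FALSE
  if (n_tumors == 1L && a_max > 1L && multi) {
    code <- "1AN"
  } else if (n_tumors > 1L && nc_max == 1L && a_max > 1L && multi) {
    code <- "T1N"
  } else if (n_tumors > 1L && a_max > 1L && !multi) {
    code <- "TA1"
  } else if (n_tumors > 1L && a_max > 1L && multi) {
    code <- "TAN"
  } else {
    degenerate <- TRUE
    code <- if (n_tumors == 1L) "1AN"
            else if (!multi) "TA1"
            else "T1N"
  }
  structure(list(code = code,
                 n_tumors = n_tumors,
                 n_arms_per_tumor = nc_max,
                 n_animals_per_cell = med_animals,
                 degenerate = degenerate),
            class = "pattern_code")
}

#' @export
print.pattern_code <- function(x, ...) {
  cat(sprintf("<pattern_code> %s%s | %d tumor(s), %d non-control arm(s), median %.3g animal(s)/cell\n",
              x$code, if (x$degenerate) " (degenerate)" else "",
              x$n_tumors, x$n_arms_per_tumor, x$n_animals_per_cell))
  invisible(x)
}

#' Percent change from baseline, per animal and day
#'
#' Computes `100 * (x_t - x_0) / x_0` for tumor volume or body weight,
#' relative to each animal's day-0 value. Animals without a positive day-0
#' baseline are excluded with a warning.
#'
#' @param ds A [trial_dataset()].
#' @param quantity `"volume"` or `"body_weight"`.
#' @return A tibble `(tumor_id, arm, animal_id, day, pct_change)` with a
#'   zero row at baseline.
#' @export
relative_change <- function(ds, quantity = c("volume", "body_weight")) {
  stopifnot(inherits(ds, "trial_dataset"))
  quantity <- match.arg(quantity)
  tab <- as_tbl(ds)
  if (!quantity %in% names(tab)) {
    stop(sprintf("dataset has no '%s' column", quantity), call. = FALSE)
  }
  tab$.x <- tab[[quantity]]
  out <- tab |>
    dplyr::group_by(.data$tumor_id, .data$arm, .data$animal_id) |>
    dplyr::mutate(.baseline = if (any(.data$day == 0 & !is.na(.data$.x))) {
      .data$.x[which(.data$day == 0)[1L]]
    } else NA_real_) |>
    dplyr::ungroup()
  excluded <- out |>
    dplyr::filter(is.na(.data$.baseline) | .data$.baseline <= 0) |>
    dplyr::distinct(.data$tumor_id, .data$arm, .data$animal_id)
  if (nrow(excluded) > 0L) {
    warning(sprintf("%d animal(s) excluded (missing or non-positive baseline): %s",
                    nrow(excluded),
                    paste(head(excluded$animal_id, 5L), collapse = ", ")),
            call. = FALSE)
  }
  out |>
    dplyr::filter(!is.na(.data$.baseline), .data$.baseline > 0,
                  !is.na(.data$.x)) |>
    dplyr::transmute(.data$tumor_id, .data$arm, .data$animal_id, .data$day,
                     pct_change = 100 * (.data$.x - .data$.baseline) / .data$.baseline) |>
    dplyr::arrange(.data$tumor_id, .data$arm, .data$animal_id, .data$day)
}

#' Per-arm volume summaries over time
#'
#' Summarises tumor volume per (tumor, arm, day) as a center (mean or
#' median) with the standard error of the mean. The SEM is reported as `NA`
#' where fewer than two animals were measured.
#'
#' @param ds A [trial_dataset()].
#' @param center `"mean"` or `"median"`.
#' @return A tibble `(tumor_id, arm, day, n, center, sem)`; the centering
#'   method is stored in the `"center"` attribute.
#' @export
summarize_arms <- function(ds, center = c("mean", "median")) {
  stopifnot(inherits(ds, "trial_dataset"))
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  out <- as_tbl(ds) |>
    dplyr::filter(!is.na(.data$volume)) |>
    dplyr::group_by(.data$tumor_id, .data$arm, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      center = fun(.data$volume),
      sem = if (dplyr::n() >= 2L) sd(.data$volume) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$tumor_id, .data$arm, .data$day)
  attr(out, "center") <- center
  out
}
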
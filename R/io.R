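cohort_columns <- c("subject_id", "week", "observed_weight",
                    "predicted_weight", "w0", "intervention_length")

validate_cohort_table <- function(table, need_predicted = TRUE) {
  if (!is.data.frame(table)) {
    stop("cohort table must be a data.frame", call. = FALSE)
  }
  required <- cohort_columns
  if (!need_predicted) {
    required <- setdiff(required, "predicted_weight")
  }
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"predicted_weight" %in% names(table)) {
    table$predicted_weight <- NA_real_
  }
  num_cols <- c("week", "observed_weight", "predicted_weight", "w0",
                "intervention_length")
  for (col in num_cols) {
    if (!is.numeric(table[[col]])) {
      stop("cohort column '", col, "' must be numeric", call. = FALSE)
    }
  }
  if (nrow(table)) {
    if (any(table$observed_weight <= 0, na.rm = TRUE)) {
      stop("observed_weight must be > 0 kg", call. = FALSE)
    }
    if (any(table$week < 1 | table$week > table$intervention_length)) {
      stop("week must lie in [1, intervention_length] for every row",
           call. = FALSE)
    }
    key <- paste(table$subject_id, table$week)
    if (anyDuplicated(key)) {
      stop("cohort table must have one row per subject-week",
           call. = FALSE)
    }
  }
  table
}

#' Read a cohort table from CSV
#'
#' Expects one row per subject-week with header columns `subject_id`,
#' `week`, `observed_weight`, `w0`, `intervention_length`, and optionally
#' `predicted_weight`. Weights are in kg. Malformed numeric fields are
#' reported with their file line number (header = line 1).
#'
#' @param path path to a CSV file.
#' @return A validated cohort table (data.frame).
#' @seealso [write_cohort_csv()], [cohort_error_summary()]
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE)
  required <- setdiff(cohort_columns, "predicted_weight")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("cohort CSV contains a header but no rows", call. = FALSE)
  }
  num_cols <- intersect(
    c("week", "observed_weight", "predicted_weight", "w0",
      "intervention_length"),
    names(raw)
  )
  for (col in num_cols) {
    vals <- trimws(raw[[col]])
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(parsed) & !is.na(vals) & !(vals %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' on line %d of %s",
                   vals[bad[1]], col, bad[1] + 1L, path), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  validate_cohort_table(raw, need_predicted = FALSE)
}

#' Write a cohort table to CSV
#'
#' @param table a cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  table <- validate_cohort_table(table, need_predicted = FALSE)
  out <- table[, cohort_columns]
  for (col in c("week", "observed_weight", "predicted_weight", "w0",
                "intervention_length")) {
    out[[col]] <- format_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

trajectory_columns <- c("t", "weight", "ffm_kg", "ree_net", "at", "paee",
                        "dit", "ei", "deficit")

# deterministic float formatting (9 significant digits) for diff-stable
# outputs; round-trips well within 6 significant digits
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.9g", v)
  }, character(1))
  out
}

#' Write a simulated trajectory to CSV
#'
#' Columns in fixed order (`t, weight, ffm_kg, ree_net, at, paee, dit, ei,
#' deficit`), formatted deterministically to 9 significant digits; a
#' written file read back with [read_trajectory_csv()] agrees to well
#' within 6 significant digits. Non-finite values are refused.
#'
#' @param traj an `eb_trajectory` from [simulate_weight()], or a data.frame
#'   with the same columns (possibly zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!is.data.frame(traj)) {
    stop("traj must be a trajectory data.frame", call. = FALSE)
  }
  missing <- setdiff(trajectory_columns, names(traj))
  if (length(missing)) {
    stop("trajectory is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(as.data.frame(traj)[, trajectory_columns])
  if (nrow(vals) && any(!is.finite(vals))) {
    stop("trajectory contains non-finite values; refusing to write",
         call. = FALSE)
  }
  out <- as.data.frame(traj)[, trajectory_columns, drop = FALSE]
  out[] <- lapply(out, format_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path path to a CSV written by [write_trajectory_csv()].
#' @return An `eb_trajectory` data.frame.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path)
  missing <- setdiff(trajectory_columns, names(raw))
  if (length(missing)) {
    stop("trajectory CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- raw[, trajectory_columns]
  class(out) <- c("eb_trajectory", "data.frame")
  out
}

#' Write a model configuration to YAML
#'
#' All fields are written flat; [read_model_config()] restores an
#' identical object (config round-trip identity).
#'
#' @param config an [model_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  validate_model_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys fall back to the
#' defaults of [model_config()].
#'
#' @param path path to a YAML file written by [write_model_config()] or by
#'   hand.
#' @return An `eb_model_config` object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- model_config_fields()
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- unclass(model_config())
  cfg[names(vals)] <- vals
  class(cfg) <- "eb_model_config"
  validate_model_config(cfg)
}
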
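#' Read and write the pipeline's CSV tables
#'
#' All tables are plain UTF-8 CSV with a header row, comma separators, dot
#' decimals and empty fields for missing values. Readers validate the
#' schema and fail naming the file and the missing column.
#'
#' * Trial logs: `subject_id, condition, block, trial, choice, outcome,
#'   side_adv` with 0-based `block`/`trial`, `choice` in
#'   `adv/disadv/none`, `outcome` in `gain/loss`, `side_adv` in `L/R`.
#' * Beat series: `subject_id, condition, block, period, beat_time_s`.
#' * Autonomic panels (long): `subject_id, condition, block, period,
#'   variable, value`.
#' * ROI tables (long): `subject_id, condition, roi, value`.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name pipeline_io
NULL

read_checked <- function(path, required, coltypes) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  out
}

check_levels <- function(df, col, levels, path) {
  bad <- !df[[col]] %in% levels
  if (any(bad)) {
    abort(sprintf("%s: row %d: invalid %s '%s' (expected one of %s)",
                  path, which(bad)[1], col, df[[col]][which(bad)[1]],
                  paste(levels, collapse = "/")))
  }
}

#' @rdname pipeline_io
#' @export
read_trials <- function(path) {
  out <- read_checked(path, c("subject_id", "condition", "block", "trial",
                              "choice", "outcome", "side_adv"))
  check_levels(out, "choice", c("adv", "disadv", "none"), path)
  check_levels(out, "outcome", c("gain", "loss"), path)
  check_levels(out, "side_adv", c("L", "R"), path)
  out
}

#' @rdname pipeline_io
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_beats <- function(path) {
  read_checked(path, c("subject_id", "condition", "block", "period",
                       "beat_time_s"))
}

#' @rdname pipeline_io
#' @export
write_beats <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_panels <- function(path) {
  out <- read_checked(path, c("subject_id", "condition", "block", "period",
                              "variable", "value"))
  check_levels(out, "period", c("baseline", "task"), path)
  out
}

#' @rdname pipeline_io
#' @export
write_panels <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_roi <- function(path) {
  read_checked(path, c("subject_id", "condition", "roi", "value"))
}

#' @rdname pipeline_io
#' @export
write_roi <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}
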
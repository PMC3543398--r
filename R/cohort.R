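# Longitudinal cohort container and CSV/JSON plumbing.
#
# A cohort is stored long: one row per (patient_id, day_since_onset, mmse).
# Simulated cohorts additionally carry the generating truth (one recovery
# model per patient) so parameter-recovery tests can compare against it.

#' Longitudinal MMSE cohort
#'
#' Container for serial MMSE assessments of a stroke cohort in long
#' format. Each patient's assessment series must have strictly
#' increasing days since onset (all >= 1) and integer scores in
#' 0--30.
#'
#' @param assessments Data frame with columns `patient_id`,
#'   `day_since_onset`, `mmse`.
#' @param truth Optional data frame with columns `patient_id`, `kind`,
#'   `a`, `b`: the generating model per patient (simulated cohorts).
#' @param config Optional [cohort_config()] the cohort was generated
#'   from.
#' @return An object of class `mmse_cohort` with elements
#'   `assessments`, `truth`, `config`.
#' @seealso [generate_cohort()], [read_cohort()], [write_cohort()]
#' @export
mmse_cohort <- function(assessments, truth = NULL, config = NULL) {
  validate_assessments(assessments)
  assessments$patient_id <- as.character(assessments$patient_id)
  assessments$day_since_onset <- as.integer(assessments$day_since_onset)
  assessments$mmse <- as.integer(assessments$mmse)
  if (!is.null(truth)) {
    need <- c("patient_id", "kind", "a", "b")
    if (!all(need %in% names(truth)))
      stop("'truth' must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    truth$patient_id <- as.character(truth$patient_id)
  }
  structure(list(assessments = assessments[, c("patient_id", "day_since_onset", "mmse")],
                 truth = truth, config = config),
            class = "mmse_cohort")
}

validate_assessments <- function(df) {
  need <- c("patient_id", "day_since_onset", "mmse")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("assessments must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  day <- suppressWarnings(as.numeric(df$day_since_onset))
  sc <- suppressWarnings(as.numeric(df$mmse))
  bad <- which(!is.finite(day) | day < 1 | day != round(day))
  if (length(bad))
    stop("invalid day_since_onset (must be integer >= 1) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(sc) | sc < MMSE_MIN | sc > MMSE_MAX | sc != round(sc))
  if (length(bad))
    stop("invalid mmse score (must be integer in [0, 30]) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  for (id in unique(df$patient_id)) {
    d <- day[df$patient_id == id]
    if (any(diff(d) <= 0))
      stop("assessment days not strictly increasing for patient '", id, "'",
           call. = FALSE)
  }
  invisible(df)
}

#' @export
print.mmse_cohort <- function(x, ...) {
  ids <- unique(x$assessments$patient_id)
  k <- table(x$assessments$patient_id)
  cat(sprintf("<mmse_cohort> %d patients, %d assessments (%s per patient)\n",
              length(ids), nrow(x$assessments),
              if (length(unique(k)) == 1L) unique(k) else
                paste(min(k), "to", max(k))))
  if (!is.null(x$truth))
    cat("  generating truth attached (", unique(x$truth$kind), " models)\n",
        sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An [mmse_cohort()].
#' @return Integer count.
#' @export
n_patients <- function(cohort) {
  length(unique(cohort$assessments$patient_id))
}

#' Split a cohort into per-patient series
#'
#' @param cohort An [mmse_cohort()] (or a long assessments data frame).
#' @return Named list of data frames (`day`, `score`), one per patient,
#'   ordered by day; names are patient ids in order of first appearance.
#' @export
cohort_series <- function(cohort) {
  df <- if (inherits(cohort, "mmse_cohort")) cohort$assessments else cohort
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    rows <- rows[order(rows$day_since_onset), , drop = FALSE]
    data.frame(day = rows$day_since_onset, score = rows$mmse)
  })
  names(out) <- ids
  out
}

#' Write / read a cohort as CSV (plus optional truth sidecar JSON)
#'
#' The CSV dialect is comma-separated, UTF-8, header
#' `patient_id,day_since_onset,mmse`, integer days and scores, no
#' quoting. The generating truth, when present, is written to a
#' sidecar JSON file keyed by patient id with records
#' `{"kind": ..., "a": ..., "b": ...}`.
#'
#' @param cohort An [mmse_cohort()].
#' @param path CSV file path.
#' @param truth_path Sidecar JSON path. For `write_cohort()` the
#'   default writes `<path minus .csv>_truth.json` when truth is
#'   attached, or nothing when it is not; for `read_cohort()` the
#'   default reads no sidecar.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns an [mmse_cohort()].
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "mmse_cohort"))
  utils::write.csv(cohort$assessments, path, row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    if (is.null(truth_path)) truth_path <- default_truth_path(path)
    tr <- cohort$truth
    rec <- lapply(seq_len(nrow(tr)), function(i)
      list(kind = tr$kind[i], a = tr$a[i], b = tr$b[i]))
    names(rec) <- tr$patient_id
    jsonlite::write_json(rec, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

default_truth_path <- function(path) {
  sub("\\.csv$", "", path, ignore.case = TRUE) |> paste0("_truth.json")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_path = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse cohort CSV '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  truth <- NULL
  if (!is.null(truth_path)) {
    rec <- jsonlite::fromJSON(truth_path)
    truth <- data.frame(patient_id = names(rec),
                        kind = vapply(rec, `[[`, "", "kind"),
                        a = vapply(rec, `[[`, 0, "a"),
                        b = vapply(rec, `[[`, 0, "b"),
                        row.names = NULL)
  }
  mmse_cohort(df, truth = truth)
}
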
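DAYS_PER_MONTH <- 30.44  # mean Gregorian month, used for day -> month conversion

#' Construct a patient cohort
#'
#' A cohort holds one record per patient: a unique id, one or more slide
#' references, the right-censored overall-survival time in months, the event
#' indicator (`1` = death observed, `0` = censored) and optional clinical
#' covariates.
#'
#' @param patients data.frame with columns `patient_id`, `time_months`,
#'   `event`, plus any covariate columns; `slide_ids` must be a list column
#'   of character vectors (one or more slides per patient).
#' @param name cohort label.
#' @return object of class `cohort`.
#' @export
cohort <- function(patients, name = "cohort") {
  stopifnot(is.data.frame(patients))
  req <- c("patient_id", "slide_ids", "time_months", "event")
  miss <- setdiff(req, names(patients))
  if (length(miss)) stop_validation("cohort is missing fields: %s", paste(miss, collapse = ", "))
  if (nrow(patients) == 0L) stop_validation("cohort must contain at least one patient")
  if (anyDuplicated(patients$patient_id)) {
    stop_validation("duplicate patient ids: %s",
                    paste(unique(patients$patient_id[duplicated(patients$patient_id)]), collapse = ", "))
  }
  bad_t <- which(!is.finite(patients$time_months) | patients$time_months < 0)
  if (length(bad_t)) stop_validation("negative or non-finite survival time in row %d", bad_t[1L])
  bad_e <- which(!(patients$event %in% c(0, 1)))
  if (length(bad_e)) stop_validation("event indicator must be 0 or 1 (row %d)", bad_e[1L])
  patients$patient_id <- as.character(patients$patient_id)
  structure(list(patients = patients, name = name), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<cohort '%s'> %d patients, %d slides, %.1f%% censored\n",
              x$name, nrow(p), length(unlist(p$slide_ids)),
              100 * mean(p$event == 0)))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$patients

n_patients <- function(x) nrow(x$patients)

#' Load a cohort from a delimited text file
#'
#' One row per slide; rows sharing a `patient_id` are merged into a single
#' patient record whose slide list carries all of that patient's slides.
#' Survival times given in days are converted to months by dividing by
#' 30.44 (the mean Gregorian month).
#'
#' @param path CSV path.
#' @param schema named list mapping roles to column names. Roles:
#'   `patient_id`, `slide`, `time` (with `time_unit` `"months"` or
#'   `"days"`), `event`, and optionally `covariates` (character vector of
#'   column names to carry along).
#' @param name cohort label (defaults to the file name).
#' @return a [cohort].
#' @export
load_cohort <- function(path,
                        schema = list(patient_id = "patient_id",
                                      slide = "slide_path",
                                      time = "time_months",
                                      time_unit = "months",
                                      event = "event",
                                      covariates = NULL),
                        name = NULL) {
  if (!file.exists(path)) stop_validation("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$patient_id, schema$slide, schema$time, schema$event, schema$covariates)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_validation("cohort file is missing column(s): %s", paste(miss, collapse = ", "))

  unit <- schema$time_unit %||% "months"
  if (!unit %in% c("months", "days")) stop_validation("time_unit must be 'months' or 'days'")
  time <- as.numeric(raw[[schema$time]])
  if (unit == "days") time <- time / DAYS_PER_MONTH
  event <- raw[[schema$event]]

  bad <- which(!is.finite(time) | time < 0)
  if (length(bad)) stop_validation("negative or missing survival time in row %d of %s", bad[1L], path)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad)) stop_validation("event must be 0 or 1 in row %d of %s", bad[1L], path)

  pid <- as.character(raw[[schema$patient_id]])
  ord <- !duplicated(pid)
  ids <- pid[ord]

  # per-patient consistency of time/event across slide rows
  for (id in ids) {
    rows <- which(pid == id)
    if (length(unique(round(time[rows], 9))) > 1L || length(unique(event[rows])) > 1L) {
      stop_validation("inconsistent time/event for patient '%s'", id)
    }
  }
  first <- match(ids, pid)
  patients <- data.frame(patient_id = ids,
                         time_months = time[first],
                         event = as.integer(event[first]),
                         stringsAsFactors = FALSE)
  patients$slide_ids <- lapply(ids, function(id) as.character(raw[[schema$slide]][pid == id]))
  for (cv in schema$covariates) patients[[cv]] <- raw[[cv]][first]
  cohort(patients, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a cohort to CSV (one row per slide)
#'
#' @param x a [cohort].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  p <- x$patients
  nslides <- lengths(p$slide_ids)
  out <- data.frame(patient_id = rep(p$patient_id, nslides),
                    slide_path = unlist(p$slide_ids),
                    time_months = rep(p$time_months, nslides),
                    event = rep(p$event, nslides),
                    stringsAsFactors = FALSE)
  for (cv in setdiff(names(p), c("patient_id", "slide_ids", "time_months", "event"))) {
    out[[cv]] <- rep(p[[cv]], nslides)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
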
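#' @useDynLib rmdor, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pchisq pnorm qnorm runif rexp rbinom rweibull setNames
#' @importFrom utils read.csv write.csv
NULL

# Canonical column order of the patient-level schema.  Times are continuous
# months from randomization; empty CSV cells encode absent optional times.
COHORT_COLUMNS <- c("patient_id", "arm", "t_response", "first_response_type",
                    "t_cr", "t_event", "pfs_event", "t_os", "os_event")

#' Construct a trial cohort from patient-level records
#'
#' A cohort is a data frame of one row per randomized patient recording the
#' observed multi-state trajectory: time of first objective response (CR or
#' PR), type of that first response, time of first complete response, the
#' observed progression-free survival (PFS) time with its event indicator,
#' and optionally overall survival.  All times are months from randomization.
#'
#' The trajectory model assumes monotone deepening of response
#' (SD to PR to CR) until progression, death or censoring, so that per
#' patient `t_response <= t_cr <= t_event` whenever the earlier times exist,
#' and a first response of type `"CR"` has `t_cr == t_response`.
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param arm arm label per patient; a cohort has one or two (or more) arms.
#' @param t_response months to first CR-or-PR, `NA` if never observed.
#' @param first_response_type `"PR"` or `"CR"` where `t_response` is present,
#'   else `NA`.
#' @param t_cr months to first CR, `NA` if never observed.
#' @param t_event observed PFS time in months (progression, death or
#'   censoring, whichever first).
#' @param pfs_event 1 if progression or death was observed, 0 if censored.
#' @param t_os,os_event optional overall survival time and indicator
#'   (descriptive only; not used by any estimator).
#' @return A validated `rmdor_cohort` data frame.
#' @examples
#' cohort(patient_id = c("p1", "p2"), arm = "A",
#'        t_response = c(2, NA), first_response_type = c("PR", NA),
#'        t_cr = NA_real_, t_event = c(10, 6), pfs_event = c(1, 0))
#' @export
cohort <- function(patient_id, arm, t_response = NA_real_,
                   first_response_type = NA_character_, t_cr = NA_real_,
                   t_event, pfs_event, t_os = NA_real_, os_event = NA_integer_) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    arm = as.character(arm),
    t_response = as.numeric(t_response),
    first_response_type = as.character(first_response_type),
    t_cr = as.numeric(t_cr),
    t_event = as.numeric(t_event),
    pfs_event = as.integer(pfs_event),
    t_os = as.numeric(t_os),
    os_event = as.integer(os_event),
    stringsAsFactors = FALSE
  )
  as_cohort(df)
}

#' Coerce a data frame to a validated cohort
#'
#' @param x a data frame with the cohort schema columns (see [cohort()]);
#'   missing optional columns (`t_os`, `os_event`) are added as `NA`.
#' @return An `rmdor_cohort` data frame.
#' @export
as_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("t_os", "os_event")) if (!col %in% names(x)) x[[col]] <- NA
  unknown <- setdiff(names(x), COHORT_COLUMNS)
  if (length(unknown) > 0L)
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[COHORT_COLUMNS]
  x$patient_id <- as.character(x$patient_id)
  x$arm <- as.character(x$arm)
  x$first_response_type <- as.character(x$first_response_type)
  for (col in c("t_response", "t_cr", "t_event", "t_os"))
    x[[col]] <- as.numeric(x[[col]])
  for (col in c("pfs_event", "os_event")) x[[col]] <- as.integer(x[[col]])
  rownames(x) <- NULL
  validate_cohort(x)
  class(x) <- c("rmdor_cohort", "data.frame")
  x
}

#' Validate patient-record invariants
#'
#' Checks every record of a cohort against the trajectory invariants and
#' stops, naming the offending row and invariant, on the first violation.
#'
#' @param x a data frame with the cohort schema.
#' @return Invisibly `x`, when valid.
#' @export
validate_cohort <- function(x) {
  fail <- function(rows, what) {
    stop(sprintf("invalid patient record (row %s): %s",
                 paste(rows, collapse = ", "), what), call. = FALSE)
  }
  if (nrow(x) == 0L) stop("cohort has no records", call. = FALSE)
  if (anyDuplicated(x$patient_id))
    fail(which(duplicated(x$patient_id)), "patient_id not unique")
  bad <- which(is.na(x$t_event) | !is.finite(x$t_event) | x$t_event < 0)
  if (length(bad)) fail(bad, "t_event must be finite and >= 0")
  bad <- which(is.na(x$pfs_event) | !(x$pfs_event %in% c(0L, 1L)))
  if (length(bad)) fail(bad, "pfs_event must be 0 or 1")
  has_resp <- !is.na(x$t_response)
  bad <- which(has_resp & (x$t_response < 0 | x$t_response > x$t_event))
  if (length(bad)) fail(bad, "requires 0 <= t_response <= t_event")
  bad <- which(has_resp & !(x$first_response_type %in% c("PR", "CR")))
  if (length(bad)) fail(bad, "first_response_type must be PR or CR when t_response present")
  bad <- which(!has_resp & !is.na(x$first_response_type))
  if (length(bad)) fail(bad, "first_response_type present without t_response")
  has_cr <- !is.na(x$t_cr)
  bad <- which(has_cr & !has_resp)
  if (length(bad)) fail(bad, "t_cr requires t_response")
  bad <- which(has_cr & (x$t_cr < x$t_response | x$t_cr > x$t_event))
  if (length(bad)) fail(bad, "requires t_response <= t_cr <= t_event")
  bad <- which(has_resp & x$first_response_type == "CR" &
                 (!has_cr | x$t_cr != x$t_response))
  if (length(bad)) fail(bad, "first_response_type CR requires t_cr == t_response")
  bad <- which(!is.na(x$t_os) & (!is.finite(x$t_os) | x$t_os < 0))
  if (length(bad)) fail(bad, "t_os must be finite and >= 0 when present")
  bad <- which(!is.na(x$os_event) & !(x$os_event %in% c(0L, 1L)))
  if (length(bad)) fail(bad, "os_event must be 0 or 1 when present")
  invisible(x)
}

#' Arm labels of a cohort
#' @param x an `rmdor_cohort`.
#' @return Character vector of distinct arm labels, in order of appearance.
#' @export
arms <- function(x) unique(x$arm)

#' Subset one arm of a cohort
#' @param x an `rmdor_cohort`.
#' @param arm an arm label present in `x`.
#' @return The single-arm `rmdor_cohort`.
#' @export
cohort_arm <- function(x, arm) {
  if (!arm %in% x$arm) stop("no such arm: ", arm)
  out <- x[x$arm == arm, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rmdor_cohort", "data.frame")
  out
}

#' Read a cohort from CSV
#'
#' The file must carry exactly the header
#' `patient_id,arm,t_response,first_response_type,t_cr,t_event,pfs_event,t_os,os_event`;
#' empty cells encode absent values.  All records are validated on read.
#'
#' @param path path to a CSV file.
#' @return An `rmdor_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(read.csv(path, nrows = 0))
  if (!identical(header, COHORT_COLUMNS))
    stop("CSV header does not match the cohort schema; expected: ",
         paste(COHORT_COLUMNS, collapse = ","))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", arm = "character",
                                first_response_type = "character"),
                 na.strings = "")
  as_cohort(df)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: absent values become empty cells and the file
#' re-reads to an identical cohort.
#'
#' @param x an `rmdor_cohort`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  write.csv(as.data.frame(x)[COHORT_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.rmdor_cohort <- function(x, ...) {
  a <- arms(x)
  cat(sprintf("Trial cohort: %d patients, %d arm(s)\n", nrow(x), length(a)))
  for (lab in a) {
    sub <- x[x$arm == lab, ]
    cat(sprintf("  %s: n=%d, responders=%d (CR first: %d), PFS events=%d\n",
                lab, nrow(sub), sum(!is.na(sub$t_response)),
                sum(sub$first_response_type == "CR", na.rm = TRUE),
                sum(sub$pfs_event)))
  }
  invisible(x)
}
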
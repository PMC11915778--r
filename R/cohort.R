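# Column schema for a cohort CSV / data.frame. Order is the canonical
# on-disk order; types drive parsing and round-trip fidelity.
.cohort_columns <- c(
  id = "character", age = "numeric", sex = "character",
  sbp = "numeric", dbp = "numeric", hr = "numeric",
  hs_ctnt = "numeric", nt_probnp = "numeric", af_status = "character",
  norepinephrine_dose = "numeric", dopamine_dose = "numeric",
  other_vasoactive = "integer",
  sofa_neuro = "integer", sofa_resp = "integer", sofa_renal = "integer",
  sofa_hepatic = "integer", sofa_coag = "integer",
  died_30d = "integer"
)

.af_levels <- c("none", "pre_existing", "new_onset")
.sex_levels <- c("female", "male")

# Assay lower limits used as detection floors so log transforms stay finite.
.detection_floor <- c(hs_ctnt = 3, nt_probnp = 5)

#' Construct a validated sepsis cohort
#'
#' A cohort is a plain \code{data.frame} (one row per patient) carrying the
#' fixed column schema used throughout the package, validated against the
#' physiological invariants below, with a \code{label} attribute naming it.
#'
#' Invariants enforced per record: \code{0 < dbp <= sbp}; \code{hr > 0};
#' both biomarkers at or above their detection floors (hs-cTnT 3 ng/L,
#' NT-proBNP 5 ng/L); each SOFA sub-score an integer in 0..4; vasoactive
#' doses non-negative; \code{af_status} one of \code{none},
#' \code{pre_existing}, \code{new_onset}; unique ids.
#'
#' @param records data.frame with the cohort column schema (see
#'   \code{\link{read_cohort}} for the column list).
#' @param label character label for the cohort (e.g. \code{"training"}).
#' @return The validated data.frame with class \code{ce_cohort}.
#' @export
as_cohort <- function(records, label = "cohort") {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.cohort_columns), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, names(.cohort_columns)]
  for (col in names(.cohort_columns)) {
    records[[col]] <- switch(.cohort_columns[[col]],
      character = as.character(records[[col]]),
      numeric   = as.numeric(records[[col]]),
      integer   = as.integer(records[[col]])
    )
  }
  validate_cohort(records)
  structure(records, class = c("ce_cohort", "data.frame"), label = label)
}

#' Validate cohort invariants
#'
#' Checks every per-record invariant and reports offending rows by number.
#' Called by \code{\link{as_cohort}} and \code{\link{read_cohort}}; exported
#' so external cohorts can be checked before analysis.
#'
#' @param records cohort data.frame.
#' @return Invisibly \code{TRUE}; stops with a row-numbered message otherwise.
#' @export
validate_cohort <- function(records) {
  fail <- function(rows, what) {
    stop("invalid cohort: ", what, " in row(s) ",
         paste(utils::head(rows, 10), collapse = ", "),
         if (length(rows) > 10) sprintf(" (and %d more)", length(rows) - 10),
         call. = FALSE)
  }
  check <- function(bad, what) if (any(bad, na.rm = FALSE)) {
    bad[is.na(bad)] <- TRUE
    fail(which(bad), what)
  }
  if (nrow(records) == 0) stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(records$id)) {
    fail(which(duplicated(records$id)), "duplicated patient id")
  }
  check(is.na(records$dbp) | records$dbp <= 0, "dbp must be > 0")
  check(records$dbp > records$sbp, "dbp exceeds sbp")
  check(is.na(records$hr) | records$hr <= 0, "hr must be > 0")
  check(is.na(records$hs_ctnt) | records$hs_ctnt < .detection_floor["hs_ctnt"],
        sprintf("hs_ctnt below detection floor %g ng/L", .detection_floor["hs_ctnt"]))
  check(is.na(records$nt_probnp) | records$nt_probnp < .detection_floor["nt_probnp"],
        sprintf("nt_probnp below detection floor %g ng/L", .detection_floor["nt_probnp"]))
  check(!(records$af_status %in% .af_levels), "unknown af_status level")
  check(!(records$sex %in% .sex_levels), "unknown sex level")
  check(is.na(records$norepinephrine_dose) | records$norepinephrine_dose < 0,
        "negative norepinephrine_dose")
  check(is.na(records$dopamine_dose) | records$dopamine_dose < 0,
        "negative dopamine_dose")
  for (col in c("sofa_neuro", "sofa_resp", "sofa_renal", "sofa_hepatic", "sofa_coag")) {
    v <- records[[col]]
    check(is.na(v) | v < 0L | v > 4L | v != round(v),
          paste(col, "must be an integer in [0,4]"))
  }
  check(!(records$died_30d %in% c(0L, 1L)), "died_30d must be 0/1")
  check(!(records$other_vasoactive %in% c(0L, 1L)), "other_vasoactive must be 0/1")
  invisible(TRUE)
}

#' @export
print.ce_cohort <- function(x, ...) {
  cat(sprintf("<ce_cohort '%s': %d patients, %d deaths (%.1f%%)>\n",
              attr(x, "label") %||% "cohort", nrow(x), sum(x$died_30d),
              100 * mean(x$died_30d)))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derived hemodynamic variables
#'
#' Computes the four derived cardiovascular variables from admission blood
#' pressure and heart rate: mean arterial pressure
#' \code{MAP = DBP + (SBP - DBP)/3}, pulse pressure \code{PP = SBP - DBP},
#' rate pressure product \code{RPP = HR x SBP}, and proportional pulse
#' pressure \code{PPP = PP / SBP}. Vectorised over its arguments.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @param hr heart rate, beats/min.
#' @return data.frame with columns \code{map}, \code{pp}, \code{rpp},
#'   \code{ppp}.
#' @examples
#' derive_hemodynamics(120, 60, 100) # map 80, pp 60, rpp 12000, ppp 0.5
#' @export
derive_hemodynamics <- function(sbp, dbp, hr) {
  if (any(dbp > sbp)) stop("dbp exceeds sbp", call. = FALSE)
  if (any(sbp == 0)) stop("sbp is zero: proportional pulse pressure undefined",
                          call. = FALSE)
  pp <- sbp - dbp
  data.frame(
    map = dbp + pp / 3,
    pp  = pp,
    rpp = hr * sbp,
    ppp = pp / sbp
  )
}

#' Read a cohort from CSV
#'
#' Expects one row per patient with header columns \code{id, age, sex, sbp,
#' dbp, hr, hs_ctnt, nt_probnp, af_status, norepinephrine_dose,
#' dopamine_dose, other_vasoactive, sofa_neuro, sofa_resp, sofa_renal,
#' sofa_hepatic, sofa_coag, died_30d}. \code{af_status} takes
#' \code{none|pre_existing|new_onset}; binary fields are coded 0/1. All
#' invariants of \code{\link{validate_cohort}} are enforced on read, with
#' violations reported by row number.
#'
#' @param path CSV file path.
#' @param label cohort label; defaults to the file name.
#' @return A \code{ce_cohort}.
#' @export
read_cohort <- function(path, label = basename(path)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(names(.cohort_columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(.cohort_columns)) {
    type <- .cohort_columns[[col]]
    if (type == "character") next
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[col]])))
    if (length(bad) > 0) {
      stop(sprintf("unparseable value in column '%s', row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    raw[[col]] <- v
  }
  as_cohort(raw, label = label)
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort}}: writing then reading reproduces all
#' fields exactly.
#'
#' @param cohort a \code{ce_cohort}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, names(.cohort_columns)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random training/test split
#'
#' Partitions a cohort into a training cohort of exactly \code{n_train}
#' records and a test cohort holding the remainder, by seeded simple random
#' sampling without replacement. The same seed always yields the same
#' partition; the union of the parts is the input and their intersection is
#' empty.
#'
#' @param cohort a \code{ce_cohort}.
#' @param n_train number of training records, \code{0 < n_train < nrow}.
#' @param seed integer seed for the split.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_cohort <- function(cohort, n_train, seed) {
  n <- nrow(cohort)
  if (n_train <= 0 || n_train >= n) {
    stop(sprintf("n_train must be in (0, %d); got %s", n, n_train),
         call. = FALSE)
  }
  idx <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    sample.int(n, n_train)
  })
  list(
    train = as_cohort(as.data.frame(cohort)[sort(idx), , drop = FALSE],
                      label = "training"),
    test  = as_cohort(as.data.frame(cohort)[sort(setdiff(seq_len(n), idx)), ,
                                            drop = FALSE],
                      label = "test")
  )
}

#' Biomarker detection floors
#'
#' Lower reporting limits used when values are recorded as "below
#' detection": hs-cTnT 3 ng/L and NT-proBNP 5 ng/L. Keeping a positive
#' floor keeps logarithmic transforms finite.
#'
#' @return named numeric vector.
#' @export
detection_floors <- function() .detection_floor
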
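# Data model and file I/O for digitized Kaplan-Meier curves, risk tables and
# reconstructed individual patient data (IPD).

VALID_TIME_UNITS <- c("weeks", "months", "years")
VALID_ENDPOINTS <- c("PFS", "OS")

WEEKS_PER_YEAR <- 365.25 / 7
MONTHS_PER_YEAR <- 12

#' Construct a digitized survival curve
#'
#' A `digitized_curve` holds the (time, survival) coordinates clicked off a
#' published Kaplan-Meier plot for one trial arm and endpoint. The constructor
#' validates and cleans the coordinates via [clean_curve()]: duplicate times
#' are collapsed, small digitization jitter is flattened, survival is clipped
#' to \[0, 1\] and an origin point (0, 1) is ensured.
#'
#' @param time Numeric vector of non-negative times.
#' @param surv Numeric vector of survival probabilities, same length as
#'   `time`. Values on the percent scale (max > 1.5) are divided by 100.
#' @param arm_id Arm label (e.g. `"experimental"`).
#' @param endpoint `"PFS"` or `"OS"`.
#' @param time_unit One of `"weeks"`, `"months"`, `"years"`.
#' @param tol Monotonicity repair tolerance in survival units; increases of at
#'   most `tol` are flattened, larger increases are an error. Default 0.005.
#' @return An object of class `digitized_curve`: a data frame with columns
#'   `time` and `surv` plus attributes `arm_id`, `endpoint`, `time_unit`.
#' @seealso [read_digitized_curve()], [clean_curve()]
#' @export
digitized_curve <- function(time, surv, arm_id, endpoint = c("PFS", "OS"),
                            time_unit = c("months", "weeks", "years"),
                            tol = 0.005) {
  endpoint <- match.arg(endpoint)
  time_unit <- match.arg(time_unit)
  if (!is.numeric(time) || !is.numeric(surv)) {
    stop("'time' and 'surv' must be numeric", call. = FALSE)
  }
  if (length(time) != length(surv)) {
    stop("'time' and 'surv' must have equal length", call. = FALSE)
  }
  keep <- is.finite(time) & is.finite(surv)
  time <- time[keep]
  surv <- surv[keep]
  if (length(time) < 3L) {
    stop("insufficient data: a digitized curve needs at least 3 valid points",
         call. = FALSE)
  }
  if (any(time < 0)) stop("negative times in digitized curve", call. = FALSE)
  if (max(surv) > 1.5) surv <- surv / 100  # percent-scale export
  ord <- order(time)
  out <- structure(
    data.frame(time = time[ord], surv = surv[ord]),
    arm_id = as.character(arm_id), endpoint = endpoint,
    time_unit = time_unit, class = c("digitized_curve", "data.frame")
  )
  clean_curve(out, tol = tol)
}

#' Read a digitized survival curve from CSV
#'
#' Expects a comma-separated file with a header and two numeric columns,
#' time then survival (columns `time,survival` in the canonical dialect).
#' Survival may be on the probability or the percent scale; percent is
#' auto-detected when the maximum exceeds 1.5.
#'
#' @param path Path to the CSV file.
#' @inheritParams digitized_curve
#' @return A [digitized_curve()].
#' @export
read_digitized_curve <- function(path, arm_id, endpoint = c("PFS", "OS"),
                                 time_unit = c("months", "weeks", "years"),
                                 tol = 0.005) {
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L) stop("curve CSV needs two columns (time, survival)", call. = FALSE)
  tm <- suppressWarnings(as.numeric(df[[1L]]))
  sv <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- (is.na(tm) & !is.na(df[[1L]])) | (is.na(sv) & !is.na(df[[2L]]))
  if (any(bad)) {
    stop(sprintf("non-numeric cells in '%s' at row(s) %s", path,
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  digitized_curve(tm, sv, arm_id = arm_id, endpoint = endpoint,
                  time_unit = time_unit, tol = tol)
}

#' Clean a digitized curve
#'
#' Repairs the artifacts that plot digitizers leave on Kaplan-Meier
#' coordinates: duplicate times are collapsed to the minimum survival,
#' survival increases of magnitude at most `tol` are flattened to the
#' preceding value, survival is clipped to \[0, 1\], and a point (0, 1) is
#' prepended when absent. Increases larger than `tol` indicate mis-extracted
#' data and raise an error naming the offending point. Idempotent.
#'
#' @param curve A `digitized_curve` (or data frame with `time`, `surv`).
#' @param tol Maximum survival increase treated as jitter. Default 0.005.
#' @return The cleaned `digitized_curve`.
#' @export
clean_curve <- function(curve, tol = 0.005) {
  time <- curve$time
  surv <- pmin(pmax(curve$surv, 0), 1)
  ord <- order(time)
  time <- time[ord]; surv <- surv[ord]
  # collapse duplicate times, keeping the lowest survival
  if (anyDuplicated(time)) {
    surv <- as.numeric(tapply(surv, match(time, unique(time)), min))
    time <- unique(time)
  }
  if (length(time) == 0L || time[1L] > 0 || abs(surv[1L] - 1) > tol) {
    if (length(time) && time[1L] == 0) {
      # first point sits at t = 0 but below 1 beyond tolerance
      if (1 - surv[1L] > tol) {
        stop(sprintf("first point at t = 0 has survival %.4f, too far below 1",
                     surv[1L]), call. = FALSE)
      }
      surv[1L] <- 1
    } else {
      time <- c(0, time)
      surv <- c(1, surv)
    }
  } else {
    surv[1L] <- 1
  }
  # flatten jitter; anything larger is a data-quality error
  flattened <- 0L
  for (i in seq_along(surv)[-1L]) {
    if (surv[i] > surv[i - 1L]) {
      if (surv[i] - surv[i - 1L] > tol) {
        stop(sprintf(
          "survival increases by %.4f at point %d (t = %g); beyond tolerance %g",
          surv[i] - surv[i - 1L], i, time[i], tol), call. = FALSE)
      }
      surv[i] <- surv[i - 1L]
      flattened <- flattened + 1L
    }
  }
  if (flattened > 0L) {
    warning(sprintf("flattened %d small survival increase(s) (digitization jitter)",
                    flattened), call. = FALSE)
  }
  structure(
    data.frame(time = time, surv = surv),
    arm_id = attr(curve, "arm_id"), endpoint = attr(curve, "endpoint"),
    time_unit = attr(curve, "time_unit"),
    class = c("digitized_curve", "data.frame")
  )
}

#' Convert between survival time units
#'
#' Conversion constants are fixed at 1 year = 12 months = 365.25/7 weeks;
#' months to weeks goes through years.
#'
#' @param x Numeric vector of times, or a `digitized_curve`.
#' @param from,to Units among `"weeks"`, `"months"`, `"years"`. For a curve,
#'   `from` defaults to the curve's own unit.
#' @return The converted times (or curve with converted time axis).
#' @export
convert_time_unit <- function(x, from, to) {
  if (inherits(x, "digitized_curve")) {
    if (missing(from)) from <- attr(x, "time_unit")
    out <- x
    out$time <- convert_time_unit(x$time, from, to)
    attr(out, "time_unit") <- to
    return(out)
  }
  chk <- function(u) {
    if (!u %in% VALID_TIME_UNITS) {
      stop(sprintf("unknown time unit '%s'", u), call. = FALSE)
    }
  }
  chk(from); chk(to)
  per_year <- c(weeks = WEEKS_PER_YEAR, months = MONTHS_PER_YEAR, years = 1)
  x / per_year[[from]] * per_year[[to]]
}

#' Construct a number-at-risk table
#'
#' @param times Strictly increasing non-negative times (curve time unit).
#' @param n_at_risk Positive integers, non-increasing.
#' @return An object of class `risk_table`.
#' @export
risk_table <- function(times, n_at_risk) {
  if (length(times) != length(n_at_risk) || length(times) == 0L) {
    stop("'times' and 'n_at_risk' must be non-empty and of equal length",
         call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]; n_at_risk <- n_at_risk[ord]
  if (any(diff(times) <= 0)) stop("risk-table times must be strictly increasing", call. = FALSE)
  if (any(times < 0)) stop("risk-table times must be non-negative", call. = FALSE)
  if (any(n_at_risk <= 0) || any(n_at_risk != round(n_at_risk))) {
    stop("n_at_risk must be positive integers", call. = FALSE)
  }
  if (any(diff(n_at_risk) > 0)) {
    stop("n_at_risk must be non-increasing", call. = FALSE)
  }
  structure(data.frame(time = times, n_risk = as.integer(round(n_at_risk))),
            class = c("risk_table", "data.frame"))
}

#' Read a risk table from CSV (columns `time,n_risk`)
#'
#' @param path Path to the CSV file.
#' @return A [risk_table()].
#' @export
read_risk_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L) stop("risk-table CSV needs columns time,n_risk", call. = FALSE)
  risk_table(as.numeric(df[[1L]]), as.numeric(df[[2L]]))
}

#' Construct an IPD dataset
#'
#' Per-subject reconstructed (or simulated) records: observation time, event
#' indicator (1 = event, 0 = censored) and arm label.
#'
#' @param time Non-negative observation times.
#' @param event 0/1 event indicators.
#' @param arm Arm labels (recycled if scalar).
#' @param endpoint `"PFS"` or `"OS"`.
#' @param time_unit Time unit of `time`.
#' @return An object of class `ipd` (a data frame with columns `time`,
#'   `event`, `arm`).
#' @export
ipd_dataset <- function(time, event, arm, endpoint = c("PFS", "OS"),
                        time_unit = c("months", "weeks", "years")) {
  endpoint <- match.arg(endpoint)
  time_unit <- match.arg(time_unit)
  if (any(time < 0)) stop("IPD times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (length(arm) == 1L) arm <- rep(arm, length(time))
  structure(
    data.frame(time = as.numeric(time), event = as.integer(event),
               arm = as.character(arm)),
    endpoint = endpoint, time_unit = time_unit,
    class = c("ipd", "data.frame")
  )
}

#' Write reconstructed IPD to CSV (columns `time,event,arm`)
#'
#' Round-trips losslessly through [read_ipd()].
#'
#' @param ipd An [ipd_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "ipd"))
  utils::write.csv(as.data.frame(ipd)[, c("time", "event", "arm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IPD CSV written by [write_ipd()]
#'
#' @param path Path to the CSV file.
#' @inheritParams ipd_dataset
#' @return An [ipd_dataset()].
#' @export
read_ipd <- function(path, endpoint = c("PFS", "OS"),
                     time_unit = c("months", "weeks", "years")) {
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = c("numeric", "integer", "character"))
  ipd_dataset(df$time, df$event, if (nrow(df)) df$arm else character(0),
              endpoint = endpoint, time_unit = time_unit)
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve: arm '%s', endpoint %s, %d points over [0, %g] %s\n",
              attr(x, "arm_id"), attr(x, "endpoint"), nrow(x),
              max(x$time), attr(x, "time_unit")))
  invisible(x)
}

#' @export
print.ipd <- function(x, ...) {
  cat(sprintf("IPD dataset (%s): %d records, %d events, arms: %s\n",
              attr(x, "endpoint"), nrow(x), sum(x$event),
              paste(unique(x$arm), collapse = ", ")))
  invisible(x)
}
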
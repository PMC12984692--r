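# Behavioural indices from 15-minute scan sampling.
#
# Scan sampling counts, at fixed intervals, how many cows are engaged in
# each behaviour (lying, standing, walking, feeding). The Cow Lying Index
# (CLI) is the lying fraction; the Cow Activity Index (CAI) is the active
# fraction. With the four behaviours partitioning the herd, CLI + CAI = 1.

#' Cow Lying Index of one scan
#'
#' Fraction of observed cows lying: `CLI = n_lying / n_total`.
#'
#' @param scan a data frame (or one row) with columns `n_lying`,
#'   `n_standing`, `n_walking`, `n_feeding`; vectorised over rows.
#' @return CLI in `[0, 1]`, one value per row.
#' @export
cow_lying_index <- function(scan) {
  validate_scan(scan)
  scan$n_lying / scan_total(scan)
}

#' Cow Activity Index of one scan
#'
#' Fraction of observed cows engaged in active behaviours:
#' `CAI = (n_standing + n_walking + n_feeding) / n_total` by default.
#' Which behaviours count as active is configurable; with the default
#' set, CLI + CAI = 1 for every valid scan.
#'
#' @inheritParams cow_lying_index
#' @param active character vector of behaviours counted as active
#'   (subset of `"standing"`, `"walking"`, `"feeding"`).
#' @return CAI in `[0, 1]`, one value per row.
#' @export
cow_activity_index <- function(scan,
                               active = c("standing", "walking", "feeding")) {
  validate_scan(scan)
  active <- match.arg(active, several.ok = TRUE)
  cols <- paste0("n_", active)
  act <- rowSums(as.data.frame(scan[cols]))
  act / scan_total(scan)
}

#' Hourly mean behavioural indices
#'
#' Averages the per-scan CLI and CAI within each clock hour (typically
#' four 15-minute scans per hour). Hours with no scans yield `NA`, never
#' zero.
#'
#' @param scans data frame of scan observations sorted by time, with a
#'   `timestamp` column (`POSIXct`) and the count columns of
#'   [cow_lying_index()].
#' @param active behaviours counted as active, passed to
#'   [cow_activity_index()].
#' @return data frame with one row per hour spanned by the scans:
#'   `timestamp` (hour start), `CLI`, `CAI`, `n_scans`.
#' @export
hourly_behaviour <- function(scans, active = c("standing", "walking", "feeding")) {
  stopifnot(is.data.frame(scans), "timestamp" %in% names(scans))
  ts <- scans$timestamp
  stopifnot(inherits(ts, "POSIXct"))
  if (is.unsorted(as.numeric(ts))) {
    stop("scans must be sorted by timestamp", call. = FALSE)
  }
  cli <- cow_lying_index(scans)
  cai <- cow_activity_index(scans, active = active)
  hour_start <- as.POSIXct(trunc(ts, units = "hours"))
  hours <- seq(min(hour_start), max(hour_start), by = "hour")
  key <- match(hour_start, hours)
  agg <- function(x) {
    out <- rep(NA_real_, length(hours))
    m <- tapply(x, key, mean)
    out[as.integer(names(m))] <- as.numeric(m)
    out
  }
  n_scans <- integer(length(hours))
  tab <- table(key)
  n_scans[as.integer(names(tab))] <- as.integer(tab)
  data.frame(timestamp = hours, CLI = agg(cli), CAI = agg(cai),
             n_scans = n_scans)
}

validate_scan <- function(scan) {
  need <- c("n_lying", "n_standing", "n_walking", "n_feeding")
  missing_cols <- setdiff(need, names(scan))
  if (length(missing_cols)) {
    stop("scan is missing count column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts <- as.data.frame(scan[need])
  if (any(counts < 0)) stop("behaviour counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) < 1)) {
    stop("each scan must observe at least one cow (n_total >= 1)", call. = FALSE)
  }
  invisible(TRUE)
}

scan_total <- function(scan) {
  if ("n_total" %in% names(scan)) {
    tot <- scan$n_total
    parts <- scan$n_lying + scan$n_standing + scan$n_walking + scan$n_feeding
    if (any(tot != parts)) {
      stop("n_total must equal the sum of the four behaviour counts",
           call. = FALSE)
    }
    tot
  } else {
    scan$n_lying + scan$n_standing + scan$n_walking + scan$n_feeding
  }
}
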
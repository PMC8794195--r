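#' Daily hospital count panels
#'
#' A `panel_series` is a data frame with one row per day and columns
#' `day` (0-based integer index, strictly increasing by 1), `adm`
#' (admissions), `dis` (discharges) and `inp` (in-patients), plus
#' attributes: `beds` (capacity), per-day logical flags
#' (`newyear_corrected`, `gap_filled`) and a cleaning log. Raw panels may
#' contain missing cells and impossible counts; the cleaning operations
#' [fix_new_year()] and [fill_gap()] repair them, flag the touched days and
#' leave every other value bit-identical.
#'
#' @name panel_series
NULL

new_panel <- function(day, adm, dis, inp, beds,
                      flags = NULL, log = NULL) {
  x <- data.frame(day = as.integer(day), adm = adm, dis = dis, inp = inp)
  attr(x, "beds") <- as.integer(beds)
  if (is.null(flags))
    flags <- data.frame(newyear_corrected = logical(nrow(x)),
                        gap_filled = logical(nrow(x)))
  attr(x, "flags") <- flags
  attr(x, "cleaning_log") <- if (is.null(log)) empty_log() else log
  class(x) <- c("panel_series", "data.frame")
  x
}

empty_log <- function() {
  data.frame(day = integer(), rule = character(), column = character(),
             old = numeric(), new = numeric())
}

append_log <- function(panel, day, rule, column, old, new) {
  attr(panel, "cleaning_log") <- rbind(
    attr(panel, "cleaning_log"),
    data.frame(day = day, rule = rule, column = column,
               old = as.numeric(old), new = as.numeric(new)))
  panel
}

#' @export
print.panel_series <- function(x, ...) {
  cat("Daily panel:", nrow(x), "days,", attr(x, "beds"), "beds;",
      sum(is.na(x$inp)), "missing census values,",
      nrow(attr(x, "cleaning_log")), "cleaning actions\n")
  NextMethod()
}

#' Read a canonical daily-panel CSV
#'
#' The canonical dialect has one row per day and columns `day` (0-based
#' integer), optional `date` (ISO-8601, ignored by all computations),
#' `adm`, `dis`, `inp` (integer counts, empty cell = missing).
#'
#' @param path CSV file path.
#' @param beds bed capacity attached to the panel.
#' @param allow_real accept non-integer counts (TRUE when re-reading a
#'   cleaned panel, whose repaired/bridged days may be reals). Raw loads
#'   keep the strict integer check.
#' @return a `panel_series`.
#' @export
load_panel <- function(path, beds = 192L, allow_real = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("day", "adm", "dis", "inp")
  if (!all(need %in% names(raw)))
    stop("canonical panel CSV needs columns ", paste(need, collapse = ", "))
  parse_count <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(out))
    if (length(bad))
      stop("non-numeric ", col, " value ", dQuote(v[bad[1]]),
           " at row ", bad[1])
    if (allow_real) return(out)
    frac <- which(!is.na(out) & out != round(out))
    if (length(frac))
      stop("non-integer ", col, " value at row ", frac[1])
    as.integer(round(out))
  }
  day <- parse_count("day")
  if (anyNA(day)) stop("missing day index at row ", which(is.na(day))[1])
  if (anyDuplicated(day)) stop("duplicate day index: ",
                               day[anyDuplicated(day)])
  if (any(diff(day) != 1L))
    stop("day index must increase by 1 (violated after day ",
         day[which(diff(day) != 1L)[1]], ")")
  new_panel(day = day, adm = parse_count("adm"), dis = parse_count("dis"),
            inp = parse_count("inp"), beds = beds)
}

#' Write a panel in the canonical CSV dialect
#'
#' Deterministic output: identical panels serialize byte-for-byte.
#'
#' @param panel a `panel_series`.
#' @param path output path.
#' @export
write_panel_csv <- function(panel, path) {
  df <- as.data.frame(panel)[c("day", "adm", "dis", "inp")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the cleaning log as JSON
#'
#' @param panel a cleaned `panel_series`.
#' @param path output path for the JSON log (day, rule, column, old, new).
#' @export
write_cleaning_log <- function(panel, path) {
  jsonlite::write_json(attr(panel, "cleaning_log"), path, digits = NA)
  invisible(path)
}

#' Repair impossible year-boundary counts
#'
#' Command-panel exports carry a software bug that books impossible
#' admission/discharge totals (hundreds more than the hospital has beds)
#' on January-1 rows. Any `adm`/`dis`/`inp` value exceeding the bed
#' capacity is replaced by the arithmetic mean of the flanking days'
#' values, and the day is flagged `newyear_corrected`.
#'
#' @param panel a `panel_series`.
#' @param suspect_days optional integer vector of 0-based day indices to
#'   restrict the check to; by default every day is screened.
#' @return the repaired `panel_series`. Errors if a suspect day sits at a
#'   series boundary or if two suspect days are adjacent (a flank would
#'   itself be suspect, so the rule cannot apply).
#' @export
fix_new_year <- function(panel, suspect_days = NULL) {
  beds <- attr(panel, "beds")
  flags <- attr(panel, "flags")
  for (col in c("adm", "dis", "inp")) {
    v <- panel[[col]]
    bad <- which(!is.na(v) & v > beds)
    if (!is.null(suspect_days))
      bad <- intersect(bad, match(suspect_days, panel$day))
    if (!length(bad)) next
    if (any(diff(bad) == 1L))
      stop("adjacent impossible values in ", col,
           " (days ", paste(panel$day[bad], collapse = ", "),
           "): a flanking day is itself suspect, cannot average")
    if (any(bad == 1L | bad == nrow(panel)))
      stop("impossible value in ", col, " at the series boundary: ",
           "no flanking pair to average")
    for (i in bad) {
      lo <- v[i - 1L]; hi <- v[i + 1L]
      if (is.na(lo) || is.na(hi))
        stop("flanking day of suspect day ", panel$day[i], " is missing")
      newv <- (lo + hi) / 2
      panel <- append_log(panel, panel$day[i], "newyear", col, v[i], newv)
      v[i] <- newv
      flags$newyear_corrected[i] <- TRUE
    }
    panel[[col]] <- v
  }
  attr(panel, "flags") <- flags
  panel
}

#' Bridge a contiguous gap of missing days
#'
#' The constant daily change (y_after - y_before) / gap_len is applied
#' cumulatively across the gap, so the last gap day reaches the value of
#' the first observed day after the gap. Filled values are kept as reals
#' (not rounded) so telescoping identities hold exactly; filled days are
#' flagged `gap_filled`.
#'
#' @param panel a `panel_series`.
#' @param gap_start 0-based day index of the first missing day, or NULL to
#'   auto-detect every contiguous missing run.
#' @param gap_len gap length in days (required with `gap_start`).
#' @param columns columns to bridge (default all three count columns).
#' @return the filled `panel_series`.
#' @export
fill_gap <- function(panel, gap_start = NULL, gap_len = NULL,
                     columns = c("adm", "dis", "inp")) {
  if (is.null(gap_start)) {
    miss <- is.na(panel$inp)
    if (!any(miss)) return(panel)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      panel <- fill_gap(panel, panel$day[starts[k]], r$lengths[k], columns)
    }
    return(panel)
  }
  stopifnot(!is.null(gap_len), gap_len >= 1)
  i0 <- match(gap_start, panel$day)
  if (is.na(i0)) stop("gap_start day ", gap_start, " not in panel")
  idx <- i0 + seq_len(gap_len) - 1L
  if (i0 == 1L) stop("gap at series start: no flanking value before it")
  if (max(idx) == nrow(panel))
    stop("gap at series end: no flanking value after it")
  flags <- attr(panel, "flags")
  for (col in columns) {
    v <- panel[[col]]
    if (!all(is.na(v[idx])))
      stop("days ", gap_start, "..", gap_start + gap_len - 1L,
           " are not all missing in ", col)
    before <- v[i0 - 1L]; after <- v[max(idx) + 1L]
    if (is.na(before) || is.na(after))
      stop("flanking day of the gap is missing in ", col)
    step <- (after - before) / gap_len
    fill <- before + step * seq_len(gap_len)
    panel[[col]] <- v
    panel[[col]][idx] <- fill
    for (k in seq_along(idx))
      panel <- append_log(panel, panel$day[idx[k]], "gap_fill", col,
                          NA_real_, fill[k])
  }
  flags$gap_filled[idx] <- TRUE
  attr(panel, "flags") <- flags
  panel
}

#' One-day difference series
#'
#' The first element is 0 by convention; thereafter
#' dy[t] = y[t] - y[t-1]. The sum of the difference series over t = 2..n
#' telescopes to y[n] - y[1].
#'
#' @param y a cleaned numeric series (no missing values).
#' @return numeric vector the same length as `y`.
#' @export
daily_diff <- function(y) {
  if (anyNA(y)) stop("difference series requires a cleaned series ",
                     "(missing values present)")
  if (!length(y)) stop("empty series")
  c(0, diff(y))
}

#' Daily admissions-minus-discharges difference (DDiAd)
#'
#' Sign convention: admissions minus discharges, so that accumulating the
#' series reproduces the census walk up to its initial value.
#'
#' @param panel a cleaned `panel_series`.
#' @return numeric vector, one value per day.
#' @export
ddiad <- function(panel) {
  if (anyNA(panel$adm) || anyNA(panel$dis))
    stop("ddiad requires a cleaned panel")
  panel$adm - panel$dis
}

#' Reconstruct the census random walk from a difference series
#'
#' Xi[1] = 0 and Xi[i] = Xi[i-1] + d[i] for i >= 2. Applied to the DDiAd
#' series of a clean panel this reproduces the in-patient series exactly,
#' shifted by the day-1 census.
#'
#' @param d a difference series.
#' @return numeric walk of the same length.
#' @export
reconstruct_walk <- function(d) {
  if (!length(d)) stop("empty difference series")
  d[1] <- 0
  cumsum(d)
}

#' Mean length of stay per day
#'
#' For each day, the mean of the accumulated stay durations of the
#' patients present; days with no patients yield NA (undefined), not 0.
#' Per-day means of this kind are ratios of random quantities and can be
#' heavy-tailed, which is why the toolbox is nonparametric throughout.
#'
#' @param stays_by_day list with one numeric vector of per-patient stay
#'   durations (days) per day.
#' @return numeric vector of daily means (NA for empty days).
#' @export
mean_los <- function(stays_by_day) {
  stopifnot(is.list(stays_by_day))
  vapply(stays_by_day, function(s) {
    if (!length(s)) return(NA_real_)
    if (any(s < 0)) stop("negative stay duration")
    mean(s)
  }, numeric(1))
}

#' Occupancy summary of a cleaned panel
#'
#' Hodges-Lehmann median of the daily census with its 95% confidence
#' interval, the census range, and the same quantities as percent of bed
#' capacity.
#'
#' @param panel a cleaned `panel_series`.
#' @param conf confidence level for the median CI.
#' @return a list: `median`, `ci` (length 2), `min`, `max`, and
#'   `pct_median`, `pct_ci`, `pct_min`, `pct_max` as percent of beds.
#' @export
occupancy_stats <- function(panel, conf = 0.95) {
  if (anyNA(panel$inp)) stop("occupancy_stats requires a cleaned panel")
  beds <- attr(panel, "beds")
  hl <- hl_median_ci(panel$inp, conf = conf)
  pct <- function(x) 100 * x / beds
  list(median = hl$estimate, ci = c(hl$lower, hl$upper),
       min = min(panel$inp), max = max(panel$inp),
       pct_median = pct(hl$estimate),
       pct_ci = pct(c(hl$lower, hl$upper)),
       pct_min = pct(min(panel$inp)), pct_max = pct(max(panel$inp)))
}
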
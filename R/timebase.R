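# ISO-8601 weekly calendar grid and time covariates.
#
# All downstream models use two covariates derived from the grid:
#   t_days -- days since 1970-01-01 of each ISO week's Monday (the within-week
#             anchor; ISO weeks start on Monday), carrying the long-term trend;
#   w      -- week of the year scaled to [0, 1), carrying seasonality.

#' Monday of ISO week 1 of a given year
#'
#' ISO 8601 places week 1 so that it contains January 4th; weeks start on
#' Monday.
#'
#' @param year integer ISO year.
#' @return a `Date`.
#' @keywords internal
iso_week1_monday <- function(year) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  jan4 - (as.integer(format(jan4, "%u")) - 1L)
}

#' Number of ISO weeks in a year
#'
#' Either 52 or 53; long (53-week) years between 2000 and 2023 are 2004,
#' 2009, 2015 and 2020.
#'
#' @param year integer ISO year (vectorised).
#' @return integer vector of 52s and 53s.
#' @export
#' @examples
#' weeks_in_iso_year(2020)  # 53
weeks_in_iso_year <- function(year) {
  vapply(year, function(y) {
    as.integer((iso_week1_monday(y + 1L) - iso_week1_monday(y)) / 7L)
  }, integer(1))
}

#' Scale an ISO week number to [0, 1)
#'
#' Maps week `iso_week` of a `weeks_in_year`-week year to
#' `(iso_week - 1) / weeks_in_year`.  Week 1 maps to 0 and the last week
#' maps to below 1, so a periodic (cyclic) seasonal function never evaluates
#' the first and the last week of a year at the same point.
#'
#' @param iso_week integer ISO week number(s), between 1 and `weeks_in_year`.
#' @param weeks_in_year 52 or 53 (recycled against `iso_week`).
#' @return numeric in `[0, 1)`.
#' @export
#' @examples
#' scale_week(1, 52)   # 0
#' scale_week(27, 52)  # 0.5
scale_week <- function(iso_week, weeks_in_year) {
  if (!all(weeks_in_year %in% c(52L, 53L)))
    stop("`weeks_in_year` must be 52 or 53", call. = FALSE)
  bad <- iso_week < 1L | iso_week > weeks_in_year
  if (any(bad))
    stop("`iso_week` out of range 1..weeks_in_year: ",
         paste(iso_week[bad], collapse = ", "), call. = FALSE)
  (iso_week - 1) / weeks_in_year
}

#' Build the ISO-8601 weekly calendar grid
#'
#' One row per ISO week of each ISO year in `start_year:end_year`, with the
#' time covariates used throughout the package.
#'
#' @param start_year,end_year integer ISO years, `1970 <= start_year <=
#'   end_year`.
#' @return a data frame of class `week_grid` with columns `iso_year`,
#'   `iso_week`, `weeks_in_year`, `t_days` (days since 1970-01-01 of the
#'   week's Monday) and `w` (scaled week of year, see [scale_week()]).
#'   Consecutive rows differ by exactly 7 in `t_days`.
#' @export
#' @examples
#' g <- week_grid(2015, 2020)
#' table(g$iso_year)  # 2015 and 2020 have 53 weeks
week_grid <- function(start_year, end_year) {
  if (length(start_year) != 1L || length(end_year) != 1L ||
      is.na(start_year) || is.na(end_year))
    stop("`start_year` and `end_year` must be single years", call. = FALSE)
  if (start_year < 1970)
    stop("`start_year` must be 1970 or later", call. = FALSE)
  if (start_year > end_year)
    stop("`start_year` must not exceed `end_year`", call. = FALSE)
  rows <- lapply(seq.int(start_year, end_year), function(y) {
    nw <- weeks_in_iso_year(y)
    monday <- iso_week1_monday(y) + 7L * (seq_len(nw) - 1L)
    data.frame(iso_year = as.integer(y), iso_week = seq_len(nw),
               weeks_in_year = nw, t_days = as.integer(monday),
               w = scale_week(seq_len(nw), nw))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("week_grid", "data.frame")
  out
}

#' Sum weekly deaths to yearly totals
#'
#' Computes the actual yearly death count `M_y`, the sum of the weekly counts
#' over all ISO weeks of year `y`.  53-week years sum 53 values.
#'
#' @param series a data frame with columns `iso_year`, `iso_week` and
#'   `deaths` (e.g. a [simulate_mortality()] result or a
#'   [read_weekly_series()] import).
#' @param years integer vector of years to total; each must be fully covered
#'   by the series.
#' @return a data frame with columns `year` and `deaths`.
#' @export
#' @examples
#' s <- simulate_mortality(seed = 1)
#' yearly_totals(s, 2020:2023)
yearly_totals <- function(series, years) {
  stopifnot(is.data.frame(series),
            all(c("iso_year", "iso_week", "deaths") %in% names(series)))
  years <- as.integer(years)
  if (length(years) == 0L)
    return(data.frame(year = integer(), deaths = numeric()))
  deaths <- vapply(years, function(y) {
    wk <- sort(series$iso_week[series$iso_year == y])
    need <- seq_len(weeks_in_iso_year(y))
    if (!identical(as.integer(wk), need))
      stop("year ", y, " is not fully covered by the series", call. = FALSE)
    sum(series$deaths[series$iso_year == y])
  }, numeric(1))
  data.frame(year = years, deaths = deaths)
}

#' Read / write a weekly mortality series as CSV
#'
#' The on-disk layout has a header and columns `iso_year,iso_week,deaths`,
#' mirroring a Eurostat `demo_r_mwk_ts`-style weekly export.  The reader
#' reconstructs the calendar covariates (`t_days`, `w`, `weeks_in_year`)
#' from the ISO year and week.
#'
#' A small synthetic example file (a [make_fixture()] output) ships with
#' the package, see the example below.
#'
#' @param path file path.
#' @return for `read_weekly_series`, a data frame with the [week_grid()]
#'   columns plus `deaths`.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_weekly_deaths.csv",
#'                     package = "baselinemort")
#' head(read_weekly_series(path))
read_weekly_series <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("iso_year", "iso_week", "deaths")
  if (!all(need %in% names(raw)))
    stop("weekly series CSV must have columns iso_year, iso_week, deaths",
         call. = FALSE)
  grid <- week_grid(min(raw$iso_year), max(raw$iso_year))
  out <- merge(grid, raw[need], by = c("iso_year", "iso_week"),
               all.x = FALSE, all.y = TRUE, sort = FALSE)
  out <- out[order(out$t_days), c(names(grid), "deaths")]
  rownames(out) <- NULL
  class(out) <- c("weekly_series", "data.frame")
  out
}

#' @rdname read_weekly_series
#' @param series data frame with columns `iso_year`, `iso_week`, `deaths`.
#' @export
write_weekly_series <- function(series, path) {
  stopifnot(all(c("iso_year", "iso_week", "deaths") %in% names(series)))
  utils::write.csv(series[, c("iso_year", "iso_week", "deaths")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
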
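#' Classify timestamps as day or night
#'
#' Night is the half-open interval from local sunset to the next sunrise:
#' a timestamp at exactly sunset is night, one at exactly sunrise is day.
#' Sunset and sunrise come from a per-date [sun_table()].
#'
#' @param timestamps POSIXct vector (local clock time).
#' @param sun a [sun_table()] covering every date in `timestamps`.
#' @return character vector of "day"/"night".
#' @examples
#' st <- sun_table(as.Date("2024-11-11"))
#' classify_diel(as.POSIXct("2024-11-11 17:46:00", tz = "UTC"), st)
#' @export
classify_diel <- function(timestamps, sun) {
  stopifnot(inherits(timestamps, "POSIXct"), is.data.frame(sun),
            all(c("date", "sunrise", "sunset") %in% names(sun)))
  dates <- as.Date(timestamps, tz = "UTC")
  i <- match(dates, sun$date)
  if (anyNA(i))
    stop("no sunrise/sunset entry for date(s): ",
         paste(unique(dates[is.na(i)]), collapse = ", "))
  mk <- function(times) as.POSIXct(paste(sun$date[i], times[i]), tz = "UTC")
  sunset <- mk(sun$sunset); sunrise <- mk(sun$sunrise)
  ifelse(timestamps >= sunset | timestamps < sunrise, "night", "day")
}

#' Aggregate stratified search effort from dive logs
#'
#' Each 10-s dive-log sample contributes its interval to the matching
#' (habitat, diel) effort cell, to its 15-min time-of-day bin and to its
#' 1-m depth bin. Bins are left-closed: depth bin i covers \[i, i+1) m and
#' the time bin starting at t covers \[t, t+15 min). With
#' `per_searcher_average = TRUE` the depth histogram reports the average
#' hours per searcher rather than the total.
#'
#' @param logs data.frame with columns `searcher_id`, `timestamp`
#'   (POSIXct), `depth_m`, `habitat`; a `diel` column is recomputed from
#'   `sun`. May also be a `dive_log_set`.
#' @param sun a [sun_table()].
#' @param sample_interval_s nominal sampling interval (default 10 s).
#' @param per_searcher_average average the depth histogram across
#'   searchers.
#' @return object of class `effort_table`: list with `cells` (habitat x
#'   diel hours), `time_histogram` (15-min bins of local time),
#'   `depth_histogram` (1-m bins split by habitat and diel),
#'   `total_hours`, `n_samples`, `n_searchers`.
#' @export
aggregate_effort <- function(logs, sun, sample_interval_s = 10,
                             per_searcher_average = FALSE) {
  if (inherits(logs, "dive_log_set")) {
    if (missing(sun)) sun <- logs$sun
    logs <- logs$logs
  }
  stopifnot(is.data.frame(logs),
            all(c("searcher_id", "timestamp", "depth_m", "habitat")
                %in% names(logs)),
            inherits(logs$timestamp, "POSIXct"))
  if (any(logs$depth_m < -0.5))
    stop("depth below surface tolerance (-0.5 m) in dive log")
  # per-searcher time ordering and duplicate detection
  for (s in unique(logs$searcher_id)) {
    tt <- logs$timestamp[logs$searcher_id == s]
    if (is.unsorted(tt)) stop(sprintf("log of searcher %s is not time-sorted", s))
    if (anyDuplicated(tt))
      stop(sprintf("overlapping duplicate samples for searcher %s", s))
  }
  diel <- classify_diel(logs$timestamp, sun)
  hours_per_sample <- sample_interval_s / 3600

  cells <- stats::aggregate(
    list(hours = rep(hours_per_sample, nrow(logs))),
    by = list(habitat = logs$habitat, diel = diel), FUN = sum)

  secs <- as.numeric(logs$timestamp) %% 86400
  tbin <- floor(secs / 900) * 900
  th <- stats::aggregate(list(hours = rep(hours_per_sample, nrow(logs))),
                         by = list(bin_start_s = tbin), FUN = sum)
  th$bin_start <- sprintf("%02d:%02d", th$bin_start_s %/% 3600,
                          (th$bin_start_s %% 3600) %/% 60)

  dbin <- floor(pmax(logs$depth_m, 0))
  dh <- stats::aggregate(
    list(hours = rep(hours_per_sample, nrow(logs))),
    by = list(depth_bin = dbin, habitat = logs$habitat, diel = diel),
    FUN = sum)
  n_searchers <- length(unique(logs$searcher_id))
  if (per_searcher_average) dh$hours <- dh$hours / n_searchers

  structure(list(cells = cells, time_histogram = th[order(th$bin_start_s), ],
                 depth_histogram = dh[order(dh$habitat, dh$diel, dh$depth_bin), ],
                 total_hours = nrow(logs) * hours_per_sample,
                 n_samples = nrow(logs), n_searchers = n_searchers,
                 per_searcher_average = per_searcher_average),
            class = "effort_table")
}

#' @export
print.effort_table <- function(x, ...) {
  cat(sprintf("Search effort: %.2f h over %d samples, %d searcher(s)\n",
              x$total_hours, x$n_samples, x$n_searchers))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Expected count from a transferred encounter rate
#'
#' Under a homogeneous-Poisson null the discovery rate observed in one
#' stratum transfers to another in proportion to effort: the expected
#' count over `effort_target` hours is
#' `n_obs * effort_target / effort_obs`.
#'
#' @param n_obs animals observed in the reference stratum.
#' @param effort_obs searcher-hours in the reference stratum (> 0).
#' @param effort_target searcher-hours in the stratum of interest.
#' @return expected count (numeric).
#' @examples
#' expected_count(25, 38.2, 32.0)  # 20.9 animals expected by day
#' expected_count(25, 57.4, 12.7)  # 5.5 animals expected on muck
#' @export
expected_count <- function(n_obs, effort_obs, effort_target) {
  stopifnot(is.numeric(n_obs), n_obs >= 0, is.numeric(effort_target),
            effort_target >= 0)
  if (!is.numeric(effort_obs) || effort_obs <= 0)
    stop("effort_obs must be positive")
  n_obs * effort_target / effort_obs
}

#' Exact Poisson rate test (conditional binomial)
#'
#' Compares two Poisson rates from counts x1, x2 observed over exposures
#' T1, T2. Conditional on the total n = x1 + x2, x1 is Binomial(n, p)
#' with p = T1 / (T1 + T2) under equal rates. Tail probabilities are
#' computed by exact summation of binomial terms (no normal
#' approximation): the `deficit` alternative is P(X <= x1), `excess` is
#' P(X >= x1), and `two.sided` sums the probabilities of all outcomes no
#' more likely than the observed one (minimum-likelihood method).
#'
#' @param x1,x2 non-negative integer counts.
#' @param T1,T2 positive exposures (searcher-hours).
#' @param alternative `"deficit"` (rate 1 lower), `"excess"` (rate 1
#'   higher) or `"two.sided"`.
#' @return an object of class `htest` with the p-value, the conditional
#'   binomial parameters and the two rate estimates.
#' @examples
#' # no daytime sightings vs 25 at night over 32.0 / 38.2 h
#' exact_poisson_rate_test(0, 32.0, 25, 38.2, "deficit")$p.value
#' @export
exact_poisson_rate_test <- function(x1, T1, x2, T2,
                                    alternative = c("deficit", "excess",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x1), is.numeric(x2), length(x1) == 1L,
            length(x2) == 1L, x1 >= 0, x2 >= 0,
            T1 > 0, T2 > 0, is.finite(T1), is.finite(T2))
  if (x1 %% 1 != 0 || x2 %% 1 != 0) stop("counts must be integers")
  n <- x1 + x2
  p <- T1 / (T1 + T2)
  pval <- if (n == 0) 1 else switch(alternative,
    deficit = sum(dbinom(0:x1, n, p)),
    excess  = sum(dbinom(x1:n, n, p)),
    two.sided = {
      d <- dbinom(0:n, n, p)
      # relative tolerance guards ties against floating-point jitter
      sum(d[d <= d[x1 + 1L] * (1 + 1e-7)])
    })
  pval <- min(pval, 1)
  structure(list(
    statistic = c(x1 = x1),
    parameter = c(n = n, p = p),
    p.value = pval,
    estimate = c(`rate 1` = x1 / T1, `rate 2` = x2 / T2),
    alternative = alternative,
    method = "Exact Poisson rate test (conditional binomial)",
    data.name = sprintf("%d of %g h vs %d of %g h", x1, T1, x2, T2)),
    class = "htest")
}
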
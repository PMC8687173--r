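#' Meal schedules
#'
#' An ordered list of oral glucose doses. Each meal is ingested at a finite
#' constant rate, so dose `D` (mg) entering at `rate` (mg/min) occupies the
#' window `[start, start + D/rate)` minutes. Ingestion windows must not
#' overlap.
#'
#' @param dose_mg numeric vector of doses (mg), all positive.
#' @param start_min numeric vector of meal start times (min from simulation
#'   start), same length as `dose_mg`.
#' @param rate_mg_min ingestion rate(s), mg/min; recycled to the number of
#'   meals.
#' @return An object of class `meal_schedule`: a data frame with columns
#'   `start`, `end`, `rate`, `dose` sorted by start time.
#' @examples
#' standard_meal_schedule()  # 37 + 74 + 74 g at 3.7 g/min
#' @export
meal_schedule <- function(dose_mg = numeric(), start_min = numeric(),
                          rate_mg_min = numeric()) {
  n <- length(dose_mg)
  if (length(start_min) != n)
    stop("dose_mg and start_min must have the same length")
  if (n == 0L) {
    ev <- data.frame(start = numeric(), end = numeric(),
                     rate = numeric(), dose = numeric())
    class(ev) <- c("meal_schedule", "data.frame")
    return(ev)
  }
  rate <- rep_len(rate_mg_min, n)
  if (any(dose_mg <= 0)) stop("meal doses must be positive")
  if (any(rate <= 0)) stop("ingestion rates must be positive")
  if (any(start_min < 0)) stop("meal start times must be nonnegative")
  o <- order(start_min)
  ev <- data.frame(start = start_min[o], rate = rate[o], dose = dose_mg[o])
  ev$end <- ev$start + ev$dose / ev$rate
  ev <- ev[, c("start", "end", "rate", "dose")]
  if (n > 1L && any(ev$start[-1L] < ev$end[-n] - 1e-12))
    stop("meal ingestion windows overlap")
  class(ev) <- c("meal_schedule", "data.frame")
  ev
}

#' Three-meal daily schedule
#'
#' Breakfast 37 g, lunch 74 g and dinner 74 g of glucose (185 g total),
#' each ingested at 3.7 g/min. With the simulation clock starting at 6 AM,
#' the meals begin at t = 120, 420 and 960 min (8 AM, 1 PM, 10 PM).
#'
#' @param doses_g doses in grams (default `c(37, 74, 74)`).
#' @param starts_min start times in minutes (default `c(120, 420, 960)`).
#' @param rate_g_min ingestion rate in g/min (default 3.7).
#' @return A [meal_schedule()].
#' @export
standard_meal_schedule <- function(doses_g = c(37, 74, 74),
                                   starts_min = c(120, 420, 960),
                                   rate_g_min = 3.7) {
  meal_schedule(dose_mg = doses_g * 1000, start_min = starts_min,
                rate_mg_min = rate_g_min * 1000)
}

#' Query a meal schedule at a time point
#'
#' @param schedule a [meal_schedule()].
#' @param t time (min).
#' @return List with `rate` — the current ingestion rate into the solid
#'   stomach compartment (mg/min, 0 outside ingestion windows) — and `D`,
#'   the dose of the most recent meal started at or before `t` (mg, 0
#'   before the first meal). `D` parameterizes the gastric-emptying shape.
#' @export
meal_input <- function(schedule, t) {
  rate <- 0
  D <- 0
  if (nrow(schedule)) {
    started <- schedule$start <= t
    if (any(started)) D <- schedule$dose[max(which(started))]
    active <- started & t < schedule$end
    if (any(active)) rate <- schedule$rate[which(active)[1L]]
  }
  list(rate = rate, D = D)
}

# schedule as plain matrix for the C++ integrator
meal_matrix <- function(schedule) {
  if (!nrow(schedule)) return(matrix(numeric(), ncol = 4L))
  as.matrix(as.data.frame(unclass(schedule)))[, c("start", "end", "rate", "dose"),
                                              drop = FALSE]
}

#' @export
print.meal_schedule <- function(x, ...) {
  cat("Meal schedule:", nrow(x), "meal(s),",
      sum(x$dose) / 1000, "g total\n")
  print(as.data.frame(unclass(x)), ...)
  invisible(x)
}
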
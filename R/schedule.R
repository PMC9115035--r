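#' Oxic/anoxic switching schedule
#'
#' A schedule is a step function over time: an ordered set of switch points
#' `(time_min, state)` starting at time 0, with half-open intervals
#' \[t_i, t_{i+1}) so a switch time belongs to the new state.
#'
#' @param time_min integer minutes of each switch, strictly increasing,
#'   first entry 0.
#' @param state character vector of `"oxic"`/`"anoxic"`, same length.
#' @return object of class `oxic_schedule` (a data.frame).
#' @export
#' @examples
#' sch <- oxic_schedule(c(0, 360), c("anoxic", "oxic"))
#' state_at(sch, 359); state_at(sch, 360)
oxic_schedule <- function(time_min, state) {
  if (length(time_min) != length(state) || !length(time_min))
    stop("time_min and state must be non-empty vectors of equal length")
  time_min <- as.numeric(time_min)
  if (any(!is.finite(time_min)) || any(time_min != floor(time_min)))
    stop("switch times must be integer minutes")
  if (time_min[1] != 0)
    stop("the first switch point must be at time 0")
  if (any(diff(time_min) <= 0))
    stop("switch times must be strictly increasing")
  state <- as.character(state)
  bad <- !state %in% c("oxic", "anoxic")
  if (any(bad))
    stop("unknown state '", state[which(bad)[1]], "'; use 'oxic' or 'anoxic'")
  structure(data.frame(time_min = time_min, state = state,
                       stringsAsFactors = FALSE),
            class = c("oxic_schedule", "data.frame"))
}

#' Look up the redox state at a time point
#'
#' @param schedule an [oxic_schedule()].
#' @param t time in minutes, `t >= 0` (vectorised).
#' @return character vector of `"oxic"`/`"anoxic"`.
#' @export
state_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "oxic_schedule"))
  if (any(t < 0)) stop("t must be >= 0")
  idx <- findInterval(t, schedule$time_min)
  schedule$state[idx]
}

#' Read a switching schedule from CSV
#'
#' Expects header `time_min,state` with integer minutes and `oxic`/`anoxic`
#' rows; the first row must be at time 0 and times must strictly increase.
#'
#' @param path CSV file path.
#' @return an [oxic_schedule()].
#' @export
read_schedule_csv <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!identical(names(df), c("time_min", "state")))
    stop("schedule CSV must have header 'time_min,state'")
  if (!nrow(df)) stop("schedule CSV has no rows")
  bad <- which(!df$state %in% c("oxic", "anoxic"))
  if (length(bad))
    stop("row ", bad[1], ": unknown state '", df$state[bad[1]], "'")
  if (df$time_min[1] != 0)
    stop("row 1: schedule must start at time 0")
  mono <- which(diff(df$time_min) <= 0)
  if (length(mono))
    stop("row ", mono[1] + 1L, ": switch times must be strictly increasing")
  oxic_schedule(df$time_min, df$state)
}

#' Write a switching schedule to CSV
#'
#' @param schedule an [oxic_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "oxic_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Oxic/anoxic cycling schedules of equal duty cycle
#'
#' Two cycling regimes sharing the total incubation time and a 3:1
#' anoxic:oxic duty cycle, differing only in switching frequency:
#' `short` cycles of 360 min anoxic + 120 min oxic versus `long` cycles of
#' 1080 min anoxic + 360 min oxic. With the default total of 2880 min this
#' yields 6 short or 2 long cycles.
#'
#' @param total total schedule length in minutes; must be divisible by the
#'   cycle length (480 for short, 1440 for long).
#' @param short logical; `TRUE` for the high-frequency regime.
#' @return an [oxic_schedule()] starting anoxic.
#' @export
cycling_schedule <- function(total = 2880, short = TRUE) {
  anox <- if (short) 360 else 1080
  ox <- if (short) 120 else 360
  cyc <- anox + ox
  if (total <= 0 || total %% cyc != 0)
    stop("total (", total, ") must be a positive multiple of the cycle length ",
         cyc)
  n <- total %/% cyc
  starts <- (seq_len(n) - 1L) * cyc
  oxic_schedule(
    time_min = as.vector(rbind(starts, starts + anox)),
    state = rep(c("anoxic", "oxic"), n)
  )
}

#' @export
print.oxic_schedule <- function(x, ...) {
  cat("<oxic_schedule> ", nrow(x), " switch points\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
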
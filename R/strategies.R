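#' Define a screening strategy
#'
#' A strategy is a start age, a stop age (inclusive) and a screening
#' interval in years. Screens fall on ages \code{start_age + k *
#' interval} up to and including \code{stop_age}, at the start of the
#' corresponding model cycle. Labels follow the
#' \code{"(CBE+BUS)+MAM/<interval>year/<start>_<stop>"} convention.
#'
#' @param start_age first screening age in years.
#' @param stop_age last eligible screening age in years (inclusive).
#' @param interval years between screens (>= 1).
#' @param label optional label; generated from the fields by default.
#' @return A \code{bc_strategy} object.
#' @examples
#' screening_strategy(35, 65, 2)$label  # "(CBE+BUS)+MAM/2year/35_65"
#' @export
screening_strategy <- function(start_age, stop_age, interval,
                               label = NULL) {
  if (start_age > stop_age)
    stop(sprintf("infeasible strategy: start age %d > stop age %d",
                 start_age, stop_age), call. = FALSE)
  if (interval < 1)
    stop("screening interval must be >= 1 year", call. = FALSE)
  if (is.null(label))
    label <- sprintf("(CBE+BUS)+MAM/%dyear/%d_%d",
                     as.integer(interval), as.integer(start_age),
                     as.integer(stop_age))
  structure(list(start_age = as.integer(start_age),
                 stop_age = as.integer(stop_age),
                 interval = as.integer(interval),
                 label = label, no_screening = FALSE),
            class = "bc_strategy")
}

#' The no-screening comparator
#'
#' @return A \code{bc_strategy} with screening disabled at all ages.
#' @export
no_screening <- function() {
  structure(list(start_age = NA_integer_, stop_age = NA_integer_,
                 interval = NA_integer_, label = "no screening",
                 no_screening = TRUE),
            class = "bc_strategy")
}

#' Enumerate a strategy design space
#'
#' Cartesian product of starting ages, stopping ages and screening
#' intervals, in deterministic order (start, then stop, then interval).
#' The default arguments span the 27-strategy design space: starts
#' \{35, 40, 45\}, stops \{65, 69, 74\}, intervals \{1, 2, 3\} years.
#'
#' @param starts starting ages.
#' @param stops stopping ages.
#' @param intervals screening intervals in years.
#' @return List of \code{bc_strategy} objects with unique labels.
#' @examples
#' length(enumerate_strategies())  # 27
#' @export
enumerate_strategies <- function(starts = c(35, 40, 45),
                                 stops = c(65, 69, 74),
                                 intervals = c(1, 2, 3)) {
  if (!length(starts) || !length(stops) || !length(intervals))
    stop("starts, stops and intervals must be non-empty", call. = FALSE)
  bad <- expand.grid(start = starts, stop = stops)
  bad <- bad[bad$start > bad$stop, ]
  if (nrow(bad))
    stop(sprintf("infeasible strategy: start age %d > stop age %d",
                 bad$start[1], bad$stop[1]), call. = FALSE)
  out <- list()
  for (s in starts) for (e in stops) for (i in intervals)
    out[[length(out) + 1L]] <- screening_strategy(s, e, i)
  labels <- vapply(out, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate strategy labels in design space", call. = FALSE)
  out
}

#' Is an age on a strategy's screening schedule?
#'
#' @param strategy a \code{bc_strategy}.
#' @param age age in years (vectorised).
#' @return Logical: \code{TRUE} iff the strategy screens at that age.
#' @export
is_screening_cycle <- function(strategy, age) {
  stopifnot(all(age >= 0))
  if (strategy$no_screening) return(rep(FALSE, length(age)))
  age >= strategy$start_age & age <= strategy$stop_age &
    (age - strategy$start_age) %% strategy$interval == 0
}

#' Number of screens a strategy delivers
#'
#' @param strategy a \code{bc_strategy}.
#' @return Integer count of scheduled screening ages.
#' @export
n_screens <- function(strategy) {
  if (strategy$no_screening) return(0L)
  as.integer((strategy$stop_age - strategy$start_age) %/%
               strategy$interval + 1L)
}

#' Convert a strategy list to a data frame
#'
#' @param strategies list of \code{bc_strategy} objects.
#' @return Data frame with columns label, start_age, stop_age, interval.
#' @export
strategies_table <- function(strategies) {
  data.frame(
    label = vapply(strategies, `[[`, character(1), "label"),
    start_age = vapply(strategies, `[[`, integer(1), "start_age"),
    stop_age = vapply(strategies, `[[`, integer(1), "stop_age"),
    interval = vapply(strategies, `[[`, integer(1), "interval")
  )
}

#' @export
print.bc_strategy <- function(x, ...) {
  if (x$no_screening) cat("<bc_strategy> no screening\n")
  else cat(sprintf("<bc_strategy> %s (%d screens)\n", x$label, n_screens(x)))
  invisible(x)
}
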
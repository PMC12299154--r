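#' Construct a cow state
#'
#' A cow is described by up to four coordinates: abortion history \code{ab}
#' (0 = never aborted, 1 = rebreeding abortion, 2 = new-lactation abortion),
#' parity \code{par} (number of calvings, 1--15), gestation month \code{preg}
#' (0 = open, 1--9 = month of pregnancy; calving occurs at 9), and month in
#' lactation \code{mil} (1--24). The base model fixes \code{ab = 0}.
#'
#' @param ab integer abortion level, 0--2.
#' @param par integer parity, 1--15.
#' @param preg integer gestation month, 0--9.
#' @param mil integer month in lactation, 1--24.
#' @return A one-row \code{data.frame} with columns \code{ab}, \code{par},
#'   \code{preg}, \code{mil}.
#' @examples
#' cow_state(par = 2, preg = 3, mil = 7)
#' @export
cow_state <- function(ab = 0L, par = 1L, preg = 0L, mil = 1L) {
  st <- data.frame(ab = as.integer(ab), par = as.integer(par),
                   preg = as.integer(preg), mil = as.integer(mil))
  check_state_ranges(st)
  st
}

check_state_ranges <- function(st) {
  if (any(is.na(st$ab)) || any(st$ab < 0L | st$ab > 2L))
    stop("'ab' must be an integer in 0..2", call. = FALSE)
  if (any(is.na(st$par)) || any(st$par < 1L | st$par > 15L))
    stop("'par' must be an integer in 1..15", call. = FALSE)
  if (any(is.na(st$preg)) || any(st$preg < 0L | st$preg > 9L))
    stop("'preg' must be an integer in 0..9", call. = FALSE)
  if (any(is.na(st$mil)) || any(st$mil < 1L | st$mil > 24L))
    stop("'mil' must be an integer in 1..24", call. = FALSE)
  invisible(st)
}

#' Structural feasibility of a cow state
#'
#' Conception is only possible from the second month in lactation, so a cow in
#' gestation month \code{p} must be at least \code{p + 2} months into the
#' lactation. States violating this (e.g. \code{mil = 1, preg = 1} or
#' \code{mil = 3, preg = 2}) can never be entered and are excluded from the
#' chain.
#'
#' @param state a state as returned by [cow_state()], or a data.frame with
#'   columns \code{ab}, \code{par}, \code{preg}, \code{mil} (vectorized).
#' @return Logical vector: \code{TRUE} where the state is feasible.
#' @examples
#' is_feasible(cow_state(par = 1, preg = 0, mil = 1))  # TRUE
#' @export
is_feasible <- function(state) {
  check_state_ranges(state)
  state$preg == 0L | state$mil >= state$preg + 2L
}

#' Enumerate the feasible cow state space
#'
#' Enumerates all feasible states in deterministic lexicographic order
#' (\code{ab}, \code{par}, \code{preg}, \code{mil}). Each parity (and abortion
#' level) admits 186 of the nominal 240 \code{(preg, mil)} combinations; the
#' base model has 2790 feasible states (nominal order 3600) and the extended
#' model 8370 (nominal order 10800).
#'
#' @param kind \code{"base"} (states over par, preg, mil with \code{ab = 0})
#'   or \code{"extended"} (adds the abortion dimension, \code{ab} in 0..2).
#' @return A \code{data.frame} of class \code{"herd_states"} with columns
#'   \code{ab}, \code{par}, \code{preg}, \code{mil} and \code{index}
#'   (1-based position), and attributes \code{kind} and \code{nominal_order}.
#' @examples
#' nrow(herd_states("base"))      # 2790
#' nrow(herd_states("extended"))  # 8370
#' @export
herd_states <- function(kind = c("base", "extended")) {
  kind <- match.arg(kind)
  ab_levels <- if (kind == "extended") 0:2 else 0L
  # expand.grid varies its first factor fastest; order columns so the result
  # is sorted by (ab, par, preg, mil)
  grid <- expand.grid(mil = 1:24, preg = 0:9, par = 1:15, ab = ab_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("ab", "par", "preg", "mil")]
  keep <- grid$preg == 0L | grid$mil >= grid$preg + 2L
  st <- grid[keep, , drop = FALSE]
  rownames(st) <- NULL
  st$index <- seq_len(nrow(st))
  attr(st, "kind") <- kind
  attr(st, "nominal_order") <- nrow(grid)
  class(st) <- c("herd_states", "data.frame")
  st
}

#' @export
print.herd_states <- function(x, ...) {
  cat(sprintf("Herd state space (%s model): %d feasible states (nominal order %d)\n",
              attr(x, "kind"), nrow(x), attr(x, "nominal_order")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more states\n", nrow(x) - 6L))
  invisible(x)
}

# Dense lookup array mapping (ab, par, preg, mil) -> row index (NA if
# infeasible). Used by the kernel for O(1) target resolution.
state_index_array <- function(states) {
  idx <- array(NA_integer_, dim = c(3L, 15L, 10L, 24L))
  idx[cbind(states$ab + 1L, states$par, states$preg + 1L, states$mil)] <-
    states$index
  idx
}

state_lookup <- function(idx, ab, par, preg, mil) {
  idx[cbind(ab + 1L, par, preg + 1L, mil)]
}

#' Export a state enumeration to CSV
#'
#' @param states a [herd_states()] table.
#' @param path file path to write.
#' @return The path, invisibly.
#' @export
write_states_csv <- function(states, path) {
  utils::write.csv(as.data.frame(states), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
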
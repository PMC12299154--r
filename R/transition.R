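EVENT_NAMES <- c("death", "involuntary_cull", "voluntary_cull", "conception",
                 "early_abortion", "ra_abortion", "nla_abortion", "calving",
                 "continue")

# Core monthly kernel for a single origin state. Competing risks resolve in a
# fixed order: death and involuntary culling first, then (for survivors)
# voluntary culling of open cows reaching the class threshold month, then the
# reproductive event (conception, abortion, gestation progress, calving).
# Returns target coordinates, probabilities, and the event decomposition.
kernel_one <- function(ab, par, preg, mil, rates, effects, policy, kind) {
  cls <- if (par == 1L) 1L else 2L  # column: primiparous / multiparous
  thr <- if (par == 1L) policy$cull_mil_primiparous else
    policy$cull_mil_multiparous

  mort <- rates$mortality[mil, cls]
  icull <- rates$inv_cull[mil, cls]
  capped <- FALSE
  if (kind == "extended" && ab >= 1L) {
    icull <- icull * effects$cull_risk_multiplier
    if (icull > 1 - mort) { icull <- 1 - mort; capped <- TRUE }
  }
  surv <- 1 - mort - icull

  ev <- stats::setNames(numeric(9L), EVENT_NAMES)
  ev["death"] <- mort
  ev["involuntary_cull"] <- icull

  # targets accumulated as parallel vectors; the initial state (0,1,0,1)
  # receives every replacement flow
  t_ab <- integer(0); t_par <- integer(0); t_preg <- integer(0)
  t_mil <- integer(0); t_p <- numeric(0)
  add <- function(a, q, g, m, p) {
    t_ab <<- c(t_ab, a); t_par <<- c(t_par, q); t_preg <<- c(t_preg, g)
    t_mil <<- c(t_mil, m); t_p <<- c(t_p, p)
  }
  replace_mass <- mort + icull

  if (preg == 0L) {
    # voluntary culling strikes when an open cow reaches the threshold month;
    # cows pushed past it by an abortion remain eligible for rebreeding and
    # are only force-replaced at the lactation bound
    if (mil == thr || mil >= policy$forced_open_cull_mil) {
      ev["voluntary_cull"] <- surv
      replace_mass <- replace_mass + surv
    } else {
      pr <- rates$preg_rate[mil, cls]
      if (kind == "extended" && ab >= 1L)
        pr <- pr * (1 - effects$conception_reduction)
      if (pr > 0) {
        ev["conception"] <- surv * pr
        add(ab, par, 1L, mil + 1L, surv * pr)
      }
      ev["continue"] <- surv * (1 - pr)
      add(ab, par, 0L, mil + 1L, surv * (1 - pr))
    }
  } else if (preg == 9L) {
    ev["calving"] <- surv
    if (par == policy$max_parity) replace_mass <- replace_mass + surv
    else add(ab, par + 1L, 0L, 1L, surv)
  } else {
    if (mil >= 24L) {
      # pregnant at the lactation bound: structurally present but never
      # reached under the packaged conception window; replaced for closure
      ev["voluntary_cull"] <- surv
      replace_mass <- replace_mass + surv
    } else {
      h <- rates$abort_hazard[preg]
      if (h > 0) {
        if (preg <= 2L || kind == "base") {
          ev["early_abortion"] <- surv * h
          add(ab, par, 0L, mil + 1L, surv * h)
        } else {
          p_ra <- surv * h * rates$ra_share
          p_nla <- surv * h * rates$nla_share
          ev["ra_abortion"] <- p_ra
          ev["nla_abortion"] <- p_nla
          if (p_ra > 0) add(max(ab, 1L), par, 0L, mil + 1L, p_ra)
          if (p_nla > 0) {
            if (par == policy$max_parity) replace_mass <- replace_mass + p_nla
            else add(max(ab, 2L), par + 1L, 0L, 1L, p_nla)
          }
        }
      }
      ev["continue"] <- surv * (1 - h)
      add(ab, par, preg + 1L, mil + 1L, surv * (1 - h))
    }
  }
  if (replace_mass > 0) add(0L, 1L, 0L, 1L, replace_mass)

  list(ab = t_ab, par = t_par, preg = t_preg, mil = t_mil, p = t_p,
       events = ev, capped = capped)
}

#' One-step transition distribution of a cow state
#'
#' Computes the distribution over successor states for a single feasible
#' origin state under the monthly kernel: death and involuntary culling (the
#' latter scaled by the culling-risk multiplier for cows with abortion
#' history in the extended model) send the cow to the replacement state
#' (0,1,0,1); surviving open cows reaching the policy threshold month are
#' voluntarily culled (cows pushed past it by an abortion keep rebreeding
#' until the forced lactation bound); otherwise open cows conceive or stay
#' open, pregnant
#' cows may abort (months 2--8 of gestation; in the extended model abortions
#' after gestation month 2 split into rebreeding and new-lactation types) or
#' progress, and cows in gestation month 9 calve into the next parity
#' (replacement if parity 15 completes).
#'
#' @param state a single [cow_state()] row (must be feasible; \code{ab} must
#'   be 0 for the base model).
#' @param rates a \code{rate_tables} list.
#' @param effects an \code{abortion_effects} list.
#' @param policy a [herd_policy()].
#' @param kind \code{"base"} or \code{"extended"}.
#' @return A \code{data.frame} with columns \code{ab}, \code{par},
#'   \code{preg}, \code{mil}, \code{prob} (probabilities sum to 1), with the
#'   event decomposition in \code{attr(, "events")}.
#' @examples
#' transition_distribution(cow_state(par = 1, preg = 0, mil = 2),
#'                         default_rates(), default_effects(),
#'                         herd_policy(), "base")
#' @export
transition_distribution <- function(state, rates, effects, policy,
                                    kind = c("base", "extended")) {
  kind <- match.arg(kind)
  check_state_ranges(state)
  if (nrow(state) != 1L) stop("'state' must be a single state", call. = FALSE)
  if (!is_feasible(state))
    stop("infeasible origin state (preg >= 1 requires mil >= preg + 2)",
         call. = FALSE)
  if (kind == "base" && state$ab != 0L)
    stop("base model states must have ab = 0", call. = FALSE)
  k <- kernel_one(state$ab, state$par, state$preg, state$mil,
                  rates, effects, policy, kind)
  # merge duplicate targets (e.g. early abortion and failed-conception paths
  # never collide, but replacement mass may coincide with a regular target)
  key <- paste(k$ab, k$par, k$preg, k$mil)
  p <- tapply(k$p, key, sum)
  parts <- do.call(rbind, strsplit(names(p), " ", fixed = TRUE))
  out <- data.frame(ab = as.integer(parts[, 1]), par = as.integer(parts[, 2]),
                    preg = as.integer(parts[, 3]), mil = as.integer(parts[, 4]),
                    prob = as.numeric(p))
  out <- out[order(out$ab, out$par, out$preg, out$mil), ]
  rownames(out) <- NULL
  attr(out, "events") <- k$events
  out
}

#' Build the monthly transition matrix
#'
#' Assembles the one-step kernel for every feasible state into a sparse
#' row-stochastic matrix, together with the per-state event-probability
#' decomposition used for cash-flow accounting.
#'
#' @param states a [herd_states()] enumeration.
#' @param rates,effects,policy model inputs (see
#'   [transition_distribution()]).
#' @return A list of class \code{"herd_transition"} with elements \code{P}
#'   (a \code{dgCMatrix}, rows = origin states in enumeration order),
#'   \code{events} (matrix states x 9), \code{states}, \code{kind},
#'   \code{nominal_order}, and \code{n_capped} (number of states whose
#'   multiplied culling probability was capped at the survival budget).
#' @export
build_transition_matrix <- function(states, rates, effects, policy) {
  kind <- attr(states, "kind")
  validate_params(rates, effects)
  idx <- state_index_array(states)
  n <- nrow(states)

  from <- vector("list", n)
  to <- vector("list", n)
  pr <- vector("list", n)
  events <- matrix(0, n, 9L, dimnames = list(NULL, EVENT_NAMES))
  n_capped <- 0L

  ab <- states$ab; par <- states$par; preg <- states$preg; mil <- states$mil
  for (i in seq_len(n)) {
    k <- kernel_one(ab[i], par[i], preg[i], mil[i], rates, effects, policy,
                    kind)
    j <- state_lookup(idx, k$ab, k$par, k$preg, k$mil)
    if (anyNA(j)) stop("kernel produced an infeasible target from state ", i,
                       call. = FALSE)
    from[[i]] <- rep.int(i, length(j))
    to[[i]] <- j
    pr[[i]] <- k$p
    events[i, ] <- k$events
    if (k$capped) n_capped <- n_capped + 1L
  }
  P <- Matrix::sparseMatrix(i = unlist(from), j = unlist(to), x = unlist(pr),
                            dims = c(n, n))
  if (n_capped > 0L)
    warning(n_capped,
            " states had involuntary culling capped at the survival budget")
  structure(list(P = P, events = events, states = states, kind = kind,
                 nominal_order = attr(states, "nominal_order"),
                 policy = policy, n_capped = n_capped),
            class = "herd_transition")
}

#' @export
print.herd_transition <- function(x, ...) {
  cat(sprintf("Monthly transition kernel (%s model)\n", x$kind))
  cat(sprintf("  %d x %d row-stochastic (nominal order %d), %d nonzeros\n",
              nrow(x$P), ncol(x$P), x$nominal_order,
              length(x$P@x)))
  cat(sprintf("  policy: cull open cows at MIL %d (primiparous) / %d (multiparous)\n",
              x$policy$cull_mil_primiparous, x$policy$cull_mil_multiparous))
  invisible(x)
}

#' Export a transition matrix as sparse triplets
#'
#' Writes the matrix in MatrixMarket coordinate format and the state index
#' as CSV next to it.
#'
#' @param tm a \code{herd_transition} object.
#' @param path base path; \code{<path>.mtx} and \code{<path>_states.csv} are
#'   written.
#' @return The \code{.mtx} path, invisibly.
#' @export
write_transition_mtx <- function(tm, path) {
  mtx <- paste0(path, ".mtx")
  Matrix::writeMM(tm$P, mtx)
  write_states_csv(tm$states, paste0(path, "_states.csv"))
  invisible(mtx)
}
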
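CASHFLOW_COMPONENTS <- c("iofc", "calf_income", "salvage_income",
                         "replacement_cost", "ai_cost", "vet_cost",
                         "twin_loss", "net")

#' Monthly milk yield of a cow state
#'
#' Yield is read from the parity-class milk curve (parities 1--2 use the
#' second-parity column, parities 3+ the later-parity column); lactation
#' months 11--12 carry the month-10 yield forward. Cows past the maximum
#' milking month or at/past the dry-off gestation month give no milk. Cows
#' with abortion history produce at a reduced yield (rebreeding and
#' new-lactation reductions respectively).
#'
#' @param state one or more states (data.frame with ab, par, preg, mil).
#' @param scenario an \code{economic_scenario}.
#' @param effects an \code{abortion_effects}.
#' @return Numeric vector of kg milk for the month.
#' @examples
#' monthly_milk(cow_state(par = 2, mil = 1), default_scenario(),
#'              default_effects())  # 1252
#' @export
monthly_milk <- function(state, scenario, effects) {
  check_state_ranges(state)
  milking <- state$mil <= scenario$max_milking_mil &
    state$preg < scenario$dry_off_preg
  curve_col <- ifelse(state$par <= 2L, 1L, 2L)
  month <- pmin(state$mil, nrow(scenario$milk_curve))
  base <- scenario$milk_curve[cbind(month, curve_col)]
  red <- c(0, effects$milk_reduction_ra, effects$milk_reduction_nla)[state$ab + 1L]
  ifelse(milking, base * (1 - red), 0)
}

# per-state monthly cash-flow components given the event decomposition.
# Exits comprise death plus culls (involuntary, voluntary, completion of the
# final parity by calving or new-lactation abortion); salvage accrues on
# culls only (a dead cow's carcass is written off), replacement cost on all
# exits. AI is charged when the cow is open, in the eligible insemination
# window, and not scheduled for voluntary culling.
cashflow_matrix <- function(states, events, rates, scenario, policy,
                            effects = default_effects()) {
  milk <- monthly_milk(states, scenario, effects)
  milking <- states$mil <= scenario$max_milking_mil &
    states$preg < scenario$dry_off_preg
  feed <- scenario$dmi * scenario$days_per_month *
    ifelse(milking, scenario$feed_cost_lact, scenario$feed_cost_dry)
  iofc <- milk * scenario$milk_price - feed

  final_par <- states$par == policy$max_parity
  cull_exit <- events[, "involuntary_cull"] + events[, "voluntary_cull"] +
    ifelse(final_par, events[, "calving"] + events[, "nla_abortion"], 0)
  exit <- events[, "death"] + cull_exit

  cls <- ifelse(states$par == 1L, 1L, 2L)
  thr <- ifelse(states$par == 1L, policy$cull_mil_primiparous,
                policy$cull_mil_multiparous)
  eligible <- states$preg == 0L & states$mil >= 2L & states$mil != thr &
    states$mil < policy$forced_open_cull_mil &
    rates$preg_rate[cbind(states$mil, cls)] > 0

  calv <- events[, "calving"]
  cf <- cbind(
    iofc = iofc,
    calf_income = scenario$calf_value * calv,
    salvage_income = scenario$carcass_price * scenario$carcass_weight *
      cull_exit,
    replacement_cost = scenario$replacement_cost * exit,
    ai_cost = scenario$ai_cost * as.numeric(eligible),
    vet_cost = scenario$vet_cost * calv,
    twin_loss = scenario$twin_loss * calv)
  cbind(cf, net = cf[, "iofc"] + cf[, "calf_income"] +
          cf[, "salvage_income"] - cf[, "replacement_cost"] -
          cf[, "ai_cost"] - cf[, "vet_cost"] - cf[, "twin_loss"])
}

#' Cash flow of a single cow state
#'
#' Income over feed cost plus event-weighted calf, salvage, replacement,
#' insemination, veterinary and twin-loss flows for one state, given its
#' one-step event probabilities.
#'
#' @param state a single [cow_state()] row.
#' @param events named event-probability vector as produced by
#'   [transition_distribution()] (attribute \code{"events"}).
#' @param scenario an \code{economic_scenario}.
#' @param rates the \code{rate_tables} used to build the kernel (needed for
#'   insemination eligibility).
#' @param effects an \code{abortion_effects} (milk reduction).
#' @param policy the [herd_policy()] used to build the kernel.
#' @return Named numeric vector over the cash-flow components (USD per cow
#'   per month), including \code{net}.
#' @export
state_cashflow <- function(state, events, scenario, rates = default_rates(),
                           effects = default_effects(),
                           policy = herd_policy()) {
  ev <- matrix(events, 1L, dimnames = list(NULL, names(events)))
  drop(cashflow_matrix(state, ev, rates, scenario, policy, effects))
}

#' Herd-level net benefit per cow per month
#'
#' Probability-weighted sum of per-state cash flows under the stationary
#' distribution, component-wise.
#'
#' @param steady a \code{herd_steady} (or a bare probability vector).
#' @param cashflows per-state cash-flow matrix (states x components), as
#'   stored in a [herd_model()] fit.
#' @return A list of class \code{"cashflow_breakdown"} with the component
#'   totals (USD/cow/month), \code{net}, and \code{annual_net} (= 12 x net).
#' @export
herd_net_benefit <- function(steady, cashflows) {
  p <- if (inherits(steady, "herd_steady")) steady$pi else as.numeric(steady)
  if (length(p) != nrow(cashflows))
    stop("steady-state vector and cash-flow matrix sizes differ", call. = FALSE)
  out <- as.list(colSums(p * cashflows))
  out$annual_net <- 12 * out$net
  class(out) <- "cashflow_breakdown"
  out
}

#' @export
print.cashflow_breakdown <- function(x, ...) {
  cat("Per-cow monthly cash flow (USD):\n")
  for (nm in CASHFLOW_COMPONENTS)
    cat(sprintf("  %-17s %9.2f\n", nm, x[[nm]]))
  cat(sprintf("  %-17s %9.2f\n", "annual_net", x$annual_net))
  invisible(x)
}
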
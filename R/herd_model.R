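#' Fit the dairy-herd replacement model
#'
#' Builds the monthly Markov chain over cow states for the requested model
#' kind, solves its stationary distribution, and evaluates the per-cow
#' monthly cash flow under that distribution. This is the package's central
#' constructor; everything else (policy sweeps, sensitivity analyses,
#' cohort simulation) is built on top of it.
#'
#' The base model tracks (parity, gestation month, month in lactation); the
#' extended model adds the abortion-history level and applies the
#' abortion-type effects (milk-yield reduction, involuntary-culling
#' multiplier) to cows that have aborted.
#'
#' @param kind \code{"extended"} (default) or \code{"base"}.
#' @param rates biological rate tables, see [default_rates()].
#' @param effects abortion-type effects, see [default_effects()]; ignored by
#'   the base model kernel except through shared plumbing.
#' @param scenario economic scenario, see [default_scenario()].
#' @param policy voluntary-culling policy, see [herd_policy()].
#' @param solver stationary solver passed to [solve_steady_state()].
#' @return An object of class \code{"herd_model"} with components
#'   \code{states}, \code{transition} (the \code{herd_transition}),
#'   \code{steady} (the \code{herd_steady}), \code{cashflows} (states x
#'   components matrix), \code{net} (a \code{cashflow_breakdown}), and the
#'   inputs. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}, \code{simulate}.
#' @examples
#' \donttest{
#' fit <- herd_model("base", policy = herd_policy(11, 10))
#' coef(fit)["net"]
#' }
#' @export
herd_model <- function(kind = c("extended", "base"),
                       rates = default_rates(),
                       effects = default_effects(),
                       scenario = default_scenario(),
                       policy = herd_policy(),
                       solver = c("direct", "power")) {
  kind <- match.arg(kind)
  solver <- match.arg(solver)
  validate_params(rates, effects, scenario)
  states <- herd_states(kind)
  tm <- build_transition_matrix(states, rates, effects, policy)
  steady <- solve_steady_state(tm, method = solver)
  cf <- cashflow_matrix(states, tm$events, rates, scenario, policy, effects)
  net <- herd_net_benefit(steady, cf)
  structure(list(call = match.call(), kind = kind, states = states,
                 transition = tm, steady = steady, cashflows = cf,
                 net = net, rates = rates, effects = effects,
                 scenario = scenario, policy = policy),
            class = "herd_model")
}

#' @export
print.herd_model <- function(x, ...) {
  cat(sprintf("Dairy-herd replacement model (%s)\n", x$kind))
  cat(sprintf("  states: %d feasible (nominal order %d)\n",
              nrow(x$states), x$transition$nominal_order))
  cat(sprintf("  policy: cull open cows at MIL %d (primiparous) / %d (multiparous)\n",
              x$policy$cull_mil_primiparous, x$policy$cull_mil_multiparous))
  cat(sprintf("  solver: %s, stationarity residual %.2e\n",
              x$steady$method, x$steady$residual))
  cat(sprintf("  net benefit: %.2f USD/cow/month (%.2f USD/cow/year)\n",
              x$net$net, x$net$annual_net))
  invisible(x)
}

#' @export
summary.herd_model <- function(object, ...) {
  hs <- herd_structure(object)
  prev <- if (object$kind == "extended") abortion_prevalence(object) else NULL
  structure(list(model = object, structure = hs, prevalence = prev),
            class = "summary.herd_model")
}

#' @export
print.summary.herd_model <- function(x, ...) {
  print(x$model)
  cat("\nParity distribution (parities 1-6):\n")
  print(round(x$structure$par_marginal[1:6], 4))
  cat("Month-in-lactation distribution (months 1-6):\n")
  print(round(x$structure$mil_marginal[1:6], 4))
  if (!is.null(x$prevalence)) {
    cat(sprintf("\nAbortion history prevalence: %.2f%% (RA %.2f%%, NLA %.2f%%)\n",
                100 * x$prevalence["total"], 100 * x$prevalence["ra"],
                100 * x$prevalence["nla"]))
  }
  cat("\nCash flow:\n")
  print(x$model$net)
  invisible(x)
}

#' @export
coef.herd_model <- function(object, ...) {
  unlist(object$net[c(CASHFLOW_COMPONENTS, "annual_net")])
}

#' Per-state predictions from a fitted herd model
#'
#' @param object a [herd_model()] fit.
#' @param newdata optional data.frame of states (defaults to the model's own
#'   state space; must be feasible states of the fitted kind).
#' @param type \code{"net"} (expected monthly net contribution of a cow in
#'   the state), \code{"milk"} (kg for the month), or \code{"cashflow"}
#'   (full component matrix).
#' @param ... unused.
#' @return Numeric vector (or matrix for \code{"cashflow"}) aligned with
#'   \code{newdata} rows.
#' @export
predict.herd_model <- function(object, newdata = NULL,
                               type = c("net", "milk", "cashflow"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    cf <- object$cashflows
    st <- object$states
  } else {
    check_state_ranges(newdata)
    if (!all(is_feasible(newdata))) stop("infeasible states in newdata",
                                         call. = FALSE)
    idx <- state_lookup(state_index_array(object$states), newdata$ab,
                        newdata$par, newdata$preg, newdata$mil)
    if (anyNA(idx)) stop("states in newdata are outside the fitted state space",
                         call. = FALSE)
    cf <- object$cashflows[idx, , drop = FALSE]
    st <- newdata
  }
  switch(type,
         net = unname(cf[, "net"]),
         milk = monthly_milk(st, object$scenario, object$effects),
         cashflow = cf)
}

#' Plot the stationary herd structure
#'
#' Barplots of the parity and month-in-lactation marginal distributions at
#' steady state.
#'
#' @param x a [herd_model()] fit.
#' @param ... passed to [graphics::barplot()].
#' @return \code{x}, invisibly.
#' @export
plot.herd_model <- function(x, ...) {
  hs <- herd_structure(x)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(hs$par_marginal, names.arg = 1:15, xlab = "Parity",
                    ylab = "Probability", main = "Parity distribution", ...)
  graphics::barplot(hs$mil_marginal, names.arg = 1:24,
                    xlab = "Month in lactation", ylab = "Probability",
                    main = "MIL distribution", ...)
  invisible(x)
}
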
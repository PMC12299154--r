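#' Default biological rate tables
#'
#' Monthly conception, mortality and involuntary-culling probabilities by
#' month in lactation and parity class (primiparous = first parity), the
#' gestation-month abortion hazards, and the split of late abortions into
#' rebreeding (RA) and new-lactation (NLA) types. Values are the published
#' herd parameters shipped with the package (Cabrera 2012 rate table; De
#' Vries 2006 abortion hazards; Keshavarzi et al. 2017 RA/NLA odds).
#'
#' @return A list of class \code{"rate_tables"} with elements
#'   \code{preg_rate}, \code{mortality}, \code{inv_cull} (24 x 2 matrices,
#'   columns \code{primiparous}/\code{multiparous}), \code{abort_hazard}
#'   (length-9 vector indexed by gestation month; nonzero only for months
#'   2--8), \code{ra_share} and \code{nla_share}.
#' @examples
#' r <- default_rates()
#' r$preg_rate[2, "primiparous"]  # 0.2368
#' sum(r$abort_hazard)            # 0.0845
#' @export
default_rates <- function() {
  tab <- utils::read.csv(pkg_file("lactation_rates.csv"))
  y <- read_defaults_yaml()
  hz <- numeric(9L)
  hz[as.integer(names(y$abortion$hazard))] <- unlist(y$abortion$hazard)
  nla <- y$abortion$nla_odds_numerator / y$abortion$nla_odds_denominator
  rates <- list(
    preg_rate = cbind(primiparous = tab$preg_rate_primiparous,
                      multiparous = tab$preg_rate_multiparous),
    mortality = cbind(primiparous = tab$mortality_primiparous,
                      multiparous = tab$mortality_multiparous),
    inv_cull  = cbind(primiparous = tab$inv_cull_primiparous,
                      multiparous = tab$inv_cull_multiparous),
    abort_hazard = hz,
    ra_share = 1 - nla,
    nla_share = nla)
  class(rates) <- "rate_tables"
  rates
}

#' Default abortion-type effects
#'
#' Productive and reproductive penalties for cows with an abortion history:
#' fractional milk-yield reduction after a rebreeding (RA) or new-lactation
#' (NLA) abortion, and the multiplier on the involuntary-culling probability
#' relative to cows with a normal calving history. The optional
#' \code{conception_reduction} scales the conception probability of cows with
#' an abortion history by \code{1 - conception_reduction}; it is 0 by default
#' and is exercised by [sensitivity_nonpregnancy()].
#'
#' @return A list of class \code{"abortion_effects"}.
#' @export
default_effects <- function() {
  y <- read_defaults_yaml()
  eff <- list(
    milk_reduction_ra = y$effects$milk_reduction_ra,
    milk_reduction_nla = y$effects$milk_reduction_nla,
    cull_risk_multiplier = y$effects$cull_risk_multiplier,
    conception_reduction = 0)
  class(eff) <- "abortion_effects"
  eff
}

#' Neutral abortion-type effects
#'
#' Effects object with no milk reduction and unit culling risk, used to check
#' that the extended model collapses onto the base model when abortion
#' history carries no penalty.
#'
#' @return A list of class \code{"abortion_effects"}.
#' @export
neutral_effects <- function() {
  eff <- list(milk_reduction_ra = 0, milk_reduction_nla = 0,
              cull_risk_multiplier = 1, conception_reduction = 0)
  class(eff) <- "abortion_effects"
  eff
}

#' Default economic scenario
#'
#' Prices and technical coefficients for the per-cow-per-month cash flow:
#' milk price (USD/kg), calf value, carcass price (USD/kg) and carcass weight
#' (kg), replacement heifer cost, veterinary cost per calving, lactating and
#' dry feed cost (USD/kg DM), dry-matter intake (kg/day), days per month,
#' artificial-insemination cost per service, twin-calving loss, the gestation
#' month at which milking stops (\code{dry_off_preg}; the default 10 means
#' milking is governed by the lactation month alone, i.e. no gestation-based
#' dry-off before calving -- set 8 for a conventional two-month dry period),
#' the maximum month in lactation with milk sales (\code{max_milking_mil},
#' 12), and the monthly milk curve by parity class (the
#' \code{second_parity} column applies to parities 1--2, \code{later_parity}
#' to parities 3+; months 11--12 carry the month-10 yield forward). The dry
#' feed price applies in months without milking.
#'
#' @return A list of class \code{"economic_scenario"}; element
#'   \code{milk_curve} is a 10 x 2 matrix.
#' @examples
#' sc <- default_scenario()
#' sc$milk_price          # 0.36
#' sc$milk_curve[1, ]     # 1252 (parity <= 2), 1025 (parity >= 3)
#' @export
default_scenario <- function() {
  y <- read_defaults_yaml()
  curve <- utils::read.csv(pkg_file("milk_curve.csv"))
  sc <- lapply(y$economics, as.numeric)
  sc$milk_curve <- cbind(second_parity = as.numeric(curve$second_parity),
                         later_parity = as.numeric(curve$later_parity))
  class(sc) <- "economic_scenario"
  sc
}

#' Voluntary-culling policy
#'
#' Open (non-pregnant) cows are voluntarily culled once their month in
#' lactation reaches the class threshold; cows completing parity 15 are
#' always replaced, and open cows reaching \code{forced_open_cull_mil} are
#' replaced unconditionally (a safety bound, unreachable under thresholds
#' below it).
#'
#' @param cull_mil_primiparous threshold month in lactation for first-parity
#'   cows (2--24).
#' @param cull_mil_multiparous threshold for parities 2+.
#' @param forced_open_cull_mil unconditional replacement month for open cows.
#' @return A list of class \code{"herd_policy"}.
#' @examples
#' herd_policy(11, 10)  # the validation policy
#' @export
herd_policy <- function(cull_mil_primiparous = 11L,
                        cull_mil_multiparous = 10L,
                        forced_open_cull_mil = 24L) {
  pol <- list(cull_mil_primiparous = as.integer(cull_mil_primiparous),
              cull_mil_multiparous = as.integer(cull_mil_multiparous),
              max_parity = 15L,
              forced_open_cull_mil = as.integer(forced_open_cull_mil))
  if (pol$cull_mil_primiparous < 2L || pol$cull_mil_primiparous > 24L ||
      pol$cull_mil_multiparous < 2L || pol$cull_mil_multiparous > 24L)
    stop("culling thresholds must lie in 2..24", call. = FALSE)
  class(pol) <- "herd_policy"
  pol
}

#' Packaged default parameters
#'
#' @return A list with elements \code{rates}, \code{effects}, \code{scenario}
#'   and \code{policy} (the validation policy: cull open primiparous cows at
#'   month 11, multiparous at month 10).
#' @export
default_params <- function() {
  list(rates = default_rates(), effects = default_effects(),
       scenario = default_scenario(), policy = herd_policy())
}

pkg_file <- function(name) {
  path <- system.file("extdata", name, package = "herdabort")
  if (!nzchar(path)) stop("packaged data file not found: ", name, call. = FALSE)
  path
}

read_defaults_yaml <- function() yaml::read_yaml(pkg_file("defaults.yaml"))

#' Validate a parameter set
#'
#' Checks probability ranges, the per-month competing-risk budget
#' (mortality + involuntary culling + conception must not exceed 1 in any
#' month/class), the RA/NLA split, and non-negativity of prices.
#'
#' @param rates a \code{rate_tables} list.
#' @param effects an \code{abortion_effects} list (optional).
#' @param scenario an \code{economic_scenario} list (optional).
#' @return \code{TRUE} invisibly; otherwise an error naming the offending
#'   field.
#' @export
validate_params <- function(rates, effects = NULL, scenario = NULL) {
  for (nm in c("preg_rate", "mortality", "inv_cull")) {
    m <- rates[[nm]]
    if (!is.matrix(m) || nrow(m) != 24L || ncol(m) != 2L)
      stop(nm, " must be a 24 x 2 matrix", call. = FALSE)
    if (any(m < 0 | m > 1)) stop(nm, " has entries outside [0, 1]", call. = FALSE)
  }
  budget <- rates$mortality + rates$inv_cull + rates$preg_rate
  if (any(budget > 1 + 1e-12))
    stop("mortality + inv_cull + preg_rate exceeds 1 for some month/class",
         call. = FALSE)
  hz <- rates$abort_hazard
  if (length(hz) != 9L || any(hz < 0 | hz > 1))
    stop("abort_hazard must be 9 probabilities (gestation months 1..9)",
         call. = FALSE)
  if (hz[1] != 0 || hz[9] != 0)
    stop("abort_hazard must be zero in gestation months 1 and 9", call. = FALSE)
  if (abs(rates$ra_share + rates$nla_share - 1) > 1e-12)
    stop("ra_share + nla_share must equal 1", call. = FALSE)
  if (rates$ra_share < 0 || rates$ra_share > 1)
    stop("ra_share outside [0, 1]", call. = FALSE)
  if (!is.null(effects)) {
    if (effects$milk_reduction_ra < 0 || effects$milk_reduction_ra >= 1 ||
        effects$milk_reduction_nla < 0 || effects$milk_reduction_nla >= 1)
      stop("milk reductions must lie in [0, 1)", call. = FALSE)
    if (effects$cull_risk_multiplier < 1)
      stop("cull_risk_multiplier must be >= 1", call. = FALSE)
    if (effects$conception_reduction < 0 || effects$conception_reduction > 1)
      stop("conception_reduction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(scenario)) {
    for (nm in c("milk_price", "calf_value", "carcass_price",
                 "replacement_cost", "vet_cost", "feed_cost_lact",
                 "feed_cost_dry", "dmi", "days_per_month", "ai_cost",
                 "carcass_weight", "twin_loss"))
      if (is.null(scenario[[nm]]) || scenario[[nm]] < 0)
        stop("scenario field ", nm, " missing or negative", call. = FALSE)
    if (!is.matrix(scenario$milk_curve) || nrow(scenario$milk_curve) != 10L)
      stop("milk_curve must be a 10 x 2 matrix", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load parameters from a YAML file
#'
#' Reads a YAML file with any subset of the sections \code{rates} (fields
#' \code{preg_rate}, \code{mortality}, \code{inv_cull} as lists with
#' \code{primiparous}/\code{multiparous} vectors of length 24;
#' \code{abort_hazard} as a map from gestation month to probability;
#' \code{ra_share}), \code{effects}, \code{economics} and \code{policy}
#' (scalar fields as in the defaults). Unspecified fields fall back to the
#' packaged defaults; the merged set is validated before being returned. An
#' empty file yields exactly [default_params()].
#'
#' @param path path to a YAML parameter file.
#' @return A list with \code{rates}, \code{effects}, \code{scenario},
#'   \code{policy}.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  p <- default_params()

  if (!is.null(y$rates)) {
    for (nm in c("preg_rate", "mortality", "inv_cull")) {
      ov <- y$rates[[nm]]
      if (is.null(ov)) next
      for (cls in c("primiparous", "multiparous")) {
        if (is.null(ov[[cls]])) next
        v <- as.numeric(ov[[cls]])
        if (length(v) != 24L)
          stop("rates$", nm, "$", cls, " must have 24 monthly values",
               call. = FALSE)
        p$rates[[nm]][, cls] <- v
      }
    }
    if (!is.null(y$rates$abort_hazard)) {
      hz <- numeric(9L)
      hz[as.integer(names(y$rates$abort_hazard))] <-
        unlist(y$rates$abort_hazard)
      p$rates$abort_hazard <- hz
    }
    if (!is.null(y$rates$ra_share)) {
      p$rates$ra_share <- y$rates$ra_share
      p$rates$nla_share <- 1 - y$rates$ra_share
    }
  }
  if (!is.null(y$effects))
    for (nm in intersect(names(y$effects), names(p$effects)))
      p$effects[[nm]] <- y$effects[[nm]]
  if (!is.null(y$economics))
    for (nm in intersect(names(y$economics), names(p$scenario)))
      p$scenario[[nm]] <- y$economics[[nm]]
  if (!is.null(y$milk_curve)) {
    for (cls in c("second_parity", "later_parity"))
      if (!is.null(y$milk_curve[[cls]]))
        p$scenario$milk_curve[, cls] <- as.numeric(y$milk_curve[[cls]])
  }
  if (!is.null(y$policy))
    p$policy <- herd_policy(
      cull_mil_primiparous = y$policy$cull_mil_primiparous %||%
        p$policy$cull_mil_primiparous,
      cull_mil_multiparous = y$policy$cull_mil_multiparous %||%
        p$policy$cull_mil_multiparous,
      forced_open_cull_mil = y$policy$forced_open_cull_mil %||%
        p$policy$forced_open_cull_mil)

  validate_params(p$rates, p$effects, p$scenario)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomized rate tables for property testing
#'
#' Draws a rate-table set satisfying every structural invariant (probability
#' ranges, per-month risk budget, hazard support on gestation months 2--8,
#' RA/NLA split summing to 1). Conception is positive only in the eligible
#' window (months 2--15), mirroring the packaged tables. Deterministic per
#' seed.
#'
#' @param seed integer seed.
#' @return A \code{rate_tables} list.
#' @export
random_rate_tables <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  draw_cls <- function() {
    mort <- stats::runif(24, 0.001, 0.05)
    cull <- stats::runif(24, 0.001, 0.08)
    pr <- numeric(24)
    pr[2:15] <- stats::runif(14, 0.01, 0.5) * (1 - mort[2:15] - cull[2:15])
    cbind(mort, cull, pr)
  }
  p1 <- draw_cls(); p2 <- draw_cls()
  hz <- numeric(9L)
  hz[2:8] <- stats::runif(7, 0, 0.05)
  ra <- stats::runif(1, 0.5, 1)
  rates <- list(
    preg_rate = cbind(primiparous = p1[, 3], multiparous = p2[, 3]),
    mortality = cbind(primiparous = p1[, 1], multiparous = p2[, 1]),
    inv_cull  = cbind(primiparous = p1[, 2], multiparous = p2[, 2]),
    abort_hazard = hz, ra_share = ra, nla_share = 1 - ra)
  class(rates) <- "rate_tables"
  validate_params(rates)
  rates
}
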
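#' Sweep the voluntary-culling month
#'
#' Evaluates the herd net benefit for each candidate culling month: open
#' cows are voluntarily replaced when their month in lactation reaches the
#' threshold. Both the abortion-extended and the base model are solved at
#' every threshold, giving the comparison table (and the optimum) reported
#' by the model.
#'
#' @param rates,effects,scenario model inputs (packaged defaults if
#'   omitted).
#' @param months integer vector of thresholds to evaluate (subset of 2..15).
#' @param apply_to \code{"both"} applies the swept threshold to both parity
#'   classes; \code{"primiparous"} sweeps the first-parity threshold while
#'   holding the multiparous threshold at \code{fixed_multiparous}.
#' @param fixed_multiparous multiparous threshold used when
#'   \code{apply_to = "primiparous"}.
#' @param solver stationary solver.
#' @return A data.frame of class \code{"herd_sweep"} with columns
#'   \code{month}, \code{net_extended}, \code{net_base}, \code{difference}
#'   (= extended - base), and attributes \code{argmax_extended},
#'   \code{argmax_base}, \code{models} (the fitted pair at the extended
#'   optimum).
#' @examples
#' \donttest{
#' sw <- sweep_culling_month(months = c(5, 6, 7))
#' attr(sw, "argmax_extended")  # 6
#' }
#' @export
sweep_culling_month <- function(rates = default_rates(),
                                effects = default_effects(),
                                scenario = default_scenario(),
                                months = 2:15,
                                apply_to = c("both", "primiparous"),
                                fixed_multiparous = 10L,
                                solver = "direct") {
  apply_to <- match.arg(apply_to)
  months <- sort(as.integer(months))
  if (any(months < 2L | months > 15L))
    stop("'months' must lie in 2..15", call. = FALSE)

  fits_ext <- vector("list", length(months))
  net_ext <- net_base <- numeric(length(months))
  for (i in seq_along(months)) {
    m <- months[i]
    pol <- if (apply_to == "both") herd_policy(m, m)
      else herd_policy(m, fixed_multiparous)
    fe <- herd_model("extended", rates, effects, scenario, pol, solver)
    fb <- herd_model("base", rates, effects, scenario, pol, solver)
    fits_ext[[i]] <- fe
    net_ext[i] <- fe$net$net
    net_base[i] <- fb$net$net
  }
  out <- data.frame(month = months, net_extended = net_ext,
                    net_base = net_base, difference = net_ext - net_base)
  attr(out, "argmax_extended") <- months[which.max(net_ext)]
  attr(out, "argmax_base") <- months[which.max(net_base)]
  attr(out, "best_extended") <- fits_ext[[which.max(net_ext)]]
  class(out) <- c("herd_sweep", "data.frame")
  out
}

#' @export
print.herd_sweep <- function(x, ...) {
  cat("Voluntary-culling month sweep (USD/cow/month):\n")
  tab <- as.data.frame(x)
  tab[-1] <- lapply(tab[-1], round, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("optimum: month %d (extended, %.2f) / month %d (base, %.2f)\n",
              attr(x, "argmax_extended"),
              max(x$net_extended), attr(x, "argmax_base"), max(x$net_base)))
  invisible(x)
}

#' @export
plot.herd_sweep <- function(x, ...) {
  graphics::plot(x$month, x$net_extended, type = "b", pch = 19,
                 xlab = "Voluntary-culling month (open cows)",
                 ylab = "Net benefit (USD/cow/month)", ...)
  graphics::lines(x$month, x$net_base, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", c("extended (RA/NLA)", "base"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Sensitivity of the net benefit to reduced conception after abortion
#'
#' Cows with an abortion history may take longer to rebreed. This analysis
#' scales their conception probability by \code{1 - f} over a grid of
#' reduction fractions \code{f} and re-solves the extended model at a fixed
#' policy, reporting the net benefit for each value and the change across
#' the grid.
#'
#' @param rates,effects,scenario model inputs.
#' @param policy culling policy (default: the optimal month-6 policy).
#' @param reduction_grid numeric vector of reduction fractions in [0, 1].
#' @param solver stationary solver.
#' @return A data.frame of class \code{"herd_sensitivity"} with columns
#'   \code{reduction} and \code{net}; attribute \code{net_change} is
#'   \code{net[f_max] - net[f_min]}.
#' @export
sensitivity_nonpregnancy <- function(rates = default_rates(),
                                     effects = default_effects(),
                                     scenario = default_scenario(),
                                     policy = herd_policy(6, 6),
                                     reduction_grid = seq(0.02, 0.60, by = 0.02),
                                     solver = "direct") {
  if (any(reduction_grid < 0 | reduction_grid > 1))
    stop("'reduction_grid' must lie in [0, 1]", call. = FALSE)
  grid <- sort(reduction_grid)
  net <- vapply(grid, function(f) {
    eff <- effects
    eff$conception_reduction <- f
    herd_model("extended", rates, eff, scenario, policy, solver)$net$net
  }, numeric(1))
  out <- data.frame(reduction = grid, net = net)
  attr(out, "net_change") <- net[length(net)] - net[1L]
  class(out) <- c("herd_sensitivity", "data.frame")
  out
}

#' @export
print.herd_sensitivity <- function(x, ...) {
  cat("Conception-reduction sensitivity (extended model):\n")
  print(data.frame(reduction = x$reduction, net = round(x$net, 2)),
        row.names = FALSE)
  cat(sprintf("net change across grid: %.2f USD/cow/month\n",
              attr(x, "net_change")))
  invisible(x)
}

#' Cell-wise relative difference against a reference table
#'
#' Compares a computed steady-state table (month in lactation x gestation
#' month) against a reference layout of the same shape, cell by cell, as
#' percentages of the reference value. Cells empty (NA or zero) in the
#' reference are skipped.
#'
#' @param table computed matrix.
#' @param reference reference matrix of identical shape.
#' @return A list: \code{rel_diff} (percent matrix, NA where the reference
#'   is empty) and \code{max_abs} (largest absolute percent difference).
#' @export
compare_with_reference <- function(table, reference) {
  if (!all(dim(table) == dim(reference)))
    stop("table and reference have different shapes", call. = FALSE)
  ref <- as.matrix(reference)
  tab <- as.matrix(table)
  mask <- !is.na(ref) & ref != 0
  rel <- matrix(NA_real_, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  rel[mask] <- 100 * (tab[mask] - ref[mask]) / ref[mask]
  list(rel_diff = rel, max_abs = max(abs(rel[mask])))
}

#' Packaged reference steady-state table for the second parity
#'
#' The published second-parity joint distribution of month in lactation and
#' gestation month under the validation policy (cull open primiparous cows
#' at month 11, multiparous at month 10), used as the golden reference for
#' model validation.
#'
#' @return A 17 x 9 matrix (rows = lactation months 1--17, columns =
#'   gestation months 0--8) with NA for structurally empty cells.
#' @export
reference_parity2_table <- function() {
  tab <- utils::read.csv(pkg_file("reference_parity2_steady_state.csv"))
  m <- as.matrix(tab[, -1L])
  dimnames(m) <- list(mil = tab$mil, preg = 0:8)
  m
}
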
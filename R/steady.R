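#' Solve the stationary herd distribution
#'
#' Computes the stationary distribution of the monthly chain. Replacement of
#' every exiting cow by a fresh heifer at (0,1,0,1) makes the chain
#' irreducible on the set of states reachable from that heifer state; the
#' solver restricts to that communicating class (found by breadth-first
#' search on the sparse pattern) and reports zero probability on structurally
#' unreachable states (e.g. a first-parity cow with a new-lactation abortion
#' history).
#'
#' @param tm a \code{herd_transition} object from
#'   [build_transition_matrix()], or a plain row-stochastic matrix.
#' @param method \code{"direct"} (sparse LU solve of the balance equations
#'   with the normalization constraint replacing one equation) or
#'   \code{"power"} (power iteration to an infinity-norm tolerance of 1e-12,
#'   capped at \code{max_iter}).
#' @param max_iter iteration cap for the power method.
#' @return A list of class \code{"herd_steady"}: \code{pi} (probabilities
#'   over feasible states, summing to 1), \code{method}, \code{residual}
#'   (max |pi P - pi|), \code{reachable} (logical), \code{iterations} (power
#'   method only).
#' @examples
#' P <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE)
#' solve_steady_state(P)$pi  # c(0.5, 0.5)
#' @export
solve_steady_state <- function(tm, method = c("direct", "power"),
                               max_iter = 1e6) {
  method <- match.arg(method)
  P <- if (inherits(tm, "herd_transition")) tm$P else
    methods::as(methods::as(as.matrix(tm), "generalMatrix"), "CsparseMatrix")
  n <- nrow(P)
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix is not row-stochastic (max |rowsum - 1| = ",
         format(max(abs(rs - 1))), ")", call. = FALSE)

  start <- if (inherits(tm, "herd_transition"))
    state_lookup(state_index_array(tm$states), 0L, 1L, 0L, 1L) else 1L
  reach <- reachable_states(P, start)
  idx <- which(reach)
  Pr <- P[idx, idx, drop = FALSE]
  # exits from the reachable class are impossible by construction; guard
  # against numeric droppage by renormalizing rows
  Pr <- Pr / Matrix::rowSums(Pr)
  m <- length(idx)

  if (method == "direct") {
    # solve pi (P - I) = 0 with sum(pi) = 1: replace the last column of
    # (P^T - I) x = 0 system's final equation by the normalization
    A <- Matrix::t(Pr) - Matrix::Diagonal(m)
    A[m, ] <- 1
    b <- c(rep(0, m - 1L), 1)
    v <- as.numeric(Matrix::solve(A, b))
    iterations <- NA_integer_
  } else {
    v <- rep(1 / m, m)
    iterations <- 0L
    repeat {
      v_new <- as.numeric(v %*% Pr)
      iterations <- iterations + 1L
      if (max(abs(v_new - v)) <= 1e-12) { v <- v_new; break }
      v <- v_new
      if (iterations >= max_iter)
        stop("power iteration did not converge after ", max_iter,
             " iterations (residual ", format(max(abs(v_new - v))), ")",
             call. = FALSE)
    }
  }
  v[v < 0] <- 0
  v <- v / sum(v)
  p <- numeric(n)
  p[idx] <- v
  residual <- max(abs(as.numeric(p %*% P) - p))
  structure(list(pi = p, method = method, residual = residual,
                 reachable = reach, iterations = iterations),
            class = "herd_steady")
}

#' @export
print.herd_steady <- function(x, ...) {
  cat(sprintf("Stationary herd distribution: %d states (%d reachable), %s solver, residual %.2e\n",
              length(x$pi), sum(x$reachable), x$method, x$residual))
  invisible(x)
}

reachable_states <- function(P, start) {
  tP <- Matrix::t(methods::as(P, "CsparseMatrix"))  # column j = successors of j
  ptr <- tP@p; rows <- tP@i
  n <- ncol(tP)
  seen <- logical(n)
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    j <- queue[[1L]]; queue <- queue[-1L]
    succ <- rows[(ptr[j] + 1L):ptr[j + 1L]] + 1L
    new <- succ[!seen[succ]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}

#' Herd-structure summaries of a stationary distribution
#'
#' Marginal distribution over parity, marginal over month in lactation, and
#' per-parity tables of the joint (month in lactation x gestation month)
#' distribution, the layout used to validate the base model against
#' published steady-state results.
#'
#' @param model a [herd_model()] fit, or a \code{herd_steady} paired with a
#'   \code{states} table via \code{herd_structure(steady, states = states)}.
#' @param states the matching [herd_states()] table (only needed when
#'   \code{model} is a \code{herd_steady}).
#' @return A list of class \code{"herd_structure"}: \code{par_marginal}
#'   (length 15), \code{mil_marginal} (length 24), and \code{parity_tables}
#'   (list of 24 x 10 matrices, rows = month in lactation, columns =
#'   gestation month 0..9; abortion levels marginalized out).
#' @export
herd_structure <- function(model, states = NULL) {
  if (inherits(model, "herd_model")) {
    p <- model$steady$pi; states <- model$states
  } else if (inherits(model, "herd_steady")) {
    if (is.null(states)) stop("'states' required", call. = FALSE)
    p <- model$pi
  } else stop("expected a herd_model or herd_steady", call. = FALSE)

  par_marginal <- as.numeric(tapply(p, factor(states$par, levels = 1:15), sum,
                                    default = 0))
  mil_marginal <- as.numeric(tapply(p, factor(states$mil, levels = 1:24), sum,
                                    default = 0))
  # abortion levels (extended model) are marginalized by summing duplicate
  # (mil, preg) pairs before placement
  parity_tables <- lapply(1:15, function(q) {
    sel <- states$par == q
    tab <- matrix(0, 24L, 10L, dimnames = list(mil = 1:24, preg = 0:9))
    if (any(sel)) {
      agg <- rowsum(p[sel], paste(states$mil[sel], states$preg[sel]))
      key <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      tab[cbind(as.integer(key[, 1L]), as.integer(key[, 2L]) + 1L)] <- agg[, 1L]
    }
    tab
  })
  structure(list(par_marginal = par_marginal, mil_marginal = mil_marginal,
                 parity_tables = parity_tables),
            class = "herd_structure")
}

#' Prevalence of abortion history at steady state
#'
#' Fraction of the herd that has experienced an abortion, split by most
#' severe type: rebreeding (ab = 1) and new-lactation (ab = 2).
#'
#' @param model an extended-model [herd_model()] fit (or a
#'   \code{herd_steady} with \code{states}).
#' @param states matching state table when passing a \code{herd_steady}.
#' @return Named numeric: \code{total}, \code{ra}, \code{nla} (proportions;
#'   \code{total = ra + nla}).
#' @export
abortion_prevalence <- function(model, states = NULL) {
  if (inherits(model, "herd_model")) {
    if (model$kind != "extended")
      stop("abortion prevalence is defined for the extended model only",
           call. = FALSE)
    p <- model$steady$pi; states <- model$states
  } else {
    if (is.null(states)) stop("'states' required", call. = FALSE)
    if (attr(states, "kind") != "extended")
      stop("abortion prevalence is defined for the extended model only",
           call. = FALSE)
    p <- model$pi
  }
  ra <- sum(p[states$ab == 1L])
  nla <- sum(p[states$ab == 2L])
  c(total = ra + nla, ra = ra, nla = nla)
}
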
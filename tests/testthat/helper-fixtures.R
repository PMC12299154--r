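# shared fixtures: the validation policy, a cached default parameter set, and
# a brute-force state enumerator independent of the package's own filter
validation_policy <- function() herd_policy(11, 10)

dp <- default_params()

# enumerate feasible states by filtering the full cartesian product with the
# raw feasibility inequality (independent of herd_states internals)
brute_force_states <- function(kind) {
  ab_levels <- if (kind == "extended") 0:2 else 0L
  g <- expand.grid(mil = 1:24, preg = 0:9, par = 1:15, ab = ab_levels,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$preg == 0 | g$mil >= g$preg + 2, c("ab", "par", "preg", "mil")]
  g[order(g$ab, g$par, g$preg, g$mil), ]
}

# rates with the new-lactation branch disabled: every late abortion follows
# the rebreeding path, which is the structural counterpart of the base model
ra_only_rates <- function(rates = dp$rates) {
  rates$ra_share <- 1
  rates$nla_share <- 0
  rates
}

expect_rows_stochastic <- function(P, tol = 1e-12) {
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), tol)
}
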
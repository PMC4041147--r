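# Shared helpers: independent oracles and small generators used across the
# test files.

# random strictly positive state for a network, log-uniform over ~3 decades
random_state <- function(net, lo = -1.5, hi = 1.5) {
  ids <- net$species$id
  stats::setNames(10^stats::runif(length(ids), lo, hi), ids)
}

# independent right-hand-side oracle: per-reaction flux summation
#   sum_j (Z[,Pj] - Z[,Sj]) v_j(x) + Z v_b(x)
rhs_flux_oracle <- function(net, x) {
  Z <- complex_matrix(net)
  dx <- numeric(nrow(Z))
  for (r in net$reactions) {
    v <- eval_rate(r$law, Z[, r$substrate], x)
    dx <- dx + (Z[, r$product] - Z[, r$substrate]) * v
  }
  dx <- dx + as.numeric(Z %*% boundary_flux_vector(net, x))
  names(dx) <- net$species$id
  dx[net$species$fixed] <- 0
  dx
}

# left null space of ZB: the conservation laws g with g' ZB = 0
conservation_laws <- function(net) {
  S <- complex_matrix(net) %*% incidence_matrix(net)
  MASS::Null(S)   # columns g satisfy t(g) %*% S == 0
}

# constant-in-time trajectory with given species values
flat_trajectory <- function(times, values) {
  states <- matrix(rep(values, each = length(times)), nrow = length(times),
                   dimnames = list(NULL, names(values)))
  crn_trajectory(times, states)
}
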
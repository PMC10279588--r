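# Shared fixtures for the test suite: small random connected graphs and
# finite-difference oracles that recompute everything from scratch.

random_connected_net <- function(n, seed, extra_edges = 2L) {
  m <- min(n - 1L + extra_edges, n * (n - 1L) / 2L)
  generate_er(n, m, seed = seed)
}

# central finite difference of a scalar- or matrix-valued function of the
# weight of one edge, recomputed fully at +/- h
fd_central <- function(net, i0, j0, h, fun) {
  up <- fun(perturb_edge_weight(net, i0, j0, h))
  dn <- fun(perturb_edge_weight(net, i0, j0, -h))
  if (is.list(up)) {
    mapply(function(a, b) (a - b) / (2 * h), up, dn, SIMPLIFY = FALSE)
  } else {
    (up - dn) / (2 * h)
  }
}

bc_of <- function(net) tau_summary(net)$bc_star

taus_of <- function(net) {
  tau <- tau_summary(net)
  c(tau$tau1, tau$tau2, tau$tau3)
}
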
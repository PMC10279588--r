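test_that("edge perturbations validate their mode constraints", {
  net <- fixture("cycle", 5)
  expect_error(edge_perturbation(net, 2, 2, -0.5), "self-loop")
  expect_error(edge_perturbation(net, 1, 2, -2), "removal")
  expect_error(edge_perturbation(net, 1, 3, -0.5), "removal") # no edge there
  expect_error(edge_perturbation(net, 1, 2, 0.5, mode = "addition"), "addition")
  expect_s3_class(edge_perturbation(net, 1, 3, 0.5), "edge_perturbation")
  expect_equal(edge_perturbation(net, 1, 3, 0.5)$mode, "addition")
  expect_equal(edge_perturbation(net, 1, 2, 0.5)$mode, "enhancement")
})

test_that("delta_pi matches its closed form and finite differences", {
  k3 <- fixture("complete", 3)
  ws <- perturbation_workspace(k3)
  dpi <- delta_pi(ws, edge_perturbation(k3, 1, 2, -0.5))
  expect_equal(dpi, c(1 / 18, 1 / 18, -1 / 9))
  # K2: symmetry keeps pi at (1/2, 1/2)
  k2 <- fixture("path", 2)
  expect_equal(delta_pi(perturbation_workspace(k2), edge_perturbation(k2, 1, 2, 0.5)),
    c(0, 0),
    tolerance = 1e-15
  )
  for (s in 1:4) {
    net <- random_connected_net(8, seed = 40 + s, extra_edges = 5L)
    ws <- perturbation_workspace(net)
    ep <- edge_pairs(net)[s, ]
    pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
    expect_equal(sum(delta_pi(ws, pert)), 0, tolerance = 1e-15)
    fd <- fd_central(net, ep[1], ep[2], 1e-6,
      function(m) random_walk_ensemble(m)$pi)
    expect_lt(max(abs(delta_pi(ws, pert) - fd)), 1e-8)
  }
})

test_that("theta matrices: entrywise forms equal compositional forms", {
  for (s in 1:5) {
    n <- c(6L, 9L, 12L, 16L, 20L)[s]
    net <- random_connected_net(n, seed = 50 + s, extra_edges = n %/% 2)
    ws <- perturbation_workspace(net)
    ep <- edge_pairs(net)[1, ]
    pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
    d <- theta_matrices(ws, pert, method = "direct")
    cm <- theta_matrices(ws, pert, method = "composition")
    expect_lt(max(abs(d$theta2 - cm$theta2)), 1e-10)
    expect_lt(max(abs(d$theta3 - cm$theta3)), 1e-10)
    # row-stochasticity is preserved to first order
    for (Th in d) expect_lt(max(abs(rowSums(Th))), 1e-12)
    # theta1 rows vanish away from the perturbed pair
    off <- setdiff(seq_len(net$n), c(pert$i0, pert$j0))
    expect_true(all(d$theta1[off, ] == 0))
  }
})

test_that("theta matrices match finite differences of P, P^2, P^3", {
  k3 <- fixture("complete", 3)
  ws <- perturbation_workspace(k3)
  th <- theta_matrices(ws, edge_perturbation(k3, 1, 2, -0.5))
  expect_equal(th$theta1[1, 2], 1 / 4)
  expect_equal(th$theta1[1, 3], -1 / 4)
  expect_equal(th$theta1[1, 1], 0)
  net <- random_connected_net(9, seed = 61, extra_edges = 6L)
  ws <- perturbation_workspace(net)
  ep <- edge_pairs(net)[2, ]
  pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
  th <- theta_matrices(ws, pert)
  fd <- fd_central(net, ep[1], ep[2], 1e-6, function(m) {
    e <- random_walk_ensemble(m)
    list(e$P, e$P2, e$P3)
  })
  expect_lt(max(abs(th$theta1 - fd[[1]])), 1e-7)
  expect_lt(max(abs(th$theta2 - fd[[2]])), 1e-7)
  expect_lt(max(abs(th$theta3 - fd[[3]])), 1e-7)
})

test_that("delta-M has exactly 4N - 6 structural rows and the right action", {
  for (n in c(5L, 8L, 12L)) {
    net <- random_connected_net(n, seed = n, extra_edges = 3L)
    ws <- perturbation_workspace(net)
    deg <- rowSums(net$weights > 0)
    eps <- edge_pairs(net)
    # a degree-one endpoint would pin its transition row and numerically
    # cancel its derivative rows; pick a pair clear of that special case
    ok <- which(deg[eps[, 1]] >= 2L & deg[eps[, 2]] >= 2L)
    ep <- eps[ok[length(ok) %/% 2L + 1L], ]
    pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
    dM <- delta_M_redundant(ws, pert)
    nz_rows <- sort(unique(dM@i)) + 1L
    expect_length(nz_rows, 4L * n - 6L)
    expect_setequal(nz_rows, delta_M_rows(n, pert$i0, pert$j0))
    act <- delta_M_action(ws, pert)
    vecT <- graphsurgery:::vec_rowmajor(ws$coal$T)
    expect_lt(max(abs(act$vec - as.numeric(dM %*% vecT))), 1e-12)
    # rows not touching the pair are exactly zero
    expect_true(all(act$vec[-nz_rows] == 0))
  }
})

test_that("delta-M matches the dense finite-difference of the assembled system", {
  net <- random_connected_net(8, seed = 71, extra_edges = 5L)
  ws <- perturbation_workspace(net)
  ep <- edge_pairs(net)[4, ]
  pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
  h <- 1e-6
  Mp <- coalescence_system_redundant(perturb_edge_weight(net, ep[1], ep[2], h))$M
  Mm <- coalescence_system_redundant(perturb_edge_weight(net, ep[1], ep[2], -h))$M
  dM_fd <- as.matrix(Mp - Mm) / (2 * h)
  vecT <- graphsurgery:::vec_rowmajor(ws$coal$T)
  expect_lt(
    max(abs(delta_M_action(ws, pert)$vec - as.numeric(dM_fd %*% vecT))), 1e-7
  )
  expect_lt(max(abs(as.matrix(delta_M_redundant(ws, pert)) - dM_fd)), 1e-7)
})

test_that("delta-T solves the redundant system and matches finite differences", {
  # K2: the single coalescence time is 1 for every edge weight
  k2 <- fixture("path", 2)
  ws2 <- perturbation_workspace(k2)
  expect_equal(delta_T(ws2, edge_perturbation(k2, 1, 2, 0.5)), matrix(0, 2, 2))
  for (s in 1:3) {
    net <- random_connected_net(8, seed = 80 + s, extra_edges = 5L)
    ws <- perturbation_workspace(net)
    ep <- edge_pairs(net)[2 * s, ]
    pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
    dT <- delta_T(ws, pert)
    expect_equal(dT, t(dT))
    expect_true(all(diag(dT) == 0))
    # dense linear-algebra oracle on the explicit redundant system
    sys <- coalescence_system_redundant(net)
    dM <- delta_M_redundant(ws, pert)
    vecT <- graphsurgery:::vec_rowmajor(ws$coal$T)
    oracle <- graphsurgery:::unvec_rowmajor(
      -solve(as.matrix(sys$M), as.numeric(dM %*% vecT)), net$n
    )
    expect_lt(max(abs(dT - oracle)), 1e-8)
    # full re-solve oracle
    fd <- fd_central(net, ep[1], ep[2], 1e-5, function(m) coalescence_times(m)$T)
    expect_lt(max(abs(dT - fd)), 1e-6)
  }
})

test_that("slope and gammas match full-recomputation finite differences", {
  net <- random_connected_net(10, seed = 91, extra_edges = 8L)
  ws <- perturbation_workspace(net)
  eps_pairs <- edge_pairs(net)
  for (r in seq_len(min(6L, nrow(eps_pairs)))) {
    ep <- eps_pairs[r, ]
    pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
    sl <- bc_slope(ws, pert)
    gam_fd <- fd_central(net, ep[1], ep[2], 1e-5, taus_of)
    expect_lt(abs(sl$gamma1 - gam_fd[1]), 1e-5)
    expect_lt(abs(sl$gamma2 - gam_fd[2]), 1e-5)
    expect_lt(abs(sl$gamma3 - gam_fd[3]), 1e-5)
    expect_lt(abs(sl$slope - fd_central(net, ep[1], ep[2], 1e-5, bc_of)), 1e-5)
  }
})

test_that("finite-difference residuals of the slope decay quadratically", {
  net <- random_connected_net(10, seed = 95, extra_edges = 7L)
  ws <- perturbation_workspace(net)
  ep <- edge_pairs(net)[5, ]
  pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
  sl <- bc_slope(ws, pert)$slope
  res <- vapply(c(1e-2, 1e-3), function(h) {
    abs(fd_central(net, ep[1], ep[2], h, bc_of) - sl)
  }, numeric(1))
  rate <- log10(res[1] / res[2])
  expect_gt(rate, 1.7)
  expect_lt(rate, 2.3)
})

test_that("every edge of a vertex-transitive graph has the same slope", {
  c6 <- fixture("cycle", 6)
  ws <- perturbation_workspace(c6)
  slopes <- apply(edge_pairs(c6), 1, function(e) {
    bc_slope(ws, edge_perturbation(c6, e[1], e[2], -0.5))$slope
  })
  expect_lt(diff(range(slopes)), 1e-10)
})

test_that("per-edge queries reuse the workspace factorization", {
  net <- random_connected_net(9, seed = 97, extra_edges = 6L)
  ws <- perturbation_workspace(net)
  expect_identical(ws$stats$factorizations, 1L)
  eps <- edge_pairs(net)
  for (r in 1:4) {
    bc_slope(ws, edge_perturbation(net, eps[r, 1], eps[r, 2], -0.5))
  }
  expect_identical(ws$stats$factorizations, 1L)
  expect_gte(ws$stats$solves, 4L)
})

test_that("the sparse workspace handle reproduces the dense one", {
  net <- random_connected_net(9, seed = 98, extra_edges = 6L)
  wsd <- perturbation_workspace(net, solver = "dense")
  wss <- perturbation_workspace(net, solver = "sparse")
  expect_equal(wss$solver, "sparse")
  ep <- edge_pairs(net)[3, ]
  pert <- edge_perturbation(net, ep[1], ep[2], -0.5)
  expect_equal(bc_slope(wss, pert)$slope, bc_slope(wsd, pert)$slope,
    tolerance = 1e-10
  )
  expect_equal(tau_summary_updated(wss, pert)$bc_star,
    tau_summary_updated(wsd, pert)$bc_star,
    tolerance = 1e-10
  )
})

test_that("repeated workspace construction is deterministic", {
  net <- random_connected_net(7, seed = 99, extra_edges = 4L)
  a <- perturbation_workspace(net)
  b <- perturbation_workspace(net)
  expect_identical(a$coal$T, b$coal$T)
  expect_identical(a$tau$bc_star, b$tau$bc_star)
})
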
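test_that("actual change is exact, zero at zero, and symmetric on transitive graphs", {
  c6 <- fixture("cycle", 6)
  ws <- perturbation_workspace(c6)
  expect_equal(actual_change(ws, edge_perturbation(c6, 1, 2, 0, mode = "removal")), 0)
  changes <- apply(edge_pairs(c6), 1, function(e) {
    actual_change(ws, edge_perturbation(c6, e[1], e[2], -0.5))
  })
  expect_lt(diff(range(changes)), 1e-9)
  # low-rank update equals fresh recomputation
  net <- random_connected_net(10, seed = 101, extra_edges = 8L)
  ws <- perturbation_workspace(net)
  for (r in c(1L, 4L, 7L)) {
    ep <- edge_pairs(net)[r, ]
    pert <- edge_perturbation(net, ep[1], ep[2], -1)
    expect_equal(actual_change(ws, pert), actual_change(net, pert),
      tolerance = 1e-8
    )
  }
})

test_that("removing a bridge is refused", {
  p5 <- fixture("path", 5)
  ws <- perturbation_workspace(p5)
  expect_error(
    actual_change(ws, edge_perturbation(p5, 2, 3, -1)),
    "disconnects"
  )
})

test_that("epsilon sweeps hit zero at zero and agree with the slope near zero", {
  net <- random_connected_net(10, seed = 105, extra_edges = 8L)
  ws <- perturbation_workspace(net)
  ep <- edge_pairs(net)[3, ]
  sw <- epsilon_sweep(ws, ep[1], ep[2], mode = "removal")
  expect_equal(sw$values[sw$grid == 0], 0)
  expect_length(sw$values, length(sw$grid))
  # numerical slope of the exact curve at the origin matches bc_slope
  fine <- epsilon_sweep(ws, ep[1], ep[2],
    mode = "removal", grid = c(-1e-5, 0, 1e-5)
  )
  num_slope <- (fine$values[3] - fine$values[1]) / 2e-5
  expect_equal(num_slope, sw$slope, tolerance = 1e-5)
})

test_that("enhancement sweeps are closer to linear than removal sweeps", {
  # an aggregate tendency at the standard network scale: individual
  # edges can go either way, the bulk of the curves separates clearly
  ba <- generate_ba(100, 3, seed = 1)
  ws <- perturbation_workspace(ba)
  eps <- edge_pairs(ba)[round(seq(1, 291, length.out = 12)), ]
  nonlin <- function(mode) {
    median(apply(eps, 1, function(e) {
      epsilon_sweep(ws, e[1], e[2], mode = mode)$nonlinearity
    }))
  }
  expect_lt(nonlin("enhancement"), nonlin("removal"))
})

test_that("correlation experiments produce the expected sample accounting", {
  net <- generate_er(20, 40, seed = 3)
  rem <- correlation_experiment(net, "removal")
  expect_equal(rem$n + rem$excluded, 40L)
  expect_true(abs(rem$pearson_r) <= 1)
  add <- correlation_experiment(net, "addition")
  expect_equal(add$n, 190L - 40L)
  enh <- correlation_experiment(net, "enhancement")
  expect_equal(enh$n, 40L)
  expect_error(correlation_experiment(fixture("path", 3), "removal"), "3 eligible")
})

test_that("removal slopes anticorrelate and enhancement slopes correlate on small BA nets", {
  for (s in 1:2) {
    ba <- generate_ba(60, 3, seed = s)
    ws <- perturbation_workspace(ba)
    rem <- correlation_experiment(ba, "removal", ws = ws)
    expect_lt(rem$pearson_r, -0.5)
    enh <- correlation_experiment(ba, "enhancement", ws = ws)
    expect_gt(enh$pearson_r, 0.9)
  }
})

test_that("greedy slope-guided removal keeps connectivity and decreases the ratio", {
  net <- generate_er(40, 90, seed = 11)
  gr <- greedy_removal(net, 5)
  expect_equal(nrow(gr$steps), 5L)
  expect_false(gr$stopped_early)
  expect_true(is_connected_matrix(gr$final$weights))
  expect_true(all(diff(c(gr$bc0, gr$steps$bc_after)) < 0))
  # zero steps: empty trajectory, base value retained
  gr0 <- greedy_removal(net, 0)
  expect_equal(nrow(gr0$steps), 0L)
  expect_equal(gr0$bc0, tau_summary(net)$bc_star)
})

test_that("greedy tie-breaking picks the lexicographically smallest pair", {
  c8 <- fixture("cycle", 8)
  gr <- greedy_removal(c8, 1)
  expect_equal(unname(unlist(gr$steps[1, c("i", "j")])), c(1L, 2L))
})

test_that("degree-sum heuristic removes hub edges first and enumerates ties", {
  # wheel: hub (degree 5) + 5-cycle rim (degree 3); all hub edges tie
  W <- fixture("cycle", 5)$weights
  W <- rbind(cbind(W, 1), c(rep(1, 5), 0))
  wheel <- weighted_network(W)
  dh <- degree_heuristic_removal(wheel, 1)
  expect_equal(length(dh$trajectories), 5L)
  for (tr in dh$trajectories) expect_true(6L %in% c(tr$i, tr$j))
})

test_that("scenario enumeration caps with seeded subsampling", {
  c8 <- fixture("cycle", 8) # every edge ties on degree sum
  dh <- degree_heuristic_removal(c8, 1, max_scenarios = 3, seed = 5)
  expect_true(dh$capped)
  expect_length(dh$trajectories, 3L)
  dh2 <- degree_heuristic_removal(c8, 1, max_scenarios = 3, seed = 5)
  expect_identical(
    lapply(dh$trajectories, `[[`, "i"),
    lapply(dh2$trajectories, `[[`, "i")
  )
})

test_that("workspace-accelerated heuristic scoring equals the direct solve", {
  net <- generate_er(30, 70, seed = 13)
  ws <- perturbation_workspace(net)
  a <- degree_heuristic_removal(net, 2, seed = 1)
  b <- degree_heuristic_removal(net, 2, seed = 1, ws = ws)
  expect_equal(
    lapply(a$trajectories, `[[`, "bc_after"),
    lapply(b$trajectories, `[[`, "bc_after"),
    tolerance = 1e-9
  )
})
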
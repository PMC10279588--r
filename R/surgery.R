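#' Exact change in the critical ratio under a finite edge update
#'
#' Directly recomputes \eqn{(b/c)^*} on the perturbed network and
#' returns \eqn{(b/c)^*(\varepsilon) - (b/c)^*(0)}.  Given a
#' [perturbation_workspace()] the recomputation reuses the base solve
#' handle through an exact low-rank update ([tau_summary_updated()]);
#' given a bare network it solves the perturbed coalescence system from
#' scratch.  Both routes are exact and agree to solver precision.
#'
#' @param x a `weighted_network` or a [perturbation_workspace()].
#' @param pert an [edge_perturbation()] with a finite `epsilon`.
#' @return numeric scalar: the exact change in \eqn{(b/c)^*}.  Errors
#'   if the perturbed network is disconnected (bridge removal).
#' @export
actual_change <- function(x, pert) {
  if (pert$epsilon == 0) {
    return(0)
  }
  if (inherits(x, "perturbation_workspace")) {
    tau_summary_updated(x, pert)$bc_star - x$tau$bc_star
  } else {
    net_eps <- perturb_edge_weight(x, pert$i0, pert$j0, pert$epsilon)
    tau_summary(net_eps)$bc_star - tau_summary(x)$bc_star
  }
}

#' Sweep the perturbation strength for one node pair
#'
#' Exact curve \eqn{(b/c)^*(\varepsilon) - (b/c)^*(0)} over a grid of
#' \eqn{\varepsilon} values for a single pair, together with the
#' first-order slope at \eqn{\varepsilon = 0} and a nonlinearity
#' statistic (maximum absolute deviation of the curve from the chord
#' connecting its endpoints, relative to the endpoint span).
#'
#' @param ws a [perturbation_workspace()].
#' @param i0,j0 the node pair.
#' @param mode `"removal"`, `"addition"` or `"enhancement"`.
#' @param grid epsilon values; defaults to 0.1 spacing over
#'   \eqn{[-w_{i_0 j_0}, 0]} for removal and \eqn{[0, 1]} otherwise.
#' @return object of class `sweep_curve`: list with `i0`, `j0`, `mode`,
#'   `grid`, `values`, `slope`, `nonlinearity`.
#' @export
epsilon_sweep <- function(ws, i0, j0, mode = NULL, grid = NULL) {
  pert0 <- edge_perturbation(ws, i0, j0, mode = mode)
  if (is.null(grid)) {
    grid <- if (pert0$mode == "removal") {
      seq(-pert0$w0, 0, by = 0.1 * pert0$w0)
    } else {
      seq(0, 1, by = 0.1)
    }
  }
  values <- vapply(grid, function(eps) {
    if (eps == 0) {
      return(0)
    }
    # mode is re-inferred per grid point so that two-sided grids around
    # zero (removal on one side, enhancement on the other) are valid
    actual_change(ws, edge_perturbation(ws, i0, j0, eps))
  }, numeric(1))
  slope <- bc_slope(ws, pert0)$slope
  # deviation from the chord through the curve's endpoints
  e1 <- grid[1L]
  e2 <- grid[length(grid)]
  chord <- values[1L] + (grid - e1) * (values[length(values)] - values[1L]) / (e2 - e1)
  span <- max(abs(values))
  nonlin <- if (span > 0) max(abs(values - chord)) / span else 0
  structure(
    list(
      i0 = pert0$i0, j0 = pert0$j0, mode = pert0$mode,
      grid = grid, values = values, slope = slope, nonlinearity = nonlin
    ),
    class = "sweep_curve"
  )
}

#' Slope-versus-actual-change correlation experiment
#'
#' For every eligible node pair, computes the perturbation-theory slope
#' \eqn{\Delta(b/c)^*} and the exact change in \eqn{(b/c)^*} under the
#' finite update defined by the mode — full removal
#' (\eqn{\varepsilon = -w}), addition of a unit-weight edge
#' (\eqn{\varepsilon = +1}) or enhancement of a unit edge to weight 2
#' (\eqn{\varepsilon = +1}) — and reports the Pearson correlation
#' between the two across pairs.  Bridges are excluded from removal
#' (their deletion disconnects the network, leaving \eqn{(b/c)^*}
#' undefined); the exclusion count is reported.
#'
#' @param net a connected `weighted_network`.
#' @param mode `"removal"`, `"addition"` or `"enhancement"`.
#' @param ws optionally, a prebuilt [perturbation_workspace()].
#' @param epsilon finite update size (default: mode convention above).
#' @param ... passed to [perturbation_workspace()].
#' @return object of class `surgery_report`: list with `mode`,
#'   `records` (data frame: `i`, `j`, `slope`, `actual`), `pearson_r`,
#'   `p_value`, `n`, `excluded`.
#' @export
correlation_experiment <- function(net, mode = c("removal", "addition", "enhancement"),
                                   ws = NULL, epsilon = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(ws)) ws <- perturbation_workspace(net, ...)
  pairs <- if (mode == "addition") nonedge_pairs(net) else edge_pairs(net)
  excluded <- 0L
  if (mode == "removal") {
    br <- bridge_pairs(net)
    if (nrow(br)) {
      keep <- !(paste(pairs[, 1L], pairs[, 2L]) %in% paste(br[, 1L], br[, 2L]))
      excluded <- sum(!keep)
      pairs <- pairs[keep, , drop = FALSE]
    }
  }
  if (nrow(pairs) < 3L) stop("fewer than 3 eligible pairs")
  slope <- numeric(nrow(pairs))
  actual <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    eps <- if (!is.null(epsilon)) {
      if (mode == "removal") -abs(epsilon) else abs(epsilon)
    } else if (mode == "removal") {
      -net$weights[i, j]
    } else {
      1
    }
    pert <- edge_perturbation(net, i, j, eps, mode = mode)
    slope[r] <- bc_slope(ws, pert)$slope
    actual[r] <- actual_change(ws, pert)
  }
  ct <- stats::cor.test(slope, actual)
  structure(
    list(
      mode = mode,
      records = data.frame(i = pairs[, 1L], j = pairs[, 2L], slope = slope, actual = actual),
      pearson_r = unname(ct$estimate), p_value = ct$p.value,
      n = nrow(pairs), excluded = excluded,
      bc_star = ws$tau$bc_star
    ),
    class = "surgery_report"
  )
}

#' @export
print.surgery_report <- function(x, ...) {
  cat(sprintf(
    "<surgery_report: %s, r = %.3f, n = %d, p = %.2g, excluded = %d>\n",
    x$mode, x$pearson_r, x$n, x$p_value, x$excluded
  ))
  invisible(x)
}

#' Greedy sequential edge removal guided by the perturbation slope
#'
#' Starting from the base network, repeatedly recomputes the
#' perturbation-theory slope for every remaining non-bridge edge,
#' removes the edge with the largest \eqn{\Delta(b/c)^*} (ties broken
#' by the lexicographically smallest pair), and records the exact
#' \eqn{(b/c)^*} of the reduced network.  Connectivity is maintained at
#' every step; if no removable edge remains the trajectory stops early
#' with a flag.
#'
#' @param net a connected `weighted_network`.
#' @param steps number of edges to remove (default 5).
#' @param ... passed to [perturbation_workspace()].
#' @return object of class `greedy_trajectory`: list with `strategy`,
#'   `bc0`, `steps` (data frame: `step`, `i`, `j`, `score`,
#'   `bc_after`), `stopped_early`.
#' @export
greedy_removal <- function(net, steps = 5L, ...) {
  bc0 <- NULL
  rows <- list()
  stopped <- FALSE
  current <- net
  for (stp in seq_len(steps)) {
    ws <- perturbation_workspace(current, ...)
    if (is.null(bc0)) bc0 <- ws$tau$bc_star
    cand <- removable_edges(current)
    if (nrow(cand) == 0L) {
      stopped <- TRUE
      break
    }
    slopes <- vapply(seq_len(nrow(cand)), function(r) {
      bc_slope(ws, edge_perturbation(current, cand[r, 1L], cand[r, 2L],
        -current$weights[cand[r, 1L], cand[r, 2L]],
        mode = "removal"
      ))$slope
    }, numeric(1))
    # ties (within floating tolerance) break to the lexicographically
    # smallest pair; candidates are already in that order
    best <- which(slopes >= max(slopes) - 1e-9 * max(1, abs(max(slopes))))[1L]
    i <- cand[best, 1L]
    j <- cand[best, 2L]
    pert <- edge_perturbation(current, i, j, -current$weights[i, j], mode = "removal")
    bc_after <- tau_summary_updated(ws, pert)$bc_star
    current <- perturb_edge_weight(current, i, j, pert$epsilon)
    rows[[stp]] <- data.frame(
      step = stp, i = i, j = j, score = slopes[best], bc_after = bc_after
    )
  }
  if (is.null(bc0)) bc0 <- tau_summary(net)$bc_star
  structure(
    list(
      strategy = "perturbation", bc0 = bc0,
      steps = if (length(rows)) do.call(rbind, rows) else
        data.frame(step = integer(), i = integer(), j = integer(),
                   score = numeric(), bc_after = numeric()),
      stopped_early = stopped, final = current
    ),
    class = "greedy_trajectory"
  )
}

removable_edges <- function(net) {
  pairs <- edge_pairs(net)
  br <- bridge_pairs(net)
  if (nrow(br)) {
    keep <- !(paste(pairs[, 1L], pairs[, 2L]) %in% paste(br[, 1L], br[, 2L]))
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

#' Sequential edge removal by the degree-sum heuristic
#'
#' Baseline strategy: at each step remove a non-bridge edge maximizing
#' the degree sum \eqn{k_i + k_j} of its endpoints.  Because several
#' edges frequently tie on this score, all tie-resolution scenarios are
#' enumerated (up to `max_scenarios` branches; beyond that a uniform
#' random subsample of branches is kept, controlled by `seed`), and the
#' exact \eqn{(b/c)^*} after each removal is recorded per scenario.
#' Each step also records whether scoring edges by the degree product
#' \eqn{k_i k_j} selects the same tie set.
#'
#' @param net a connected `weighted_network`.
#' @param steps number of edges to remove.
#' @param max_scenarios cap on enumerated tie-resolution branches.
#' @param seed RNG seed for subsampling beyond the cap.
#' @param ws optionally, a base-network [perturbation_workspace()]; the
#'   exact \eqn{(b/c)^*} of every reduced network is then obtained by a
#'   low-rank update of the base solve ([tau_summary_for()]) instead of
#'   a fresh system solve per scenario step.
#' @return object of class `greedy_trajectory_set`: list with `bc0`,
#'   `trajectories` (list of per-scenario data frames `step`, `i`, `j`,
#'   `score`, `bc_after`), `product_rule_agrees` (logical), `capped`.
#' @export
degree_heuristic_removal <- function(net, steps = 5L, max_scenarios = 64L,
                                     seed = NULL, ws = NULL) {
  bc_of <- function(reduced) {
    if (is.null(ws)) tau_summary(reduced)$bc_star else tau_summary_for(ws, reduced)$bc_star
  }
  bc0 <- if (is.null(ws)) tau_summary(net)$bc_star else ws$tau$bc_star
  scenarios <- list(list(net = net, rows = list()))
  product_agrees <- TRUE
  capped <- FALSE
  with_seed_if(seed, {
    for (stp in seq_len(steps)) {
      nxt <- list()
      for (sc in scenarios) {
        cand <- removable_edges(sc$net)
        if (nrow(cand) == 0L) {
          nxt[[length(nxt) + 1L]] <- sc
          next
        }
        deg <- rowSums(sc$net$weights > 0)
        score_sum <- deg[cand[, 1L]] + deg[cand[, 2L]]
        score_prod <- deg[cand[, 1L]] * deg[cand[, 2L]]
        top <- which(score_sum == max(score_sum))
        top_prod <- which(score_prod == max(score_prod))
        if (!setequal(top, top_prod)) product_agrees <- FALSE
        for (b in top) {
          i <- cand[b, 1L]
          j <- cand[b, 2L]
          reduced <- perturb_edge_weight(sc$net, i, j, -sc$net$weights[i, j])
          rows <- c(sc$rows, list(data.frame(
            step = stp, i = i, j = j, score = score_sum[b],
            bc_after = bc_of(reduced)
          )))
          nxt[[length(nxt) + 1L]] <- list(net = reduced, rows = rows)
        }
      }
      if (length(nxt) > max_scenarios) {
        capped <- TRUE
        nxt <- nxt[sort(sample.int(length(nxt), max_scenarios))]
      }
      scenarios <- nxt
    }
  })
  structure(
    list(
      strategy = "degree_sum", bc0 = bc0,
      trajectories = lapply(scenarios, function(sc) do.call(rbind, sc$rows)),
      product_rule_agrees = product_agrees, capped = capped
    ),
    class = "greedy_trajectory_set"
  )
}
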
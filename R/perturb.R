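#' Single-edge perturbation descriptor
#'
#' Describes the perturbation of the weight of one node pair
#' \eqn{(i_0, j_0)} by a signed amount \eqn{\varepsilon}.  Three modes
#' are distinguished: `removal` reduces the weight of an existing edge
#' (\eqn{-w_{i_0 j_0} \le \varepsilon < 0}; \eqn{\varepsilon = -w}
#' deletes it), `addition` creates a new edge
#' (\eqn{w_{i_0 j_0} = 0}, \eqn{\varepsilon > 0}), and `enhancement`
#' increases the weight of an existing edge (\eqn{\varepsilon > 0}).
#' Self-loop perturbation (`i0 == j0`) is not supported.
#'
#' @param net a `weighted_network` (or a [perturbation_workspace()]).
#' @param i0,j0 1-based internal node indices of the perturbed pair.
#' @param epsilon signed weight change; may be omitted when only the
#'   first-order slope is required (it does not depend on epsilon).
#' @param mode one of `"removal"`, `"addition"`, `"enhancement"`;
#'   inferred from the sign of `epsilon` and the current weight when
#'   missing.
#' @return list of class `edge_perturbation` with fields `i0`, `j0`,
#'   `epsilon`, `mode`, `w0` (unperturbed weight).
#' @export
edge_perturbation <- function(net, i0, j0, epsilon = NA_real_, mode = NULL) {
  if (inherits(net, "perturbation_workspace")) net <- net$net
  i0 <- as.integer(i0)
  j0 <- as.integer(j0)
  if (i0 == j0) stop("self-loop perturbation (i0 == j0) is not supported")
  if (i0 < 1L || j0 < 1L || i0 > net$n || j0 > net$n) stop("node index out of range")
  w0 <- net$weights[i0, j0]
  if (is.null(mode)) {
    mode <- if (!is.na(epsilon) && epsilon < 0) {
      "removal"
    } else if (w0 == 0) "addition" else "enhancement"
  }
  mode <- match.arg(mode, c("removal", "addition", "enhancement"))
  if (!is.na(epsilon) && epsilon != 0) {
    if (mode == "removal" && !(w0 > 0 && epsilon < 0 && epsilon >= -w0 - 1e-12)) {
      stop("removal requires an existing edge and -w <= epsilon < 0")
    }
    if (mode == "addition" && !(w0 == 0 && epsilon > 0)) {
      stop("addition requires w = 0 and epsilon > 0")
    }
    if (mode == "enhancement" && !(w0 > 0 && epsilon > 0)) {
      stop("enhancement requires an existing edge and epsilon > 0")
    }
  }
  structure(
    list(
      i0 = min(i0, j0), j0 = max(i0, j0),
      epsilon = epsilon, mode = mode, w0 = w0
    ),
    class = "edge_perturbation"
  )
}

#' Perturbation workspace
#'
#' One-time precomputation for per-edge perturbation queries on a fixed
#' base network: the random-walk ensemble, the coalescence solution
#' \eqn{T(0)}, its summaries, and a reusable solve handle for the
#' compact coalescence system \eqn{A}.  With the `"dense"` handle the
#' inverse \eqn{A^{-1}} is materialized once (\eqn{O(N^6)} once,
#' \eqn{N(N-1)/2} unknowns), after which every per-edge slope or exact
#' edge-update query costs at most \eqn{O(N^3)}; the `"sparse"` handle
#' keeps a sparse LU factorization instead, trading per-query speed for
#' memory on large networks.  No per-edge query triggers a fresh
#' factorization (see the `stats` counter fields).
#'
#' @param net a connected `weighted_network`.
#' @param solver `"auto"`, `"dense"` or `"sparse"`.
#' @param dense_limit maximum pair-unknown count for the dense handle
#'   under `"auto"` (default keeps networks up to about 170 nodes on
#'   the dense path).
#' @return An object of class `perturbation_workspace`.
#' @examples
#' ws <- perturbation_workspace(fixture("cycle", 6))
#' ws$tau$bc_star # 4
#' @export
perturbation_workspace <- function(net, solver = c("auto", "dense", "sparse"),
                                   dense_limit = 15000L) {
  solver <- match.arg(solver)
  ens <- random_walk_ensemble(net)
  A <- coalescence_compact_system(ens$P)
  np <- nrow(A)
  use_dense <- solver == "dense" || (solver == "auto" && np <= dense_limit)
  stats_env <- new.env(parent = emptyenv())
  stats_env$factorizations <- 1L
  stats_env$solves <- 0L
  if (use_dense) {
    Ainv <- solve(as.matrix(A))
    solve_cols <- function(rows) Ainv[, rows, drop = FALSE]
    solve_vec <- function(b) {
      stats_env$solves <- stats_env$solves + 1L
      nz <- which(b != 0)
      as.numeric(Ainv[, nz, drop = FALSE] %*% b[nz])
    }
  } else {
    fac <- Matrix::lu(A)
    solve_cols <- function(rows) {
      E <- matrix(0, np, length(rows))
      E[cbind(rows, seq_along(rows))] <- 1
      as.matrix(Matrix::solve(fac, E))
    }
    solve_vec <- function(b) {
      stats_env$solves <- stats_env$solves + 1L
      as.numeric(Matrix::solve(fac, b))
    }
  }
  t_vec <- solve_vec(rep(1, np))
  Tm <- pair_vector_to_matrix(t_vec, net$n)
  res <- coalescence_residual(Tm, ens$P)
  if (!is.finite(res) || res > 1e-6) {
    stop(sprintf("coalescence system solve failed (residual %.3e)", res))
  }
  coal <- structure(list(T = Tm, residual = res, n = net$n),
    class = "coalescence_solution"
  )
  tau <- tau_summary(net, ens, coal)
  structure(
    list(
      net = net, ens = ens, coal = coal, tau = tau,
      # per-node row sums of P^k o T, reused by every Gamma_k query
      h = cbind(
        rowSums(ens$P * Tm),
        rowSums(ens$P2 * Tm),
        rowSums(ens$P3 * Tm)
      ),
      t_vec = t_vec,
      solver = if (use_dense) "dense" else "sparse",
      solve_vec = solve_vec, solve_cols = solve_cols,
      stats = stats_env
    ),
    class = "perturbation_workspace"
  )
}

#' @export
print.perturbation_workspace <- function(x, ...) {
  cat(sprintf(
    "<perturbation_workspace: N = %d, |E| = %d, (b/c)* = %.6g, %s handle>\n",
    x$net$n, n_edges(x$net), x$tau$bc_star, x$solver
  ))
  invisible(x)
}

#' First-order change of the stationary distribution
#'
#' \deqn{\Delta\pi_i = (\delta_{i i_0} + \delta_{i j_0})/S - 2\pi_i/S,}
#' the derivative of the stationary distribution with respect to the
#' perturbed edge weight; its entries sum to zero.
#'
#' @param ws a [perturbation_workspace()].
#' @param pert an [edge_perturbation()].
#' @return numeric vector of length N.
#' @export
delta_pi <- function(ws, pert) {
  S <- ws$ens$total_strength
  d <- -2 * ws$ens$pi / S
  d[pert$i0] <- d[pert$i0] + 1 / S
  d[pert$j0] <- d[pert$j0] + 1 / S
  d
}

#' First-order change of the transition matrix and its powers
#'
#' The matrices \eqn{\Theta^{(k)}} such that
#' \eqn{P^k(\varepsilon) = P^k + \varepsilon \Theta^{(k)} +
#' o(\varepsilon)} for \eqn{k = 1, 2, 3}.  `method = "direct"`
#' evaluates the explicit entrywise expressions;
#' `method = "composition"` uses the product rule
#' \eqn{\Theta^{(2)} = \Theta^{(1)} P + P \Theta^{(1)}} and
#' \eqn{\Theta^{(3)} = \Theta^{(1)} P^2 + P \Theta^{(1)} P +
#' P^2 \Theta^{(1)}}; the two agree and are cross-checked in the test
#' suite.  Every row of each \eqn{\Theta^{(k)}} sums to zero because
#' \eqn{P^k(\varepsilon)} stays row-stochastic.
#'
#' @inheritParams delta_pi
#' @param method `"direct"` or `"composition"`.
#' @return list with matrices `theta1`, `theta2`, `theta3`.
#' @export
theta_matrices <- function(ws, pert, method = c("direct", "composition")) {
  method <- match.arg(method)
  th1 <- theta1_matrix(ws, pert)
  if (method == "composition") {
    P <- ws$ens$P
    P2 <- ws$ens$P2
    th2 <- th1 %*% P + P %*% th1
    th3 <- th1 %*% P2 + P %*% th1 %*% P + P2 %*% th1
    return(list(theta1 = th1, theta2 = th2, theta3 = th3))
  }
  i0 <- pert$i0
  j0 <- pert$j0
  s <- ws$ens$strengths
  P <- ws$ens$P
  P2 <- ws$ens$P2
  P3 <- ws$ens$P3
  n <- ws$net$n
  th2 <- matrix(0, n, n)
  th2[i0, ] <- (P[j0, ] - P2[i0, ]) / s[i0]
  th2[j0, ] <- (P[i0, ] - P2[j0, ]) / s[j0]
  th2[, j0] <- th2[, j0] + P[, i0] / s[i0]
  th2[, i0] <- th2[, i0] + P[, j0] / s[j0]
  th2 <- th2 - outer(P[, i0], P[i0, ]) / s[i0] - outer(P[, j0], P[j0, ]) / s[j0]
  th3 <- matrix(0, n, n)
  th3[i0, ] <- (P2[j0, ] - P3[i0, ]) / s[i0]
  th3[j0, ] <- (P2[i0, ] - P3[j0, ]) / s[j0]
  th3 <- th3 +
    outer(P[, i0], P[j0, ]) / s[i0] + outer(P[, j0], P[i0, ]) / s[j0] -
    outer(P[, i0], P2[i0, ]) / s[i0] - outer(P[, j0], P2[j0, ]) / s[j0]
  th3[, j0] <- th3[, j0] + P2[, i0] / s[i0]
  th3[, i0] <- th3[, i0] + P2[, j0] / s[j0]
  th3 <- th3 -
    outer(P2[, i0], P[i0, ]) / s[i0] - outer(P2[, j0], P[j0, ]) / s[j0]
  list(theta1 = th1, theta2 = th2, theta3 = th3)
}

# Theta^(1): nonzero only in rows i0 and j0
theta1_matrix <- function(ws, pert) {
  i0 <- pert$i0
  j0 <- pert$j0
  s <- ws$ens$strengths
  P <- ws$ens$P
  n <- ws$net$n
  th1 <- matrix(0, n, n)
  th1[i0, ] <- -P[i0, ] / s[i0]
  th1[i0, j0] <- th1[i0, j0] + 1 / s[i0]
  th1[j0, ] <- -P[j0, ] / s[j0]
  th1[j0, i0] <- th1[j0, i0] + 1 / s[j0]
  th1
}

#' Action of the coalescence-system derivative on vec(T)
#'
#' The derivative \eqn{\Delta M} of the redundant coalescence system
#' matrix has at most \eqn{4N - 6} structurally nonzero rows: the rows
#' indexed by ordered pairs \eqn{(i, j)}, \eqn{i \ne j}, with
#' \eqn{i \in \{i_0, j_0\}} or \eqn{j \in \{i_0, j_0\}}.  Because every
#' row of \eqn{M} is affine in the entries of \eqn{P}, each row of
#' \eqn{\Delta M} is the same linear form evaluated on
#' \eqn{\Theta^{(1)}}, so the product \eqn{\Delta M\,\mathrm{vec}(T)}
#' collapses to
#' \deqn{v_{ij} = -\tfrac12\left[(\Theta^{(1)} T)_{ij} +
#'   (\Theta^{(1)} T)_{ji}\right],}
#' computed here by touching only the two nonzero rows of
#' \eqn{\Theta^{(1)}}.
#'
#' @inheritParams delta_pi
#' @return list with `V` (the \eqn{N \times N} matrix \eqn{v_{ij}},
#'   zero diagonal), `vec` (its redundant row-major \eqn{N^2} vector),
#'   and `rows` (the structurally nonzero redundant row indices).
#' @export
delta_M_action <- function(ws, pert) {
  Tm <- ws$coal$T
  th1 <- theta1_matrix(ws, pert)
  r_i0 <- as.numeric(th1[pert$i0, ] %*% Tm)
  r_j0 <- as.numeric(th1[pert$j0, ] %*% Tm)
  n <- ws$net$n
  ThT <- matrix(0, n, n)
  ThT[pert$i0, ] <- r_i0
  ThT[pert$j0, ] <- r_j0
  V <- -(ThT + t(ThT)) / 2
  diag(V) <- 0
  list(V = V, vec = vec_rowmajor(V), rows = delta_M_rows(n, pert$i0, pert$j0))
}

#' @rdname delta_M_action
#' @param n number of nodes.
#' @param i0,j0 perturbed pair (1-based).
#' @export
delta_M_rows <- function(n, i0, j0) {
  vidx <- function(a, b) (a - 1L) * n + b
  others <- setdiff(seq_len(n), c(i0, j0))
  sort(unique(c(
    vidx(i0, seq_len(n)[-i0]), vidx(j0, seq_len(n)[-j0]),
    vidx(others, i0), vidx(others, j0)
  )))
}

#' Explicit sparse derivative of the redundant coalescence system
#'
#' Assembles \eqn{\Delta M} entrywise for validation against the dense
#' finite-difference oracle; intended for small networks only.
#'
#' @inheritParams delta_pi
#' @return sparse \eqn{N^2 \times N^2} matrix.
#' @export
delta_M_redundant <- function(ws, pert) {
  n <- ws$net$n
  th1 <- theta1_matrix(ws, pert)
  vidx <- function(a, b) (a - 1L) * n + b
  rows <- list()
  cols <- list()
  vals <- list()
  push <- function(r, cc, v) {
    rows[[length(rows) + 1L]] <<- r
    cols[[length(cols) + 1L]] <<- cc
    vals[[length(vals) + 1L]] <<- v
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      r <- vidx(i, j)
      for (k in seq_len(n)[-j]) {
        if (th1[i, k] != 0) push(r, vidx(min(k, j), max(k, j)), -th1[i, k] / 2)
      }
      for (k in seq_len(n)[-i]) {
        if (th1[j, k] != 0) push(r, vidx(min(k, i), max(k, i)), -th1[j, k] / 2)
      }
    }
  }
  Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(n^2, n^2)
  )
}

#' First-order change of the coalescence times
#'
#' Solves \eqn{\mathrm{vec}(\Delta T) = -M^{-1} \Delta M\,
#' \mathrm{vec}(T)} through the workspace's reusable handle for the
#' compact pair system (the compact and redundant systems are
#' algebraically equivalent; see [coalescence_system_redundant()]).
#' \eqn{\Delta T} is symmetric with zero diagonal.
#'
#' @inheritParams delta_pi
#' @return \eqn{N \times N} matrix \eqn{\Delta T}.
#' @export
delta_T <- function(ws, pert) {
  act <- delta_M_action(ws, pert)
  w <- pair_matrix_to_vector(act$V)
  dt <- -ws$solve_vec(w)
  pair_vector_to_matrix(dt, ws$net$n)
}

#' First-order change of the coalescence summaries and the slope
#'
#' Computes \deqn{\Gamma_k = \Delta\pi (P^k \circ T)\mathbf{1} +
#'   \pi (\Theta^{(k)} \circ T)\mathbf{1} +
#'   \pi (P^k \circ \Delta T)\mathbf{1}} for \eqn{k = 1, 2, 3} and the
#' first-order slope of the critical ratio,
#' \deqn{\Delta(b/c)^* = \frac{(\tau_3 - \tau_1)\Gamma_2 -
#'   \tau_2(\Gamma_3 - \Gamma_1)}{(\tau_3 - \tau_1)^2},}
#' the derivative of \eqn{(b/c)^*} with respect to the perturbed edge
#' weight at \eqn{\varepsilon = 0}.
#'
#' @inheritParams delta_pi
#' @param details also return `delta_pi`, `delta_T` and the
#'   \eqn{\Theta^{(k)}} matrices.
#' @return list of class `bc_slope` with `gamma1`, `gamma2`, `gamma3`,
#'   `slope` and, if requested, the intermediate objects.
#' @export
bc_slope <- function(ws, pert, details = FALSE) {
  tau <- ws$tau
  if (tau$degenerate) {
    stop("degenerate base network: tau3 = tau1, the critical ratio is infinite")
  }
  dpi <- delta_pi(ws, pert)
  th <- theta_matrices(ws, pert)
  dT <- delta_T(ws, pert)
  Tm <- ws$coal$T
  pi0 <- ws$ens$pi
  Pk <- list(ws$ens$P, ws$ens$P2, ws$ens$P3)
  thk <- list(th$theta1, th$theta2, th$theta3)
  gam <- vapply(1:3, function(k) {
    sum(dpi * ws$h[, k]) +
      sum(pi0 * rowSums(thk[[k]] * Tm)) +
      sum(pi0 * rowSums(Pk[[k]] * dT))
  }, numeric(1))
  denom <- tau$tau3 - tau$tau1
  slope <- (denom * gam[2L] - tau$tau2 * (gam[3L] - gam[1L])) / denom^2
  out <- list(
    gamma1 = gam[1L], gamma2 = gam[2L], gamma3 = gam[3L],
    slope = slope, i0 = pert$i0, j0 = pert$j0, mode = pert$mode
  )
  if (details) {
    out$delta_pi <- dpi
    out$delta_T <- dT
    out$theta <- th
  }
  structure(out, class = "bc_slope")
}

#' @export
print.bc_slope <- function(x, ...) {
  cat(sprintf(
    "<bc_slope: pair (%d, %d), %s, Delta(b/c)* = %.6g>\n",
    x$i0, x$j0, x$mode, x$slope
  ))
  invisible(x)
}

#' Exact critical ratio after a finite single-edge update
#'
#' Recomputes \eqn{(b/c)^*} on the network with \eqn{w_{i_0 j_0}}
#' changed by a finite \eqn{\varepsilon}, exactly but without solving
#' the coalescence system from scratch: the compact system matrix
#' changes in only \eqn{2N - 3} rows, so the updated solve is obtained
#' from the base handle by a low-rank (Woodbury) correction.  On the
#' sparse handle this costs \eqn{2N - 3} triangular solves; on the
#' dense handle it is a column extraction plus a small dense solve.
#'
#' @inheritParams delta_pi
#' @param check_connected verify the perturbed network stays connected
#'   (a full bridge removal errors).
#' @return a `tau_summary` for the perturbed network.
#' @export
tau_summary_updated <- function(ws, pert, check_connected = TRUE) {
  eps <- pert$epsilon
  if (is.na(eps)) stop("edge_perturbation has no epsilon")
  net <- ws$net
  W <- net$weights
  w_new <- W[pert$i0, pert$j0] + eps
  if (w_new < -1e-12) stop("perturbation would make the edge weight negative")
  W[pert$i0, pert$j0] <- max(w_new, 0)
  W[pert$j0, pert$i0] <- max(w_new, 0)
  if (check_connected && w_new <= 1e-12 && !is_connected_matrix(W)) {
    stop("edge removal disconnects the network")
  }
  tau_summary_for(ws, weighted_network(W, labels = net$labels, check = FALSE))
}

#' @rdname tau_summary_updated
#'
#' @details
#' `tau_summary_for()` accepts any network on the same node set: the
#' compact system matrix differs from the base one only in the rows
#' whose pair touches a node with a changed weight row, so the update
#' stays low-rank as long as few nodes are affected (rank at most
#' \eqn{2N - 3} per perturbed node pair).
#'
#' @param net_new a connected `weighted_network` on the same nodes as
#'   the workspace's base network.
#' @export
tau_summary_for <- function(ws, net_new) {
  if (net_new$n != ws$net$n) stop("node count differs from the base network")
  n <- net_new$n
  ens_new <- random_walk_ensemble(net_new)
  dP <- ens_new$P - ws$ens$P
  if (max(abs(dP)) == 0) {
    return(ws$tau)
  }
  dA <- coalescence_operator(dP)
  rows <- sort(unique(dA@i)) + 1L # nonzero rows of the update
  Z <- dA[rows, , drop = FALSE]
  X <- ws$solve_cols(rows)
  Zy <- as.numeric(Z %*% ws$t_vec)
  ZX <- as.matrix(Z %*% X)
  u <- solve(diag(length(rows)) + ZX, Zy)
  t_new <- ws$t_vec - as.numeric(X %*% u)
  Tm <- pair_vector_to_matrix(t_new, n)
  res <- coalescence_residual(Tm, ens_new$P)
  if (!is.finite(res) || res > 1e-6) {
    stop(sprintf("low-rank update solve failed (residual %.3e)", res))
  }
  coal <- structure(list(T = Tm, residual = res, n = n),
    class = "coalescence_solution"
  )
  tau_summary(net_new, ens_new, coal)
}
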
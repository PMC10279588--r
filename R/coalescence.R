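#' Random-walk ensemble of a weighted network
#'
#' Computes the objects that the coalescence theory is built on: node
#' strengths \eqn{s_i = \sum_j w_{ij}}, total strength
#' \eqn{S = \sum_i s_i}, the row-stochastic transition matrix
#' \eqn{P = D^{-1} W} of the simple random walk, its second and third
#' powers, and the stationary distribution \eqn{\pi_i = s_i / S}.
#'
#' @param net a connected `weighted_network`.
#' @return An object of class `random_walk_ensemble`: a list with
#'   fields `pi`, `P`, `P2`, `P3`, `strengths`, `total_strength`, `n`.
#' @examples
#' ens <- random_walk_ensemble(fixture("path", 3))
#' ens$pi  # (1/4, 1/2, 1/4)
#' @export
random_walk_ensemble <- function(net) {
  W <- net$weights
  s <- rowSums(W)
  if (any(s <= 0)) stop("isolated node: zero strength")
  P <- W / s
  P2 <- P %*% P
  structure(
    list(
      pi = s / sum(s), P = P, P2 = P2, P3 = P2 %*% P,
      strengths = s, total_strength = sum(s), n = net$n
    ),
    class = "random_walk_ensemble"
  )
}

# ---- compact indexing of unordered node pairs -------------------------------
# pairs (i, j) with i < j in lexicographic (row-major) order, matching the
# redundant N^2 vectorization's upper triangle

pair_table <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  list(i = i, j = j, np = (n * (n - 1L)) %/% 2L)
}

# 1-based compact index of the unordered pair {a, b}, a != b
pair_index <- function(a, b, n) {
  i <- pmin(a, b)
  j <- pmax(a, b)
  (i - 1L) * n - (i * (i + 1L)) %/% 2L + j
}

# ---- compact coalescence system ---------------------------------------------

# Linear part L(P) of the compact coalescence system: for each unordered
# pair row {a, b} the equation is
#   t_ab - (1/2) sum_{k != b} p_ak t_{k,b} - (1/2) sum_{k != a} p_bk t_{k,a} = 1
# so the full system matrix is A = I + L(P) with L(P) collecting the
# -p/2 terms.  L is linear in the entries of P, so the same assembler
# yields the derivative of A when handed dP/deps.
coalescence_operator <- function(Pmat) {
  n <- nrow(Pmat)
  np <- (n * (n - 1L)) %/% 2L
  nz <- which(Pmat != 0, arr.ind = TRUE)
  a <- nz[, 1L]
  k <- nz[, 2L]
  p <- Pmat[nz]
  rows <- vector("list", length(a))
  cols <- vector("list", length(a))
  vals <- vector("list", length(a))
  all_nodes <- seq_len(n)
  for (e in seq_along(a)) {
    b <- if (a[e] == k[e]) all_nodes[-a[e]] else all_nodes[-c(a[e], k[e])]
    rows[[e]] <- pair_index(a[e], b, n)
    cols[[e]] <- pair_index(k[e], b, n)
    vals[[e]] <- rep.int(-p[e] / 2, length(b))
  }
  Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(np, np)
  )
}

coalescence_compact_system <- function(Pmat) {
  Matrix::Diagonal(nrow(Pmat) * (nrow(Pmat) - 1L) / 2) + coalescence_operator(Pmat)
}

#' Pairwise mean coalescence times
#'
#' Solves for the matrix \eqn{T = (t_{ij})} of mean coalescence times
#' of two random walkers, one starting at \eqn{i} and one at \eqn{j},
#' where at each step one of the two walkers (picked with probability
#' 1/2) performs a simple random-walk move:
#' \deqn{t_{ij} = 1 + \tfrac12 \sum_k (p_{ik} t_{jk} + p_{jk} t_{ik}),
#'   \quad t_{ii} = 0.}
#' Symmetry \eqn{t_{ij} = t_{ji}} reduces this to a linear system in the
#' \eqn{N(N-1)/2} unordered pairs, which is solved by a dense LU for
#' moderate sizes and a sparse LU above `dense_limit` unknowns.
#'
#' @param net a connected `weighted_network`.
#' @param ens optionally, a precomputed [random_walk_ensemble()].
#' @param method `"auto"`, `"dense"` or `"sparse"` solver for the
#'   compact pair system.
#' @param dense_limit maximum number of pair unknowns for the dense
#'   path under `method = "auto"`.
#' @return An object of class `coalescence_solution`: list with fields
#'   `T` (symmetric \eqn{N \times N}, zero diagonal), `residual` (max
#'   norm of the defining equations at the solution) and `n`.
#' @examples
#' coalescence_times(fixture("complete", 3))$T  # all off-diagonal 2
#' @export
coalescence_times <- function(net, ens = NULL,
                              method = c("auto", "dense", "sparse"),
                              dense_limit = 15000L) {
  method <- match.arg(method)
  if (is.null(ens)) ens <- random_walk_ensemble(net)
  n <- net$n
  if (n == 1L) {
    return(structure(list(T = matrix(0, 1, 1), residual = 0, n = 1L),
      class = "coalescence_solution"
    ))
  }
  A <- coalescence_compact_system(ens$P)
  np <- nrow(A)
  use_dense <- method == "dense" || (method == "auto" && np <= dense_limit)
  t_vec <- if (use_dense) {
    solve(as.matrix(A), rep(1, np))
  } else {
    as.numeric(Matrix::solve(A, rep(1, np)))
  }
  Tm <- pair_vector_to_matrix(t_vec, n)
  res <- coalescence_residual(Tm, ens$P)
  if (!is.finite(res) || res > 1e-6) {
    stop(sprintf("coalescence system solve failed (residual %.3e)", res))
  }
  structure(list(T = Tm, residual = res, n = n), class = "coalescence_solution")
}

pair_vector_to_matrix <- function(t_vec, n) {
  pt <- pair_table(n)
  Tm <- matrix(0, n, n)
  Tm[cbind(pt$i, pt$j)] <- t_vec
  Tm[cbind(pt$j, pt$i)] <- t_vec
  Tm
}

pair_matrix_to_vector <- function(Tm) {
  n <- nrow(Tm)
  pt <- pair_table(n)
  Tm[cbind(pt$i, pt$j)]
}

# max-norm residual of the defining fixed-point equations
coalescence_residual <- function(Tm, Pmat) {
  PT <- Pmat %*% Tm
  R <- Tm - (1 + (PT + t(PT)) / 2)
  diag(R) <- 0
  max(abs(R))
}

# ---- redundant N^2 vectorization -------------------------------------------

#' Redundant vectorized coalescence system
#'
#' Assembles the full \eqn{N^2 \times N^2} linear system
#' \eqn{M \mathrm{vec}(T) = d} over the row-major vectorization
#' \eqn{\mathrm{vec}(T) = (t_{11}, \ldots, t_{1N}, t_{21}, \ldots,
#' t_{NN})^\top}.  Row \eqn{(i,i)} pins \eqn{t_{ii} = 0}; every row
#' \eqn{(i,j)} with \eqn{i \ne j} carries the symmetrized pair
#' equation with all coefficients placed on upper-triangle positions.
#' This redundant form is what the single-edge perturbation theory is
#' phrased in; the compact pair solver of [coalescence_times()] is
#' algebraically equivalent and is cross-checked against this assembly
#' in the test suite.  Intended for small networks (cost grows as
#' \eqn{N^4}).
#'
#' @param net a connected `weighted_network`.
#' @param ens optionally, a precomputed [random_walk_ensemble()].
#' @return list with sparse `M` (\eqn{N^2 \times N^2}) and numeric `d`.
#' @export
coalescence_system_redundant <- function(net, ens = NULL) {
  if (is.null(ens)) ens <- random_walk_ensemble(net)
  n <- net$n
  P <- ens$P
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
    push(vidx(i, i), vidx(i, i), 1)
    for (j in seq_len(n)[-i]) {
      r <- vidx(i, j)
      push(r, r, 1)
      for (k in seq_len(n)[-j]) {
        if (P[i, k] != 0) push(r, vidx(min(k, j), max(k, j)), -P[i, k] / 2)
      }
      for (k in seq_len(n)[-i]) {
        if (P[j, k] != 0) push(r, vidx(min(k, i), max(k, i)), -P[j, k] / 2)
      }
    }
  }
  M <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(n^2, n^2)
  )
  d <- rep(1, n^2)
  d[vidx(seq_len(n), seq_len(n))] <- 0
  list(M = M, d = d)
}

# row-major vec of a square matrix, matching the redundant system
vec_rowmajor <- function(Tm) as.numeric(t(Tm))

unvec_rowmajor <- function(v, n) t(matrix(v, n, n))

# ---- coalescence summaries and the critical ratio ---------------------------

#' Coalescence summaries and the critical benefit-to-cost ratio
#'
#' Computes \eqn{\tau_k = \pi (P^k \circ T) \mathbf{1}} for
#' \eqn{k = 1, 2, 3} — the expected coalescence time between the two
#' ends of a k-step stationary random-walk trajectory — and the
#' critical benefit-to-cost ratio
#' \deqn{(b/c)^* = \tau_2 / (\tau_3 - \tau_1).}
#' Cooperation is favored by selection (fixation probability above
#' \eqn{1/N} under weak selection) when \eqn{b/c > (b/c)^*} and
#' \eqn{(b/c)^* > 0}.  When \eqn{\tau_3 = \tau_1} the ratio is reported
#' as signed infinity with `degenerate = TRUE`; a negative value means
#' no benefit-to-cost ratio favors cooperation on that network.
#'
#' @param net a connected `weighted_network`.
#' @param ens optionally, a precomputed [random_walk_ensemble()].
#' @param coal optionally, a precomputed [coalescence_times()] solution.
#' @param ... passed on to [coalescence_times()].
#' @return An object of class `tau_summary`: list with `tau1`, `tau2`,
#'   `tau3`, `bc_star`, `degenerate`, `n`.
#' @examples
#' tau_summary(fixture("cycle", 6)) # tau = (5, 4, 6), (b/c)* = 4
#' @export
tau_summary <- function(net, ens = NULL, coal = NULL, ...) {
  if (is.null(ens)) ens <- random_walk_ensemble(net)
  if (is.null(coal)) coal <- coalescence_times(net, ens, ...)
  if (ens$n != coal$n || ens$n != net$n) stop("inputs refer to different networks")
  Tm <- coal$T
  tau <- c(
    sum(ens$pi * rowSums(ens$P * Tm)),
    sum(ens$pi * rowSums(ens$P2 * Tm)),
    sum(ens$pi * rowSums(ens$P3 * Tm))
  )
  denom <- tau[3L] - tau[1L]
  degenerate <- abs(denom) < 1e-12 * max(1, abs(tau[3L]))
  bc <- if (degenerate) {
    if (tau[2L] >= 0) Inf else -Inf
  } else {
    tau[2L] / denom
  }
  structure(
    list(
      tau1 = tau[1L], tau2 = tau[2L], tau3 = tau[3L],
      bc_star = bc, degenerate = degenerate, n = net$n
    ),
    class = "tau_summary"
  )
}

#' @export
print.tau_summary <- function(x, ...) {
  cat(sprintf(
    "<tau_summary: N = %d, tau = (%.6g, %.6g, %.6g), (b/c)* = %.6g%s>\n",
    x$n, x$tau1, x$tau2, x$tau3, x$bc_star,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Critical ratio of a network
#'
#' Convenience wrapper: ensemble + coalescence times + summaries in one
#' call, returning just the `tau_summary`.
#'
#' @inheritParams tau_summary
#' @return a `tau_summary`.
#' @export
bc_star <- function(net, ...) tau_summary(net, ...)

#' Closed-form summaries for regular networks
#'
#' For a connected regular network of degree k the coalescence
#' summaries have closed forms
#' \eqn{\tau_1 = N - 1}, \eqn{\tau_2 = N - 2},
#' \eqn{\tau_3 = N + N/k - 3}, hence
#' \eqn{(b/c)^* = (N - 2) / (N/k - 2)}, which tends to k as
#' \eqn{N \to \infty}.  Serves as an independent oracle for the exact
#' solver on regular fixtures.
#'
#' @param n number of nodes.
#' @param k degree.
#' @return a `tau_summary`.
#' @examples
#' regular_reference(6, 2) # cycle C6: (b/c)* = 4
#' @export
regular_reference <- function(n, k) {
  if (k <= 0) stop("degree must be positive")
  tau1 <- n - 1
  tau2 <- n - 2
  tau3 <- n + n / k - 3
  denom <- tau3 - tau1
  degenerate <- abs(denom) < 1e-12
  structure(
    list(
      tau1 = tau1, tau2 = tau2, tau3 = tau3,
      bc_star = if (degenerate) Inf else tau2 / denom,
      degenerate = degenerate, n = as.integer(n)
    ),
    class = "tau_summary"
  )
}

#' Donation-game parameters
#'
#' The donation game: a cooperating donor pays cost `c` to hand benefit
#' `b > c` to the recipient; `eta` is the selection strength scaling
#' the payoff's contribution to the reproductive rate
#' \eqn{R_i = 1 + \eta f_i}.
#'
#' @param b benefit (`b > c`).
#' @param c cost (`c > 0`).
#' @param eta selection strength (`eta >= 0`).
#' @return list of class `game_params`.
#' @export
game_params <- function(b, c, eta) {
  if (!(b > c && c > 0)) stop("require b > c > 0")
  if (eta < 0) stop("eta must be nonnegative")
  structure(list(b = b, c = c, eta = eta), class = "game_params")
}

#' Weak-selection fixation probability, first order
#'
#' The first-order expansion of the fixation probability of cooperation
#' under uniform single-cooperator initialization:
#' \deqn{\rho_C = 1/N + \frac{\eta}{2N}\left[-c\,\tau_2 +
#'   b(\tau_3 - \tau_1)\right] + O(\eta^2).}
#'
#' @param tau a [tau_summary()].
#' @param game a [game_params()].
#' @param n number of nodes (must match `tau$n`).
#' @return numeric scalar: the first-order fixation probability.
#' @export
fixation_linear <- function(tau, game, n = tau$n) {
  if (n != tau$n) stop("n does not match the tau summary")
  1 / n + game$eta / (2 * n) *
    (-game$c * tau$tau2 + game$b * (tau$tau3 - tau$tau1))
}
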
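#' Payoffs and reproductive rates of a configuration
#'
#' For a binary strategy vector `x` (1 = cooperator, 0 = defector) the
#' neighbor-averaged donation-game payoff of node i is
#' \eqn{f_i = -c x_i + b \sum_j p_{ij} x_j} and the reproductive rate
#' is \eqn{R_i = 1 + \eta f_i}.  Payoffs are bounded in
#' \eqn{[-c, b]}, so all rates are positive whenever
#' \eqn{\eta < 1/c}; a nonpositive rate signals too strong a selection
#' strength and errors.
#'
#' @param x binary vector of length N.
#' @param net a `weighted_network`.
#' @param game a [game_params()].
#' @param ens optionally, a precomputed [random_walk_ensemble()].
#' @return list with numeric vectors `f` and `R`.
#' @export
reproductive_rates <- function(x, net, game, ens = NULL) {
  P <- if (is.null(ens)) net$weights / rowSums(net$weights) else ens$P
  f <- -game$c * x + game$b * as.numeric(P %*% x)
  R <- 1 + game$eta * f
  if (any(R <= 0)) {
    stop("nonpositive reproductive rate: decrease the selection strength eta")
  }
  list(f = f, R = R)
}

#' Death-birth selection probabilities at one node
#'
#' Given that node `i` dies, each node `j` is selected for reproduction
#' with probability proportional to \eqn{w_{ij} R_j(x)}.  At
#' \eqn{\eta = 0} this reduces to \eqn{w_{ij}/s_i} (the voter model).
#'
#' @inheritParams reproductive_rates
#' @param i the dying node.
#' @return numeric vector of length N summing to 1.
#' @export
db_selection_probs <- function(x, net, game, i, ens = NULL) {
  R <- reproductive_rates(x, net, game, ens)$R
  w <- net$weights[i, ]
  q <- w * R
  q / sum(q)
}

#' One round of the death-birth process
#'
#' A node `i` is selected to die uniformly at random; one of its
#' neighbors `j` is selected for reproduction with probability
#' proportional to \eqn{w_{ij} R_j(x)}; `i` adopts the type of `j`.
#' Uses the current RNG state.
#'
#' @inheritParams reproductive_rates
#' @return the updated binary vector.
#' @export
db_step <- function(x, net, game, ens = NULL) {
  i <- sample.int(length(x), 1L)
  q <- db_selection_probs(x, net, game, i, ens)
  j <- sample.int(length(x), 1L, prob = q)
  x[i] <- x[j]
  x
}

#' Monte-Carlo fixation probability of cooperation
#'
#' Each replicate starts from a uniformly chosen single-cooperator
#' configuration and runs the death-birth process to absorption
#' (all-cooperator or all-defector; absorption occurs in finite time
#' with probability 1).  Returns the fraction of replicates fixing at
#' all-cooperator with its binomial standard error.
#'
#' @inheritParams reproductive_rates
#' @param replicates number of independent replicates.
#' @param seed integer seed; replicate r runs under `seed + r` so runs
#'   are reproducible and independent of replicate order.
#' @param max_steps safety cap per replicate (practically unreachable
#'   at validation sizes).
#' @return object of class `fixation_estimate`: list with `rho_C`,
#'   `stderr`, `replicates`.
#' @export
simulate_fixation <- function(net, game, replicates = 1000L, seed = NULL,
                              max_steps = 1e9) {
  n <- net$n
  ens <- random_walk_ensemble(net)
  fixed <- logical(replicates)
  for (r in seq_len(replicates)) {
    fixed[r] <- with_seed_if(
      if (is.null(seed)) NULL else seed + r,
      run_one_replicate(net, game, ens, max_steps)
    )
  }
  rho <- mean(fixed)
  structure(
    list(
      rho_C = rho,
      stderr = sqrt(rho * (1 - rho) / replicates),
      replicates = replicates
    ),
    class = "fixation_estimate"
  )
}

run_one_replicate <- function(net, game, ens, max_steps) {
  n <- net$n
  x <- integer(n)
  x[sample.int(n, 1L)] <- 1L
  W <- net$weights
  b <- game$b
  cc <- game$c
  eta <- game$eta
  P <- ens$P
  steps <- 0
  total <- sum(x)
  while (total > 0L && total < n) {
    if (eta == 0) {
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L, prob = W[i, ])
    } else {
      R <- 1 + eta * (-cc * x + b * as.numeric(P %*% x))
      if (any(R <= 0)) {
        stop("nonpositive reproductive rate: decrease the selection strength eta")
      }
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L, prob = W[i, ] * R)
    }
    total <- total - x[i] + x[j]
    x[i] <- x[j]
    steps <- steps + 1
    if (steps > max_steps) stop("absorption not reached within max_steps")
  }
  total == n
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf(
    "<fixation_estimate: rho_C = %.5f +/- %.5f (%s replicates)>\n",
    x$rho_C, x$stderr, format(x$replicates)
  ))
  invisible(x)
}

#' Exact fixation probability by full state-space enumeration
#'
#' Builds the absorbing Markov chain of the death-birth process over
#' all \eqn{2^N} strategy configurations and solves the absorption
#' probabilities into the all-cooperator state exactly.  This is the
#' brute-force oracle used to validate the weak-selection expansion
#' and the critical-ratio threshold; its cost grows as \eqn{2^N}, so
#' it is capped at small N.
#'
#' @inheritParams reproductive_rates
#' @param cap maximum admitted N (default 12).
#' @return object of class `fixation_estimate` with `rho_C` (uniform
#'   single-cooperator initialization), `stderr = 0`, `replicates = 0`,
#'   and `per_start` (fixation probability from each single-cooperator
#'   state).
#' @export
exact_fixation_small <- function(net, game, cap = 12L) {
  n <- net$n
  if (n > cap) stop(sprintf("N = %d exceeds the 2^N oracle cap (%d)", n, cap))
  ns <- 2L^n
  W <- net$weights
  P <- W / rowSums(W)
  bits <- function(s) as.integer(intToBits(s)[seq_len(n)])
  trip_i <- vector("list", ns)
  trip_j <- vector("list", ns)
  trip_x <- vector("list", ns)
  pow2 <- 2^(seq_len(n) - 1)
  for (s in 0:(ns - 1L)) {
    x <- bits(s)
    tot <- sum(x)
    if (tot == 0L || tot == n) next
    f <- -game$c * x + game$b * as.numeric(P %*% x)
    R <- 1 + game$eta * f
    if (any(R <= 0)) {
      stop("nonpositive reproductive rate: decrease the selection strength eta")
    }
    targets <- integer(0)
    probs <- numeric(0)
    for (i in seq_len(n)) {
      q <- W[i, ] * R
      q <- q / sum(q)
      # probability that node i flips (adopts the opposite type)
      p_new1 <- sum(q[x == 1L])
      s_new <- if (x[i] == 1L) s - pow2[i] else s + pow2[i]
      p_flip <- if (x[i] == 1L) 1 - p_new1 else p_new1
      targets <- c(targets, s_new, s)
      probs <- c(probs, p_flip / n, (1 - p_flip) / n)
    }
    trip_i[[s + 1L]] <- rep.int(s + 1L, length(targets))
    trip_j[[s + 1L]] <- targets + 1L
    trip_x[[s + 1L]] <- probs
  }
  Pmat <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(ns, ns)
  )
  transient <- which(Matrix::rowSums(Pmat) > 0)
  Q <- Pmat[transient, transient, drop = FALSE]
  r <- as.numeric(Pmat[transient, ns, drop = FALSE]) # into all-cooperator
  h <- as.numeric(Matrix::solve(Matrix::Diagonal(length(transient)) - Q, r))
  habs <- numeric(ns)
  habs[ns] <- 1
  habs[transient] <- h
  single <- vapply(seq_len(n), function(i) habs[pow2[i] + 1L], numeric(1))
  structure(
    list(
      rho_C = mean(single), stderr = 0, replicates = 0L,
      per_start = single
    ),
    class = "fixation_estimate"
  )
}
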
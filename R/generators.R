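#' Synthetic network generators
#'
#' Generators for the four synthetic network families used throughout
#' the package.  All generators return connected, unweighted (weight-1)
#' networks without self-loops, are bit-reproducible under `seed`, and
#' record their configuration in the `"generator"` attribute (model,
#' parameters, seed, number of rejection retries).
#'
#' `generate_er()` draws exactly `m_edges` distinct edges uniformly at
#' random among the \eqn{N(N-1)/2} node pairs and rejection-samples
#' whole graphs until connected.
#'
#' @param n number of nodes.
#' @param m_edges number of edges (`n - 1 <= m_edges <= n(n-1)/2`).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param max_retries rejection-sampling budget for connectivity.
#' @return a `weighted_network`.
#' @examples
#' net <- generate_er(20, 40, seed = 1)
#' n_edges(net)
#' @export
generate_er <- function(n, m_edges, seed = NULL, max_retries = 10000L) {
  n <- as.integer(n)
  m_edges <- as.integer(m_edges)
  n_pairs <- n * (n - 1L) / 2
  if (m_edges > n_pairs) {
    stop(sprintf("m_edges = %d exceeds the %d available node pairs", m_edges, n_pairs))
  }
  if (m_edges < n - 1L) {
    stop(sprintf("m_edges = %d cannot yield a connected graph on %d nodes", m_edges, n))
  }
  pairs <- which(upper.tri(matrix(0, n, n)))
  with_seed_if(seed, {
    retries <- 0L
    repeat {
      chosen <- sample(pairs, m_edges)
      W <- matrix(0, n, n)
      W[chosen] <- 1
      W <- W + t(W)
      if (is_connected_matrix(W)) break
      retries <- retries + 1L
      if (retries > max_retries) stop("connectivity not reached within retry budget")
    }
    net <- weighted_network(W)
    attr(net, "generator") <- list(
      model = "er", n = n, m_edges = m_edges, seed = seed, retries = retries
    )
    net
  })
}

#' @rdname generate_er
#'
#' @details
#' `generate_ba()` grows a Barabasi-Albert network from a star on
#' `m + 1` nodes: each new node attaches to `m` distinct existing nodes
#' drawn sequentially without replacement with probability proportional
#' to current degree (degree weights renormalized after each draw), so
#' no multi-edges arise and the edge count is deterministic:
#' \eqn{m + m(n - m - 1)} edges, i.e. \eqn{3 + 3(n-4)} for `m = 3`.
#'
#' @param m edges brought in by each new node.
#' @export
generate_ba <- function(n, m = 3L, seed = NULL) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  n_seed <- m + 1L
  if (n < n_seed) stop(sprintf("n must be at least the %d-node star seed", n_seed))
  with_seed_if(seed, {
    W <- matrix(0, n, n)
    W[1L, 2:n_seed] <- 1
    W[2:n_seed, 1L] <- 1
    deg <- numeric(n)
    deg[1L] <- m
    deg[2:n_seed] <- 1
    if (n > n_seed) {
      for (v in (n_seed + 1L):n) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing])
        W[v, targets] <- 1
        W[targets, v] <- 1
        deg[targets] <- deg[targets] + 1
        deg[v] <- m
      }
    }
    net <- weighted_network(W)
    attr(net, "generator") <- list(
      model = "ba", n = n, m = m, seed = seed, retries = 0L
    )
    net
  })
}

#' @rdname generate_er
#'
#' @details
#' `generate_planted_partition()` splits the `n` nodes into `l` equal
#' groups; within-group pairs are adjacent with probability `p_in`,
#' between-group pairs with probability `p_out`, and whole graphs are
#' rejection-sampled until connected.  The theoretical mean degree is
#' \eqn{p_{in}(N/l - 1) + p_{out} N (l-1)/l}.
#'
#' @param l number of groups (must divide `n`).
#' @param p_in,p_out within- and between-group edge probabilities.
#' @export
generate_planted_partition <- function(n, l, p_in, p_out, seed = NULL,
                                       max_retries = 10000L) {
  n <- as.integer(n)
  l <- as.integer(l)
  if (n %% l != 0L) stop("l must divide n")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("require 0 <= p_out <= p_in <= 1")
  }
  group <- rep(seq_len(l), each = n %/% l)
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p_pair <- ifelse(group[up[, 1L]] == group[up[, 2L]], p_in, p_out)
  with_seed_if(seed, {
    retries <- 0L
    repeat {
      present <- stats::runif(nrow(up)) < p_pair
      W <- matrix(0, n, n)
      W[up[present, , drop = FALSE]] <- 1
      W <- W + t(W)
      if (is_connected_matrix(W)) break
      retries <- retries + 1L
      if (retries > max_retries) stop("connectivity not reached within retry budget")
    }
    net <- weighted_network(W)
    attr(net, "generator") <- list(
      model = "planted_partition", n = n, l = l, p_in = p_in, p_out = p_out,
      seed = seed, retries = retries, group = group
    )
    net
  })
}

#' @rdname generate_er
#'
#' @details
#' `generate_lfr()` builds an LFR-style benchmark graph with community
#' structure: node degrees follow a truncated power law with exponent
#' `gamma` (lower cutoff tuned so the expected degree matches `k_mean`,
#' upper cutoff `k_max`), community sizes follow a power law with
#' exponent `kappa`, and a fraction `mu` of each node's stubs connect
#' outside its community.  Edges are realized by stub matching within
#' and between communities with duplicate edges dropped, and whole
#' graphs are rejection-sampled until connected.  This is this package's
#' own implementation of the LFR construction; realized mean degree and
#' mixing fraction are therefore approximate (matching only in
#' expectation), which is the same caveat that applies to any LFR
#' realization.
#'
#' @param gamma degree power-law exponent.
#' @param kappa community-size power-law exponent.
#' @param k_mean target mean degree.
#' @param k_max maximum degree.
#' @param mu mixing parameter: expected fraction of inter-community
#'   stubs per node, in (0, 1).
#' @param size_range community-size bounds used by the size sampler.
#' @export
generate_lfr <- function(n, gamma = 3, kappa = 2, k_mean = 6, k_max = 100,
                         mu = 0.1, seed = NULL, size_range = NULL,
                         max_retries = 2000L) {
  n <- as.integer(n)
  if (is.null(size_range)) size_range <- c(max(8L, ceiling(k_mean)), max(16L, n %/% 2L))
  k_max <- min(k_max, n - 1L)
  k_min <- powerlaw_lower_cutoff(gamma, k_mean, k_max)
  with_seed_if(seed, {
    retries <- 0L
    repeat {
      out <- tryCatch(lfr_realization(n, gamma, kappa, k_min, k_max, mu, size_range),
        error = function(e) NULL
      )
      if (!is.null(out) && is_connected_matrix(out$W)) break
      retries <- retries + 1L
      if (retries > max_retries) stop("LFR generator did not converge within retry budget")
    }
    net <- weighted_network(out$W)
    attr(net, "generator") <- list(
      model = "lfr", n = n, gamma = gamma, kappa = kappa, k_mean = k_mean,
      k_max = k_max, mu = mu, seed = seed, retries = retries,
      community = out$community
    )
    net
  })
}

# lower cutoff a such that a continuous power law on [a, k_max] with
# exponent gamma has mean k_mean
powerlaw_lower_cutoff <- function(gamma, k_mean, k_max) {
  mean_of <- function(a) {
    # E[X], X ~ x^-gamma on [a, k_max]
    if (abs(gamma - 2) < 1e-12) {
      (log(k_max) - log(a)) / (1 / a - 1 / k_max)
    } else {
      g1 <- 2 - gamma
      g0 <- 1 - gamma
      ((k_max^g1 - a^g1) / g1) / ((k_max^g0 - a^g0) / g0)
    }
  }
  stats::uniroot(function(a) mean_of(a) - k_mean,
    lower = 1.01, upper = k_max - 1e-6, tol = 1e-10
  )$root
}

# draw from a continuous truncated power law by inverse CDF
rpowerlaw <- function(n, gamma, a, b) {
  u <- stats::runif(n)
  g <- 1 - gamma
  (a^g + u * (b^g - a^g))^(1 / g)
}

lfr_realization <- function(n, gamma, kappa, k_min, k_max, mu, size_range) {
  deg <- pmax(2L, pmin(as.integer(round(rpowerlaw(n, gamma, k_min, k_max))), k_max))
  # community sizes: power law with exponent kappa, summing to n
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- as.integer(round(rpowerlaw(1L, kappa, size_range[1L], size_range[2L])))
    sizes <- c(sizes, s)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  if (sizes[length(sizes)] < 2L) {
    sizes <- sizes[-length(sizes)]
    sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  }
  n_comm <- length(sizes)
  k_int <- as.integer(round((1 - mu) * deg))
  # assign nodes to communities so internal degree fits (k_int <= size - 1)
  community <- integer(n)
  capacity <- sizes
  ord <- order(k_int, decreasing = TRUE)
  for (v in ord) {
    ok <- which(capacity > 0L & sizes - 1L >= k_int[v])
    if (length(ok) == 0L) stop("no community can host node")
    pick <- ok[sample.int(length(ok), 1L, prob = capacity[ok])]
    community[v] <- pick
    capacity[pick] <- capacity[pick] - 1L
  }
  W <- matrix(0, n, n)
  add_matching <- function(W, stubs_nodes, allowed) {
    # configuration-model matching; self/multi/forbidden pairs dropped
    if (length(stubs_nodes) < 2L) return(W)
    if (length(stubs_nodes) %% 2L == 1L) stubs_nodes <- stubs_nodes[-length(stubs_nodes)]
    stubs_nodes <- sample(stubs_nodes)
    half <- length(stubs_nodes) / 2L
    a <- stubs_nodes[seq_len(half)]
    b <- stubs_nodes[half + seq_len(half)]
    keep <- a != b & allowed[cbind(a, b)] & W[cbind(a, b)] == 0
    W[cbind(a[keep], b[keep])] <- 1
    W[cbind(b[keep], a[keep])] <- 1
    W
  }
  same <- outer(community, community, "==")
  # matching collisions leave degree deficits; a few top-up rounds on the
  # deficient stubs bring realized degrees close to their targets
  fill <- function(W, target, allowed, rounds = 8L) {
    for (r in seq_len(rounds)) {
      deficit <- pmax(target - rowSums(W), 0)
      if (sum(deficit) < 2) break
      W <- add_matching(W, rep(seq_len(n), deficit), allowed)
    }
    # greedy repair: pair up remaining deficient nodes directly
    blocked <- logical(n)
    repeat {
      deficit <- pmax(target - rowSums(W), 0)
      open <- which(deficit > 0)
      active <- open[!blocked[open]]
      if (length(active) == 0L || length(open) < 2L) break
      v <- active[which.max(deficit[active])]
      cand <- open[open != v & allowed[v, open] & W[v, open] == 0]
      if (length(cand) == 0L) {
        blocked[v] <- TRUE
        next
      }
      u <- if (length(cand) == 1L) cand else sample(cand, 1L)
      W[v, u] <- 1
      W[u, v] <- 1
    }
    W
  }
  W <- fill(W, k_int, same)
  W_ext <- fill(matrix(0, n, n), deg - k_int, !same)
  W <- pmax(W, W_ext)
  diag(W) <- 0
  list(W = W, community = community)
}

#' Dispatch a generator from a configuration list
#'
#' Convenience wrapper mapping a model name plus parameter list to the
#' matching generator or fixture, mirroring the command-line interface.
#'
#' @param model one of `"er"`, `"ba"`, `"planted_partition"`, `"lfr"`,
#'   `"cycle"`, `"complete"`, `"star"`, `"path"`.
#' @param params named list of generator parameters.
#' @param seed integer RNG seed.
#' @return a `weighted_network`.
#' @export
generate_network <- function(model, params = list(), seed = NULL) {
  switch(model,
    er = do.call(generate_er, c(params, list(seed = seed))),
    ba = do.call(generate_ba, c(params, list(seed = seed))),
    planted_partition = do.call(generate_planted_partition, c(params, list(seed = seed))),
    lfr = do.call(generate_lfr, c(params, list(seed = seed))),
    cycle = ,
    complete = ,
    star = ,
    path = do.call(fixture, c(list(kind = model), params)),
    stop(sprintf("unknown model '%s'", model))
  )
}

# evaluate expr under a fixed seed without clobbering the caller's RNG;
# seed = NULL uses (and advances) the current RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
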
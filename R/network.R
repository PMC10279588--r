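#' Weighted undirected networks
#'
#' A `weighted_network` wraps a symmetric, nonnegative \eqn{N \times N}
#' weight matrix \eqn{W = (w_{ij})} together with external node labels.
#' The graph defined by the positive off-diagonal entries must be
#' connected; this is the object every computation in the package
#' consumes.  Self-loops (\eqn{w_{ii} > 0}) are representable but none of
#' the bundled generators produce them.
#'
#' @param weights numeric \eqn{N \times N} matrix of edge weights,
#'   symmetric with all entries \eqn{\ge 0}.
#' @param labels optional vector of external node labels (defaults to
#'   `0:(N-1)`).
#' @param check validate symmetry, nonnegativity and connectivity.
#'
#' @return An object of class `weighted_network` with fields `n`
#'   (node count), `weights` (the matrix) and `labels`.
#' @examples
#' net <- weighted_network(matrix(c(0, 1, 1, 0), 2))
#' net$n
#' @export
weighted_network <- function(weights, labels = NULL, check = TRUE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (is.null(labels)) labels <- seq_len(n) - 1L
  if (length(labels) != n) stop("labels length must equal node count")
  net <- structure(
    list(n = n, weights = unname(weights), labels = labels),
    class = "weighted_network"
  )
  if (check) validate_network(net)
  net
}

#' @rdname weighted_network
#' @param net a `weighted_network`.
#' @export
validate_network <- function(net) {
  W <- net$weights
  if (any(!is.finite(W))) stop("weights must be finite")
  if (any(W < 0)) stop("negative edge weight")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE)))
    stop("weight matrix must be symmetric")
  if (!is_connected_matrix(W)) stop("network must be connected")
  invisible(net)
}

# connectivity of the graph induced by positive off-diagonal weights
is_connected_matrix <- function(W) {
  n <- nrow(W)
  if (n == 1L) return(TRUE)
  A <- W > 0
  diag(A) <- FALSE
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf(
    "<weighted_network: %d nodes, %d edges, total weight %g>\n",
    x$n, n_edges(x), sum(x$weights) / 2
  ))
  invisible(x)
}

#' Edge utilities
#'
#' `n_edges()` counts unordered node pairs with positive weight
#' (self-loops excluded); `edge_pairs()` lists them as a two-column
#' matrix of 1-based internal indices with `i < j`; `mean_degree()` is
#' the mean number of neighbors per node.
#'
#' @param net a `weighted_network`.
#' @return `n_edges()`: integer; `edge_pairs()`: integer matrix with
#'   columns `i`, `j` (and a `weight` column if `weights = TRUE`);
#'   `mean_degree()`: numeric scalar.
#' @export
n_edges <- function(net) {
  W <- net$weights
  sum(W[upper.tri(W)] > 0)
}

#' @rdname n_edges
#' @param weights also return the weight of each edge.
#' @export
edge_pairs <- function(net, weights = FALSE) {
  W <- net$weights
  up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  out <- cbind(i = as.integer(up[, 1L]), j = as.integer(up[, 2L]))
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  if (weights) out <- cbind(out, weight = W[out])
  out
}

#' @rdname n_edges
#' @export
mean_degree <- function(net) {
  A <- net$weights > 0
  diag(A) <- FALSE
  mean(rowSums(A))
}

#' Non-adjacent node pairs
#'
#' Unordered node pairs with zero weight (candidate edge additions).
#'
#' @param net a `weighted_network`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`).
#' @export
nonedge_pairs <- function(net) {
  W <- net$weights
  up <- which(upper.tri(W) & W == 0, arr.ind = TRUE)
  out <- cbind(i = as.integer(up[, 1L]), j = as.integer(up[, 2L]))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Convert to an igraph object
#'
#' Used internally for connectivity and bridge detection; exported for
#' convenience.
#'
#' @param net a `weighted_network`.
#' @return an `igraph` graph with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights,
    mode = "undirected",
    weighted = TRUE, diag = FALSE
  )
}

#' Bridges of a network
#'
#' Edges whose removal disconnects the graph.  Such edges are excluded
#' from full-removal experiments because (b/c)* is undefined on a
#' disconnected network.
#'
#' @param net a `weighted_network`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`);
#'   zero rows if there is no bridge.
#' @export
bridge_pairs <- function(net) {
  g <- as_igraph(net)
  br <- igraph::bridges(g)
  if (length(br) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  ends <- igraph::ends(g, br, names = FALSE)
  out <- cbind(
    i = as.integer(pmin(ends[, 1L], ends[, 2L])),
    j = as.integer(pmax(ends[, 1L], ends[, 2L]))
  )
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Canonical unweighted fixtures
#'
#' Deterministic small graphs used as analytic test beds: for a
#' k-regular graph the coalescence summaries have closed forms (see
#' [regular_reference()]), so cycles and complete graphs exercise the
#' exact machinery end to end.
#'
#' @param kind one of `"cycle"`, `"complete"`, `"star"`, `"path"`.
#' @param n number of nodes (`n >= 3` for a cycle, else `n >= 2`).
#' @return a `weighted_network` with unit edge weights.
#' @examples
#' fixture("cycle", 6)
#' @export
fixture <- function(kind = c("cycle", "complete", "star", "path"), n) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  min_n <- if (kind == "cycle") 3L else 2L
  if (n < min_n) stop(sprintf("'%s' needs at least %d nodes", kind, min_n))
  W <- matrix(0, n, n)
  switch(kind,
    cycle = {
      idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
      W[idx] <- 1
      W[idx[, 2:1, drop = FALSE]] <- 1
    },
    complete = {
      W[] <- 1
      diag(W) <- 0
    },
    star = {
      W[1L, -1L] <- 1
      W[-1L, 1L] <- 1
    },
    path = {
      idx <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
      W[idx] <- 1
      W[idx[, 2:1, drop = FALSE]] <- 1
    }
  )
  weighted_network(W)
}

#' Circulant graph fixture
#'
#' Nodes on a ring, each connected to the `offsets` nearest neighbors on
#' both sides; with `offsets = 1:2` this is a 4-regular graph, another
#' closed-form regular test case.
#'
#' @param n number of nodes.
#' @param offsets integer vector of circulant offsets.
#' @return a `weighted_network`.
#' @export
fixture_circulant <- function(n, offsets = 1:2) {
  n <- as.integer(n)
  if (n <= 2L * max(offsets)) stop("n too small for the requested offsets")
  W <- matrix(0, n, n)
  for (d in offsets) {
    idx <- cbind(seq_len(n), (seq_len(n) - 1L + d) %% n + 1L)
    W[idx] <- 1
    W[idx[, 2:1, drop = FALSE]] <- 1
  }
  weighted_network(W)
}

#' Apply a single-edge weight change
#'
#' Returns a copy of the network with \eqn{w_{i_0 j_0}} changed by
#' `epsilon` (both symmetric entries).  The result is validated, so a
#' change that disconnects the graph or makes a weight negative errors.
#'
#' @param net a `weighted_network`.
#' @param i0,j0 1-based internal node indices, `i0 != j0`.
#' @param epsilon signed weight change.
#' @param check validate the perturbed network.
#' @return a `weighted_network`.
#' @export
perturb_edge_weight <- function(net, i0, j0, epsilon, check = TRUE) {
  if (i0 == j0) stop("self-loop perturbation is not supported")
  W <- net$weights
  W[i0, j0] <- W[i0, j0] + epsilon
  W[j0, i0] <- W[j0, i0] + epsilon
  if (abs(W[i0, j0]) < 1e-14) {
    W[i0, j0] <- 0
    W[j0, i0] <- 0
  }
  weighted_network(W, labels = net$labels, check = check)
}
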
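#' Read and write plain-text edge lists
#'
#' The interchange format is one edge per line, whitespace-separated:
#' `u v weight`, with the weight optional (default 1).  Blank lines and
#' `#` comments are ignored.  Node labels may be arbitrary integers;
#' internal indices are assigned in sorted label order.  Duplicate
#' `(u, v)` / `(v, u)` lines are accepted only when their weights agree.
#'
#' @param path file path.
#' @return `read_edgelist()`: a connected `weighted_network`;
#'   `write_edgelist()`: `path`, invisibly.
#' @examples
#' f <- tempfile()
#' write_edgelist(fixture("path", 3), f)
#' net <- read_edgelist(f)
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no edges in file")
  tok <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(tok)
  if (any(nf < 2L | nf > 3L)) {
    stop(sprintf("malformed line: '%s'", lines[which(nf < 2L | nf > 3L)[1L]]))
  }
  u <- vapply(tok, `[[`, "", 1L)
  v <- vapply(tok, `[[`, "", 2L)
  w <- vapply(tok, function(x) if (length(x) == 3L) x[[3L]] else "1", "")
  w <- suppressWarnings(as.numeric(w))
  labels <- sort(unique(suppressWarnings(as.numeric(c(u, v)))))
  if (any(is.na(labels)) || any(is.na(w))) stop("malformed edge list entry")
  ui <- match(as.numeric(u), labels)
  vi <- match(as.numeric(v), labels)
  if (any(w < 0)) stop("negative edge weight in edge list")
  if (any(ui == vi)) stop("self-loop in edge list")
  n <- length(labels)
  key <- paste(pmin(ui, vi), pmax(ui, vi))
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(w[key == k])) > 1L) {
      stop(sprintf("conflicting duplicate weights for edge pair %s", k))
    }
  }
  W <- matrix(0, n, n)
  W[cbind(ui, vi)] <- w
  W[cbind(vi, ui)] <- w
  if (!is_connected_matrix(W)) stop("edge list describes a disconnected network")
  weighted_network(W, labels = if (all(labels == round(labels))) as.integer(labels) else labels)
}

#' @rdname read_edgelist
#' @param net a `weighted_network`.
#' @param header write a comment line with node and edge counts.
#' @export
write_edgelist <- function(net, path, header = TRUE) {
  ep <- edge_pairs(net, weights = TRUE)
  lines <- sprintf(
    "%s %s %.12g",
    format(net$labels[ep[, "i"]], scientific = FALSE, trim = TRUE),
    format(net$labels[ep[, "j"]], scientific = FALSE, trim = TRUE),
    ep[, "weight"]
  )
  if (header) {
    lines <- c(sprintf("# %d nodes, %d edges", net$n, nrow(ep)), lines)
  }
  writeLines(lines, path)
  invisible(path)
}
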
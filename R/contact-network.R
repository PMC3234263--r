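# C-alpha residue contact network and centrality measures.

#' Build the C-alpha contact graph of a protein chain
#'
#' Vertices are the chain's amino acids (one per residue with a C-alpha
#' atom); an undirected edge connects two residues whose C-alpha distance is
#' at most `cutoff` (default 8 Angstrom, inclusive).
#'
#' @param ca_coords numeric matrix (n x 3) of C-alpha coordinates with
#'   residue keys as row names, e.g. from a structure's protein chain; a
#'   `dbp_structure` plus `chain_id` may be given instead.
#' @param chain_id chain identifier when `ca_coords` is a structure.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return Object of class `contact_graph`: vertex keys, an edge table
#'   (i, j, distance) and the adjacency list.
#' @export
contact_graph <- function(ca_coords, chain_id = NULL, cutoff = 8.0) {
  if (inherits(ca_coords, "dbp_structure")) {
    stopifnot(!is.null(chain_id))
    res <- select_chain(ca_coords, chain_id)
    res <- res[res$molecule_class == "protein", ]
    no_ca <- res$key[!res$has_ca]
    if (length(no_ca))
      warning("residues without C-alpha excluded from contact graph: ",
              paste(no_ca, collapse = ", "))
    ca_coords <- .ca_coords(ca_coords, chain_id)
  }
  stopifnot(is.matrix(ca_coords), ncol(ca_coords) == 3,
            !is.null(rownames(ca_coords)))
  n <- nrow(ca_coords)
  if (n < 3)
    warning("contact graph has fewer than 3 vertices; ",
            "centrality normalization is degenerate")
  d <- as.matrix(stats::dist(ca_coords))
  adjm <- d <= cutoff & upper.tri(d)
  idx <- which(adjm, arr.ind = TRUE)
  edges <- data.frame(i = rownames(ca_coords)[idx[, 1]],
                      j = rownames(ca_coords)[idx[, 2]],
                      distance = d[adjm],
                      stringsAsFactors = FALSE)
  adj <- lapply(seq_len(n), function(v)
    sort(unique(c(idx[idx[, 1] == v, 2], idx[idx[, 2] == v, 1]))))
  out <- list(keys = rownames(ca_coords), n = n, edges = edges, adj = adj)
  class(out) <- "contact_graph"
  out
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("Contact graph:", x$n, "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each vertex,
#' computed by Brandes' accumulation over unweighted breadth-first shortest
#' paths and normalized by the number of unordered vertex pairs excluding
#' the vertex, (n-1)(n-2)/2, so that scores lie in \[0, 1\]. Pairs in
#' different connected components contribute nothing.
#'
#' @param graph a `contact_graph`.
#' @return Named numeric vector of betweenness scores; all zero (with a
#'   warning) when the graph has fewer than 3 vertices.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- graph$n
  bc <- stats::setNames(numeric(n), graph$keys)
  if (n < 3) {
    warning("betweenness undefined for fewer than 3 vertices; returning 0")
    return(bc)
  }
  adj <- graph$adj
  for (s in seq_len(n)) {
    # single-source shortest paths (BFS)
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair {s,t} was accumulated from both endpoints
  bc <- bc / 2
  bc / ((n - 1) * (n - 2) / 2)
}

#' Degree and closeness centrality
#'
#' Degree centrality is the vertex degree divided by n-1. Closeness uses
#' the reachable-component convention: the number of reachable vertices
#' divided by the sum of shortest-path lengths to them (0 for isolated
#' vertices); on a connected graph this is the usual (n-1)/sum(d).
#'
#' @param graph a `contact_graph`.
#' @return Data frame with columns `key`, `degree`, `closeness`.
#' @export
degree_closeness_centrality <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- graph$n
  deg <- vapply(graph$adj, length, integer(1))
  clo <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in graph$adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    reach <- which(dist > 0)
    clo[s] <- if (length(reach)) length(reach) / sum(dist[reach]) else 0
  }
  data.frame(key = graph$keys,
             degree = if (n > 1) deg / (n - 1) else 0,
             closeness = clo,
             stringsAsFactors = FALSE)
}

#' Export the contact-graph edge list
#'
#' @param graph a `contact_graph`.
#' @param path TSV output file (res_i, res_j, distance).
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
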
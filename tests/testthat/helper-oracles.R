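# Independent oracles and small fixture builders shared across tests.

# Hand-rolled PDB ATOM line (fixed columns), independent of the package's
# writer.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, chain, resno, x, y, z, element)
}

# Three-residue poly-ALA chain with backbone + CB, as PDB text.
poly_ala_pdb <- function(n = 3, chain = "A", spacing = 3.8) {
  lines <- character(0); serial <- 0
  for (i in seq_len(n)) {
    x0 <- (i - 1) * spacing
    at <- list(c("N", x0 - 1.2, 0.5, 0), c("CA", x0, 0, 0),
               c("C", x0 + 1.2, 0.5, 0), c("O", x0 + 1.2, 1.7, 0),
               c("CB", x0, -1.5, 0.4))
    for (a in at) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, a[[1]], "ALA", chain, i,
                                      as.numeric(a[[2]]), as.numeric(a[[3]]),
                                      as.numeric(a[[4]])))
    }
  }
  c(lines, "END")
}

# Brute-force Shrake-Rupley at arbitrary density, written as plain loops:
# the reference for the vectorized implementation.
brute_force_asa <- function(xyz, radii, probe = 1.4, n_points = 9600) {
  i_seq <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i_seq / n_points)
  theta <- pi * (1 + sqrt(5)) * i_seq
  unit <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    re_i <- radii[i] + probe
    exposed <- 0L
    for (p in seq_len(n_points)) {
      pt <- xyz[i, ] + re_i * unit[p, ]
      ok <- TRUE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - xyz[j, ])^2) < (radii[j] + probe)^2) { ok <- FALSE; break }
      }
      if (ok) exposed <- exposed + 1L
    }
    out[i] <- 4 * pi * re_i^2 * exposed / n_points
  }
  out
}

# Build a contact_graph object directly from a symmetric adjacency matrix
# (vertex keys v1..vn); used to test centrality on arbitrary graphs.
graph_from_adjacency <- function(adjm) {
  n <- nrow(adjm)
  keys <- paste0("v", seq_len(n))
  idx <- which(adjm & upper.tri(adjm), arr.ind = TRUE)
  edges <- data.frame(i = keys[idx[, 1]], j = keys[idx[, 2]],
                      distance = rep(NA_real_, nrow(idx)),
                      stringsAsFactors = FALSE)
  adj <- lapply(seq_len(n), function(v) which(adjm[v, ] != 0))
  structure(list(keys = keys, n = n, edges = edges, adj = adj),
            class = "contact_graph")
}

# Exhaustive betweenness oracle: per-source BFS shortest-path counts, then
# direct evaluation of the pair condition sigma_sv * sigma_vt / sigma_st;
# nothing shared with the package's Brandes dependency accumulation.
bfs_sigma <- function(adjm, s) {
  n <- nrow(adjm)
  dist <- rep(-1L, n); dist[s] <- 0L
  sigma <- numeric(n); sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adjm[v, ] != 0)) {
      if (dist[w] < 0) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
      if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

oracle_betweenness <- function(adjm) {
  n <- nrow(adjm)
  dists <- lapply(seq_len(n), function(s) bfs_sigma(adjm, s))
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
      if (s == v || t == v) next
      ds <- dists[[s]]; dt <- dists[[t]]
      if (ds$dist[t] < 0) next
      if (ds$dist[v] >= 0 && ds$dist[v] + dt$dist[v] == ds$dist[t])
        bc[v] <- bc[v] + ds$sigma[v] * dt$sigma[v] / ds$sigma[t]
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

random_adjacency <- function(n, p = 0.3) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  m <- m | t(m)
  storage.mode(m) <- "integer"
  m
}

# Tiny prepared synthetic dataset reused by several test files.
small_dataset <- function(n_chains = 6, seed = 42, ...) {
  synthetic_dataset(fixture_spec(n_chains = n_chains, seed = seed, ...))
}
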
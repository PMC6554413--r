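# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph where the package itself leans on igraph):
# everything is recomputed from the raw adjacency matrix.

adj_of <- function(g) igraph::as_adjacency_matrix(g, sparse = FALSE)

# Sorted neighbour-degree sequences straight from the adjacency matrix.
oracle_seqs <- function(g) {
  A <- adj_of(g)
  k <- rowSums(A)
  lapply(seq_len(nrow(A)), function(i) sort(k[A[i, ] == 1]))
}

oracle_Vn <- function(g, sample_var = FALSE) {
  A <- adj_of(g); k <- rowSums(A)
  seqs <- oracle_seqs(g)
  vf <- function(x) if (sample_var) var(x) else mean((x - mean(x))^2)
  tot <- 0
  for (i in seq_along(seqs)) if (k[i] > 1) tot <- tot + vf(seqs[[i]])
  tot / sum(k > 0)
}

# S by O(n^2) pairwise comparison over non-isolated nodes.
oracle_S <- function(g) {
  k <- rowSums(adj_of(g))
  seqs <- oracle_seqs(g)[k > 0]
  n <- length(seqs)
  matched <- 0
  for (i in seq_len(n)) {
    hit <- FALSE
    for (j in seq_len(n)) if (j != i && identical(seqs[[i]], seqs[[j]])) {
      hit <- TRUE; break
    }
    if (hit) matched <- matched + 1
  }
  matched / n
}

# omega_p by the literal summed formula, from scratch.
oracle_omega <- function(g, p) {
  k <- rowSums(adj_of(g))
  seqs <- oracle_seqs(g)[k == p]
  q <- length(seqs)
  keys <- sapply(seqs, paste, collapse = "|")
  cvec <- as.integer(table(keys))
  length(cvec) * sum(q - cvec) / (q^2 * (q - 1))
}

# R and R_Omega by the naive triple sum (over D2, positions, members),
# without the per-node factor (the literal defining formula).
oracle_R <- function(g, weighted = FALSE) {
  k <- rowSums(adj_of(g))
  seqs <- oracle_seqs(g)
  degs <- sort(unique(k[k > 0]))
  D2 <- degs[sapply(degs, function(p) sum(k == p) >= 2)]
  if (length(D2) == 0) return(NA_real_)
  acc <- 0
  for (p in D2) {
    sp <- seqs[k == p]
    q <- length(sp)
    inner <- 0
    for (j in seq_len(p)) {
      ej <- sapply(sp, `[[`, j)
      mu <- mean(ej)
      for (i in seq_len(q)) inner <- inner + (sp[[i]][j] - mu)^2
    }
    term <- inner / (p * (q - 1))
    if (weighted) term <- term * oracle_omega(g, p)
    acc <- acc + term
  }
  acc / length(D2)
}

# Transitivity by explicit enumeration of connected triples.
oracle_transitivity <- function(g) {
  A <- adj_of(g); n <- nrow(A)
  closed <- 0; triples <- 0
  for (j in seq_len(n)) {
    nb <- which(A[j, ] == 1)
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      triples <- triples + 1
      if (A[nb[a], nb[b]] == 1) closed <- closed + 1
    }
  }
  if (triples == 0) return(0)
  closed / triples
}

# Mean finite shortest-path length by hand-rolled BFS.
oracle_cpl <- function(g) {
  A <- adj_of(g); n <- nrow(A)
  tot <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(A[u, ] == 1)) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  if (cnt == 0) return(NA_real_)
  tot / cnt  # both orientations counted; ratio equals pair mean
}

# Newman modularity of a fixed partition, from the definition.
oracle_modularity <- function(g, memb) {
  A <- adj_of(g)
  m2 <- sum(A)
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# Spearman by rank-then-Pearson.
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_le <- mean(Wall <= W + 1e-9)
  p_ge <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Small seeded Erdos-Renyi graph guaranteed at least one edge.
random_test_graph <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(20:200, 1)
  if (is.null(p)) p <- min(1, 6 / n)
  g <- igraph::sample_gnp(n, p)
  if (igraph::ecount(g) == 0) g <- igraph::add_edges(g, c(1, 2))
  g
}
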
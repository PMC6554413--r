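#' Global transitivity (clustering coefficient)
#'
#' The ratio of closed to open triples: 3 times the number of triangles
#' divided by the number of connected triples (paths of length two). Returns
#' 0 when the graph has no triples at all.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @return A fraction in [0, 1].
#' @export
transitivity_index <- function(g) {
  out <- igraph::transitivity(g, type = "global")
  if (is.nan(out)) 0 else out
}

#' Degree variance
#'
#' The variance of the degree sequence, a classical graph-heterogeneity
#' index; zero exactly for regular graphs. The optional normalised variant
#' divides by the degree variance of an Erdős–Rényi graph with the same size
#' and density, \eqn{\bar k (1 - \bar k / (n-1))}, so that values above 1
#' mean "more heterogeneous than a density-matched random graph". (The
#' normalisation in the literature varies; this package's choice is
#' documented here and excluded from any published-value comparison.)
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param variance \code{"population"} or \code{"sample"}.
#' @param normalised Apply the ER normalisation described above.
#' @return A nonnegative number.
#' @export
degree_variance <- function(g, variance = c("population", "sample"),
                            normalised = FALSE) {
  vf <- variance_fun(variance)
  k <- igraph::degree(g)
  if (length(k) < 2L) stop("degree variance needs at least 2 nodes")
  v <- vf(k)
  if (!normalised) return(v)
  n <- length(k); kbar <- mean(k)
  er <- kbar * (1 - kbar / (n - 1))
  if (er == 0) NA_real_ else v / er
}

#' Characteristic path length
#'
#' The mean shortest-path length over all node pairs between which a path
#' exists. Disconnected graphs are handled by averaging only over the
#' existing (finite) paths; \code{NA} if no pair is connected.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @return A positive number, or \code{NA}.
#' @export
characteristic_path_length <- function(g) {
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each edge (each
#' edge counted in both orientations). Positive when similar-degree nodes
#' tend to be connected. Undefined (NA) when the endpoint degrees are
#' constant, e.g. on regular graphs.
#'
#' @param g A simple undirected \pkg{igraph} graph with at least 2 edges.
#' @return A number in [−1, 1], or \code{NA}.
#' @export
assortativity_index <- function(g) {
  if (igraph::ecount(g) < 2L) stop("assortativity needs at least 2 edges")
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::degree(g)
  x <- c(k[el[, 1]], k[el[, 2]])
  y <- c(k[el[, 2]], k[el[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Newman modularity of a detected community partition
#'
#' Runs a community-detection method and reports the modularity \eqn{Q} of
#' the partition it finds, together with the partition itself (so that any
#' comparison can be reproduced on the same communities). The default
#' method, greedy agglomerative modularity maximisation, is deterministic.
#'
#' @param g A simple undirected \pkg{igraph} graph with at least 1 edge.
#' @param method \code{"greedy"} (deterministic, default) or
#'   \code{"louvain"}.
#' @param seed RNG seed used for stochastic methods.
#' @return A list with \code{Q} (number) and \code{membership} (integer
#'   vector named by node label).
#' @export
modularity_index <- function(g, method = c("greedy", "louvain"), seed = 1L) {
  method <- match.arg(method)
  if (igraph::ecount(g) < 1L) stop("modularity needs at least 1 edge")
  cm <- with_seed(seed, switch(method,
    greedy = igraph::cluster_fast_greedy(g),
    louvain = igraph::cluster_louvain(g)))
  memb <- igraph::membership(cm)
  list(Q = igraph::modularity(g, memb), membership = setNames(
    as.integer(memb), vertex_labels(g)))
}

#' Newman modularity of a given partition
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param membership Integer community labels, one per node.
#' @return The modularity \eqn{Q} of that partition.
#' @export
modularity_of <- function(g, membership) {
  igraph::modularity(g, membership)
}

#' All classical global network indices
#'
#' Transitivity \eqn{C}, degree variance \eqn{v}, characteristic path length
#' \eqn{L}, degree assortativity \eqn{r} and modularity \eqn{Q} of a greedy
#' community partition — the comparison set against which the neighbourhood
#' degree sequence indices are evaluated.
#'
#' @inheritParams modularity_index
#' @param variance Variance convention for \eqn{v}.
#' @param normalised_v Normalise \eqn{v}; see [degree_variance()].
#' @return An object of class \code{"classical_report"}: list with \code{C},
#'   \code{v}, \code{L}, \code{r}, \code{Q}, \code{membership},
#'   \code{flags}.
#' @export
classical_report <- function(g, variance = c("population", "sample"),
                             normalised_v = FALSE,
                             method = c("greedy", "louvain"), seed = 1L) {
  flags <- character(0)
  C <- if (igraph::vcount(g) >= 3L) transitivity_index(g) else NA_real_
  v <- degree_variance(g, variance = variance, normalised = normalised_v)
  L <- characteristic_path_length(g)
  if (is.na(L)) flags <- c(flags, "L undefined: no connected pairs")
  r <- if (igraph::ecount(g) >= 2L) assortativity_index(g) else NA_real_
  if (is.na(r)) flags <- c(flags, "r undefined: constant endpoint degrees")
  if (igraph::ecount(g) >= 1L) {
    mod <- modularity_index(g, method = method, seed = seed)
    Q <- mod$Q; memb <- mod$membership
  } else {
    Q <- NA_real_; memb <- NULL
    flags <- c(flags, "Q undefined: no edges")
  }
  structure(list(C = C, v = v, L = L, r = r, Q = Q, membership = memb,
                 flags = flags),
            class = "classical_report")
}

#' @export
print.classical_report <- function(x, digits = 4, ...) {
  print(round(c(C = x$C, v = x$v, L = x$L, r = x$r, Q = x$Q), digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
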
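# Edge key for the rewiring hash (endpoints as integer indices, low first).
edge_key <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)

#' Degree-preserving configuration-model rewiring
#'
#' Randomises a graph by repeated double-edge swaps: two edges (a,b), (c,d)
#' are replaced by (a,d), (c,b) whenever the replacement keeps the graph
#' simple. The degree of every node — hence the whole degree multiset — is
#' preserved exactly, which is what makes the result a configuration-model
#' null for the input. \code{swaps_per_edge * m} swap attempts are made.
#'
#' Graphs that admit no valid swap (e.g. a star, where every swap would
#' create a loop or parallel edge) are returned unchanged with a warning.
#'
#' @param g A simple undirected \pkg{igraph} graph with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (default 10, a common
#'   mixing heuristic for double-edge-swap randomisation).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A simple undirected \pkg{igraph} graph with the same vertices and
#'   degree multiset.
#' @export
configuration_rewire <- function(g, swaps_per_edge = 10L, seed = NULL) {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  m <- igraph::ecount(g)
  if (m < 2L) stop("rewiring needs at least 2 edges")
  labs <- vertex_labels(g)
  E <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(E) <- "integer"
  successes <- 0L
  E <- with_seed(seed, {
    present <- new.env(hash = TRUE, parent = emptyenv())
    for (e in seq_len(m)) assign(edge_key(E[e, 1], E[e, 2]), TRUE, present)
    attempts <- as.integer(swaps_per_edge) * m
    for (it in seq_len(attempts)) {
      e1 <- sample.int(m, 1L); e2 <- sample.int(m, 1L)
      if (e1 == e2) next
      a <- E[e1, 1]; b <- E[e1, 2]; c <- E[e2, 1]; d <- E[e2, 2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed new edges: (a, d) and (c, b)
      if (a == d || c == b) next
      k1 <- edge_key(a, d); k2 <- edge_key(c, b)
      if (k1 == k2) next
      if (exists(k1, present, inherits = FALSE) ||
          exists(k2, present, inherits = FALSE)) next
      rm(list = c(edge_key(a, b), edge_key(c, d)), envir = present)
      assign(k1, TRUE, present); assign(k2, TRUE, present)
      E[e1, ] <- c(a, d); E[e2, ] <- c(c, b)
      successes <- successes + 1L
    }
    E
  })
  if (successes == 0L) {
    warning("no valid degree-preserving swap found; returning input unchanged")
    return(g)
  }
  out <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  if (!is.null(igraph::vertex_attr(g, "name")))
    out <- igraph::set_vertex_attr(out, "name", value = labs)
  igraph::add_edges(out, t(E))
}

#' Configuration-model null ensemble of index values
#'
#' Generates \code{n_realisations} independent degree-preserving rewirings
#' of a graph and computes the full set of neighbourhood degree sequence
#' indices (and optionally the classical indices) on each, together with
#' per-index means and standard deviations. Comparing an observed network
#' against these summaries asks: is this feature explained by the degree
#' distribution alone?
#'
#' Each realisation uses its own RNG stream derived up front from
#' \code{seed}, so results do not depend on evaluation order.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param n_realisations Number of rewired realisations (>= 1). Published
#'   analyses have used 10 (per-network tables) and 50 (corpus tests).
#' @param seed Integer seed for the ensemble.
#' @param swaps_per_edge Passed to [configuration_rewire()].
#' @param classical Also compute the classical indices per realisation.
#' @param variance,normalisation Passed to [compute_all()].
#' @return An object of class \code{"null_ensemble"}: list with
#'   \code{values} (realisations x indices matrix), \code{summary} (data
#'   frame: index, mean, sd, n_defined), \code{seed},
#'   \code{n_realisations}, \code{swaps_per_edge}.
#' @export
null_ensemble <- function(g, n_realisations = 10L, seed = 1L,
                          swaps_per_edge = 10L, classical = FALSE,
                          variance = c("population", "sample"),
                          normalisation = c("per_node", "equation")) {
  stopifnot(n_realisations >= 1L)
  variance <- match.arg(variance)
  normalisation <- match.arg(normalisation)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_realisations))
  rows <- lapply(seq_len(n_realisations), function(r) {
    gr <- configuration_rewire(g, swaps_per_edge = swaps_per_edge,
                               seed = seeds[r])
    v <- as_index_vector(compute_all(gr, variance = variance,
                                     normalisation = normalisation))
    if (classical) v <- c(v, as_index_vector(classical_report(gr)))
    v
  })
  values <- do.call(rbind, rows)
  summary <- data.frame(
    index = colnames(values),
    mean = apply(values, 2, mean, na.rm = TRUE),
    sd = apply(values, 2, stats::sd, na.rm = TRUE),
    n_defined = apply(values, 2, function(x) sum(!is.na(x))),
    row.names = NULL)
  structure(list(values = values, summary = summary, seed = seed,
                 n_realisations = n_realisations,
                 swaps_per_edge = swaps_per_edge),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Configuration-model ensemble:", x$n_realisations,
      "realisations (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' Random-graph generators
#'
#' The four standard graph models used as comparison families:
#' Erdős–Rényi \code{G(n, p)}, random geometric graphs on the unit square,
#' Watts–Strogatz small-world rings, and Barabási–Albert preferential
#' attachment (the growth variant that starts from \code{m} isolated nodes,
#' so the result has exactly \code{m * (n - m)} edges). All are
#' deterministic given \code{seed}; self-loops/multi-edges never occur.
#'
#' @param model One of \code{"erdos_renyi"}, \code{"random_geometric"},
#'   \code{"watts_strogatz"}, \code{"barabasi_albert"}.
#' @param n Number of nodes.
#' @param p Edge probability (Erdős–Rényi) .
#' @param radius Connection radius (random geometric).
#' @param k Half-neighbourhood width of the ring lattice (Watts–Strogatz:
#'   each node starts connected to its \code{k} nearest neighbours on each
#'   side).
#' @param beta Rewiring probability (Watts–Strogatz); \code{beta = 0} is the
#'   regular ring lattice.
#' @param m Edges added per new node (Barabási–Albert).
#' @param seed Integer seed.
#' @return A simple undirected \pkg{igraph} graph.
#' @export
generate_graph <- function(model = c("erdos_renyi", "random_geometric",
                                     "watts_strogatz", "barabasi_albert"),
                           n, p = NULL, radius = NULL, k = NULL, beta = NULL,
                           m = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  g <- with_seed(seed, switch(model,
    erdos_renyi = {
      if (is.null(p) || p < 0 || p > 1) stop("erdos_renyi needs p in [0, 1]")
      igraph::sample_gnp(n, p)
    },
    random_geometric = {
      if (is.null(radius) || radius <= 0)
        stop("random_geometric needs a positive radius")
      igraph::sample_grg(n, radius)
    },
    watts_strogatz = {
      if (is.null(k) || k < 1) stop("watts_strogatz needs k >= 1")
      if (is.null(beta) || beta < 0 || beta > 1)
        stop("watts_strogatz needs beta in [0, 1]")
      igraph::simplify(igraph::sample_smallworld(1, n, k, beta))
    },
    barabasi_albert = {
      if (is.null(m) || m < 1 || m >= n)
        stop("barabasi_albert needs 1 <= m < n")
      ba_graph(as.integer(n), as.integer(m))
    }))
  as_undirected_simple(g)
}

# Preferential attachment starting from m isolated seed nodes; each new node
# attaches to m distinct existing nodes chosen proportionally to degree
# (uniformly over the seed nodes at the first step). Gives m(n - m) edges.
ba_graph <- function(n, m) {
  targets <- seq_len(m)
  repeated <- integer(0)
  edges <- vector("list", n - m)
  for (v in (m + 1L):n) {
    edges[[v - m]] <- rbind(rep(v, m), targets)
    repeated <- c(repeated, targets, rep(v, m))
    if (v < n) {
      t <- integer(0)
      while (length(t) < m) {
        x <- repeated[sample.int(length(repeated), 1L)]
        if (!x %in% t) t <- c(t, x)
      }
      targets <- t
    }
  }
  igraph::make_graph(as.integer(do.call(cbind, edges)), n = n,
                     directed = FALSE)
}

#' Canonical fixture graphs
#'
#' Named small graphs used throughout the tests and examples: stars, paths,
#' cycles, complete graphs; the 34-node/78-edge Zachary karate club network
#' (shipped as a plain-text edge list); the "symmetric double" \code{H ⊔ H}
#' of any graph \code{H} (two disjoint copies — a rotationally symmetric
#' arrangement, so its neighbourhood similarity is always 1); and planted
#' multi-ordered graphs whose degree-2 class falls into exactly
#' \code{length(multiplicities)} distinct sequence groups with the given
#' multiplicities.
#'
#' The planted construction: for each group \eqn{j}, two hubs of equal,
#' group-specific degree \eqn{d_j} are joined by \code{multiplicities[j]}
#' parallel length-2 paths; the middle node of each path has degree 2 and
#' sequence \eqn{\{d_j, d_j\}}. Hub degrees are padded with leaves to
#' distinct values \eqn{d_j \ge 3}, so the degree-2 class contains exactly
#' the middle nodes.
#'
#' @param name One of \code{"star"}, \code{"path"}, \code{"cycle"},
#'   \code{"complete"}, \code{"karate"}, \code{"symmetric_double"},
#'   \code{"planted_multiorder"}.
#' @param n Node count (star/path/cycle/complete).
#' @param base A graph \code{H} (symmetric_double).
#' @param multiplicities Integer vector \eqn{c_1, \ldots, c_g} of group
#'   sizes (planted_multiorder); their sum is the size \eqn{q} of the
#'   degree-2 class.
#' @return A simple undirected \pkg{igraph} graph.
#' @export
fixture_graph <- function(name = c("star", "path", "cycle", "complete",
                                   "karate", "symmetric_double",
                                   "planted_multiorder"),
                          n = NULL, base = NULL, multiplicities = NULL) {
  name <- match.arg(name)
  need_n <- name %in% c("star", "path", "cycle", "complete")
  if (need_n && (is.null(n) || n < 2)) stop("fixture '", name, "' needs n >= 2")
  switch(name,
    star = igraph::make_star(n, mode = "undirected", center = 1),
    path = igraph::make_ring(n, circular = FALSE),
    cycle = igraph::make_ring(n, circular = TRUE),
    complete = igraph::make_full_graph(n),
    karate = {
      path <- system.file("extdata", "karate.tsv", package = "ndseq")
      read_graph_file(path, format = "edgelist")
    },
    symmetric_double = {
      if (is.null(base) || !igraph::is_igraph(base))
        stop("symmetric_double needs base = an igraph graph")
      h <- base
      if (!is.null(igraph::vertex_attr(h, "name")))
        h <- igraph::delete_vertex_attr(h, "name")
      igraph::disjoint_union(h, h)
    },
    planted_multiorder = {
      cvec <- as.integer(multiplicities)
      if (is.null(cvec) || length(cvec) < 1 || any(cvec < 1))
        stop("planted_multiorder needs positive integer multiplicities")
      if (sum(cvec) < 2) stop("the planted degree-2 class needs q >= 2")
      gnum <- length(cvec)
      d <- max(cvec) + seq_len(gnum) + 1L   # distinct hub degrees >= 3
      el <- list(); nid <- 0L
      for (j in seq_len(gnum)) {
        u <- nid + 1L; w <- nid + 2L; nid <- nid + 2L
        for (mm in seq_len(cvec[j])) {      # parallel 2-paths u - mid - w
          mid <- nid + 1L; nid <- nid + 1L
          el[[length(el) + 1L]] <- rbind(c(u, mid), c(mid, w))
        }
        pad <- d[j] - cvec[j]               # leaf padding to degree d_j
        for (hub in c(u, w)) for (t in seq_len(pad)) {
          leaf <- nid + 1L; nid <- nid + 1L
          el[[length(el) + 1L]] <- rbind(c(hub, leaf))
        }
      }
      igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
    })
}
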
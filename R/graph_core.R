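#' @importFrom stats var cor pnorm median setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# Internal: vertex labels as character; igraph names if present, else 1..n.
vertex_labels <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else as.character(nm)
}

# Internal: evaluate with a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Coerce input to a simple undirected graph
#'
#' Validates and cleans a graph for neighbourhood degree sequence analysis:
#' directions are dropped (an undirected edge exists wherever an arc existed
#' in either direction), self-loops are removed and parallel edges collapsed.
#' The counts of dropped elements are recorded in the graph attribute
#' \code{"provenance"}.
#'
#' @param g An \pkg{igraph} graph, possibly directed and/or with multi-edges.
#' @return A simple undirected \pkg{igraph} graph.
#' @export
as_undirected_simple <- function(g) {
  stopifnot(igraph::is_igraph(g))
  prov <- igraph::graph_attr(g, "provenance")
  if (is.null(prov)) prov <- list()
  prov$directed_input <- igraph::is_directed(g)
  if (igraph::is_directed(g))
    g <- igraph::as_undirected(g, mode = "each")  # duplicates counted below
  n_loops <- sum(igraph::which_loop(g))
  m_before <- igraph::ecount(g) - n_loops
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  prov$self_loops_dropped <- as.integer(n_loops)
  prov$duplicate_edges_collapsed <- as.integer(m_before - igraph::ecount(g))
  prov$isolates <- sum(igraph::degree(g) == 0)
  g <- igraph::set_graph_attr(g, "provenance", prov)
  g
}

#' Retrieve the provenance record attached to a graph
#'
#' @param g An \pkg{igraph} graph produced by the package's readers or
#'   preprocessing functions.
#' @return A list (possibly empty) with entries such as
#'   \code{directed_input}, \code{weights_dropped},
#'   \code{self_loops_dropped}, \code{duplicate_edges_collapsed},
#'   \code{isolates}.
#' @export
graph_provenance <- function(g) {
  p <- igraph::graph_attr(g, "provenance")
  if (is.null(p)) list() else p
}

#' Neighbourhood degree sequence of one node
#'
#' The neighbourhood degree sequence \eqn{s_i} of node \eqn{i} is the
#' nondecreasing list of the degrees of \eqn{i}'s neighbours; its length is
#' the degree \eqn{k_i} of \eqn{i}.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param i A node label (character) or index.
#' @return An integer vector, sorted nondecreasing; length 0 for an isolated
#'   node.
#' @examples
#' g <- igraph::make_ring(5)
#' neighbourhood_degree_sequence(g, 1)  # c(2, 2)
#' @export
neighbourhood_degree_sequence <- function(g, i) {
  labs <- vertex_labels(g)
  if (is.character(i)) {
    idx <- match(i, labs)
    if (is.na(idx)) stop("unknown node label: ", i)
  } else {
    idx <- as.integer(i)
    if (is.na(idx) || idx < 1 || idx > igraph::vcount(g))
      stop("unknown node index: ", i)
  }
  deg <- igraph::degree(g)
  sort(as.integer(deg[as.integer(igraph::neighbors(g, idx))]))
}

#' Neighbourhood degree sequences of all nodes
#'
#' Computes \eqn{s_i} for every node. Isolated (degree-0) nodes get an empty
#' sequence and are flagged; they are excluded from all downstream degree
#' classes and index denominators, with a warning, since pairwise sequence
#' comparison is degenerate for empty sequences.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @return An object of class \code{"ndseq_table"}: a list with elements
#'   \code{labels}, \code{degree} (named integer), \code{seqs} (named list of
#'   sorted integer vectors), \code{n_active} (non-isolated node count),
#'   \code{n_total}, \code{m}, \code{isolates} (labels of degree-0 nodes).
#' @export
sequence_table <- function(g) {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  labs <- vertex_labels(g)
  deg <- as.integer(igraph::degree(g))
  names(deg) <- labs
  adj <- igraph::as_adj_list(g)
  seqs <- lapply(adj, function(nb) sort(deg[as.integer(nb)], method = "radix"))
  seqs <- lapply(seqs, unname)
  names(seqs) <- labs
  iso <- labs[deg == 0L]
  if (length(iso) > 0)
    warning(length(iso), " isolated node(s) excluded from degree classes ",
            "and index denominators")
  structure(list(labels = labs, degree = deg, seqs = seqs,
                 n_active = sum(deg > 0L), n_total = length(labs),
                 m = igraph::ecount(g), isolates = iso),
            class = "ndseq_table")
}

#' @export
print.ndseq_table <- function(x, ...) {
  cat("Neighbourhood degree sequence table:", x$n_total, "nodes,",
      x$m, "edges", if (length(x$isolates))
        paste0("(", length(x$isolates), " isolated)") else "", "\n")
  invisible(x)
}

# Internal: canonical string key of a sequence (for hashing/grouping).
seq_key <- function(s) paste(s, collapse = ",")

#' Degree-class bookkeeping for neighbourhood degree sequences
#'
#' Groups the neighbourhood degree sequences by their length \eqn{p} (the
#' node degree) and records, per degree class: the member nodes
#' \eqn{\mathcal{V}_p}, the number of sequences \eqn{q_p}, the set of unique
#' sequences \eqn{\sigma_p}, the multiplicity \eqn{c_{pj}} of each unique
#' sequence, and the positional means \eqn{\mu^p(j)}. \eqn{D_2} is the set of
#' degrees held by at least two nodes; it is the domain of all per-degree
#' indices. Degree-0 nodes are excluded.
#'
#' @param tab An \code{"ndseq_table"} from [sequence_table()], or an
#'   \pkg{igraph} graph (converted internally).
#' @return An object of class \code{"degree_class_index"}: a list with
#'   \code{classes} (named by degree; each holds \code{p}, \code{members},
#'   \code{q}, \code{sigma} (list of unique sequences), \code{c}
#'   (multiplicities, summing to \code{q}), \code{mu}, and the q-by-p
#'   sequence matrix \code{S}) and \code{D2} (integer vector).
#' @export
degree_class_index <- function(tab) {
  if (igraph::is_igraph(tab)) tab <- sequence_table(tab)
  stopifnot(inherits(tab, "ndseq_table"))
  active <- tab$degree > 0L
  deg <- tab$degree[active]
  seqs <- tab$seqs[active]
  if (length(deg) == 0L) stop("graph has no edges: no degree classes exist")
  classes <- list()
  for (p in sort(unique(deg))) {
    members <- names(deg)[deg == p]
    s_p <- seqs[members]
    S <- do.call(rbind, s_p)            # q x p matrix of sequences
    keys <- vapply(s_p, seq_key, character(1))
    cnt <- table(keys)
    uk <- names(cnt)
    sigma <- lapply(uk, function(k) s_p[[match(k, keys)]])
    classes[[as.character(p)]] <- list(
      p = as.integer(p), members = members, q = length(members),
      sigma = sigma, c = as.integer(cnt), mu = colMeans(S), S = S)
  }
  q_all <- vapply(classes, function(cl) cl$q, integer(1))
  structure(list(classes = classes,
                 D2 = as.integer(names(classes))[q_all >= 2L],
                 n_active = tab$n_active),
            class = "degree_class_index")
}

#' @export
print.degree_class_index <- function(x, ...) {
  cat("Degree classes:", length(x$classes), "| D2 =",
      paste(x$D2, collapse = ", "), "\n")
  invisible(x)
}

#' Symmetrise a directed graph
#'
#' An undirected edge \{i, j\} is created wherever an arc i->j or j->i
#' exists; weights are discarded and self-loops dropped. Used to preprocess
#' directed inputs (e.g. directed connectomes taken as undirected).
#'
#' @param d A directed \pkg{igraph} graph, or a 2- or 3-column data frame of
#'   arcs (third column = weight, ignored).
#' @return A simple undirected \pkg{igraph} graph with provenance recorded.
#' @export
symmetrize <- function(d) {
  if (is.data.frame(d)) {
    d <- igraph::graph_from_data_frame(d[, 1:2, drop = FALSE], directed = TRUE)
  }
  stopifnot(igraph::is_igraph(d))
  g <- as_undirected_simple(d)
  drop_weights(g)
}

# Internal: strip any weight attribute (weights never enter the indices).
drop_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Binarise a weighted graph at a target density
#'
#' Keeps the \eqn{\lceil d \cdot n(n-1)/2 \rceil} largest-weight node pairs
#' as (unweighted) edges. Ties at the cut weight are all kept, so the
#' realised density can slightly exceed \code{d}; this rule is deterministic
#' and order-independent. Asymmetric weight matrices are symmetrised first by
#' taking the elementwise maximum of \eqn{w_{ij}} and \eqn{w_{ji}}.
#'
#' @param w A square numeric weight matrix (zero/NA = no relation), or a
#'   weighted \pkg{igraph} graph.
#' @param d Target density, a fraction in (0, 1].
#' @return A simple undirected \pkg{igraph} graph with provenance recording
#'   the requested density and tie handling.
#' @export
binarize_by_density <- function(w, d) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0 || d > 1)
    stop("density d must be a single number in (0, 1]")
  if (igraph::is_igraph(w)) {
    labs <- vertex_labels(w)
    w <- igraph::as_adjacency_matrix(w, attr = if ("weight" %in%
      igraph::edge_attr_names(w)) "weight" else NULL, sparse = FALSE)
    rownames(w) <- colnames(w) <- labs
  }
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  w[is.na(w)] <- 0
  sym <- isTRUE(all.equal(w, t(w), check.attributes = FALSE))
  if (!sym) w <- pmax(w, t(w))
  diag(w) <- 0
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  wt <- w[ut]
  keep_n <- ceiling(d * n * (n - 1) / 2)
  if (length(wt) > keep_n) {
    cut <- sort(wt, decreasing = TRUE)[keep_n]
    sel <- wt >= cut      # all ties at the cut kept
  } else sel <- rep(TRUE, length(wt))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (any(sel))
    g <- igraph::add_edges(g, rbind(ut[sel, 1], ut[sel, 2]))
  g <- igraph::set_graph_attr(g, "provenance", list(
    directed_input = FALSE, weights_dropped = TRUE,
    requested_density = d,
    realised_density = igraph::ecount(g) / (n * (n - 1) / 2),
    symmetrised = !sym, isolates = sum(igraph::degree(g) == 0)))
  g
}
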
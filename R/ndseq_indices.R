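# Variance helpers: "population" divides by length(x), "sample" by
# length(x) - 1 (stats::var). Which convention a published table used is
# rarely stated, so every index that involves a variance takes the
# convention as an argument and records it in its provenance.
variance_fun <- function(convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (convention == "population")
    function(x) mean((x - mean(x))^2)
  else
    function(x) stats::var(x)
}

resolve_table <- function(g) {
  if (inherits(g, "ndseq_table")) g else sequence_table(g)
}

#' Node heterogeneity of a graph
#'
#' The mean variance of the neighbourhood degree sequences,
#' \deqn{V_n(G) = \frac{1}{n}\sum_{i:\,k_i>1} \mathrm{var}(s_i),}
#' where the sum skips nodes of degree 0 or 1 (whose sequences have no
#' spread) but the divisor \eqn{n} counts all non-isolated nodes. Regular
#' graphs and star graphs both give 0: every neighbourhood is
#' degree-homogeneous even though the star's global degree distribution is
#' maximally spread.
#'
#' @param g A simple undirected \pkg{igraph} graph or an
#'   \code{"ndseq_table"}.
#' @param variance \code{"population"} (divide by sequence length, the
#'   default) or \code{"sample"} (divide by length − 1).
#' @param denominator \code{"all"} divides by the number of non-isolated
#'   nodes (the published convention); \code{"contributing"} averages only
#'   over nodes with degree > 1.
#' @return A nonnegative number.
#' @export
node_heterogeneity <- function(g, variance = c("population", "sample"),
                               denominator = c("all", "contributing")) {
  vf <- variance_fun(variance)
  denominator <- match.arg(denominator)
  tab <- resolve_table(g)
  contrib <- tab$seqs[tab$degree > 1L]
  denom <- if (denominator == "all") tab$n_active else length(contrib)
  if (denom == 0L) return(NA_real_)
  sum(vapply(contrib, vf, numeric(1))) / denom
}

#' Relative node heterogeneity
#'
#' Node heterogeneity divided by the global degree variance
#' \eqn{\mathrm{var}(k)} (same variance convention applied to both), i.e.
#' local versus global heterogeneity. Values below 1 mean neighbourhoods are
#' more degree-homogeneous than the graph as a whole. Undefined (NA) for
#' regular graphs, where \eqn{\mathrm{var}(k) = 0}.
#'
#' @inheritParams node_heterogeneity
#' @return A nonnegative number, or \code{NA} when the degree variance is 0.
#' @export
relative_node_heterogeneity <- function(g,
                                        variance = c("population", "sample"),
                                        denominator = c("all", "contributing")) {
  vf <- variance_fun(variance)
  tab <- resolve_table(g)
  k <- tab$degree[tab$degree > 0L]
  if (length(k) < 2L) return(NA_real_)
  vk <- vf(k)
  if (vk == 0) return(NA_real_)
  node_heterogeneity(tab, variance = variance, denominator = denominator) / vk
}

#' Neighbourhood similarity
#'
#' The fraction of (non-isolated) nodes whose neighbourhood degree sequence
#' is identical to that of at least one *other* node,
#' \deqn{S(G) = \frac{1}{n}\sum_i \big[\exists j \ne i : s_i = s_j\big].}
#' \eqn{S = 1} for every regular graph and, more generally, for any graph
#' that can be drawn with mirror or rotational symmetry whose axis pivots on
#' no node (each node then has a symmetric partner with the same sequence).
#'
#' The literal double-delta formula includes the self-match \eqn{j = i} and
#' is therefore identically 1; set \code{include_self = TRUE} to get that
#' variant for transparency.
#'
#' @inheritParams node_heterogeneity
#' @param include_self Count a node's match with itself (degenerate; default
#'   \code{FALSE}).
#' @param method \code{"hash"} groups sequences by a canonical key (O(n));
#'   \code{"pairwise"} compares all pairs (O(n^2)), kept as a cross-checking
#'   route.
#' @return A fraction in [0, 1].
#' @export
neighbourhood_similarity <- function(g, include_self = FALSE,
                                     method = c("hash", "pairwise")) {
  method <- match.arg(method)
  tab <- resolve_table(g)
  seqs <- tab$seqs[tab$degree > 0L]
  n <- length(seqs)
  if (n < 2L) stop("neighbourhood similarity needs at least 2 non-isolated nodes")
  if (include_self) return(1)
  if (method == "hash") {
    keys <- vapply(seqs, seq_key, character(1))
    cnt <- table(keys)
    mean(cnt[keys] >= 2L)
  } else {
    matched <- logical(n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (!matched[i] || !matched[j]) {
        if (identical(seqs[[i]], seqs[[j]])) matched[i] <- matched[j] <- TRUE
      }
    }
    mean(matched)
  }
}

#' Per-degree multi-orderedness coefficient
#'
#' For a degree class \eqn{p} with \eqn{q_p \ge 2} sequences of which
#' \eqn{|\sigma_p|} are distinct with multiplicities \eqn{c_{pj}},
#' \deqn{\omega_p = \frac{|\sigma_p| \sum_j (q_p - c_{pj})}{q_p^2 (q_p - 1)}
#'   = \frac{|\sigma_p|(|\sigma_p| - 1)}{q_p(q_p - 1)},}
#' which is 0 when all sequences in the class coincide and 1 when all
#' differ. The closed form follows from
#' \eqn{\sum_j (q_p - c_{pj}) = q_p(|\sigma_p| - 1)}; note it depends on the
#' multiplicities only through their count, so e.g. \eqn{c = (1,1,3)} and
#' \eqn{c = (1,2,2)} give equal \eqn{\omega_p}.
#'
#' @param dci A \code{"degree_class_index"} (or graph, converted).
#' @param p A degree in \code{D2} (held by at least two nodes).
#' @param method \code{"closed"} (default) or \code{"literal"} (the summed
#'   form, kept as a cross-checking route).
#' @return A number in [0, 1].
#' @export
omega_p <- function(dci, p, method = c("closed", "literal")) {
  method <- match.arg(method)
  if (!inherits(dci, "degree_class_index")) dci <- degree_class_index(dci)
  if (!p %in% dci$D2)
    stop("degree p = ", p, " is not in D2 (needs at least 2 nodes of that degree)")
  cl <- dci$classes[[as.character(p)]]
  q <- cl$q; ns <- length(cl$sigma)
  if (method == "closed") {
    ns * (ns - 1) / (q * (q - 1))
  } else {
    ns * sum(q - cl$c) / (q^2 * (q - 1))
  }
}

# Internal: omega_p for every p in D2, as a named vector.
omega_all <- function(dci) {
  setNames(vapply(dci$D2, function(p) omega_p(dci, p), numeric(1)),
           as.character(dci$D2))
}

#' Neighbourhood organisation coefficient
#'
#' \deqn{\Omega(G) = 1 - \frac{1}{|D_2|} \sum_{p \in D_2} \omega_p,}
#' where \eqn{D_2} is the set of degrees held by at least two nodes. High
#' values indicate that equal-degree nodes fall into few distinct
#' neighbourhood degree sequence groups (an ordered or multi-ordered graph);
#' \eqn{\Omega = 1} for regular graphs. Undefined (NA) when \eqn{D_2} is
#' empty.
#'
#' @param g A simple undirected \pkg{igraph} graph, an \code{"ndseq_table"},
#'   or a \code{"degree_class_index"}.
#' @return A number in [0, 1], or \code{NA}.
#' @export
neighbourhood_organisation <- function(g) {
  dci <- if (inherits(g, "degree_class_index")) g else degree_class_index(g)
  if (length(dci$D2) == 0L) return(NA_real_)
  1 - mean(omega_all(dci))
}

# Internal: per-degree positional-variance terms of hierarchical complexity:
# for p in D2, term_p = (1 / (p (q_p - 1))) * sum_j sum_i (S[i,j] - mu_j)^2.
hc_terms <- function(dci) {
  setNames(vapply(dci$D2, function(p) {
    cl <- dci$classes[[as.character(p)]]
    dev <- sweep(cl$S, 2, cl$mu)
    sum(dev^2) / (cl$p * (cl$q - 1))
  }, numeric(1)), as.character(dci$D2))
}

#' Hierarchical complexity
#'
#' The mean positional variance of equal-length neighbourhood degree
#' sequences: for each degree \eqn{p \in D_2}, the sequences of the
#' \eqn{q_p} nodes of degree \eqn{p} are compared entrywise and their
#' positional sum of squared deviations is scaled by
#' \eqn{1/(p(q_p - 1))}; the index averages these terms over \eqn{D_2}.
#' High values mean that nodes of equal degree occupy heterogeneous
#' neighbourhoods — a feature of complex (notably brain) networks that
#' ordered and simple random graphs lack. Zero for regular graphs.
#'
#' Two normalisations are in circulation: the published per-network tables
#' divide the average additionally by the node count \eqn{n}
#' (\code{normalisation = "per_node"}, the default, which reproduces those
#' tables), whereas the printed defining equation does not
#' (\code{"equation"}). The two differ exactly by the factor \eqn{n}.
#'
#' @inheritParams neighbourhood_organisation
#' @param normalisation \code{"per_node"} (divide by the number of
#'   non-isolated nodes; matches published tables) or \code{"equation"}
#'   (the literal defining formula).
#' @return A nonnegative number, or \code{NA} when \eqn{D_2} is empty.
#' @export
hierarchical_complexity <- function(g, normalisation = c("per_node", "equation")) {
  normalisation <- match.arg(normalisation)
  dci <- if (inherits(g, "degree_class_index")) g else degree_class_index(g)
  if (length(dci$D2) == 0L) return(NA_real_)
  r <- mean(hc_terms(dci))
  if (normalisation == "per_node") r / dci$n_active else r
}

#' Hierarchical complexity corrected for multi-ordered degrees
#'
#' As [hierarchical_complexity()], but each degree's positional-variance term
#' is multiplied by its multi-orderedness coefficient \eqn{\omega_p}, so that
#' degrees whose sequences fall into few repeated groups (small
#' \eqn{\omega_p}) are suppressed. Since \eqn{\omega_p \in [0,1]}, the
#' corrected index never exceeds the uncorrected one.
#'
#' @inheritParams hierarchical_complexity
#' @return A nonnegative number \eqn{\le R}, or \code{NA}.
#' @export
hierarchical_complexity_corrected <- function(g,
    normalisation = c("per_node", "equation")) {
  normalisation <- match.arg(normalisation)
  dci <- if (inherits(g, "degree_class_index")) g else degree_class_index(g)
  if (length(dci$D2) == 0L) return(NA_real_)
  r <- mean(omega_all(dci) * hc_terms(dci))
  if (normalisation == "per_node") r / dci$n_active else r
}

#' Height-2 Weisfeiler–Lehman subtree signature
#'
#' In an unlabeled graph, the rooted subtree of height 2 at node \eqn{i} is
#' fully described by the pair \eqn{(k_i, s_i)}: the degree gives the number
#' of children at height 1, and the neighbourhood degree sequence gives the
#' number of grandchildren under each child. The signature serialises this
#' pair canonically, so two nodes receive equal tokens exactly when their
#' (degree, sequence) pairs are equal. Equal tokens imply equal degrees: the
#' signature partition refines the degree partition.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param i A node label or index; if \code{NULL}, signatures for all nodes
#'   are returned as a named character vector.
#' @return A character token, or a named character vector when
#'   \code{i = NULL}.
#' @export
wl2_signature <- function(g, i = NULL) {
  tab <- resolve_table(g)
  tok <- function(lab) paste0(tab$degree[[lab]], "|",
                              seq_key(tab$seqs[[lab]]))
  if (is.null(i)) {
    out <- vapply(tab$labels, tok, character(1))
    names(out) <- tab$labels
    return(out)
  }
  lab <- if (is.character(i)) i else tab$labels[as.integer(i)]
  if (is.na(lab) || !lab %in% tab$labels) stop("unknown node: ", i)
  tok(lab)
}

#' Compute all neighbourhood degree sequence indices
#'
#' One pass over the graph producing neighbourhood similarity \eqn{S}, node
#' heterogeneity \eqn{V_n}, relative node heterogeneity \eqn{\hat V_n},
#' neighbourhood organisation \eqn{\Omega}, and hierarchical complexity
#' \eqn{R} with its multi-order correction \eqn{R_\Omega}, plus a per-degree
#' diagnostic table. Indices that are undefined for the input (regular
#' graphs, empty \eqn{D_2}) are returned as \code{NA} with an explanatory
#' flag — never silently zeroed.
#'
#' @param g A simple undirected \pkg{igraph} graph.
#' @param variance Variance convention for \eqn{V_n}, \eqn{\hat V_n}; see
#'   [node_heterogeneity()].
#' @param normalisation Normalisation for \eqn{R}, \eqn{R_\Omega}; see
#'   [hierarchical_complexity()].
#' @param include_self Self-matching variant of \eqn{S}; see
#'   [neighbourhood_similarity()].
#' @return An object of class \code{"ndseq_report"}: list with \code{S},
#'   \code{V_n}, \code{V_hat_n}, \code{Omega}, \code{R}, \code{R_Omega},
#'   \code{per_degree} (data frame: \code{p}, \code{q_p}, \code{n_unique},
#'   \code{omega_p}, \code{R_contrib}), \code{flags}, \code{provenance}.
#' @examples
#' compute_all(igraph::make_ring(5))
#' @export
compute_all <- function(g, variance = c("population", "sample"),
                        normalisation = c("per_node", "equation"),
                        include_self = FALSE) {
  variance <- match.arg(variance)
  normalisation <- match.arg(normalisation)
  tab <- sequence_table(g)
  dci <- degree_class_index(tab)
  flags <- character(0)

  S <- neighbourhood_similarity(tab, include_self = include_self)
  V_n <- node_heterogeneity(tab, variance = variance)
  V_hat <- relative_node_heterogeneity(tab, variance = variance)
  if (is.na(V_hat)) flags <- c(flags, "V_hat_n undefined: zero global degree variance")

  if (length(dci$D2) == 0L) {
    Omega <- R <- R_Om <- NA_real_
    flags <- c(flags, "Omega/R/R_Omega undefined: every degree class is a singleton")
    per_degree <- data.frame(p = integer(0), q_p = integer(0),
                             n_unique = integer(0), omega_p = numeric(0),
                             R_contrib = numeric(0))
  } else {
    om <- omega_all(dci)
    terms <- hc_terms(dci)
    scale <- if (normalisation == "per_node") dci$n_active else 1
    Omega <- 1 - mean(om)
    R <- mean(terms) / scale
    R_Om <- mean(om * terms) / scale
    per_degree <- data.frame(
      p = dci$D2,
      q_p = vapply(as.character(dci$D2), function(p) dci$classes[[p]]$q, integer(1)),
      n_unique = vapply(as.character(dci$D2),
                        function(p) length(dci$classes[[p]]$sigma), integer(1)),
      omega_p = unname(om),
      R_contrib = unname(terms) / (scale * length(dci$D2)))
  }
  structure(list(S = S, V_n = V_n, V_hat_n = V_hat, Omega = Omega, R = R,
                 R_Omega = R_Om, per_degree = per_degree, flags = flags,
                 provenance = list(variance_convention = variance,
                                   hc_normalisation = normalisation,
                                   include_self = include_self,
                                   n = tab$n_total, n_active = tab$n_active,
                                   m = tab$m,
                                   isolates_dropped = length(tab$isolates))),
            class = "ndseq_report")
}

#' @export
print.ndseq_report <- function(x, digits = 4, ...) {
  cat("Neighbourhood degree sequence indices (n =", x$provenance$n,
      ", m =", x$provenance$m, ")\n")
  v <- c(S = x$S, V_n = x$V_n, V_hat_n = x$V_hat_n, Omega = x$Omega,
         R = x$R, R_Omega = x$R_Omega)
  print(round(v, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten an index report to a named numeric vector
#'
#' @param x An \code{"ndseq_report"} or \code{"classical_report"}.
#' @return A named numeric vector (undefined entries are \code{NA}).
#' @export
as_index_vector <- function(x) {
  if (inherits(x, "ndseq_report"))
    c(S = x$S, V_n = x$V_n, V_hat_n = x$V_hat_n, Omega = x$Omega,
      R = x$R, R_Omega = x$R_Omega)
  else if (inherits(x, "classical_report"))
    c(C = x$C, v = x$v, L = x$L, r = x$r, Q = x$Q)
  else stop("not an index report")
}
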
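#' Build a term-term co-occurrence graph
#'
#' Two terms share a link whenever they occur in the same tweet; each tweet
#' contributes at most 1 to an edge's weight regardless of token multiplicity
#' (set semantics within a tweet). Every observed token becomes a node, so
#' single-token tweets contribute isolated nodes. Self-loops cannot arise.
#'
#' @param x a [tweet_corpus()] (tokenized internally with the query term
#'   dropped) or a list of token streams as returned by [tokenize()].
#' @param ... passed to [tokenize()] when `x` is a corpus.
#' @return an undirected weighted [igraph::igraph] graph with edge attribute
#'   `weight` (co-occurrence count).
#' @export
build_cooccurrence_graph <- function(x, ...) {
  streams <- if (inherits(x, "tweet_corpus")) {
    tokenize(x$tweets$text, query_term = x$query_term, drop_query = TRUE, ...)
  } else {
    x
  }
  stopifnot(is.list(streams))
  nodes <- unique(unlist(streams, use.names = FALSE))
  pair_keys <- unlist(lapply(streams, function(toks) {
    u <- sort(unique(toks))
    if (length(u) < 2L) return(character(0))
    pairs <- utils::combn(u, 2L)
    paste(pairs[1L, ], pairs[2L, ], sep = "\r")
  }), use.names = FALSE)
  g <- if (length(pair_keys) == 0L) {
    igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    counts <- table(pair_keys)
    ends <- strsplit(names(counts), "\r", fixed = TRUE)
    el <- data.frame(from = vapply(ends, `[`, "", 1L),
                     to = vapply(ends, `[`, "", 2L),
                     weight = as.numeric(counts))
    igraph::graph_from_data_frame(el, directed = FALSE)
  }
  isolated <- setdiff(nodes, igraph::V(g)$name)
  if (length(isolated) > 0L) g <- igraph::add_vertices(g, length(isolated), name = isolated)
  g
}

#' Top terms by degree centrality
#'
#' Degree centrality of a term is its number of distinct neighbours ("how many
#' different links that term had to other terms"); set `weighted = TRUE` to
#' rank by weighted degree (sum of incident edge weights) instead.
#'
#' @param graph a term co-occurrence graph.
#' @param k number of terms to return.
#' @param weighted rank by weighted degree?
#' @return tibble with columns `term`, `degree`, descending, ties broken
#'   lexicographically.
#' @export
top_terms <- function(graph, k, weighted = FALSE) {
  stopifnot(k >= 1)
  deg <- if (weighted) igraph::strength(graph) else igraph::degree(graph)
  ord <- order(-deg, names(deg))
  out <- tibble::tibble(term = names(deg)[ord], degree = unname(deg[ord]))
  utils::head(out, k)
}

#' Top edges by co-occurrence weight
#'
#' @param graph a term co-occurrence graph.
#' @param k number of edges to return.
#' @return tibble with columns `term1`, `term2`, `weight`, descending by
#'   weight; within an edge the lexicographically smaller term is `term1`, and
#'   weight ties are broken lexicographically on (`term1`, `term2`).
#' @export
top_edges <- function(graph, k) {
  stopifnot(k >= 1)
  if (igraph::ecount(graph) == 0L) {
    return(tibble::tibble(term1 = character(0), term2 = character(0),
                          weight = numeric(0)))
  }
  ends <- igraph::as_edgelist(graph)
  t1 <- pmin(ends[, 1L], ends[, 2L])
  t2 <- pmax(ends[, 1L], ends[, 2L])
  w <- igraph::E(graph)$weight
  ord <- order(-w, t1, t2)
  utils::head(tibble::tibble(term1 = t1[ord], term2 = t2[ord], weight = w[ord]), k)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - resolution * (s(c)/(2W))^2 ]`, where `W` is the
#' total edge weight, `w_in(c)` the weight inside community `c` and `s(c)` the
#' sum of weighted degrees of its nodes.
#'
#' @param graph an undirected weighted igraph graph.
#' @param membership community ids: named vector over all vertex names, or an
#'   unnamed vector in vertex order.
#' @param resolution resolution parameter gamma (default 1 = classic Q).
#' @return the modularity score (a number `<= 1`).
#' @export
modularity_q <- function(graph, membership, resolution = 1.0) {
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  if (!is.null(names(membership))) {
    missing <- setdiff(vnames, names(membership))
    if (length(missing) > 0L) {
      stop("membership missing node(s): ", paste(utils::head(missing, 5), collapse = ", "))
    }
    membership <- membership[vnames]
  } else if (length(membership) != length(vnames)) {
    stop("membership length must match vertex count")
  }
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  W <- sum(w)
  if (W == 0) return(0)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  comm <- as.integer(factor(membership))
  c1 <- comm[ends[, 1L]]
  c2 <- comm[ends[, 2L]]
  w_in <- tapply(w[c1 == c2], c1[c1 == c2], sum)
  strength <- igraph::strength(graph, weights = w)
  s_c <- tapply(strength, comm, sum)
  sum(w_in) / W - resolution * sum((s_c / (2 * W))^2)
}

#' Louvain community detection (from scratch)
#'
#' Two-phase greedy modularity maximization: repeated local moves of single
#' nodes to the neighbouring community with the largest modularity gain,
#' followed by aggregation of communities into super-nodes, until a full pass
#' improves Q by no more than `tol`. Node visit order is shuffled from `seed`,
#' making the run deterministic given the seed; gain ties go to the lowest
#' community id.
#'
#' @param graph nonempty undirected igraph graph (edge attribute `weight`,
#'   defaulting to 1).
#' @param seed integer seed controlling node visit order.
#' @param resolution resolution parameter gamma (1 = default modularity).
#' @param tol minimum modularity gain to continue (default 1e-7).
#' @return object of class `community_partition`: list with `membership`
#'   (named community ids), `Q` (modularity at resolution 1 recomputed from the
#'   final assignment), `n_communities`, and `pass_q` (Q after each pass).
#' @export
louvain_communities <- function(graph, seed = 1L, resolution = 1.0, tol = 1e-7) {
  n0 <- igraph::vcount(graph)
  if (n0 == 0L) stop("graph is empty")
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n0))
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)

  # running state: current aggregated graph (edge arrays) + orig -> community map
  ei <- ends[, 1L]; ej <- ends[, 2L]; ew <- w
  node_of_orig <- seq_len(n0)
  pass_q <- numeric(0)
  q_prev <- -Inf
  repeat {
    n <- max(node_of_orig)
    res <- louvain_one_level(n, ei, ej, ew, resolution, tol, seed)
    node_of_orig <- res$comm[node_of_orig]
    q_now <- modularity_from_arrays(max(node_of_orig), ei_map(res, ei), ei_map(res, ej),
                                    ew, resolution)
    pass_q <- c(pass_q, q_now)
    if (q_now - q_prev <= tol) break
    q_prev <- q_now
    # aggregate: communities become nodes, parallel edges summed, intra -> loops
    ci <- res$comm[ei]; cj <- res$comm[ej]
    key <- paste(pmin(ci, cj), pmax(ci, cj))
    agg <- rowsum(ew, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    ei <- as.integer(vapply(parts, `[`, "", 1L))
    ej <- as.integer(vapply(parts, `[`, "", 2L))
    ew <- as.numeric(agg)
    seed <- seed + 1L  # vary visit order between levels, still seed-determined
  }
  membership <- stats::setNames(as.integer(factor(node_of_orig)), vnames)
  structure(list(membership = membership,
                 Q = modularity_q(graph, membership, resolution = 1.0),
                 n_communities = length(unique(membership)),
                 pass_q = pass_q),
            class = "community_partition")
}

ei_map <- function(res, e) res$comm[e]

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$Q))
  invisible(x)
}

# modularity on raw edge arrays (community ids in ci/cj), self-loop aware:
# k_i counts self-loops twice, W counts every edge once
modularity_from_arrays <- function(n, ci, cj, ew, resolution) {
  W <- sum(ew)
  if (W == 0) return(0)
  w_in <- sum(ew[ci == cj])
  s <- numeric(n)
  add <- rowsum(c(ew, ew), c(ci, cj))  # degree contribution to both endpoints
  s[as.integer(rownames(add))] <- add  # self-loop appears in both -> counted twice
  w_in / W - resolution * sum((s / (2 * W))^2)
}

# one level of local moves on an aggregated graph given as edge arrays;
# returns dense community ids per node
louvain_one_level <- function(n, ei, ej, ew, resolution, tol, seed) {
  self_w <- numeric(n)
  loops <- ei == ej
  if (any(loops)) {
    add <- rowsum(ew[loops], ei[loops])
    self_w[as.integer(rownames(add))] <- add
  }
  ai <- c(ei[!loops], ej[!loops])
  aj <- c(ej[!loops], ei[!loops])
  aw <- c(ew[!loops], ew[!loops])
  ord_adj <- order(ai)
  ai <- ai[ord_adj]; aj <- aj[ord_adj]; aw <- aw[ord_adj]
  # CSR-style index into the adjacency arrays
  ptr <- findInterval(0:n, ai) + 1L  # ptr[v]..(ptr[v+1]-1) rows for node v
  k <- numeric(n)
  deg_add <- rowsum(aw, ai)
  k[as.integer(rownames(deg_add))] <- deg_add
  k <- k + 2 * self_w
  W <- sum(ew)
  comm <- seq_len(n)
  sigma_tot <- k
  order_nodes <- withr::with_seed(seed, sample.int(n))
  if (W > 0) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (v in order_nodes) {
        lo <- ptr[v]; hi <- ptr[v + 1L] - 1L
        if (hi < lo) next
        nb_comm <- comm[aj[lo:hi]]
        l_vc <- rowsum(aw[lo:hi], nb_comm)
        cand <- as.integer(rownames(l_vc))
        c0 <- comm[v]
        sigma_tot[c0] <- sigma_tot[c0] - k[v]
        links0 <- if (c0 %in% cand) l_vc[match(c0, cand), 1L] else 0
        gain0 <- links0 - resolution * sigma_tot[c0] * k[v] / (2 * W)
        gains <- l_vc[, 1L] - resolution * sigma_tot[cand] * k[v] / (2 * W)
        best <- which(gains == max(gains))
        best <- best[which.min(cand[best])]  # tie -> lowest community id
        if (gains[best] > gain0 + 1e-12 && cand[best] != c0) {
          comm[v] <- cand[best]
          sigma_tot[cand[best]] <- sigma_tot[cand[best]] + k[v]
          improved <- TRUE
        } else {
          sigma_tot[c0] <- sigma_tot[c0] + k[v]
        }
      }
    }
  }
  list(comm = as.integer(factor(comm)))
}

#' Community size report
#'
#' Sizes of the detected communities in descending order with cumulative
#' fractions of all terms, and the fraction of terms contained in the `m`
#' largest communities.
#'
#' @param partition a [louvain_communities()] result (or any named membership
#'   vector).
#' @param m number of top communities to report the covered fraction for.
#' @return list with `table` (tibble: `rank`, `community`, `size`, `fraction`,
#'   `cumulative_fraction`) and `top_m_fraction`.
#' @export
community_size_report <- function(partition, m = 10L) {
  stopifnot(m >= 1)
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    partition
  }
  sizes <- sort(table(membership), decreasing = TRUE)
  tab <- tibble::tibble(
    rank = seq_along(sizes),
    community = names(sizes),
    size = as.integer(sizes),
    fraction = as.integer(sizes) / length(membership)
  )
  tab$cumulative_fraction <- cumsum(tab$fraction)
  list(table = tab,
       top_m_fraction = tab$cumulative_fraction[min(m, nrow(tab))])
}

#' Export a graph to GraphML
#'
#' Writes a Gephi-compatible GraphML file, attaching `community` as a vertex
#' attribute when a partition is supplied.
#'
#' @param graph an igraph graph.
#' @param path output file.
#' @param partition optional [louvain_communities()] result.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path, partition = NULL) {
  if (!is.null(partition)) {
    membership <- if (inherits(partition, "community_partition")) {
      partition$membership
    } else {
      partition
    }
    igraph::V(graph)$community <- as.integer(membership[igraph::V(graph)$name])
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
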
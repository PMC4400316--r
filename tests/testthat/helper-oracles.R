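# Independent brute-force oracles used to validate the package implementations.
# These deliberately re-derive each quantity from its definition through a
# different code path (dense matrices, explicit loops, exhaustive enumeration).

# --- rule scorer: explicit window scan --------------------------------------
bf_rule_score <- function(tokens, lexicon, window = 5L) {
  score <- 0
  n_matches <- 0L
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% names(lexicon$emoticon_weights)) {
      score <- score + lexicon$emoticon_weights[[tok]]
      n_matches <- n_matches + 1L
    } else if (tok %in% names(lexicon$weights)) {
      w <- lexicon$weights[[tok]]
      negated <- FALSE
      for (j in seq_len(window)) {
        if (i - j < 1L) break
        if (tokens[i - j] %in% lexicon$negators) negated <- TRUE
      }
      score <- score + if (negated) -sign(w) else w
      n_matches <- n_matches + 1L
    }
  }
  list(score = score, n_matches = n_matches)
}

# --- modularity: dense double sum over ordered node pairs -------------------
bf_modularity <- function(graph, membership, resolution = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = TRUE))
  vn <- igraph::V(graph)$name
  m <- membership[vn]
  k <- rowSums(A)
  W2 <- sum(A)  # 2W
  if (W2 == 0) return(0)
  q <- 0
  for (i in seq_along(vn)) {
    for (j in seq_along(vn)) {
      if (m[i] == m[j]) q <- q + A[i, j] - resolution * k[i] * k[j] / W2
    }
  }
  unname(q / W2)
}

# --- naive Bayes: direct product-form Bayes enumeration ---------------------
bf_nb_posterior <- function(tokens_list, labels, k_features, new_tokens,
                            smoothing = 0.5) {
  ranked <- risk_ratio_rank(tokens_list, labels, smoothing = smoothing)
  feats <- ranked$term[seq_len(min(k_features, nrow(ranked)))]
  agg <- function(class) {
    f <- stats::setNames(numeric(length(feats)), feats)
    for (d in which(labels == class)) {
      toks <- tokens_list[[d]]
      if (length(toks) == 0) next
      for (t in feats) f[t] <- f[t] + sum(toks == t) / length(toks)
    }
    f <- f / sum(labels == class)
    (f + 1) / (sum(f) + length(feats))
  }
  th_pos <- agg("positive"); th_neg <- agg("negative")
  prior <- mean(labels == "positive")
  lik <- function(theta) {
    out <- 1
    for (t in feats) out <- out * theta[[t]]^sum(new_tokens == t)
    out
  }
  prior * lik(th_pos) / (prior * lik(th_pos) + (1 - prior) * lik(th_neg))
}

# --- Mann-Whitney U: exhaustive enumeration of group assignments ------------
bf_mwu_exact <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  pooled_ranks <- rank(c(a, b))
  U_obs <- sum(pooled_ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(n, n_a)
  U_null <- apply(sets, 2, function(s) sum(pooled_ranks[s]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(U_null <= U_obs), mean(U_null >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# --- directed-graph metrics: Floyd-Warshall + explicit closures -------------
bf_digraph_metrics <- function(edges, nodes) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  Adir <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(edges))) {
    Adir[idx[[edges$source[r]]], idx[[edges$target[r]]]] <- TRUE
  }
  diag(Adir) <- FALSE
  n_edges_simple <- sum(Adir)
  Aund <- Adir | t(Adir)
  fw <- function(adj) {
    D <- ifelse(adj, 1, Inf); diag(D) <- 0
    for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
    D
  }
  Du <- fw(Aund)
  # weak components from finite undirected distances
  comp <- rep(NA_integer_, n); cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) { cid <- cid + 1L; comp[is.finite(Du[v, ])] <- cid }
  }
  sizes <- table(comp)
  giant <- as.integer(names(sizes)[which.max(sizes)])
  gmask <- comp == giant
  Dg <- Du[gmask, gmask, drop = FALSE]
  off <- Dg[upper.tri(Dg) | lower.tri(Dg)]
  # strong components: mutual reachability closure
  Dd <- fw(Adir)
  mutual <- is.finite(Dd) & is.finite(t(Dd))
  scomp <- rep(NA_integer_, n); sid <- 0L
  for (v in seq_len(n)) {
    if (is.na(scomp[v])) { sid <- sid + 1L; scomp[mutual[v, ]] <- sid }
  }
  list(
    n_nodes = n, n_edges = n_edges_simple,
    diameter = if (sum(gmask) == 1L) 0 else max(off),
    avg_path_length = if (sum(gmask) == 1L) 0 else mean(off),
    density = if (n > 1) n_edges_simple / (n * (n - 1)) else 0,
    n_wcc = cid, n_scc = sid, giant_fraction = max(sizes) / n
  )
}

random_digraph_edges <- function(n, p) {
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(source = paste0("u", pairs$source[keep]),
             target = paste0("u", pairs$target[keep]),
             stringsAsFactors = FALSE)
}

# adjusted Rand index between two labelings (closed form over the pair table)
bf_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

make_corpus <- function(texts, users = NULL, ts = NULL, query_term = "pain",
                        ...) {
  n <- length(texts)
  tweet_corpus(tibble::tibble(
    id = sprintf("x%04d", seq_len(n)),
    user = if (is.null(users)) sprintf("u%03d", seq_len(n)) else users,
    text = texts,
    timestamp_utc = if (is.null(ts))
      as.POSIXct("2012-09-15 12:00:00", tz = "UTC") + seq_len(n) else ts,
    ...
  ), query_term = query_term)
}
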
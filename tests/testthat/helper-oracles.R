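# Independent brute-force oracles used to validate the package's graph and
# embedding operations. These deliberately avoid the code paths they check:
# distances/betweenness/MST are validated by exhaustive simple-path and
# spanning-tree enumeration, double centering by a naive triple loop, ROC
# AUC by explicit positive-negative pair counting.

# random connected graph: random spanning tree plus extra random edges
random_connected_graph <- function(n, extra = 2L, weighted = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  a <- character(0); b <- character(0)
  for (i in seq_len(n - 1L)) {
    a <- c(a, nodes[i + 1L])
    b <- c(b, nodes[sample.int(i, 1L)])
  }
  all_pairs <- t(combn(nodes, 2))
  key <- paste(pmin(a, b), pmax(a, b))
  cand <- which(!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key))
  if (extra > 0L && length(cand) > 0L) {
    pick <- sample(cand, min(extra, length(cand)))
    a <- c(a, all_pairs[pick, 1]); b <- c(b, all_pairs[pick, 2])
  }
  w <- if (weighted) round(stats::runif(length(a), 0.5, 3), 2) else NULL
  make_interactome(a, b, w)
}

adj_list_of <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  nodes <- igraph::V(g)$name
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(el))) {
    adj[[el[k, 1]]] <- c(adj[[el[k, 1]]], el[k, 2])
    adj[[el[k, 2]]] <- c(adj[[el[k, 2]]], el[k, 1])
  }
  adj
}

edge_weight_lookup <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, nrow(el))
  stats::setNames(w, paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# all simple paths s -> t as lists of node vectors (DFS)
enumerate_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in adj[[last]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

# shortest-path length by exhaustive simple-path enumeration
oracle_distance <- function(g, s, t, use_weights = FALSE) {
  if (s == t) return(0)
  adj <- adj_list_of(g)
  wl <- edge_weight_lookup(g)
  paths <- enumerate_simple_paths(adj, s, t)
  lens <- vapply(paths, function(p) {
    if (!use_weights) return(length(p) - 1)
    sum(vapply(seq_len(length(p) - 1L), function(i) {
      wl[[paste(min(p[i], p[i + 1L]), max(p[i], p[i + 1L]))]]
    }, numeric(1)))
  }, numeric(1))
  min(lens)
}

# betweenness by exhaustive enumeration of all unweighted shortest paths
oracle_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  adj <- adj_list_of(g)
  out <- stats::setNames(numeric(length(nodes)), nodes)
  pairs <- t(combn(nodes, 2))
  for (k in seq_len(nrow(pairs))) {
    s <- pairs[k, 1]; t <- pairs[k, 2]
    paths <- enumerate_simple_paths(adj, s, t)
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    n_st <- length(shortest)
    for (u in nodes) {
      if (u == s || u == t) next
      n_through <- sum(vapply(shortest, function(p) u %in% p, logical(1)))
      out[u] <- out[u] + n_through / n_st
    }
  }
  out
}

# minimum spanning tree weight by enumerating all (n-1)-edge subsets
oracle_mst_weight <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, nrow(el))
  best <- Inf
  for (idx in utils::combn(nrow(el), n - 1L, simplify = FALSE)) {
    sub <- igraph::graph_from_data_frame(
      data.frame(from = el[idx, 1], to = el[idx, 2]), directed = FALSE,
      vertices = data.frame(name = igraph::V(g)$name))
    if (igraph::is_connected(sub)) best <- min(best, sum(w[idx]))
  }
  best
}

# nearest-neighbour module separation computed with plain loops
oracle_sab <- function(d, a, b) {
  a <- unique(a); b <- unique(b)
  nearest <- function(gene, set) {
    set <- setdiff(set, gene)
    if (length(set) == 0L) return(0)
    min(vapply(set, function(x) d[gene, x], numeric(1)))
  }
  cross <- vapply(union(a, b), function(gene) {
    if (gene %in% a && gene %in% b) return(0)
    other <- if (gene %in% a) b else a
    min(vapply(other, function(x) d[gene, x], numeric(1)))
  }, numeric(1))
  within <- function(set) {
    if (length(set) < 2L) return(0)
    mean(vapply(set, function(gene) nearest(gene, set), numeric(1)))
  }
  mean(cross) - (within(a) + within(b)) / 2
}

# naive triple-loop -1/2 J D^2 J
oracle_double_center <- function(d) {
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  a <- matrix(0, n, n)
  s <- d^2
  js <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    js[i, k] <- sum(j[i, ] * s[, k])
  }
  for (i in seq_len(n)) for (k in seq_len(n)) {
    a[i, k] <- -0.5 * sum(js[i, ] * j[, k])
  }
  dimnames(a) <- dimnames(d)
  a
}

# AUC by explicit positive-negative pair comparison, ties credited 0.5
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# small helper: write lines to a temp file and return the path
tmp_text_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
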
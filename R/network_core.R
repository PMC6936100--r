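#' Read an interactome edge list
#'
#' Parses a plain-text edge list into an undirected interactome graph.
#' Each non-comment line holds two gene identifiers (tab- or
#' whitespace-separated) and, when `weighted = TRUE`, a positive numeric
#' weight in the third column. Lines starting with `#` and blank lines are
#' ignored. Self-loops and duplicate edges (including reversed duplicates)
#' are dropped with a warning; for duplicated weighted edges the first
#' occurrence wins. Nodes are ordered lexicographically.
#'
#' @param path Path to the edge-list file.
#' @param weighted Logical; read a third column of positive edge weights.
#' @return An [igraph::igraph] undirected graph. When `weighted = TRUE` the
#'   graph carries a `weight` edge attribute.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  ncols <- lengths(fields)
  need <- if (weighted) 3L else 2L
  bad <- which(ncols < need)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d: expected at least %d columns, found %d",
                 idx[bad[1L]], need, ncols[bad[1L]]), call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- NULL
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(w) | w <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("invalid weight at line %d: weights must be positive numbers",
                   idx[bad[1L]]), call. = FALSE)
    }
  }
  make_interactome(a, b, w)
}

#' Build an interactome from edge endpoint vectors
#'
#' Low-level constructor shared by [read_edge_list()] and the synthetic
#' generators. Enforces the interactome invariants: undirected, no
#' self-loops, no duplicate edges, lexicographic node order, positive
#' weights.
#'
#' @param a,b Character vectors of edge endpoints.
#' @param w Optional numeric vector of positive edge weights.
#' @param extra_nodes Additional isolated node names to include.
#' @return An undirected [igraph::igraph].
#' @export
make_interactome <- function(a, b, w = NULL, extra_nodes = character()) {
  stopifnot(length(a) == length(b))
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
    if (!is.null(w)) w <- w[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge(s)", sum(dup)), call. = FALSE)
    lo <- lo[!dup]; hi <- hi[!dup]
    if (!is.null(w)) w <- w[!dup]
  }
  nodes <- sort(unique(c(lo, hi, extra_nodes)))
  ord <- order(lo, hi)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[ord], to = hi[ord], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(w)) igraph::E(g)$weight <- w[ord]
  g
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component of the
#' interactome. PPI networks typically consist of one dominant component
#' plus small fragments, and the geometric embedding is only defined on a
#' connected graph, so all downstream analysis is restricted to this
#' component. Size ties are broken in favour of the component containing
#' the lexicographically smallest node label.
#'
#' @param g An interactome graph.
#' @return The induced subgraph on the largest component, node order
#'   preserved (hence lexicographic if `g` was).
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph has no components", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    # among tied components, pick the one whose smallest member sorts first
    firsts <- vapply(cand, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    cand <- cand[order(firsts)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1L]))
}

#' All-pairs shortest path (geodesic) distances
#'
#' Computes the symmetric matrix D of shortest-path distances between every
#' pair of nodes: breadth-first hop counts in unweighted mode, minimal sums
#' of edge weights in weighted mode. This is the input to the double
#' centering step of the geometric embedding.
#'
#' @param g A connected interactome.
#' @param use_weights Logical; use the `weight` edge attribute.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = node
#'   names in the graph's node order.
#' @export
all_pairs_shortest_paths <- function(g, use_weights = FALSE) {
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; take largest_connected_component() first",
         call. = FALSE)
  }
  w <- if (use_weights) {
    ew <- igraph::E(g)$weight
    if (igraph::ecount(g) > 0L && is.null(ew)) {
      stop("use_weights = TRUE but graph has no 'weight' edge attribute",
           call. = FALSE)
    }
    if (!is.null(ew) && any(ew <= 0)) stop("edge weights must be positive", call. = FALSE)
    ew
  } else {
    NA  # force unweighted even if a weight attribute is present
  }
  d <- igraph::distances(g, weights = w)
  d[igraph::V(g)$name, igraph::V(g)$name, drop = FALSE]
}

#' Betweenness centrality
#'
#' For each node u, the sum over unordered node pairs \{s, t\} (s, t != u)
#' of the fraction of shortest s-t paths passing through u. Shortest paths
#' are unweighted; endpoints do not count as passing through.
#'
#' @param g A connected interactome.
#' @return Named numeric vector of centralities, one per node.
#' @export
betweenness_centrality <- function(g) {
  if (!igraph::is_connected(g)) stop("graph must be connected", call. = FALSE)
  igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Average degree of a gene set
#'
#' Arithmetic mean of the interactome degrees of the listed genes.
#'
#' @param g An interactome.
#' @param genes Non-empty character vector of node names present in `g`.
#' @return A single number.
#' @export
average_degree <- function(g, genes) {
  genes <- unique(genes)
  if (length(genes) == 0L) stop("gene set is empty", call. = FALSE)
  missing <- setdiff(genes, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in interactome: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  mean(igraph::degree(g)[genes])
}

#' Minimum spanning tree with deterministic tie-breaking
#'
#' Kruskal's algorithm with edges ordered by (weight, lexicographic edge
#' label), so equal-weight choices are resolved reproducibly. An unweighted
#' graph is treated as having unit weights. The returned tree keeps the
#' weight attribute of its selected edges (unit weights are not added to an
#' unweighted input).
#'
#' @param g A connected interactome, optionally weighted.
#' @return An [igraph::igraph] spanning tree of `g`.
#' @export
minimum_spanning_tree <- function(g) {
  if (!igraph::is_connected(g)) stop("graph must be connected", call. = FALSE)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  had_w <- "weight" %in% igraph::edge_attr_names(g)
  w <- if (had_w) igraph::E(g)$weight else rep(1, nrow(el))
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  ord <- order(w, lo, hi)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  vid <- stats::setNames(seq_len(n), igraph::V(g)$name)
  pick <- integer(0)
  for (k in ord) {
    ra <- find(vid[[lo[k]]]); rb <- find(vid[[hi[k]]])
    if (ra != rb) {
      parent[ra] <- rb
      pick <- c(pick, k)
      if (length(pick) == n - 1L) break
    }
  }
  make_interactome(lo[pick], hi[pick],
                   w = if (had_w) w[pick] else NULL,
                   extra_nodes = igraph::V(g)$name)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: identifier, description, then member genes,
#' tab-separated (the Reactome/MSigDB convention).
#'
#' @param path Path to a GMT file.
#' @return Named list mapping pathway identifier to a character vector of
#'   gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed GMT line %d: need id, description and >= 1 gene",
                 bad[1L]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway identifiers in GMT", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  stats::setNames(sets, ids)
}

#' Write gene sets in GMT format
#'
#' @param ann Named list of gene-identifier vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to `"na"`).
#' @export
write_gmt <- function(ann, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(ann))
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, names(ann), descriptions, ann)
  writeLines(unname(lines), path)
}

#' Pathway-derived edge weights
#'
#' Assigns each interactome edge a weight reflecting how often its two
#' endpoints co-occur in an annotated pathway: with freq(e) = number of
#' pathways containing both endpoints, the weight is w(e) = 1 / (1 +
#' freq(e)). Edges supported by many pathways therefore get low weights and
#' are preferentially selected by the minimum spanning tree, steering the
#' minimum-curvilinear embedding along biologically co-functional routes.
#' Genes absent from the annotation contribute frequency 0 (weight 1).
#'
#' @param g An interactome.
#' @param ann Pathway annotation: named list of gene-identifier vectors
#'   (see [read_gmt()]).
#' @return A copy of `g` with a `weight` edge attribute in (0, 1].
#' @export
pathway_edge_weights <- function(g, ann) {
  el <- igraph::as_edgelist(g, names = TRUE)
  membership <- list()
  for (i in seq_along(ann)) {
    for (gene in ann[[i]]) {
      membership[[gene]] <- c(membership[[gene]], i)
    }
  }
  freq <- vapply(seq_len(nrow(el)), function(k) {
    pa <- membership[[el[k, 1]]]
    pb <- membership[[el[k, 2]]]
    if (is.null(pa) || is.null(pb)) 0L else length(intersect(pa, pb))
  }, integer(1))
  igraph::E(g)$weight <- 1 / (1 + freq)
  g
}

#' Per-gene pathway membership counts
#'
#' @param ann Pathway annotation (named list of gene vectors).
#' @param genes Character vector of genes to count for.
#' @return Named integer vector: number of pathways containing each gene
#'   (0 for unannotated genes).
#' @export
pathway_counts <- function(ann, genes) {
  counts <- stats::setNames(integer(length(genes)), genes)
  for (set in ann) {
    hit <- genes %in% set
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Write an interactome as a plain-text edge list
#'
#' @param g An interactome.
#' @param path Output file path.
#' @param weighted Write the `weight` edge attribute as a third column.
#' @export
write_edge_list <- function(g, path, weighted = FALSE) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (weighted) {
    lines <- paste(el[, 1], el[, 2], format(igraph::E(g)$weight, digits = 15),
                   sep = "\t")
  } else {
    lines <- paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(lines, path)
}
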
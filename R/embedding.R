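#' Double centering of a distance matrix
#'
#' Converts a matrix D of pairwise distances into the Gram (inner-product)
#' matrix A = -1/2 J D^2 J, with the centering matrix J = I - n^-1 11' and
#' D^2 the elementwise square. Rows and columns of A sum to zero; its top
#' eigenvectors give the classical MDS coordinates.
#'
#' @param d Symmetric numeric matrix of non-negative distances, zero
#'   diagonal, with dimnames.
#' @return Symmetric matrix A with the same dimnames, rows/columns
#'   centered to zero sum.
#' @export
double_center <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  s <- d^2
  rm_ <- rowMeans(s)
  cm_ <- colMeans(s)
  a <- -0.5 * (s - outer(rm_, rep(1, ncol(s))) -
                 outer(rep(1, nrow(s)), cm_) + mean(s))
  dimnames(a) <- dimnames(d)
  a
}

#' Spectral embedding of a Gram matrix
#'
#' Extracts the m largest eigenvalues and eigenvectors of a symmetric Gram
#' matrix and returns coordinates X = E_m Lambda_m^(1/2). Graph geodesic
#' distances are generally non-Euclidean, so A can be indefinite; negative
#' retained eigenvalues are clamped to zero with a warning. Eigenvector
#' sign is canonicalized so the first entry of nonneglible magnitude in
#' each eigenvector is positive, making results reproducible across
#' platforms.
#'
#' @param a Symmetric numeric matrix with dimnames (row names are the node
#'   index).
#' @param m Number of dimensions to retain, 1 <= m <= nrow(a).
#' @param method Label stored on the result (`"mds"`, `"mce"`, ...).
#' @param weighted Logical flag stored on the result.
#' @return An object of class `comorb_embedding`: list with `index`
#'   (node names), `X` (n x m coordinate matrix), `eigenvalues` (the m
#'   retained eigenvalues, non-increasing, before clamping), `method`,
#'   `weighted`.
#' @export
eigen_embed <- function(a, m, method = "mds", weighted = FALSE) {
  n <- nrow(a)
  if (m < 1 || m > n) stop(sprintf("m must be in [1, %d]", n), call. = FALSE)
  eg <- eigen(a, symmetric = TRUE)
  vals <- eg$values[seq_len(m)]
  vecs <- eg$vectors[, seq_len(m), drop = FALSE]
  vecs <- canonicalize_signs(vecs)
  if (any(vals < -1e-12)) {
    warning(sprintf("%d negative eigenvalue(s) clamped to zero (non-Euclidean distances)",
                    sum(vals < -1e-12)), call. = FALSE)
  }
  x <- vecs %*% diag(sqrt(pmax(vals, 0)), nrow = m)
  rownames(x) <- rownames(a)
  colnames(x) <- paste0("dim_", seq_len(m))
  structure(list(index = rownames(a), X = x, eigenvalues = vals,
                 method = method, weighted = weighted),
            class = "comorb_embedding")
}

canonicalize_signs <- function(v, tol = 1e-9) {
  for (j in seq_len(ncol(v))) {
    nz <- which(abs(v[, j]) > tol)
    if (length(nz) > 0L && v[nz[1L], j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.comorb_embedding <- function(x, ...) {
  cat(sprintf("<comorb_embedding> %s%s: %d nodes x %d dimensions\n",
              x$method, if (isTRUE(x$weighted)) " (weighted)" else "",
              length(x$index), ncol(x$X)))
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 5), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classical MDS / Isomap embedding of an interactome
#'
#' Composes the embedding pipeline on geodesic distances: all-pairs
#' shortest paths, double centering, spectral embedding. With
#' `use_weights = TRUE` the geodesics are weighted path lengths.
#'
#' @param g A connected interactome.
#' @param m Target dimension.
#' @param use_weights Logical; use the `weight` edge attribute for the
#'   shortest paths.
#' @return A `comorb_embedding` with `method = "mds"`.
#' @export
embed_mds <- function(g, m, use_weights = FALSE) {
  d <- all_pairs_shortest_paths(g, use_weights = use_weights)
  eigen_embed(double_center(d), m, method = "mds", weighted = use_weights)
}

#' Minimum-curvilinear distance matrix
#'
#' Pairwise distances measured along the minimum spanning tree of the
#' graph: the tree is built on the graph's weights (unit weights if
#' unweighted) and path lengths are sums of the tree's edge weights. These
#' "curvilinear" distances follow the tree's backbone and are the input to
#' MCE/ncMCE.
#'
#' @param g A connected interactome.
#' @return Symmetric distance matrix over the tree, node order of `g`.
#' @export
mc_distances <- function(g) {
  tree <- minimum_spanning_tree(g)
  use_w <- "weight" %in% igraph::edge_attr_names(tree)
  d <- all_pairs_shortest_paths(tree, use_weights = use_w)
  d[igraph::V(g)$name, igraph::V(g)$name, drop = FALSE]
}

#' Centered minimum curvilinear embedding (MCE)
#'
#' Double-centered spectral embedding of the minimum-curvilinear distance
#' matrix (all-pairs distances along the minimum spanning tree). When the
#' graph carries pathway-derived weights (see [pathway_edge_weights()]),
#' both the tree selection and the path lengths use those weights.
#'
#' @param g A connected interactome, weighted or unweighted.
#' @param m Target dimension.
#' @return A `comorb_embedding` with `method = "mce"`.
#' @export
embed_mce <- function(g, m) {
  weighted <- "weight" %in% igraph::edge_attr_names(g)
  d <- mc_distances(g)
  eigen_embed(double_center(d), m, method = "mce", weighted = weighted)
}

#' Non-centered minimum curvilinear embedding (ncMCE)
#'
#' Singular value decomposition applied directly to the
#' minimum-curvilinear distance matrix, skipping the centering step:
#' X = U_m Sigma_m^(1/2), columns ordered by non-increasing singular
#' value, left singular vectors sign-canonicalized.
#'
#' @param g A connected interactome.
#' @param m Target dimension.
#' @return A `comorb_embedding` with `method = "ncmce"`; the `eigenvalues`
#'   slot holds the retained singular values.
#' @export
embed_ncmce <- function(g, m) {
  weighted <- "weight" %in% igraph::edge_attr_names(g)
  d <- mc_distances(g)
  n <- nrow(d)
  if (m < 1 || m > n) stop(sprintf("m must be in [1, %d]", n), call. = FALSE)
  sv <- svd(d, nu = m, nv = 0)
  u <- canonicalize_signs(sv$u)
  x <- u %*% diag(sqrt(sv$d[seq_len(m)]), nrow = m)
  rownames(x) <- rownames(d)
  colnames(x) <- paste0("dim_", seq_len(m))
  structure(list(index = rownames(d), X = x, eigenvalues = sv$d[seq_len(m)],
                 method = "ncmce", weighted = weighted),
            class = "comorb_embedding")
}

#' Embed an interactome by name
#'
#' Dispatch helper used by the command-line interface.
#'
#' @param g A connected interactome.
#' @param m Target dimension.
#' @param method One of `"mds"`, `"mce"`, `"ncmce"`.
#' @param use_weights For `"mds"`, use edge weights for geodesics (MCE
#'   variants use the graph's weights automatically).
#' @return A `comorb_embedding`.
#' @export
embed_interactome <- function(g, m, method = c("mce", "mds", "ncmce"),
                              use_weights = FALSE) {
  method <- match.arg(method)
  switch(method,
         mds = embed_mds(g, m, use_weights = use_weights),
         mce = embed_mce(g, m),
         ncmce = embed_ncmce(g, m))
}

#' Reconstruction error of an embedding
#'
#' Root-mean-square difference, over all unordered node pairs, between the
#' pairwise Euclidean distances of the embedded coordinates and the target
#' distance matrix. Diagnostic for choosing the dimension m.
#'
#' @param e A `comorb_embedding`.
#' @param d Target distance matrix with matching index.
#' @return A single non-negative number.
#' @export
reconstruction_error <- function(e, d) {
  if (!identical(sort(e$index), sort(rownames(d)))) {
    stop("embedding index does not match distance matrix index", call. = FALSE)
  }
  d <- d[e$index, e$index, drop = FALSE]
  emb <- as.matrix(stats::dist(e$X))
  diffs <- (emb - d)[upper.tri(d)]
  if (length(diffs) == 0L) return(0)
  sqrt(mean(diffs^2))
}

#' Persist an embedding as a tab-separated table
#'
#' Writes a TSV with header `gene dim_1 ... dim_m` and a sidecar
#' `<path>.meta` plain key=value file holding method, weighted flag and
#' eigenvalues.
#'
#' @param e A `comorb_embedding`.
#' @param path Output TSV path.
#' @export
write_embedding <- function(e, path) {
  df <- data.frame(gene = e$index, e$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(paste0("method=", e$method),
            paste0("weighted=", tolower(as.character(isTRUE(e$weighted)))),
            paste0("eigenvalues=", paste(format(e$eigenvalues, digits = 17),
                                         collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path TSV path (the `<path>.meta` sidecar must exist alongside).
#' @return A `comorb_embedding`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$gene
  meta_lines <- readLines(paste0(path, ".meta"))
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          vapply(kv, `[[`, character(1), 1L))
  structure(list(index = df$gene, X = x,
                 eigenvalues = as.numeric(strsplit(meta[["eigenvalues"]],
                                                   ",", fixed = TRUE)[[1]]),
                 method = meta[["method"]],
                 weighted = identical(meta[["weighted"]], "true")),
            class = "comorb_embedding")
}
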
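#' Project a gene module onto the embedding dimensions
#'
#' The i-th component is the sum of the i-th embedded coordinate over all
#' genes of the module: f_i = sum_{g in module} z_i(g). These m sums
#' "fingerprint" where the module sits along each geometric axis.
#'
#' @param e A `comorb_embedding`.
#' @param genes Character vector of genes (a set; duplicates collapse).
#'   An empty set yields the zero vector.
#' @return Numeric vector of length m.
#' @export
module_projection <- function(e, genes) {
  genes <- unique(genes)
  if (length(genes) == 0L) return(stats::setNames(numeric(ncol(e$X)), colnames(e$X)))
  missing <- setdiff(genes, e$index)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in embedding: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  colSums(e$X[genes, , drop = FALSE])
}

#' Feature vector for one disease pair
#'
#' The pair's module M is the union of the two diseases' gene sets. The
#' (m+3)-dimensional feature vector is the m module projections followed
#' by the module's average interactome degree, average betweenness
#' centrality, and average per-gene pathway membership count (genes with
#' no annotation count 0 pathways).
#'
#' @param e A `comorb_embedding` of the interactome.
#' @param g The interactome.
#' @param ann Pathway annotation (named list of gene vectors).
#' @param pair One-row data frame (or list) with `disease_a`, `disease_b`.
#' @param map Disease-gene map.
#' @param centrality Optional precomputed [betweenness_centrality()]
#'   vector (computed on the fly if `NULL`; precompute when featurizing
#'   many pairs).
#' @return Named numeric vector of length m + 3: `dim_1 ... dim_m`,
#'   `avg_degree`, `avg_centrality`, `avg_pathways`.
#' @export
pair_feature_vector <- function(e, g, ann, pair, map, centrality = NULL) {
  for (dn in c(pair$disease_a, pair$disease_b)) {
    if (!dn %in% names(map)) stop(sprintf("disease not in map: %s", dn), call. = FALSE)
  }
  module <- union(map[[pair$disease_a]], map[[pair$disease_b]])
  if (is.null(centrality)) centrality <- betweenness_centrality(g)
  f <- module_projection(e, module)
  c(f,
    avg_degree = average_degree(g, module),
    avg_centrality = mean(centrality[module]),
    avg_pathways = mean(pathway_counts(ann, module)))
}

#' Feature matrix for a set of disease pairs
#'
#' Vectorized front end to [pair_feature_vector()]: betweenness is
#' computed once for the whole interactome and reused across pairs.
#'
#' @param e A `comorb_embedding`.
#' @param g The interactome.
#' @param ann Pathway annotation.
#' @param pairs Data frame with columns `disease_a`, `disease_b`, `rr`.
#' @param map Disease-gene map.
#' @return Data frame `disease_a, disease_b, rr, dim_1 ... dim_m,
#'   avg_degree, avg_centrality, avg_pathways`.
#' @export
build_feature_matrix <- function(e, g, ann, pairs, map) {
  centrality <- betweenness_centrality(g)
  feats <- t(vapply(seq_len(nrow(pairs)), function(i) {
    pair_feature_vector(e, g, ann, pairs[i, ], map, centrality = centrality)
  }, numeric(ncol(e$X) + 3L)))
  cbind(pairs[, c("disease_a", "disease_b", "rr")],
        as.data.frame(feats), stringsAsFactors = FALSE)
}

#' Names of the feature columns in a feature matrix
#'
#' @param features A feature matrix from [build_feature_matrix()].
#' @return Character vector of feature column names (everything except
#'   the pair identity and rr columns).
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features), c("disease_a", "disease_b", "rr"))
}

#' Common-gene pathway profile of disease pairs
#'
#' For each pair, counts the genes shared by the two diseases and the
#' number of annotated pathways containing at least one of those shared
#' genes. With `randomize = TRUE` each pair's shared genes are first
#' replaced by uniformly random interactome genes (preserving the shared
#' count), giving the null profile against which the real common genes'
#' pathway parsimony is judged: genuinely comorbid pairs tend to hit fewer
#' pathways than random gene sets of the same size.
#'
#' @param pairs Data frame with `disease_a`, `disease_b`.
#' @param map Disease-gene map.
#' @param ann Pathway annotation.
#' @param g The interactome (source of random replacement genes).
#' @param randomize Logical; substitute random genes for the shared genes.
#' @param seed Integer seed for the randomization.
#' @return Data frame `disease_a, disease_b, n_common_genes, n_pathways`.
#' @export
common_gene_pathway_profile <- function(pairs, map, ann, g,
                                        randomize = FALSE, seed = 1L) {
  nodes <- igraph::V(g)$name
  if (randomize) set.seed(seed)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    common <- intersect(map[[pairs$disease_a[i]]], map[[pairs$disease_b[i]]])
    n_common <- length(common)
    if (randomize && n_common > 0L) common <- sample(nodes, n_common)
    n_path <- if (n_common == 0L) 0L else sum(vapply(ann, function(set) {
      any(common %in% set)
    }, logical(1)))
    data.frame(disease_a = pairs$disease_a[i], disease_b = pairs$disease_b[i],
               n_common_genes = n_common, n_pathways = n_path,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a feature matrix as TSV
#'
#' @param features Data frame from [build_feature_matrix()].
#' @param path Output path.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_feature_matrix <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
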
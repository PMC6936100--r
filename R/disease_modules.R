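#' Load a disease-gene association table
#'
#' Reads a two-column (disease, gene) TSV and restricts each disease's gene
#' set to the nodes of the given interactome (typically its largest
#' connected component, since distances are undefined elsewhere). Genes
#' outside the interactome are dropped with a per-disease message;
#' diseases left with no mapped genes are removed with a warning.
#' Duplicate (disease, gene) rows collapse to a single membership.
#'
#' @param path Path to a tab/whitespace-separated table with columns
#'   (disease, gene). `#` comment lines are ignored.
#' @param g The interactome the modules live on.
#' @return Named list mapping disease name to a character vector of genes.
#' @export
load_disease_gene_map <- function(path, g) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(stats::setNames(list(), character(0)))
  fields <- strsplit(trimws(lines[idx]), "\t|\\s{2,}|\\s")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d: expected (disease, gene)", idx[bad[1L]]),
         call. = FALSE)
  }
  disease <- vapply(fields, `[[`, character(1), 1L)
  gene <- vapply(fields, `[[`, character(1), 2L)
  restrict_disease_gene_map(split(gene, disease), g)
}

#' Restrict a disease-gene map to an interactome
#'
#' @param map Named list of gene vectors.
#' @param g Interactome whose node set defines the universe.
#' @return The map with genes outside `g` dropped and empty diseases
#'   removed (with a warning).
#' @export
restrict_disease_gene_map <- function(map, g) {
  nodes <- igraph::V(g)$name
  out <- lapply(map, function(genes) intersect(unique(genes), nodes))
  dropped <- vapply(map, function(genes) length(setdiff(unique(genes), nodes)),
                    integer(1))
  if (any(dropped > 0L)) {
    message(sprintf("dropped genes outside the interactome for %d disease(s) (%d total)",
                    sum(dropped > 0L), sum(dropped)))
  }
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning(sprintf("removed %d disease(s) with no genes in the interactome: %s",
                    sum(empty), paste(utils::head(names(out)[empty], 5), collapse = ", ")),
            call. = FALSE)
    out <- out[!empty]
  }
  out
}

#' Module separation S_AB of two disease gene sets
#'
#' Network-based separation of two disease modules on the interactome:
#' S_AB = <d_AB> - (<d_AA> + <d_BB>) / 2. In the default nearest-neighbour
#' form, <d_AB> averages, over every gene in the union of the two modules,
#' its shortest distance to the closest gene of the other module (0 for a
#' gene belonging to both), and <d_AA> averages each A-gene's distance to
#' its closest *other* A-gene (a singleton module has <d_AA> = 0 by
#' convention). Negative S_AB indicates topologically overlapping modules;
#' comorbid disease pairs tend to have smaller S_AB. `variant = "mean"`
#' gives a naive all-pairs-mean alternative for sensitivity analysis:
#' plain means of cross-module and within-module pair distances.
#'
#' @param d All-pairs distance matrix (see [all_pairs_shortest_paths()]).
#' @param genes_a,genes_b Non-empty character vectors of genes in `d`'s
#'   index.
#' @param variant `"nearest"` (default) or `"mean"`.
#' @return The separation S_AB (a real number, possibly negative).
#' @export
module_separation <- function(d, genes_a, genes_b,
                              variant = c("nearest", "mean")) {
  variant <- match.arg(variant)
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  if (length(genes_a) == 0L || length(genes_b) == 0L) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(genes_a, genes_b), rownames(d))
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in distance matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  if (variant == "nearest") {
    d_ab <- mean_nearest_cross(d, genes_a, genes_b)
    d_aa <- mean_nearest_within(d, genes_a)
    d_bb <- mean_nearest_within(d, genes_b)
  } else {
    d_ab <- mean(d[genes_a, genes_b, drop = FALSE])
    d_aa <- mean_pair_within(d, genes_a)
    d_bb <- mean_pair_within(d, genes_b)
  }
  d_ab - (d_aa + d_bb) / 2
}

# average over A union B of each gene's distance to the nearest gene of the
# other set; shared genes contribute 0
mean_nearest_cross <- function(d, a, b) {
  u <- union(a, b)
  vals <- vapply(u, function(g) {
    if (g %in% a && g %in% b) return(0)
    other <- if (g %in% a) b else a
    min(d[g, other])
  }, numeric(1))
  mean(vals)
}

mean_nearest_within <- function(d, a) {
  if (length(a) < 2L) return(0)
  vals <- vapply(a, function(g) min(d[g, setdiff(a, g)]), numeric(1))
  mean(vals)
}

mean_pair_within <- function(d, a) {
  if (length(a) < 2L) return(0)
  sub <- d[a, a, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Module-separation baseline scores for disease pairs
#'
#' Scores each disease pair by the negated module separation -S_AB, so
#' that larger scores mean a prediction of higher comorbidity; this is the
#' baseline ranking the embedding classifier is compared against.
#'
#' @param pairs Data frame with columns `disease_a`, `disease_b` (and
#'   typically `rr`).
#' @param d All-pairs distance matrix.
#' @param map Disease-gene map (named list).
#' @param variant Passed to [module_separation()].
#' @return Numeric vector of scores aligned with the rows of `pairs`.
#' @export
sab_baseline_scores <- function(pairs, d, map, variant = c("nearest", "mean")) {
  variant <- match.arg(variant)
  missing <- setdiff(unique(c(pairs$disease_a, pairs$disease_b)), names(map))
  if (length(missing) > 0L) {
    stop(sprintf("disease(s) missing from the disease-gene map: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    -module_separation(d, map[[pairs$disease_a[i]]], map[[pairs$disease_b[i]]],
                       variant = variant)
  }, numeric(1))
}

#' Read a disease-pair comorbidity table
#'
#' @param path TSV with columns (disease_a, disease_b, rr); `#` comments
#'   ignored; a header row is detected when the third field is not numeric.
#' @return Data frame with columns `disease_a`, `disease_b`, `rr`.
#' @export
read_pair_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(disease_a = character(0), disease_b = character(0),
                      rr = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\t|\\s{2,}|\\s")
  if (length(fields[[1]]) >= 3L &&
      tolower(fields[[1]][3]) %in% c("rr", "relative_risk")) {
    fields <- fields[-1]  # header row
  }
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed pair row %d: expected (disease_a, disease_b, rr)",
                 bad[1L]), call. = FALSE)
  }
  rr <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(rr) || any(rr < 0)) stop("rr must be a non-negative number", call. = FALSE)
  data.frame(disease_a = vapply(fields, `[[`, character(1), 1L),
             disease_b = vapply(fields, `[[`, character(1), 2L),
             rr = rr, stringsAsFactors = FALSE)
}
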
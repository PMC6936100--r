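#' Configuration for the synthetic benchmark generator
#'
#' Parameters of the synthetic interactome / pathway / disease-pair
#' generator used for end-to-end benchmarking without external data. The
#' defaults describe the benchmark condition: a 2000-node
#' preferential-attachment interactome (degree-heterogeneous, connected),
#' 400 locally connected pathways of 5-25 genes, and 200 disease pairs of
#' which half are comorbid — comorbid pairs share 3-6 genes and both
#' modules grow from a common network neighbourhood (so their relative
#' risk exceeds 1), while non-comorbid pairs are disjoint modules seeded
#' at graph distance >= 4 with RR below 1 and a 0.3 point mass at exactly
#' RR = 0.
#'
#' @param n_nodes Number of interactome nodes.
#' @param attachment_edges Edges added per node by preferential attachment.
#' @param n_pathways Number of pathway gene sets.
#' @param pathway_size_range Min/max random-walk length per pathway.
#' @param n_pairs Number of disease pairs.
#' @param frac_comorbid Fraction of pairs that are comorbid.
#' @param module_size_range Min/max genes per disease module.
#' @param n_shared_range Min/max genes shared by a comorbid pair.
#' @param rr_comorbid_range RR range for comorbid pairs (low >= 1).
#' @param rr_noncomorbid_range RR range for non-comorbid pairs (high < 1).
#' @param p_rr_zero Probability a non-comorbid pair has RR exactly 0.
#' @param frac_scatter Fraction of each module's non-shared genes replaced
#'   by uniformly random interactome genes. Real disease-gene
#'   associations are noisy and disease modules are not clean connected
#'   neighbourhoods; this scatter makes the module-separation statistic an
#'   informative but imperfect predictor, as it is on clinical data.
#' @param frac_confusable Fraction of the non-comorbid pairs that share
#'   genes and sit in a common (wider) neighbourhood despite their low RR.
#'   Gene sharing without clinical comorbidity is common in real disease
#'   data and is the main reason overlap-based statistics misrank pairs.
#' @param hub_power Exponent of the degree weighting used when sampling
#'   comorbid module genes (pleiotropy: genes driving comorbid disease
#'   pairs tend to be multifunctional, high-degree, pathway-rich hubs).
#' @param spread_comorbid,spread_confusable,spread_distant Neighbourhood
#'   width multipliers: module genes are sampled from the
#'   `spread * module size` nodes nearest to the seed in the
#'   minimum-spanning-tree (backbone) metric, so smaller values give more
#'   compact, functionally coherent modules.
#' @param min_seed_separation Minimum graph distance between the two
#'   module seeds of a non-comorbid pair.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 2000L, attachment_edges = 2L,
                             n_pathways = 400L, pathway_size_range = c(5L, 25L),
                             n_pairs = 200L, frac_comorbid = 0.5,
                             module_size_range = c(10L, 25L),
                             n_shared_range = c(3L, 6L),
                             rr_comorbid_range = c(1, 10),
                             rr_noncomorbid_range = c(0, 0.9),
                             p_rr_zero = 0.3,
                             frac_scatter = 0.15,
                             frac_confusable = 0.5,
                             hub_power = 1.5,
                             spread_comorbid = 2,
                             spread_confusable = 5,
                             spread_distant = 2,
                             min_seed_separation = 4L,
                             seed = 42L) {
  stopifnot(n_nodes >= 10L, attachment_edges >= 1L,
            frac_comorbid > 0, frac_comorbid < 1,
            pathway_size_range[1] <= pathway_size_range[2],
            module_size_range[1] <= module_size_range[2],
            n_shared_range[1] <= n_shared_range[2],
            n_shared_range[2] <= module_size_range[1],
            rr_comorbid_range[1] >= 1,
            rr_noncomorbid_range[2] < 1,
            p_rr_zero >= 0, p_rr_zero <= 1,
            frac_scatter >= 0, frac_scatter < 1,
            frac_confusable >= 0, frac_confusable <= 1,
            hub_power >= 0, spread_comorbid >= 1, spread_confusable >= 1,
            spread_distant >= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment_edges = as.integer(attachment_edges),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_pairs = as.integer(n_pairs),
                 frac_comorbid = frac_comorbid,
                 module_size_range = as.integer(module_size_range),
                 n_shared_range = as.integer(n_shared_range),
                 rr_comorbid_range = rr_comorbid_range,
                 rr_noncomorbid_range = rr_noncomorbid_range,
                 p_rr_zero = p_rr_zero,
                 frac_scatter = frac_scatter,
                 frac_confusable = frac_confusable,
                 hub_power = hub_power,
                 spread_comorbid = spread_comorbid,
                 spread_confusable = spread_confusable,
                 spread_distant = spread_distant,
                 min_seed_separation = as.integer(min_seed_separation),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset synthetic configurations
#'
#' `"small"` is a fast fixture-scale condition (400 nodes, 40 pairs);
#' `"benchmark"` is the full planted-signal benchmark (2000 nodes, 200
#' pairs).
#'
#' @param preset `"small"` or `"benchmark"`.
#' @param seed Integer master seed.
#' @return A [synthetic_config()].
#' @export
preset_config <- function(preset = c("benchmark", "small"), seed = 42L) {
  preset <- match.arg(preset)
  switch(preset,
         benchmark = synthetic_config(seed = seed),
         small = synthetic_config(n_nodes = 400L, n_pathways = 80L,
                                  n_pairs = 40L, seed = seed))
}

#' Generate a synthetic interactome
#'
#' Connected preferential-attachment graph: nodes arrive one at a time
#' and attach `attachment_edges` edges to existing nodes with probability
#' proportional to degree (no multi-edges), producing the heavy-tailed
#' degree distribution characteristic of PPI networks. Node labels
#' `g00001 ...` sort lexicographically in attachment order.
#'
#' @param cfg A [synthetic_config()].
#' @return A connected undirected [igraph::igraph].
#' @export
generate_interactome <- function(cfg) {
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_nodes, m = cfg$attachment_edges,
                         directed = FALSE, algorithm = "psumtree")
  igraph::V(g)$name <- sprintf("g%05d", seq_len(cfg$n_nodes))
  g
}

#' Generate synthetic pathway gene sets
#'
#' Each pathway is the node set visited by a random walk whose length is
#' drawn uniformly from `pathway_size_range`, so every pathway induces a
#' connected subgraph — emulating the local connectedness of curated
#' pathways on the interactome. Walk start nodes are uniform over the
#' graph unless `seed_nodes` is supplied, in which case walks start from
#' those nodes (recycled), concentrating pathways on a region of interest
#' such as disease modules.
#'
#' @param g A connected interactome.
#' @param cfg A [synthetic_config()].
#' @param seed_nodes Optional character vector of walk start nodes.
#' @return Named list of pathway gene sets (`pw0001 ...`).
#' @export
generate_pathways <- function(g, cfg, seed_nodes = NULL) {
  if (cfg$n_pathways == 0L) return(stats::setNames(list(), character(0)))
  set.seed(cfg$seed + 1L)
  starts <- if (is.null(seed_nodes)) {
    sample(igraph::V(g)$name, cfg$n_pathways, replace = TRUE)
  } else {
    rep_len(seed_nodes, cfg$n_pathways)
  }
  lens <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                 cfg$n_pathways, replace = TRUE)
  sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    walk <- igraph::random_walk(g, start = starts[i], steps = lens[i])
    unique(igraph::V(g)$name[as.integer(walk)])
  })
  stats::setNames(sets, sprintf("pw%04d", seq_len(cfg$n_pathways)))
}

#' Generate a disease-pair dataset with planted comorbidity structure
#'
#' Encodes, statistically rather than deterministically, the premises the
#' classifier is meant to exploit: comorbid diseases tend to share genes,
#' their modules tend to sit close together on the interactome, and the
#' genes driving comorbidity tend to be pleiotropic hubs. Three pair
#' types are planted (module genes are always drawn from the
#' `spread * size` nodes nearest to a random seed in the
#' minimum-spanning-tree backbone metric, with equidistant nodes
#' shuffled):
#'
#' * comorbid pairs (`frac_comorbid`): one compact common neighbourhood
#'   (`spread_comorbid`), `n_shared` forced common genes, gene selection
#'   weighted by degree^`hub_power` (pleiotropy), RR drawn from
#'   `rr_comorbid_range`;
#' * confusable non-comorbid pairs (`frac_confusable` of the negatives):
#'   the same shared-gene construction but over a wide, less coherent
#'   neighbourhood (`spread_confusable`) with uniform gene selection —
#'   pairs that share genes without being clinically comorbid, which is
#'   what makes overlap statistics imperfect predictors;
#' * distant non-comorbid pairs (the rest): disjoint modules around two
#'   seeds at graph distance >= `min_seed_separation`.
#'
#' Non-comorbid RR comes from `rr_noncomorbid_range` with a point mass of
#' `p_rr_zero` at exactly 0. All modules then receive `frac_scatter`
#' association noise (random gene swaps preserving sizes and overlap).
#' Each disease participates in exactly one pair.
#'
#' @param g A connected interactome.
#' @param ann Pathway annotation (part of the generator interface; the
#'   planted signal is purely topological).
#' @param cfg A [synthetic_config()].
#' @return List with `map` (disease-gene map) and `pairs` (data frame
#'   `disease_a, disease_b, rr`, plus a logical `comorbid` column and a
#'   `kind` column recording the planted pair type).
#' @export
generate_disease_dataset <- function(g, ann, cfg) {
  set.seed(cfg$seed + 2L)
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  dmc <- mc_distances(g)  # backbone metric for module locality
  n_com <- round(cfg$n_pairs * cfg$frac_comorbid)
  n_conf <- round((cfg$n_pairs - n_com) * cfg$frac_confusable)
  sizes <- function() sample(seq(cfg$module_size_range[1],
                                 cfg$module_size_range[2]), 2, replace = TRUE)
  # k nodes nearest to seed_node in the backbone metric, ties shuffled
  neighborhood <- function(seed_node, k, avoid = character()) {
    ord <- nodes[order(dmc[seed_node, ], stats::runif(length(nodes)))]
    setdiff(ord, avoid)[seq_len(k)]
  }
  grow_module <- function(seed_node, size, avoid = character(),
                          hub = FALSE, spread = 2) {
    cand <- neighborhood(seed_node, min(ceiling(spread * size),
                                        length(nodes) - length(avoid)), avoid)
    if (hub) sample(cand, size, prob = deg[cand]^cfg$hub_power)
    else sample(cand, size)
  }
  # association noise: swap a fraction of the non-protected genes for
  # uniform random genes outside both modules (sizes and overlap preserved)
  scatter_module <- function(genes, protected, avoid) {
    candidates <- setdiff(genes, protected)
    k <- round(cfg$frac_scatter * length(candidates))
    if (k == 0L) return(genes)
    drop <- sample(candidates, k)
    repl <- sample(setdiff(nodes, union(genes, avoid)), k)
    c(setdiff(genes, drop), repl)
  }
  # two modules with nsh shared genes from one seeded neighbourhood
  shared_pair <- function(sz, nsh, hub, spread) {
    need <- sz[1] + sz[2] - nsh
    pool <- sample(grow_module(sample(nodes, 1), need, hub = hub,
                               spread = spread))
    shared <- pool[seq_len(nsh)]
    rest <- pool[-seq_len(nsh)]
    genes_a <- c(shared, rest[seq_len(sz[1] - nsh)])
    genes_b <- c(shared, setdiff(rest, genes_a))
    genes_a <- scatter_module(genes_a, shared, genes_b)
    genes_b <- scatter_module(genes_b, shared, genes_a)
    list(genes_a, genes_b)
  }
  draw_noncom_rr <- function() {
    if (stats::runif(1) < cfg$p_rr_zero) 0 else {
      stats::runif(1, cfg$rr_noncomorbid_range[1], cfg$rr_noncomorbid_range[2])
    }
  }
  map <- list()
  rows <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    sz <- sizes()
    na_ <- sprintf("D%03d_A", i); nb_ <- sprintf("D%03d_B", i)
    if (i <= n_com) {
      nsh <- sample(seq(cfg$n_shared_range[1], cfg$n_shared_range[2]), 1)
      mods <- shared_pair(sz, nsh, hub = TRUE, spread = cfg$spread_comorbid)
      rr <- stats::runif(1, cfg$rr_comorbid_range[1], cfg$rr_comorbid_range[2])
      kind <- "comorbid"
    } else if (i <= n_com + n_conf) {
      nsh <- sample(seq(cfg$n_shared_range[1], cfg$n_shared_range[2]), 1)
      mods <- shared_pair(sz, nsh, hub = FALSE, spread = cfg$spread_confusable)
      rr <- draw_noncom_rr()
      kind <- "confusable"
    } else {
      seed1 <- sample(nodes, 1)
      d1 <- as.numeric(igraph::distances(g, v = seed1, weights = NA))
      far <- nodes[d1 >= cfg$min_seed_separation]
      if (length(far) == 0L) {
        stop(sprintf("no node at distance >= %d from %s; graph too dense for the non-comorbid construction",
                     cfg$min_seed_separation, seed1), call. = FALSE)
      }
      seed2 <- sample(far, 1)
      genes_a <- grow_module(seed1, sz[1], spread = cfg$spread_distant)
      genes_b <- grow_module(seed2, sz[2], avoid = genes_a,
                             spread = cfg$spread_distant)
      genes_a <- scatter_module(genes_a, character(0), genes_b)
      genes_b <- scatter_module(genes_b, character(0), genes_a)
      mods <- list(genes_a, genes_b)
      rr <- draw_noncom_rr()
      kind <- "distant"
    }
    map[[na_]] <- mods[[1]]
    map[[nb_]] <- mods[[2]]
    rows[[i]] <- data.frame(disease_a = na_, disease_b = nb_, rr = rr,
                            comorbid = kind == "comorbid", kind = kind,
                            stringsAsFactors = FALSE)
  }
  list(map = map, pairs = do.call(rbind, rows))
}

#' Randomize the genes of each disease pair
#'
#' Control transformation: every pair's two gene sets are replaced by
#' uniformly random interactome genes while preserving |genes(A)|,
#' |genes(B)| and |A intersect B| exactly, destroying module locality but
#' keeping the per-pair gene-count topology. Used to show that the
#' classifier's signal comes from where the genes sit on the interactome,
#' not from how many there are.
#'
#' @param map Disease-gene map.
#' @param pairs Data frame with `disease_a`, `disease_b`.
#' @param g The interactome supplying replacement genes.
#' @param seed Integer seed.
#' @return A new disease-gene map with the same disease names.
#' @export
randomize_pair_genes <- function(map, pairs, g, seed = 1L) {
  set.seed(seed)
  nodes <- igraph::V(g)$name
  out <- map
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$disease_a[i]; b <- pairs$disease_b[i]
    ga <- map[[a]]; gb <- map[[b]]
    if (is.null(ga) || is.null(gb)) {
      stop(sprintf("pair %d references a disease missing from the map", i),
           call. = FALSE)
    }
    nsh <- length(intersect(ga, gb))
    total <- length(ga) + length(gb) - nsh
    if (total > length(nodes)) stop("module larger than interactome", call. = FALSE)
    draw <- sample(nodes, total)
    shared <- draw[seq_len(nsh)]
    rest <- if (nsh > 0L) draw[-seq_len(nsh)] else draw
    out[[a]] <- c(shared, rest[seq_len(length(ga) - nsh)])
    out[[b]] <- c(shared, setdiff(rest, out[[a]]))
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes `edges.tsv` (edge list), `pathways.gmt`, `disease_genes.tsv`
#' and `comorbidity.tsv` in the package's plain-text interchange formats.
#'
#' @param g Interactome.
#' @param ann Pathway annotation.
#' @param map Disease-gene map.
#' @param pairs Pair table.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(g, ann, map, pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(g, file.path(dir, "edges.tsv"))
  write_gmt(ann, file.path(dir, "pathways.gmt"))
  dg <- data.frame(disease = rep(names(map), lengths(map)),
                   gene = unlist(map, use.names = FALSE))
  utils::write.table(dg, file.path(dir, "disease_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(pairs[, c("disease_a", "disease_b", "rr")],
                     file.path(dir, "comorbidity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
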
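#' Filter genomes on assembly quality
#'
#' Genomes with contamination above `max_contamination` or completion
#' below `min_completion` are removed; boundary values survive (the
#' removal rule uses strict inequalities).  Defaults (completion >= 90%,
#' contamination <= 5%) are the usual gate for entering the species
#' graph.
#'
#' @param quality Tibble as from [read_quality_table()].
#' @param genome_ids Optional character vector of genomes that must be
#'   covered; a genome without a quality record is an error, never a
#'   silent default.
#' @param min_completion Minimum completion percent kept.
#' @param max_contamination Maximum contamination percent kept.
#' @return The filtered quality tibble (rows that pass).
#' @export
quality_filter <- function(quality, genome_ids = NULL,
                           min_completion = 90, max_contamination = 5) {
  stopifnot(all(c("genome_id", "completion", "contamination") %in%
                  names(quality)))
  if (!is.null(genome_ids)) {
    missing <- setdiff(genome_ids, quality$genome_id)
    if (length(missing)) {
      abort(sprintf("no quality record for genome(s): %s",
                    paste(missing, collapse = ", ")))
    }
    quality <- quality %>% filter(.data$genome_id %in% genome_ids)
  }
  quality %>%
    filter(.data$completion >= min_completion,
           .data$contamination <= max_contamination)
}

#' Build the thresholded species graph
#'
#' Nodes are the quality-filtered genomes; an edge joins two genomes iff
#' their Mash distance is at most `max_dist` (default 0.06, i.e. a 94%
#' ANI cutoff, a usual species boundary).  Edge weight is the ANI-like
#' similarity `1 - d`.
#'
#' @param dist Symmetric distance matrix with genome ids as dimnames.
#' @param kept_ids Genomes to include (must be a subset of the matrix
#'   names); defaults to all.
#' @param max_dist Distance threshold; pairs with `d <= max_dist` get an
#'   edge.
#' @return Undirected `igraph` with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
build_species_graph <- function(dist, kept_ids = NULL, max_dist = 0.06) {
  stopifnot(is.matrix(dist), !is.null(rownames(dist)))
  if (is.null(kept_ids)) kept_ids <- rownames(dist)
  if (!all(kept_ids %in% rownames(dist))) {
    abort("kept_ids must be a subset of the distance matrix names")
  }
  d <- dist[kept_ids, kept_ids, drop = FALSE]
  hit <- which(upper.tri(d) & d <= max_dist, arr.ind = TRUE)
  edges <- tibble(from = kept_ids[hit[, 1]], to = kept_ids[hit[, 2]],
                  weight = 1 - d[hit])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = tibble(name = kept_ids))
}

#' Species clusters by Louvain community detection
#'
#' Runs weighted Louvain modularity optimisation (resolution 1) on the
#' species graph and returns one species-cluster label per genome.
#' Labels are renumbered canonically — `MICGC1` is the largest cluster,
#' ties broken by the lexicographically smallest member — so the output
#' is stable under genome input order.  Isolated genomes become
#' singleton clusters.
#'
#' @param graph Species graph from [build_species_graph()].
#' @param seed Integer seed controlling Louvain's node visit order.
#' @return Tibble with columns `genome_id`, `micgc`.
#' @export
louvain_partition <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) == 0L) {
    return(tibble(genome_id = character(), micgc = character()))
  }
  w <- if (igraph::ecount(graph) > 0) igraph::E(graph)$weight else NULL
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(graph, weights = w))
  })
  tb <- tibble(genome_id = names(memb), comm = as.integer(memb))
  ord <- tb %>%
    group_by(.data$comm) %>%
    summarise(sz = n(), minid = min(.data$genome_id), .groups = "drop") %>%
    arrange(desc(.data$sz), .data$minid)
  label_map <- setNames(sprintf("MICGC%d", seq_len(nrow(ord))),
                        as.character(ord$comm))
  tb %>%
    transmute(genome_id = .data$genome_id,
              micgc = unname(label_map[as.character(.data$comm)])) %>%
    arrange(.data$micgc, .data$genome_id)
}

# Redistribute negative NJ branch lengths: clamp to zero and add the
# deficit to the sibling branch, preserving leaf-to-leaf path lengths
# as far as possible.
.fix_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou–Nei neighbor joining, exact on additive matrices.
#' Negative branch lengths (possible on non-additive input) are clamped
#' to zero with the deficit moved to the sibling branch.  The two-taxon
#' case splits the distance evenly.
#'
#' @param dist Symmetric distance matrix with zero diagonal and ids as
#'   dimnames.
#' @param ids Optional subset of taxa (>= 2).
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dist, ids = NULL) {
  stopifnot(is.matrix(dist), !is.null(rownames(dist)))
  if (is.null(ids)) ids <- rownames(dist)
  if (length(ids) < 2) abort("need at least 2 taxa for a tree")
  d <- dist[ids, ids, drop = FALSE]
  if (length(ids) == 2L) {
    tree <- structure(
      list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
           edge.length = rep(d[1, 2] / 2, 2),
           tip.label = ids, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(tree)
  }
  .fix_negative_branches(ape::nj(d))
}
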
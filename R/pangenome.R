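#' Family-by-genome presence/absence matrix
#'
#' Binarises gene counts: entry is 1 iff the family has at least one
#' gene (paralogs included) in the genome.  Pangenomes are only computed
#' for species clusters with at least `min_genomes` genomes (default
#' 15); smaller inputs are refused unless `allow_fewer = TRUE`.
#'
#' @param family_assignment Tibble with `gene_id`, `genome_id`,
#'   `family_id`.
#' @param min_genomes Minimum number of genomes (default 15).
#' @param allow_fewer Override the minimum (logged).
#' @return Integer matrix, families (sorted ids) x genomes (sorted ids).
#' @export
presence_absence <- function(family_assignment, min_genomes = 15,
                             allow_fewer = FALSE) {
  stopifnot(all(c("genome_id", "family_id") %in% names(family_assignment)))
  n_genomes <- dplyr::n_distinct(family_assignment$genome_id)
  if (n_genomes < min_genomes) {
    if (!allow_fewer) {
      abort(sprintf(
        paste0("only %d genomes; pangenomes are computed for clusters of ",
               "at least %d genomes (set allow_fewer = TRUE to override)"),
        n_genomes, min_genomes))
    }
    inform(sprintf("proceeding with %d genomes (< %d) on explicit override",
                   n_genomes, min_genomes))
  }
  tab <- table(family_assignment$family_id, family_assignment$genome_id)
  m <- matrix(as.integer(tab > 0), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Build the pangenome graph
#'
#' Nodes are gene families; an edge's weight is the number of genomes in
#' which genes of the two families are immediate neighbours on a contig.
#' Genes are sorted per contig by start (ties by gene_id); circular
#' contigs close the loop (last gene adjacent to first); each genome
#' contributes at most 1 to any edge weight; tandem copies of the same
#' family produce no self-loop — neighbourhood information is between
#' families.
#'
#' @param genes Tibble with `gene_id`, `genome_id`, `contig_id`,
#'   `start` and optionally a logical `circular` column (default
#'   `FALSE`).
#' @param family_assignment Tibble mapping `gene_id` to `family_id`;
#'   every gene must be covered.
#' @return Undirected `igraph` with one vertex per family and edge
#'   attribute `weight`.
#' @export
build_pangenome_graph <- function(genes, family_assignment) {
  stopifnot(all(c("gene_id", "genome_id", "contig_id", "start") %in%
                  names(genes)))
  df <- genes %>%
    left_join(family_assignment %>% select("gene_id", "family_id"),
              by = "gene_id")
  if (anyNA(df$family_id)) {
    abort(sprintf("gene without family assignment: %s",
                  df$gene_id[is.na(df$family_id)][1]))
  }
  if (!"circular" %in% names(df)) df$circular <- FALSE
  edges <- df %>%
    arrange(.data$genome_id, .data$contig_id, .data$start, .data$gene_id) %>%
    group_by(.data$genome_id, .data$contig_id) %>%
    reframe({
      f <- .data$family_id
      a <- f[-length(f)]
      b <- f[-1]
      if (isTRUE(.data$circular[1]) && length(f) >= 2) {
        a <- c(a, f[length(f)])
        b <- c(b, f[1])
      }
      tibble(fa = pmin(a, b), fb = pmax(a, b))
    }) %>%
    filter(.data$fa != .data$fb) %>%
    distinct(.data$genome_id, .data$fa, .data$fb) %>%
    count(.data$fa, .data$fb, name = "weight")
  fams <- sort(unique(family_assignment$family_id))
  igraph::graph_from_data_frame(
    edges %>% rename(from = "fa", to = "fb"),
    directed = FALSE, vertices = tibble(name = fams))
}

#' Strict core/variable components
#'
#' The exact partition: a family is strict core iff present in every
#' genome of the matrix; everything else is variable.
#'
#' @param pa Presence/absence matrix from [presence_absence()].
#' @return Tibble with `family_id` and `component`
#'   (`"core"`/`"variable"`).
#' @export
strict_components <- function(pa) {
  stopifnot(is.matrix(pa))
  tibble(
    family_id = rownames(pa),
    component = unname(ifelse(rowSums(pa) == ncol(pa), "core", "variable"))
  )
}

#' Partition gene families into persistent, shell and cloud
#'
#' Fits a three-component multivariate Bernoulli mixture to the
#' presence/absence matrix by EM, smoothed by a Markov random field on
#' the pangenome graph under a mean-field approximation: in the E-step
#' each family's component scores are boosted by
#' `beta * sum_j (w_ij / N) * r_jk` over its graph neighbours, so
#' neighbouring families are pulled toward the same partition.  At
#' `beta = 0` this reduces to standard EM on the plain mixture, whose
#' log-likelihood is guaranteed non-decreasing.  Components are
#' relabelled by decreasing mean presence probability as
#' persistent/shell/cloud; a family's label is the argmax of its
#' responsibilities, ties resolved toward the higher-presence component.
#'
#' @param pa Presence/absence matrix (families x genomes).
#' @param graph Optional pangenome graph from
#'   [build_pangenome_graph()]; `NULL` or an empty graph gives the plain
#'   mixture.
#' @param beta MRF coupling strength (>= 0, default 0.5).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the maximum responsibility change
#'   (default 1e-6).
#' @param eps_floor Clamp for the Bernoulli parameters, keeping them in
#'   `[eps_floor, 1 - eps_floor]` (default 1e-3) to avoid degenerate
#'   log-likelihoods.
#' @param random_init Initialise the Bernoulli parameters uniformly at
#'   random instead of the deterministic 0.9/0.5/0.1 profile.
#' @param seed Seed for `random_init`.
#' @return Object of class `pangenome_partition` with elements `pi`,
#'   `eps`, `responsibilities`, `partition` (tibble), `objective`
#'   (per-iteration penalised log-likelihood), `iterations`,
#'   `converged`, `beta`.
#' @export
partition_em <- function(pa, graph = NULL, beta = 0.5, max_iter = 500,
                         tol = 1e-6, eps_floor = 1e-3,
                         random_init = FALSE, seed = 1L) {
  stopifnot(is.matrix(pa), beta >= 0, eps_floor > 0, eps_floor < 0.5)
  x <- pa
  storage.mode(x) <- "double"
  M <- nrow(x); N <- ncol(x); K <- 3L
  if (M < K) abort("need at least 3 families to fit 3 components")

  W <- NULL
  if (!is.null(graph) && igraph::ecount(graph) > 0) {
    ed <- igraph::as_data_frame(graph, what = "edges")
    ed <- ed[ed$from %in% rownames(x) & ed$to %in% rownames(x) &
               ed$from != ed$to, , drop = FALSE]
    if (nrow(ed)) {
      i <- match(ed$from, rownames(x))
      j <- match(ed$to, rownames(x))
      w <- if (!is.null(ed$weight)) ed$weight else rep(1, nrow(ed))
      W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(w, 2),
                                dims = c(M, M))
    }
  }

  eps <- matrix(rep(c(0.9, 0.5, 0.1), N), nrow = K)
  if (random_init) {
    eps <- withr::with_seed(seed, {
      matrix(runif(K * N, eps_floor, 1 - eps_floor), nrow = K)
    })
  }
  prop <- rep(1 / K, K)
  r <- matrix(1 / K, M, K)
  obj <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # E-step: log responsibilities from mixture likelihood + field term
    logB <- x %*% t(log(eps)) + (1 - x) %*% t(log1p(-eps))
    S <- sweep(logB, 2, log(prop), "+")
    if (!is.null(W) && beta > 0) {
      S <- S + beta * as.matrix(W %*% r) / N
    }
    mx <- pmax(S[, 1], S[, 2], S[, 3])
    P <- exp(S - mx)
    rs <- rowSums(P)
    ll <- sum(mx + log(rs))
    if (!is.finite(ll)) {
      abort(sprintf("non-finite objective at iteration %d", it))
    }
    r_new <- P / rs
    delta <- max(abs(r_new - r))
    r <- r_new
    obj <- c(obj, ll)

    # M-step
    ck <- colSums(r)
    prop <- pmax(ck / M, 1e-12)
    prop <- prop / sum(prop)
    eps <- sweep(t(r) %*% x, 1, ck, "/")
    eps <- pmin(pmax(eps, eps_floor), 1 - eps_floor)

    if (delta < tol) { converged <- TRUE; break }
    if (it > 1 && abs(obj[it] - obj[it - 1]) < tol * abs(obj[it])) {
      converged <- TRUE; break
    }
  }

  # canonical relabeling: persistent has the highest mean presence
  parts <- c("persistent", "shell", "cloud")
  ord <- order(-rowMeans(eps))
  r_ord <- r[, ord, drop = FALSE]
  colnames(r_ord) <- parts
  rownames(r_ord) <- rownames(x)
  eps_ord <- eps[ord, , drop = FALSE]
  dimnames(eps_ord) <- list(parts, colnames(x))
  prop_ord <- setNames(prop[ord], parts)
  z <- parts[max.col(r_ord, ties.method = "first")]
  partition <- tibble(
    family_id = rownames(x),
    partition = factor(z, levels = parts),
    n_genomes_present = as.integer(rowSums(pa))
  )
  structure(
    list(pi = prop_ord, eps = eps_ord, responsibilities = r_ord,
         partition = partition, objective = obj,
         iterations = length(obj), converged = converged, beta = beta,
         n_families = M, n_genomes = N),
    class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cnt <- table(x$partition$partition)
  cat(sprintf(
    paste0("<pangenome_partition> %d families x %d genomes | ",
           "persistent %d, shell %d, cloud %d\n",
           "beta = %g, %d iteration(s), %sconverged, ",
           "final objective %.3f\n"),
    x$n_families, x$n_genomes,
    cnt[["persistent"]], cnt[["shell"]], cnt[["cloud"]],
    x$beta, x$iterations, if (x$converged) "" else "NOT ",
    x$objective[length(x$objective)]))
  invisible(x)
}

#' @describeIn partition_em One row per family: partition label,
#'   genomes present and the three responsibilities.
#' @param x A `pangenome_partition` object.
#' @param ... Unused.
#' @export
tidy.pangenome_partition <- function(x, ...) {
  bind_cols(
    x$partition,
    as_tibble(x$responsibilities) %>%
      rename(r_persistent = "persistent", r_shell = "shell",
             r_cloud = "cloud")
  )
}

#' @describeIn partition_em One-row model summary.
#' @export
glance.pangenome_partition <- function(x, ...) {
  cnt <- table(x$partition$partition)
  tibble(
    n_families = x$n_families, n_genomes = x$n_genomes,
    n_persistent = as.integer(cnt[["persistent"]]),
    n_shell = as.integer(cnt[["shell"]]),
    n_cloud = as.integer(cnt[["cloud"]]),
    beta = x$beta, iterations = x$iterations, converged = x$converged,
    objective = x$objective[length(x$objective)]
  )
}

#' Gene and family counts per pangenome partition
#'
#' Mirrors the per-partition summary tables of a pangenome analysis:
#' for each of persistent/shell/cloud, the number of families and the
#' number of member genes.  Totals equal the global counts.
#'
#' @param model A `pangenome_partition`.
#' @param family_assignment Tibble with `gene_id`, `family_id` giving
#'   the gene-level membership.
#' @return Tibble with `partition`, `n_families`, `n_genes`.
#' @export
pangenome_summary <- function(model, family_assignment) {
  stopifnot(inherits(model, "pangenome_partition"))
  gene_counts <- family_assignment %>% count(.data$family_id, name = "n_genes")
  model$partition %>%
    left_join(gene_counts, by = "family_id") %>%
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) %>%
    group_by(.data$partition, .drop = FALSE) %>%
    summarise(n_families = n(), n_genes = sum(.data$n_genes),
              .groups = "drop")
}
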
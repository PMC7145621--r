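#' Scoring parameters for RGP detection
#'
#' Shell/cloud genes score `variable_gain` (+1), persistent genes score
#' `persistent_penalty` (-3); a region must reach `min_score` (4) and
#' span more than `min_length` (3000 bp, strict) to be reported.  The
#' defaults tolerate one interspersed persistent gene inside a strong
#' variable region while two consecutive ones break it.
#'
#' @param variable_gain Score per shell/cloud gene (> 0).
#' @param persistent_penalty Score per persistent gene (< 0).
#' @param min_score Minimum region score.
#' @param min_length Minimum genomic span in bp (strict).
#' @return List of class `rgp_scoring`.
#' @export
rgp_scoring <- function(variable_gain = 1, persistent_penalty = -3,
                        min_score = 4, min_length = 3000) {
  stopifnot(variable_gain > 0, persistent_penalty < 0, min_length > 0)
  structure(list(variable_gain = variable_gain,
                 persistent_penalty = persistent_penalty,
                 min_score = min_score, min_length = min_length),
            class = "rgp_scoring")
}

#' Project pangenome partitions onto genomes
#'
#' Tags every gene with the partition label of its family and orders
#' genes by coordinate within each contig, giving the per-contig label
#' sequence that the RGP scanner consumes.
#'
#' @param genes Tibble with `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end` and optionally `circular`/`contig_length`.
#' @param family_assignment Tibble mapping `gene_id` to `family_id`.
#' @param model A `pangenome_partition`, or any data frame with
#'   `family_id` and `partition` columns; every family must be labelled.
#' @return `genes` with `family_id` and `partition` columns, sorted by
#'   genome, contig, start, gene_id.
#' @export
project_partitions <- function(genes, family_assignment, model) {
  labels <- if (inherits(model, "pangenome_partition")) {
    model$partition
  } else {
    as_tibble(model)
  }
  stopifnot(all(c("family_id", "partition") %in% names(labels)))
  df <- genes %>%
    left_join(family_assignment %>% select("gene_id", "family_id"),
              by = "gene_id") %>%
    left_join(labels %>% select("family_id", "partition"),
              by = "family_id")
  if (anyNA(df$family_id)) {
    abort(sprintf("gene without family: %s",
                  df$gene_id[is.na(df$family_id)][1]))
  }
  if (anyNA(df$partition)) {
    abort(sprintf("family without partition label: %s",
                  df$family_id[is.na(df$partition)][1]))
  }
  df %>% arrange(.data$genome_id, .data$contig_id, .data$start,
                 .data$gene_id)
}

# Core scan: walk genes accumulating scores; a segment opens at a
# variable gene, closes when the running score drops to <= 0 (or the
# walk ends), and the candidate is the prefix achieving the maximum
# score.  `limit` caps segment length (used by the circular
# doubled-walk).  Returns list of c(start_idx, end_idx, score).
.scan_segments <- function(sc, variable, limit = length(sc)) {
  n <- length(sc)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!variable[i]) { i <- i + 1L; next }
    run <- 0
    best <- -Inf
    best_j <- i - 1L
    j <- i
    while (j <= n && (j - i) < limit) {
      run <- run + sc[j]
      if (run > best) { best <- run; best_j <- j }
      if (run <= 0) break
      j <- j + 1L
    }
    segs[[length(segs) + 1L]] <- c(i, best_j, best)
    i <- max(j, best_j) + 1L
  }
  segs
}

.scan_contig <- function(labels, starts, ends, scoring, circular,
                         contig_length) {
  n <- length(labels)
  variable <- labels %in% c("shell", "cloud")
  sc <- ifelse(variable, scoring$variable_gain, scoring$persistent_penalty)
  if (!circular) {
    segs <- .scan_segments(sc, variable)
    segs <- lapply(segs, function(s) {
      list(idx = s[1]:s[2], score = s[3], wrapped = FALSE)
    })
  } else {
    # doubled walk so regions crossing the origin are found once
    segs0 <- .scan_segments(rep(sc, 2), rep(variable, 2), limit = n)
    segs0 <- Filter(function(s) s[1] <= n, segs0)
    segs <- lapply(segs0, function(s) {
      idx <- ((s[1]:s[2]) - 1L) %% n + 1L
      list(idx = idx, score = s[3], wrapped = s[2] > n)
    })
  }
  rows <- lapply(segs, function(s) {
    idx <- s$idx
    span <- if (s$wrapped) {
      (contig_length - starts[idx[1]]) + ends[idx[length(idx)]]
    } else {
      ends[idx[length(idx)]] - starts[idx[1]]
    }
    tibble(start = starts[idx[1]], end = ends[idx[length(idx)]],
           span = span, score = s$score, n_genes = length(idx),
           idx = list(idx))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out <- out %>% filter(.data$score >= scoring$min_score,
                        .data$span > scoring$min_length)
  if (circular && nrow(out) > 1L) {
    # a region found once in the doubled walk can reappear shifted by n;
    # drop later segments that reuse genes already claimed (the filter
    # above runs first, so a rejected prefix cannot mask a wrapped
    # region that covers the same genes)
    taken <- logical(n)
    keep <- vapply(out$idx, function(ii) {
      if (any(taken[ii])) return(FALSE)
      taken[ii] <<- TRUE
      TRUE
    }, logical(1))
    out <- out[keep, ]
  }
  out
}

#' Detect regions of genomic plasticity
#'
#' Score-based scan over the partition-labelled gene order of each
#' contig: maximal runs of shell/cloud genes (tolerating isolated
#' persistent genes per the scoring) that reach the minimum score and
#' span more than the minimum length are reported as RGPs — candidate
#' genomic islands / horizontally transferred regions.  Circular
#' contigs are scanned with a doubled walk so regions crossing the
#' origin are found once; for those, `end < start` and `span` carries
#' the true genomic extent.
#'
#' @param projected Output of [project_partitions()].
#' @param scoring An [rgp_scoring()] object.
#' @return Tibble with one row per RGP: `rgp_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `span`, `n_genes`, `score`, and
#'   list-columns `genes` (ordered gene ids) and `families` (family-id
#'   set, for cross-strain matching).
#' @export
detect_rgps <- function(projected, scoring = rgp_scoring()) {
  need <- c("gene_id", "genome_id", "contig_id", "start", "end",
            "partition")
  stopifnot(all(need %in% names(projected)))
  df <- projected %>%
    arrange(.data$genome_id, .data$contig_id, .data$start, .data$gene_id)
  if (!"circular" %in% names(df)) df$circular <- FALSE
  groups <- df %>% group_by(.data$genome_id, .data$contig_id)
  keys <- dplyr::group_keys(groups)
  out <- lapply(seq_len(nrow(keys)), function(gi) {
    sub <- df %>%
      filter(.data$genome_id == keys$genome_id[gi],
             .data$contig_id == keys$contig_id[gi])
    circ <- isTRUE(sub$circular[1])
    clen <- if ("contig_length" %in% names(sub) &&
                is.finite(sub$contig_length[1])) {
      sub$contig_length[1]
    } else {
      max(sub$end)
    }
    segs <- .scan_contig(as.character(sub$partition), sub$start, sub$end,
                         scoring, circ, clen)
    if (nrow(segs) == 0L) return(NULL)
    segs %>%
      mutate(genome_id = keys$genome_id[gi],
             contig_id = keys$contig_id[gi],
             genes = lapply(.data$idx, function(ii) sub$gene_id[ii]),
             families = lapply(.data$idx, function(ii) {
               sort(unique(sub$family_id[ii]))
             })) %>%
      select(-"idx")
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(rgp_id = character(), genome_id = character(),
                  contig_id = character(), start = integer(),
                  end = integer(), span = integer(), n_genes = integer(),
                  score = double(), genes = list(), families = list()))
  }
  out %>%
    arrange(.data$genome_id, .data$contig_id, .data$start) %>%
    group_by(.data$genome_id) %>%
    mutate(rgp_id = sprintf("%s_RGP_%03d", .data$genome_id,
                            row_number())) %>%
    ungroup() %>%
    select("rgp_id", "genome_id", "contig_id", "start", "end", "span",
           "n_genes", "score", "genes", "families")
}

#' Match an RGP against RGPs of other strains
#'
#' For each candidate RGP, the percentage of the query's gene families
#' that are also present in the candidate
#' (`100 * |shared| / |families(query)|`).  Candidates are typically
#' restricted to genomes of the same species cluster; pass `clusters`
#' to apply that restriction here.
#'
#' @param rgps RGP tibble from [detect_rgps()].
#' @param query_id `rgp_id` of the query.
#' @param clusters Optional tibble with `genome_id`, `micgc`; when
#'   given, candidates are limited to genomes sharing the query's
#'   cluster.
#' @return Tibble with `target_rgp`, `genome_id`, `shared_families`,
#'   `shared_family_percent`, sorted by decreasing percentage then
#'   target id.
#' @export
match_rgps <- function(rgps, query_id, clusters = NULL) {
  q <- rgps %>% filter(.data$rgp_id == query_id)
  if (nrow(q) != 1L) abort(sprintf("unknown rgp_id: %s", query_id))
  qf <- q$families[[1]]
  if (length(qf) == 0L) abort("query RGP has an empty family set")
  cand <- rgps %>% filter(.data$rgp_id != query_id)
  if (!is.null(clusters)) {
    qc <- clusters$micgc[match(q$genome_id, clusters$genome_id)]
    same <- clusters$genome_id[clusters$micgc == qc]
    cand <- cand %>% filter(.data$genome_id %in% same)
  }
  cand %>%
    mutate(shared_families = vapply(.data$families, function(f) {
      length(intersect(qf, f))
    }, integer(1)),
    shared_family_percent = 100 * .data$shared_families / length(qf)) %>%
    select(target_rgp = "rgp_id", "genome_id", "shared_families",
           "shared_family_percent") %>%
    arrange(desc(.data$shared_family_percent), .data$target_rgp)
}

#' Cross-link RGPs with external functional annotations
#'
#' Consumes externally produced gene-level feature tables (AMR,
#' virulence, secretion systems, biosynthetic clusters, integrons, ...)
#' and counts flagged genes per RGP and category.  This package does
#' not predict any of these categories itself.
#'
#' @param rgps RGP tibble from [detect_rgps()].
#' @param feature_table Tibble with `gene_id`, `category`, or `NULL`
#'   (no annotations: all counts are zero and the result has no rows).
#' @param known_genes Optional character vector of valid gene ids; table
#'   rows referencing unknown genes are skipped with a warning.
#' @return Tibble with `rgp_id`, `category`, `n` — the full grid of
#'   RGPs x categories seen in the table, zero-filled.
#' @export
rgp_annotation_crosslinks <- function(rgps, feature_table = NULL,
                                      known_genes = NULL) {
  empty <- tibble(rgp_id = character(), category = character(),
                  n = integer())
  if (is.null(feature_table) || nrow(feature_table) == 0L) return(empty)
  stopifnot(all(c("gene_id", "category") %in% names(feature_table)))
  if (!is.null(known_genes)) {
    bad <- !feature_table$gene_id %in% known_genes
    if (any(bad)) {
      warn(sprintf("%d annotation row(s) reference unknown genes; skipped",
                   sum(bad)))
      feature_table <- feature_table[!bad, ]
    }
  }
  if (nrow(rgps) == 0L || nrow(feature_table) == 0L) return(empty)
  long <- rgps %>%
    select("rgp_id", "genes") %>%
    tidyr::unnest_longer("genes", values_to = "gene_id") %>%
    inner_join(feature_table, by = "gene_id",
               relationship = "many-to-many") %>%
    count(.data$rgp_id, .data$category)
  tidyr::expand_grid(rgp_id = rgps$rgp_id,
                     category = sort(unique(feature_table$category))) %>%
    left_join(long, by = c("rgp_id", "category")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Write RGP intervals as BED
#'
#' 0-based half-open intervals, one line per RGP (two lines for a
#' region crossing the origin of a circular contig).
#'
#' @param rgps RGP tibble from [detect_rgps()].
#' @param path Output file.
#' @param contig_lengths Optional tibble with `genome_id`, `contig_id`,
#'   `length`, needed to split origin-crossing regions.
#' @return `path`, invisibly.
#' @export
write_rgp_bed <- function(rgps, path, contig_lengths = NULL) {
  rows <- lapply(seq_len(nrow(rgps)), function(i) {
    r <- rgps[i, ]
    if (r$end > r$start) {
      tibble(chrom = r$contig_id, start = r$start, end = r$end,
             name = r$rgp_id, score = r$score)
    } else {
      clen <- NA_real_
      if (!is.null(contig_lengths)) {
        m <- contig_lengths$genome_id == r$genome_id &
          contig_lengths$contig_id == r$contig_id
        if (any(m)) clen <- contig_lengths$length[which(m)[1]]
      }
      if (!is.finite(clen)) clen <- r$start + r$span - r$end
      tibble(chrom = rep(r$contig_id, 2),
             start = c(r$start, 0), end = c(clen, r$end),
             name = paste0(r$rgp_id, c("_a", "_b")),
             score = rep(r$score, 2))
    }
  })
  tbl <- bind_rows(rows)
  readr::write_tsv(tbl, path, col_names = FALSE)
  invisible(path)
}
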
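suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dna_genome <- function(id, seq, circular = FALSE) {
  genome_record(id, tibble(contig_id = "chr1", sequence = seq,
                           circular = circular))
}

# Exact Jaccard index of the full canonical k-mer sets, by direct
# enumeration (independent of the sketch path).
brute_jaccard <- function(x, y, k = 18) {
  kx <- unique(canonical_kmers(x, k))
  ky <- unique(canonical_kmers(y, k))
  length(intersect(kx, ky)) / length(unique(c(kx, ky)))
}

# Gotoh local alignment with exhaustive enumeration of ALL optimal
# alignments.  Returns the optimal score and the set of
# (identity, coverage_a, coverage_b) rows realised by optimal
# alignments; identity counts gap columns in the denominator.
oracle_local_align <- function(a, b, open = 11, ext = 1) {
  sm <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sm[av[i], bv[j]]
    H[i + 1, j + 1] <- s + max(0, H[i, j], E[i, j], F_[i, j])
    E[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, E[i, j + 1] - ext)
    F_[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, F_[i + 1, j] - ext)
  }
  best <- max(H)
  if (best <= 0) return(list(score = 0, stats = NULL))
  out <- list()
  walk <- function(i, j, state, cols, matches, ei, ej) {
    if (state == "H") {
      cols <- cols + 1
      matches <- matches + (av[i] == bv[j])
      v <- H[i + 1, j + 1] - sm[av[i], bv[j]]
      if (abs(v) < 1e-9) {
        out[[length(out) + 1]] <<- c(matches / cols,
                                     (ei - i + 1) / n, (ej - j + 1) / m)
      }
      if (i > 1 && j > 1) {
        if (abs(H[i, j] - v) < 1e-9) walk(i - 1, j - 1, "H", cols, matches, ei, ej)
        if (abs(E[i, j] - v) < 1e-9) walk(i - 1, j - 1, "E", cols, matches, ei, ej)
        if (abs(F_[i, j] - v) < 1e-9) walk(i - 1, j - 1, "F", cols, matches, ei, ej)
      }
    } else if (state == "E") {
      cols <- cols + 1
      v <- E[i + 1, j + 1]
      if (i > 1) {
        if (abs(H[i, j + 1] - open - ext - v) < 1e-9) walk(i - 1, j, "H", cols, matches, ei, ej)
        if (abs(E[i, j + 1] - ext - v) < 1e-9) walk(i - 1, j, "E", cols, matches, ei, ej)
      }
    } else {
      cols <- cols + 1
      v <- F_[i + 1, j + 1]
      if (j > 1) {
        if (abs(H[i + 1, j] - open - ext - v) < 1e-9) walk(i, j - 1, "H", cols, matches, ei, ej)
        if (abs(F_[i + 1, j] - ext - v) < 1e-9) walk(i, j - 1, "F", cols, matches, ei, ej)
      }
    }
  }
  ends <- which(abs(H - best) < 1e-9, arr.ind = TRUE)
  for (r in seq_len(nrow(ends))) {
    i <- ends[r, 1] - 1
    j <- ends[r, 2] - 1
    walk(i, j, "H", 0, 0, i, j)
  }
  list(score = best, stats = unique(do.call(rbind, out)))
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# TRUE iff align_pair's stats coincide with one of the oracle's optimal
# alignments (and the score matches).
align_pair_matches_oracle <- function(a, b) {
  o <- oracle_local_align(a, b)
  st <- align_pair(a, b)
  if (is.null(o$stats)) return(st$score <= 0)
  if (abs(o$score - st$score) > 1e-9) return(FALSE)
  any(apply(o$stats, 1, function(r) {
    all(abs(r - c(st$identity, st$coverage_a, st$coverage_b)) < 1e-9)
  }))
}

# All set partitions of 1..n (Bell-number enumeration), as lists of
# integer membership vectors.  Used to maximise modularity by brute
# force on small graphs.
all_set_partitions <- function(n) {
  res <- list()
  memb <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      res[[length(res) + 1]] <<- memb[seq_len(n)]
      return(invisible())
    }
    for (b in seq_len(k + 1)) {
      memb[i] <<- b
      recurse(i + 1, max(k, b))
    }
  }
  recurse(1, 0)
  res
}

# Independent segment oracle: for every possible segment start (first
# variable gene after the previous segment), enumerate all prefix
# windows via cumulative sums, close at the first prefix dropping to
# <= 0, and take the maximum-scoring prefix.  Returns kept segments as
# list(idx, score) after score/span filtering.
oracle_rgp_segments <- function(labels, starts, ends, scoring) {
  variable <- labels %in% c("shell", "cloud")
  sc <- ifelse(variable, scoring$variable_gain, scoring$persistent_penalty)
  n <- length(sc)
  segs <- list()
  i <- 1
  while (i <= n) {
    if (!variable[i]) { i <- i + 1; next }
    cs <- cumsum(sc[i:n])
    closed <- which(cs <= 0)
    lastj <- if (length(closed)) i + closed[1] - 1 else n
    prefix <- cs[seq_len(lastj - i + 1)]
    best <- max(prefix)
    bj <- i + which.max(prefix) - 1
    segs[[length(segs) + 1]] <- list(idx = i:bj, score = best)
    i <- max(lastj, bj) + 1
  }
  Filter(function(s) {
    span <- ends[s$idx[length(s$idx)]] - starts[s$idx[1]]
    s$score >= scoring$min_score && span > scoring$min_length
  }, segs)
}

# Build a projected one-contig gene table from partition labels with
# controllable per-gene lengths and gaps.
make_labeled_contig <- function(labels, gene_len = 1000, gap = 100,
                                genome = "g1", contig = "c1",
                                circular = FALSE) {
  n <- length(labels)
  gene_len <- rep_len(gene_len, n)
  gap <- rep_len(gap, n)
  starts <- cumsum(c(0, (gene_len + gap)[-n]))
  tibble(
    gene_id = sprintf("%s_%03d", genome, seq_len(n)),
    genome_id = genome, contig_id = contig,
    start = starts, end = starts + gene_len, strand = "+",
    family_id = sprintf("F%03d", seq_len(n)),
    partition = factor(labels, levels = c("persistent", "shell", "cloud")),
    circular = circular,
    contig_length = starts[n] + gene_len[n] + gap[n]
  )
}

# Adjusted Rand index between two label vectors.
ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# Fraction of families whose inferred partition equals the truth.
partition_accuracy <- function(model, truth) {
  td <- tidy(model)
  truth_lab <- truth$partition[match(td$family_id, truth$family_id)]
  mean(as.character(td$partition) == as.character(truth_lab))
}
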
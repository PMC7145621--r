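#' Canonical k-mers of a DNA sequence
#'
#' Emits, for every window of length `k`, the lexicographic minimum of
#' the k-mer and its reverse complement.  Windows containing `N` (or any
#' non-ACGT character) are skipped; sequences shorter than `k` emit
#' nothing.  Circular contigs are treated as linear (no wrap-around
#' windows).  Duplicate windows are kept: this is the raw stream that
#' the sketcher deduplicates by hash.
#'
#' @param sequence Single uppercase DNA string.
#' @param k K-mer length (bp).
#' @return Character vector of canonical k-mers, one per valid window.
#' @export
canonical_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 1)
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0L) return(character(0))
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", km))
  ifelse(km <= rc, km, rc)
}

#' Build a bottom-s MinHash sketch of a genome
#'
#' Hashes every canonical k-mer across all contigs with a seeded 64-bit
#' hash and keeps the `s` smallest distinct values.  Defaults (`k = 18`,
#' `s = 5000`) are the settings used for genome-wide species clustering.
#' Hashes are stored as fixed-width lowercase hex strings so that
#' lexicographic (byte) order equals numeric order.
#'
#' @param genome A [genome_record()].
#' @param k K-mer length (default 18 bp).
#' @param s Sketch size (default 5000 hashes).
#' @param hash_seed Integer seed of the hash function, recorded in the
#'   sketch; sketches are only comparable at equal `(k, s, hash_seed)`.
#' @return An object of class `mash_sketch` with fields `genome_id`,
#'   `k`, `s`, `hash_seed`, `hashes` (ascending) and `total_kmers`
#'   (number of distinct canonical k-mers seen).
#' @export
build_sketch <- function(genome, k = 18, s = 5000, hash_seed = 42) {
  stopifnot(inherits(genome, "genome_record"))
  res <- .sketch_hashes(genome$contigs$sequence, as.integer(k),
                        as.integer(s), as.double(hash_seed))
  if (length(res$hashes) == 0L) {
    warn(sprintf("genome '%s': no k-mer survived masking; empty sketch",
                 genome$genome_id))
  }
  structure(
    list(genome_id = genome$genome_id, k = as.integer(k), s = as.integer(s),
         hash_seed = as.double(hash_seed),
         hashes = as.character(res$hashes),
         total_kmers = as.double(res$total_kmers)),
    class = "mash_sketch"
  )
}

#' @export
print.mash_sketch <- function(x, ...) {
  cat(sprintf("<mash_sketch> %s: k=%d s=%d, %d hashes (of %s distinct k-mers)\n",
              x$genome_id, x$k, x$s, length(x$hashes),
              format(x$total_kmers, big.mark = ",")))
  invisible(x)
}

.check_sketch_params <- function(x, y) {
  if (x$k != y$k || x$s != y$s || x$hash_seed != y$hash_seed) {
    abort(sprintf(
      "sketch parameter mismatch between '%s' and '%s' (k/s/seed must agree)",
      x$genome_id, y$genome_id))
  }
}

#' Estimate Jaccard similarity from two sketches
#'
#' Merge estimator: the `s` smallest hashes of the union of both
#' sketches form a random sample of the union of the two k-mer sets;
#' the fraction of that sample present in both sketches estimates the
#' Jaccard index.  When `s` is at least the size of the true k-mer-set
#' union the estimate is exact.
#'
#' @param x,y `mash_sketch` objects with identical parameters.
#' @return List with `shared` (count) and `jaccard` (estimate in
#'   `[0, 1]`).
#' @export
jaccard_estimate <- function(x, y) {
  stopifnot(inherits(x, "mash_sketch"), inherits(y, "mash_sketch"))
  .check_sketch_params(x, y)
  if (length(x$hashes) == 0L && length(y$hashes) == 0L) {
    abort("both sketches are empty: Jaccard undefined")
  }
  merged <- sort(unique(c(x$hashes, y$hashes)), method = "radix")
  m <- merged[seq_len(min(x$s, length(merged)))]
  shared <- sum(m %in% x$hashes & m %in% y$hashes)
  list(shared = shared, jaccard = shared / length(m))
}

#' Mash distance from a Jaccard estimate
#'
#' `d = -(1/k) * log(2j / (1 + j))`, clamped to `[0, 1]`; `j = 0` maps
#' to `d = 1` by convention (the formula diverges there), so fully
#' unrelated genomes simply contribute no edge to the species graph.
#' Under a Poisson model of random substitution, `d` estimates the
#' per-base divergence between the two genomes, i.e. `1 - ANI/100`.
#'
#' @param j Jaccard estimate(s) in `[0, 1]`.
#' @param k K-mer length used for the sketches.
#' @return Distance(s) in `[0, 1]`.
#' @export
mash_distance <- function(j, k = 18) {
  if (any(!is.finite(j)) || any(j < 0) || any(j > 1)) {
    abort("jaccard must be within [0, 1]")
  }
  d <- ifelse(j == 0, 1, -(1 / k) * log(2 * j / (1 + j)))
  pmin(pmax(d, 0), 1)
}

#' Pairwise Mash distances between sketches
#'
#' @param sketches List of `mash_sketch` objects with identical
#'   parameters and unique genome ids.
#' @return `mash_distances()`: tibble with one row per unordered pair
#'   (`a`, `b`, `shared`, `jaccard`, `distance`).
#' @export
mash_distances <- function(sketches) {
  stopifnot(is.list(sketches), length(sketches) >= 2)
  ids <- vapply(sketches, function(x) x$genome_id, "")
  if (anyDuplicated(ids)) abort("duplicate genome_id among sketches")
  for (i in seq_along(sketches)[-1]) {
    .check_sketch_params(sketches[[1]], sketches[[i]])
  }
  k <- sketches[[1]]$k
  pairs <- combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    est <- jaccard_estimate(sketches[[i]], sketches[[j]])
    tibble(a = ids[i], b = ids[j], shared = est$shared,
           jaccard = est$jaccard, distance = mash_distance(est$jaccard, k))
  })
  bind_rows(rows)
}

#' @rdname mash_distances
#' @return `distance_matrix()`: symmetric numeric matrix with zero
#'   diagonal, genome ids as dimnames.
#' @export
distance_matrix <- function(sketches) {
  ids <- vapply(sketches, function(x) x$genome_id, "")
  tbl <- mash_distances(sketches)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(tbl$a, tbl$b)] <- tbl$distance
  m[cbind(tbl$b, tbl$a)] <- tbl$distance
  m
}

#' Read and write sketches as JSON lines
#'
#' One JSON object per line with fields `genome_id`, `k`, `s`,
#' `hash_seed`, `total_kmers`, `hashes`.
#'
#' @param sketches List of `mash_sketch` objects.
#' @param path File path.
#' @return `write_sketches()` returns `path` invisibly;
#'   `read_sketches()` returns a list of `mash_sketch` objects.
#' @export
write_sketches <- function(sketches, path) {
  lines <- vapply(sketches, function(x) {
    as.character(jsonlite::toJSON(
      list(genome_id = x$genome_id, k = x$k, s = x$s,
           hash_seed = x$hash_seed, total_kmers = x$total_kmers,
           hashes = x$hashes),
      auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    structure(
      list(genome_id = x$genome_id, k = as.integer(x$k), s = as.integer(x$s),
           hash_seed = as.double(x$hash_seed),
           hashes = as.character(x$hashes),
           total_kmers = as.double(x$total_kmers)),
      class = "mash_sketch")
  })
}
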
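#' Local alignment statistics for a protein pair
#'
#' Smith–Waterman local alignment under BLOSUM62 with affine gap
#' penalties (open 11, extend 1).  Identity is matches divided by
#' aligned columns, counting gap columns in the denominator (so
#' indel-riddled alignments are penalised); coverage is the aligned span
#' divided by sequence length, computed for each sequence separately.
#'
#' @param protein_a,protein_b Non-empty amino-acid strings.
#' @return One-row tibble with `identity`, `coverage_a`, `coverage_b`,
#'   `score`, `matches`, `columns`.
#' @export
align_pair <- function(protein_a, protein_b) {
  if (!nzchar(protein_a) || !nzchar(protein_b)) {
    abort("both protein sequences must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  tibble(
    identity = matches / cols,
    coverage_a = (Biostrings::end(pat) - Biostrings::start(pat) + 1) /
      nchar(protein_a),
    coverage_b = (Biostrings::end(sub) - Biostrings::start(sub) + 1) /
      nchar(protein_b),
    score = Biostrings::score(aln),
    matches = matches,
    columns = cols
  )
}

#' Candidate protein pairs sharing a k-mer
#'
#' Conservative prefilter before alignment: emits every unordered pair
#' of proteins sharing at least one common `kmer_size`-mer.  At the
#' 80/80 identity-coverage operating point, sequences of 20 residues or
#' more that could pass always share a 4-mer, so no qualifying pair is
#' lost.
#'
#' @param proteins Tibble with columns `gene_id`, `protein`.
#' @param kmer_size Word size of the prefilter (default 4).
#' @return Tibble with columns `gene_a`, `gene_b` (`gene_a < gene_b`).
#' @export
candidate_pairs <- function(proteins, kmer_size = 4) {
  stopifnot(all(c("gene_id", "protein") %in% names(proteins)),
            nrow(proteins) >= 1)
  if (anyDuplicated(proteins$gene_id)) abort("duplicate gene_id")
  kms <- lapply(proteins$protein, function(p) {
    n <- nchar(p)
    if (n < kmer_size) return(character(0))
    unique(substring(p, seq_len(n - kmer_size + 1L),
                     seq_len(n - kmer_size + 1L) + kmer_size - 1L))
  })
  idx <- data.frame(kmer = unlist(kms),
                    i = rep(seq_len(nrow(proteins)), lengths(kms)))
  prs <- lapply(split(idx$i, idx$kmer), function(v) {
    v <- sort(unique(v))
    if (length(v) < 2) return(NULL)
    t(combn(v, 2))
  })
  prs <- do.call(rbind, prs)
  if (is.null(prs) || nrow(prs) == 0L) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  tibble(gene_a = proteins$gene_id[prs[, 1]],
         gene_b = proteins$gene_id[prs[, 2]]) %>%
    distinct() %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Cluster proteins into homologous gene families
#'
#' MICFAM-style families: every candidate pair is aligned, a pair passes
#' when identity >= `min_identity` and the coverage of *both* sequences
#' is >= `min_coverage` (the stricter symmetric reading, which keeps the
#' pass relation symmetric as single linkage requires), and families are
#' the connected components of the pass graph.  Genes with no passing
#' pair become singleton families.  Family ids are canonical: `FAM1` is
#' the largest family, ties broken by lexicographically smallest member,
#' so output is invariant to input order.
#'
#' @param proteins Tibble with columns `gene_id`, `protein` and
#'   optionally `genome_id` (carried through).
#' @param min_identity Identity threshold (default 0.8).
#' @param min_coverage Coverage threshold on both sequences
#'   (default 0.8).
#' @return Tibble with columns `gene_id`, (`genome_id`,) `family_id`;
#'   one row per gene.
#' @export
cluster_families <- function(proteins, min_identity = 0.8,
                             min_coverage = 0.8) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  pairs <- candidate_pairs(proteins)
  prot <- setNames(proteins$protein, proteins$gene_id)
  if (nrow(pairs)) {
    pass <- vapply(seq_len(nrow(pairs)), function(i) {
      st <- align_pair(prot[[pairs$gene_a[i]]], prot[[pairs$gene_b[i]]])
      st$identity >= min_identity &&
        min(st$coverage_a, st$coverage_b) >= min_coverage
    }, logical(1))
    pairs <- pairs[pass, ]
  }
  g <- igraph::graph_from_data_frame(
    pairs, directed = FALSE, vertices = tibble(name = proteins$gene_id))
  memb <- igraph::components(g)$membership
  tb <- tibble(gene_id = names(memb), comp = as.integer(memb))
  ord <- tb %>%
    group_by(.data$comp) %>%
    summarise(sz = n(), minid = min(.data$gene_id), .groups = "drop") %>%
    arrange(desc(.data$sz), .data$minid)
  fam_map <- setNames(sprintf("FAM%d", seq_len(nrow(ord))),
                      as.character(ord$comp))
  out <- tb %>%
    transmute(gene_id = .data$gene_id,
              family_id = unname(fam_map[as.character(.data$comp)]))
  if ("genome_id" %in% names(proteins)) {
    out <- proteins %>%
      select("gene_id", "genome_id") %>%
      left_join(out, by = "gene_id")
  }
  out %>% arrange(.data$family_id, .data$gene_id)
}

#' Per-family summary counts
#'
#' @param family_assignment Tibble with `gene_id`, `genome_id`,
#'   `family_id`.
#' @return Tibble with `family_id`, `n_genes`, `n_genomes`, sorted by
#'   decreasing size.
#' @export
family_summary <- function(family_assignment) {
  stopifnot(all(c("gene_id", "genome_id", "family_id") %in%
                  names(family_assignment)))
  family_assignment %>%
    group_by(.data$family_id) %>%
    summarise(n_genes = n(),
              n_genomes = dplyr::n_distinct(.data$genome_id),
              .groups = "drop") %>%
    arrange(desc(.data$n_genes), .data$family_id)
}
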
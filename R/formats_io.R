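#' Construct a genome record
#'
#' A genome record bundles a genome identifier with an ordered table of
#' contigs (replicons).  Sequences are uppercase DNA over `A/C/G/T/N`;
#' a `circular` flag per contig controls wrap-around behaviour in the
#' pangenome graph and RGP detection.
#'
#' @param genome_id Single string, unique within a run.
#' @param contigs Tibble with columns `contig_id`, `sequence` and
#'   (optionally) `circular`; `circular` defaults to `FALSE`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  contigs <- as_tibble(contigs)
  if (!all(c("contig_id", "sequence") %in% names(contigs))) {
    abort("contigs must have columns 'contig_id' and 'sequence'")
  }
  if (!"circular" %in% names(contigs)) contigs$circular <- FALSE
  if (anyDuplicated(contigs$contig_id)) {
    abort(sprintf("duplicate contig_id in genome '%s'", genome_id))
  }
  if (any(!nzchar(contigs$sequence))) {
    abort(sprintf("empty contig sequence in genome '%s'", genome_id))
  }
  structure(
    list(genome_id = genome_id,
         contigs = contigs[, c("contig_id", "sequence", "circular")]),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp total\n",
              x$genome_id, nrow(x$contigs),
              format(sum(nchar(x$contigs$sequence)), big.mark = ",")))
  invisible(x)
}

#' Read a genome assembly from nucleotide FASTA
#'
#' One file per genome, one record per contig.  Lowercase is normalised
#' to uppercase and any character outside `A/C/G/T/N` (IUPAC ambiguity
#' codes included) is masked to `N`; `N`-containing k-mer windows are
#' later skipped by the sketcher.
#'
#' @param path FASTA file.
#' @param genome_id Genome identifier; defaults to the file name without
#'   its extension.
#' @param circular Logical, recycled over contigs.
#' @return A [genome_record()].
#' @export
read_genome_fasta <- function(path, genome_id = NULL, circular = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf(
                    "malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) abort(sprintf("empty FASTA: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate contig id in %s: %s", path,
                  ids[duplicated(ids)][1]))
  }
  seqs <- gsub("[^ACGTN]", "N", toupper(as.character(set)))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  genome_record(
    genome_id,
    tibble(contig_id = ids, sequence = unname(seqs),
           circular = rep_len(as.logical(circular), length(ids)))
  )
}

#' Read gene coordinates and protein translations
#'
#' Parses a GFF3 file (1-based inclusive coordinates) together with a
#' companion protein FASTA keyed by the same feature IDs.  Coordinates
#' are converted at the boundary to the package-internal 0-based
#' half-open convention, which keeps interval arithmetic for RGP spans
#' unambiguous.  CDS features are used when present, otherwise `gene`
#' features.  Genes lacking a protein sequence are dropped with a
#' warning.
#'
#' @param path GFF3 file.
#' @param protein_fasta_path Protein FASTA whose record names match the
#'   GFF3 feature `ID`s.
#' @param genome_id Genome identifier; defaults to the GFF3 file name
#'   without extension.
#' @return Tibble with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `strand`,
#'   `protein`, sorted by contig then start then gene_id.
#' @export
read_gff3_genes <- function(path, protein_fasta_path, genome_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) abort(sprintf(
                   "malformed GFF3 '%s': %s", path, conditionMessage(e))))
  keep_type <- if (any(gr$type == "CDS")) "CDS" else "gene"
  gr <- gr[gr$type == keep_type]
  if (length(gr) == 0L) abort(sprintf("no CDS/gene features in %s", path))
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | !nzchar(ids))) abort("feature without an ID attribute")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate feature ID: %s", ids[duplicated(ids)][1]))
  }
  prot_set <- Biostrings::readAAStringSet(protein_fasta_path)
  prots <- setNames(as.character(prot_set), sub("\\s.*$", "", names(prot_set)))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gff3?|gff)(\\.gz)?$", "", basename(path))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  genes <- tibble(
    gene_id = ids,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    protein = unname(prots[ids])
  )
  missing <- is.na(genes$protein)
  if (any(missing)) {
    warn(sprintf("%d gene(s) lack a protein sequence and were dropped (e.g. %s)",
                 sum(missing), genes$gene_id[missing][1]))
    genes <- genes[!missing, ]
  }
  genes %>% arrange(.data$contig_id, .data$start, .data$gene_id)
}

#' Write gene records as GFF3
#'
#' Converts internal 0-based half-open coordinates back to GFF3's
#' 1-based inclusive convention, so read/write round-trips are identity
#' on `(start, end, strand)`.
#'
#' @param genes Tibble as returned by [read_gff3_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "pangraphr"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome quality table
#'
#' TSV with header `genome_id`, `completion`, `contamination` — the
#' per-genome completeness/contamination estimates (CheckM-style) that
#' gate entry into the species graph.  Any unparseable value aborts.
#'
#' @param path TSV file.
#' @return Tibble with one row per genome.
#' @export
read_quality_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- suppressWarnings(readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  need <- c("genome_id", "completion", "contamination")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("quality table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  tbl <- tbl[, need]
  if (nrow(tbl) == 0L) {
    return(tibble(genome_id = character(), completion = double(),
                  contamination = double()))
  }
  completion <- suppressWarnings(as.numeric(tbl$completion))
  contamination <- suppressWarnings(as.numeric(tbl$contamination))
  bad <- !is.finite(completion) | !is.finite(contamination)
  if (any(bad)) {
    abort(sprintf("non-numeric quality value for genome '%s'",
                  tbl$genome_id[bad][1]))
  }
  if (anyDuplicated(tbl$genome_id)) {
    abort("duplicate genome_id in quality table")
  }
  tibble(genome_id = tbl$genome_id, completion = completion,
         contamination = contamination)
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned only.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a graph in GraphML format
#'
#' Node and edge attributes are preserved.
#'
#' @param graph An `igraph` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write a table as TSV
#'
#' Deterministic writer: fixed column order as given, header row, no
#' quoting of plain fields, `NA` written as empty.
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Write a distance matrix as TSV (row/column header) or PHYLIP
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  tbl <- as_tibble(d)
  tbl <- bind_cols(tibble(genome_id = rownames(d)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$genome_id
  storage.mode(m) <- "double"
  m
}

#' @rdname write_distance_tsv
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "), con)
  }
  invisible(path)
}
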
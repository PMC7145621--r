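.DNA <- c("A", "C", "G", "T")
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_string <- function(n, alphabet) {
  ab <- charToRaw(paste(alphabet, collapse = ""))
  rawToChar(ab[sample.int(length(ab), n, replace = TRUE)])
}

# Point-substitute each position with probability `rate`, replacing the
# base by a uniformly chosen *different* symbol of the alphabet.
.mutate_string <- function(seq, rate, alphabet) {
  r <- charToRaw(seq)
  n <- length(r)
  idx <- which(runif(n) < rate)
  if (length(idx) == 0L) return(seq)
  ab <- charToRaw(paste(alphabet, collapse = ""))
  curpos <- match(r[idx], ab)
  ok <- !is.na(curpos)
  idx <- idx[ok]; curpos <- curpos[ok]
  if (length(idx) == 0L) return(seq)
  pick <- sample.int(length(ab) - 1L, length(idx), replace = TRUE)
  altpos <- pick + (pick >= curpos)
  r[idx] <- ab[altpos]
  rawToChar(r)
}

#' Randomly substitute bases of a DNA sequence
#'
#' Each base is independently substituted (to a uniformly chosen
#' different base) with probability `rate`; length is preserved.  Used
#' to simulate genomes at a known per-base divergence, which the Mash
#' distance should recover.
#'
#' @param seq Uppercase DNA string.
#' @param rate Substitution probability per base, in `[0, 1]`.
#' @param seed Optional seed; when given the call leaves the global RNG
#'   state untouched.
#' @return Mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (is.null(seed)) return(.mutate_string(seq, rate, .DNA))
  withr::with_seed(seed, .mutate_string(seq, rate, .DNA))
}

#' Simulate genomes from several species with known labels
#'
#' One random ancestor per species (each a mutated copy of a common
#' root at `rate_between`); species members are independent mutations of
#' their ancestor at `rate_within`.  With the defaults, within-species
#' Mash distances fall well below the 0.06 species cutoff and
#' between-species distances well above it.
#'
#' @param n_genomes Genomes per species.
#' @param genome_length Genome length in bp (single contig).
#' @param rate_within Substitution rate ancestor -> member.
#' @param rate_between Substitution rate root -> species ancestor; must
#'   exceed `rate_within`.
#' @param n_species Number of species.
#' @param seed Mandatory integer seed.
#' @return List with `genomes` (list of [genome_record()]), `truth`
#'   (tibble `genome_id`, `species`) and `quality` (an all-passing
#'   quality tibble for pipeline use).
#' @export
simulate_species <- function(n_genomes = 5, genome_length = 50000,
                             rate_within = 0.01, rate_between = 0.2,
                             n_species = 3, seed) {
  stopifnot(rate_within < rate_between, n_genomes >= 1, n_species >= 1)
  withr::with_seed(seed, {
    root <- .random_string(genome_length, .DNA)
    genomes <- list()
    truth <- list()
    for (s in seq_len(n_species)) {
      anc <- .mutate_string(root, rate_between, .DNA)
      for (g in seq_len(n_genomes)) {
        gid <- sprintf("sp%02d_g%02d", s, g)
        genomes[[gid]] <- genome_record(
          gid, tibble(contig_id = "chr1",
                      sequence = .mutate_string(anc, rate_within, .DNA),
                      circular = FALSE))
        truth[[gid]] <- tibble(genome_id = gid,
                               species = sprintf("species%d", s))
      }
    }
    truth <- bind_rows(truth)
    list(genomes = genomes, truth = truth,
         quality = tibble(genome_id = truth$genome_id, completion = 100,
                          contamination = 0))
  })
}

#' Simulate a planted protein family set
#'
#' Family prototypes diverge from a common base at `between` (far below
#' the 80% identity threshold); members diverge from their prototype at
#' `within` (comfortably above it).  Truth labels make single-linkage
#' family recovery exactly checkable.
#'
#' @param n_families Number of families.
#' @param genes_per_family Members per family.
#' @param protein_length Protein length (residues).
#' @param within Within-family divergence (default 0.05).
#' @param between Between-family divergence from the base
#'   (default 0.6).
#' @param seed Mandatory seed.
#' @return Tibble with `gene_id`, `true_family`, `protein`.
#' @export
simulate_protein_families <- function(n_families = 3, genes_per_family = 4,
                                      protein_length = 200, within = 0.05,
                                      between = 0.6, seed) {
  withr::with_seed(seed, {
    base <- .random_string(protein_length, .AA)
    rows <- list()
    for (f in seq_len(n_families)) {
      proto <- .mutate_string(base, between, .AA)
      for (g in seq_len(genes_per_family)) {
        rows[[length(rows) + 1L]] <- tibble(
          gene_id = sprintf("fam%02d_p%02d", f, g),
          true_family = sprintf("TFAM%02d", f),
          protein = .mutate_string(proto, within, .AA))
      }
    }
    bind_rows(rows)
  })
}

#' Specification of a synthetic pangenome
#'
#' Defines the statistical structure the partitioner assumes: persistent
#' families present in almost every genome (p = 0.99), shell families in
#' correlated blocks at p = 0.5 (shared per-genome block draws emulate
#' co-occurring adaptation modules, giving the MRF real neighbourhood
#' signal), cloud families at p = 0.05, plus optional cloud-gene islands
#' planted into the otherwise conserved backbone as ready-made RGPs.
#'
#' @param n_genomes Number of genomes (default 30).
#' @param n_persistent,n_shell,n_cloud Family counts per class
#'   (defaults 300/300/400).
#' @param p_persistent,p_shell,p_cloud Presence probabilities
#'   (defaults 0.99/0.5/0.05).
#' @param shell_block_size Families per correlated shell block
#'   (default 30).
#' @param substitution_rate Per-base divergence of gene DNA from its
#'   family prototype (default 0.02).
#' @param gene_length Backbone gene length in bp (default 900).
#' @param intergenic Intergenic gap in bp (default 100).
#' @param protein_length Protein length in residues (default 200).
#' @param protein_within,protein_between Protein divergence within a
#'   family / between prototypes (defaults 0.05/0.6).
#' @param rgp_islands List of `list(n_genes =, span =)` islands.
#' @param island_prob Probability that a genome receives each island
#'   (default 0.25; at least one genome always receives it).
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genomes = 30, n_persistent = 300,
                            n_shell = 300, n_cloud = 400,
                            p_persistent = 0.99, p_shell = 0.5,
                            p_cloud = 0.05, shell_block_size = 30,
                            substitution_rate = 0.02, gene_length = 900,
                            intergenic = 100, protein_length = 200,
                            protein_within = 0.05, protein_between = 0.6,
                            rgp_islands = list(), island_prob = 0.25,
                            seed) {
  probs <- c(p_persistent, p_shell, p_cloud)
  stopifnot(all(probs >= 0), all(probs <= 1), n_genomes >= 1,
            is.numeric(seed), length(seed) == 1)
  for (isl in rgp_islands) {
    stopifnot(all(c("n_genes", "span") %in% names(isl)))
    if (isl$span < isl$n_genes * 30) {
      abort(sprintf("island span %d bp too short for %d genes",
                    isl$span, isl$n_genes))
    }
  }
  structure(
    list(n_genomes = n_genomes, n_persistent = n_persistent,
         n_shell = n_shell, n_cloud = n_cloud,
         p_persistent = p_persistent, p_shell = p_shell,
         p_cloud = p_cloud, shell_block_size = shell_block_size,
         substitution_rate = substitution_rate, gene_length = gene_length,
         intergenic = intergenic, protein_length = protein_length,
         protein_within = protein_within,
         protein_between = protein_between, rgp_islands = rgp_islands,
         island_prob = island_prob, seed = seed),
    class = "simulation_spec")
}

# Draw the family-by-genome presence matrix with block-correlated shell
# families; every family is conditioned on being present in at least
# one genome (a family observed nowhere does not exist).
.draw_presence <- function(spec, fam_class) {
  M <- length(fam_class)
  G <- spec$n_genomes
  x <- matrix(0L, M, G)
  pers <- which(fam_class == "persistent")
  cloud <- which(fam_class == "cloud")
  shell <- which(fam_class == "shell")
  if (length(pers)) {
    x[pers, ] <- matrix(rbinom(length(pers) * G, 1, spec$p_persistent),
                        ncol = G)
  }
  if (length(cloud)) {
    x[cloud, ] <- matrix(rbinom(length(cloud) * G, 1, spec$p_cloud),
                         ncol = G)
  }
  if (length(shell)) {
    blocks <- split(shell, ceiling(seq_along(shell) / spec$shell_block_size))
    for (b in blocks) {
      draw <- rbinom(G, 1, spec$p_shell)
      x[b, ] <- matrix(rep(draw, each = length(b)), ncol = G)
    }
  }
  for (i in seq_len(M)) {
    while (sum(x[i, ]) == 0L) {
      x[i, ] <- rbinom(G, 1, switch(fam_class[i],
                                    persistent = spec$p_persistent,
                                    shell = spec$p_shell,
                                    cloud = spec$p_cloud))
    }
  }
  x
}

#' Simulate a pangenome with known truth
#'
#' Generates genomes, gene coordinates, proteins and (optionally) DNA
#' according to a [simulation_spec()]: each family gets a prototype,
#' genes are its point-mutated copies; present backbone genes are laid
#' on one linear contig in a conserved canonical order; islands are
#' inserted as contiguous runs of island-specific cloud genes at a
#' random backbone position per receiving genome, with coordinates
#' synthesised so the genomic span matches the requested value exactly.
#' All truth (family membership, partition labels, island intervals) is
#' returned for diff-based testing.
#'
#' @param spec A [simulation_spec()].
#' @param with_dna Generate contig DNA (needed for FASTA/sketching
#'   stages; default `TRUE`).
#' @param with_proteins Generate protein sequences (needed for family
#'   clustering; default `TRUE`).
#' @return List with `genes` (tibble incl. `circular`,
#'   `contig_length`), `proteins` (named vector, when requested),
#'   `genomes` (list of [genome_record()], when requested), `quality`,
#'   and `truth` (list of tibbles `families`, `partitions`, `rgps`).
#' @export
simulate_pangenome <- function(spec, with_dna = TRUE, with_proteins = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    M <- spec$n_persistent + spec$n_shell + spec$n_cloud
    fam_class <- rep(c("persistent", "shell", "cloud"),
                     c(spec$n_persistent, spec$n_shell, spec$n_cloud))
    fam_id <- sprintf("TFAM%04d", seq_len(M))
    G <- spec$n_genomes
    gids <- sprintf("genome%02d", seq_len(G))

    x <- .draw_presence(spec, fam_class)

    # islands: dedicated cloud families, one per island gene
    islands <- list()
    for (ii in seq_along(spec$rgp_islands)) {
      isl <- spec$rgp_islands[[ii]]
      lens <- rep(isl$span %/% isl$n_genes, isl$n_genes)
      lens[isl$n_genes] <- isl$span - sum(lens[-isl$n_genes])
      received <- runif(G) < spec$island_prob
      if (!any(received)) received[sample.int(G, 1)] <- TRUE
      islands[[ii]] <- list(
        id = sprintf("ISL%02d", ii),
        fams = sprintf("ISL%02d_F%02d", ii, seq_len(isl$n_genes)),
        lens = lens, received = received)
    }

    aa_base <- .random_string(spec$protein_length, .AA)
    protos_aa <- NULL
    protos_dna <- NULL
    all_fams <- c(fam_id, unlist(lapply(islands, `[[`, "fams")))
    all_lens <- c(rep(spec$gene_length, M),
                  unlist(lapply(islands, `[[`, "lens")))
    if (with_proteins) {
      protos_aa <- setNames(vapply(all_fams, function(f) {
        .mutate_string(aa_base, spec$protein_between, .AA)
      }, ""), all_fams)
    }
    if (with_dna) {
      protos_dna <- setNames(vapply(seq_along(all_fams), function(i) {
        .random_string(all_lens[i], .DNA)
      }, ""), all_fams)
    }

    genes <- list(); prots <- list(); contigs <- list(); truth_rgps <- list()
    for (g in seq_len(G)) {
      gid <- gids[g]
      backbone <- fam_id[x[, g] == 1L]
      units <- tibble(family_id = backbone,
                      len = rep(spec$gene_length, length(backbone)),
                      island = NA_character_, gap_after = spec$intergenic)
      for (isl in islands) {
        if (!isl$received[g]) next
        at <- sample.int(nrow(units) + 1L, 1)
        block <- tibble(family_id = isl$fams, len = isl$lens,
                        island = isl$id,
                        gap_after = c(rep(0L, length(isl$fams) - 1L),
                                      spec$intergenic))
        tail_units <- if (at <= nrow(units)) units[at:nrow(units), ]
        units <- bind_rows(units[seq_len(at - 1L), ], block, tail_units)
      }
      pos <- spec$intergenic
      starts <- integer(nrow(units)); ends <- integer(nrow(units))
      for (u in seq_len(nrow(units))) {
        starts[u] <- pos
        ends[u] <- pos + units$len[u]
        pos <- ends[u] + units$gap_after[u]
      }
      contig_length <- pos
      gene_ids <- sprintf("%s_g%05d", gid, seq_len(nrow(units)))
      genes[[g]] <- tibble(
        gene_id = gene_ids, genome_id = gid, contig_id = "chr1",
        start = starts, end = ends,
        strand = sample(c("+", "-"), nrow(units), replace = TRUE),
        family_id = units$family_id, circular = FALSE,
        contig_length = contig_length)
      if (with_proteins) {
        prots[[g]] <- setNames(vapply(units$family_id, function(f) {
          .mutate_string(protos_aa[[f]], spec$protein_within, .AA)
        }, ""), gene_ids)
      }
      if (with_dna) {
        chunks <- character(2L * nrow(units) + 1L)
        chunks[1] <- .random_string(spec$intergenic, .DNA)
        for (u in seq_len(nrow(units))) {
          chunks[2L * u] <- .mutate_string(protos_dna[[units$family_id[u]]],
                                           spec$substitution_rate, .DNA)
          chunks[2L * u + 1L] <- if (units$gap_after[u] > 0) {
            .random_string(units$gap_after[u], .DNA)
          } else ""
        }
        contigs[[g]] <- paste(chunks, collapse = "")
      }
      isl_here <- units$island
      for (iid in unique(isl_here[!is.na(isl_here)])) {
        w <- which(isl_here == iid)
        truth_rgps[[length(truth_rgps) + 1L]] <- tibble(
          genome_id = gid, contig_id = "chr1", island = iid,
          start = starts[min(w)], end = ends[max(w)],
          span = ends[max(w)] - starts[min(w)])
      }
    }
    genes <- bind_rows(genes)

    truth_partitions <- tibble(
      family_id = all_fams,
      partition = c(fam_class, rep("cloud", length(all_fams) - M)))
    # only families realised in at least one genome exist
    truth_partitions <- truth_partitions %>%
      filter(.data$family_id %in% genes$family_id)

    genomes <- NULL
    if (with_dna) {
      genomes <- lapply(seq_len(G), function(g) {
        genome_record(gids[g],
                      tibble(contig_id = "chr1", sequence = contigs[[g]],
                             circular = FALSE))
      })
      names(genomes) <- gids
    }
    list(
      genes = genes %>% select(-"family_id"),
      proteins = if (with_proteins) unlist(unname(prots)) else NULL,
      genomes = genomes,
      quality = tibble(genome_id = gids, completion = 100,
                       contamination = 0),
      truth = list(
        families = genes %>% select("gene_id", "family_id"),
        partitions = truth_partitions,
        rgps = if (length(truth_rgps)) bind_rows(truth_rgps) else
          tibble(genome_id = character(), contig_id = character(),
                 island = character(), start = integer(), end = integer(),
                 span = integer()))
    )
  })
}

#' Write a simulated data set to disk
#'
#' Emits the same plain-text dialects the pipeline consumes: one
#' nucleotide FASTA and one GFF3 per genome, a global protein FASTA, a
#' quality TSV, and the truth tables as TSV, enabling diff-based tests
#' against pipeline output.
#'
#' @param sim Result of [simulate_pangenome()] (with DNA and proteins).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gr in sim$genomes) {
    seqs <- Biostrings::DNAStringSet(setNames(gr$contigs$sequence,
                                              gr$contigs$contig_id))
    Biostrings::writeXStringSet(
      seqs, file.path(dir, paste0(gr$genome_id, ".fna")))
    write_gff3_genes(sim$genes %>% filter(.data$genome_id == gr$genome_id),
                     file.path(dir, paste0(gr$genome_id, ".gff3")))
  }
  if (!is.null(sim$proteins)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins),
                                file.path(dir, "proteins.faa"))
  }
  write_table_tsv(sim$quality, file.path(dir, "quality.tsv"))
  write_table_tsv(sim$truth$families, file.path(dir, "truth_families.tsv"))
  write_table_tsv(sim$truth$partitions,
                  file.path(dir, "truth_partitions.tsv"))
  write_table_tsv(sim$truth$rgps, file.path(dir, "truth_rgps.tsv"))
  invisible(dir)
}
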
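test_that("a five-gene cloud island above 3 kb is reported once", {
  labs <- c(rep("persistent", 3), rep("cloud", 5), rep("persistent", 3))
  ctg <- make_labeled_contig(labs, gene_len = 1000, gap = 50)
  rgps <- detect_rgps(ctg)
  expect_equal(nrow(rgps), 1L)
  expect_equal(rgps$n_genes, 5L)
  expect_equal(rgps$score, 5)
  expect_equal(rgps$span, 5 * 1000 + 4 * 50)
  expect_equal(rgps$genes[[1]], ctg$gene_id[4:8])
  expect_equal(rgps$families[[1]], sort(ctg$family_id[4:8]))
  expect_equal(rgps$rgp_id, "g1_RGP_001")
})

test_that("short or low-scoring regions are rejected", {
  # 2.1 kb island: enough score, not enough span (> 3000 is strict)
  labs <- c("persistent", rep("cloud", 4), "persistent")
  ctg <- make_labeled_contig(labs, gene_len = c(1000, 510, 510, 510, 510, 1000),
                             gap = c(100, 20, 20, 20, 100, 100))
  expect_equal(nrow(detect_rgps(ctg)), 0L)
  # exactly 3000 bp rejected, 3001 accepted
  at <- function(total) {
    lens <- c(1000, 750, 750, 750, total - 2250, 1000)
    ctg <- make_labeled_contig(labs, gene_len = lens, gap = 0)
    nrow(detect_rgps(ctg))
  }
  expect_equal(at(3000), 0L)
  expect_equal(at(3001), 1L)
  # 3 cloud genes score 3 < 4: rejected however long
  ctg <- make_labeled_contig(c("persistent", rep("cloud", 3), "persistent"),
                             gene_len = 2000)
  expect_equal(nrow(detect_rgps(ctg)), 0L)
  # all persistent: typed empty result
  ctg <- make_labeled_contig(rep("persistent", 10))
  out <- detect_rgps(ctg)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("rgp_id", "span", "genes", "families") %in% names(out)))
})

test_that("one interspersed persistent gene is tolerated, two break the region", {
  one <- c(rep("cloud", 4), "persistent", rep("cloud", 4))
  ctg <- make_labeled_contig(c("persistent", one, "persistent"))
  rgps <- detect_rgps(ctg)
  expect_equal(nrow(rgps), 1L)
  expect_equal(rgps$n_genes, 9L)
  expect_equal(rgps$score, 4 - 3 + 4)
  two <- c(rep("cloud", 4), "persistent", "persistent", rep("cloud", 4))
  ctg <- make_labeled_contig(c("persistent", two, "persistent"))
  rgps <- detect_rgps(ctg)
  expect_equal(nrow(rgps), 2L)
  expect_equal(rgps$n_genes, c(4L, 4L))
  expect_equal(rgps$score, c(4, 4))
})

test_that("regions crossing the origin of a circular contig are found once", {
  labs <- c(rep("cloud", 3), rep("persistent", 6), rep("cloud", 3))
  ctg <- make_labeled_contig(labs, gene_len = 1000, gap = 100,
                             circular = TRUE)
  rgps <- detect_rgps(ctg)
  expect_equal(nrow(rgps), 1L)
  expect_equal(rgps$n_genes, 6L)
  expect_equal(rgps$score, 6)
  # wrapped region: end < start and span carries the genomic extent
  expect_lt(rgps$end, rgps$start)
  expect_equal(rgps$start, ctg$start[10])
  expect_equal(rgps$end, ctg$end[3])
  clen <- ctg$contig_length[1]
  expect_equal(rgps$span, (clen - ctg$start[10]) + ctg$end[3])
  expect_setequal(rgps$genes[[1]], ctg$gene_id[c(10:12, 1:3)])
  # the same contig linearised yields two sub-threshold fragments: none
  expect_equal(nrow(detect_rgps(ctg %>% mutate(circular = FALSE))), 0L)
  # fully variable circular contig: one region, not two
  allc <- make_labeled_contig(rep("cloud", 8), circular = TRUE)
  expect_equal(nrow(detect_rgps(allc)), 1L)
  expect_equal(detect_rgps(allc)$n_genes, 8L)
})

test_that("the scanner matches exhaustive prefix enumeration on random contigs", {
  scoring <- rgp_scoring()
  withr::with_seed(59, {
    for (rep in 1:30) {
      n <- sample(5:50, 1)
      labs <- sample(c("persistent", "shell", "cloud"), n, replace = TRUE,
                     prob = c(0.55, 0.2, 0.25))
      lens <- sample(100:1500, n, replace = TRUE)
      gaps <- sample(0:300, n, replace = TRUE)
      ctg <- make_labeled_contig(labs, gene_len = lens, gap = gaps)
      got <- detect_rgps(ctg, scoring)
      want <- oracle_rgp_segments(labs, ctg$start, ctg$end, scoring)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$start, vapply(want, function(s) ctg$start[s$idx[1]],
                                       0))
        expect_equal(got$end,
                     vapply(want, function(s) ctg$end[s$idx[length(s$idx)]],
                            0))
        expect_equal(got$score, vapply(want, `[[`, 0, "score"))
      }
    }
  })
})

test_that("cross-strain RGP matching uses the query family denominator", {
  island <- function(genome, fams) {
    n <- length(fams) + 2L
    tibble(gene_id = sprintf("%s_%d", genome, seq_len(n)),
           genome_id = genome, contig_id = "c1",
           start = (seq_len(n) - 1L) * 1100L,
           end = (seq_len(n) - 1L) * 1100L + 1000L,
           strand = "+",
           family_id = c("CORE1", fams, "CORE2"),
           partition = c("persistent", rep("cloud", length(fams)),
                         "persistent"),
           circular = FALSE, contig_length = n * 1100L)
  }
  proj <- bind_rows(island("g1", c("A", "B", "C", "D")),
                    island("g2", c("A", "B", "C", "D")),
                    island("g3", c("E", "F", "G", "H")),
                    island("g4", c("A", "B", "X", "Y")))
  rgps <- detect_rgps(proj)
  expect_equal(nrow(rgps), 4L)
  m <- match_rgps(rgps, "g1_RGP_001")
  expect_equal(m$target_rgp, c("g2_RGP_001", "g4_RGP_001", "g3_RGP_001"))
  expect_equal(m$shared_family_percent, c(100, 50, 0))
  # restrict candidates to the query's species cluster
  clusters <- tibble(genome_id = c("g1", "g2", "g3", "g4"),
                     micgc = c("MICGC1", "MICGC1", "MICGC1", "MICGC2"))
  m2 <- match_rgps(rgps, "g1_RGP_001", clusters = clusters)
  expect_setequal(m2$genome_id, c("g2", "g3"))
  expect_error(match_rgps(rgps, "nope"), "unknown rgp_id")
})

test_that("annotation cross-links zero-fill the RGP x category grid", {
  labs <- c("persistent", rep("cloud", 5), rep("persistent", 3),
            rep("cloud", 5), "persistent")
  ctg <- make_labeled_contig(labs)
  rgps <- detect_rgps(ctg)
  expect_equal(nrow(rgps), 2L)
  expect_equal(nrow(rgp_annotation_crosslinks(rgps, NULL)), 0L)
  feat <- tibble(gene_id = c(rgps$genes[[1]][1:2], "ghost"),
                 category = c("AMR", "AMR", "virulence"))
  expect_warning(
    xl <- rgp_annotation_crosslinks(rgps, feat, known_genes = ctg$gene_id),
    "unknown genes")
  expect_equal(nrow(xl), 2L)   # 2 RGPs x 1 surviving category
  expect_equal(xl$n[xl$rgp_id == rgps$rgp_id[1] & xl$category == "AMR"], 2L)
  expect_equal(xl$n[xl$rgp_id == rgps$rgp_id[2] & xl$category == "AMR"], 0L)
})

test_that("projection validates family and partition coverage", {
  genes <- tibble(gene_id = c("a", "b"), genome_id = "g", contig_id = "c",
                  start = c(0L, 1000L), end = c(900L, 1900L))
  fam <- tibble(gene_id = c("a", "b"), family_id = c("F1", "F2"))
  part <- tibble(family_id = "F1", partition = "cloud")
  expect_error(project_partitions(genes, fam[1, ], part), "without family")
  expect_error(project_partitions(genes, fam, part), "without partition")
  part2 <- tibble(family_id = c("F1", "F2"),
                  partition = c("cloud", "persistent"))
  proj <- project_partitions(genes, fam, part2)
  expect_equal(proj$partition, c("cloud", "persistent"))
})

test_that("BED output splits origin-crossing regions into two intervals", {
  labs <- c(rep("cloud", 3), rep("persistent", 6), rep("cloud", 3))
  wrap <- detect_rgps(make_labeled_contig(labs, circular = TRUE))
  plain <- detect_rgps(make_labeled_contig(
    c("persistent", rep("cloud", 5), "persistent")))
  f <- withr::local_tempfile(fileext = ".bed")
  write_rgp_bed(bind_rows(plain, wrap), f,
                contig_lengths = tibble(genome_id = "g1", contig_id = "c1",
                                        length = 12 * 1100))
  lines <- read.delim(f, header = FALSE)
  expect_equal(nrow(lines), 3L)
  expect_true(all(lines$V3 > lines$V2))
})
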
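test_that("presence/absence binarises paralogs and enforces the genome minimum", {
  fam <- tibble(
    gene_id = sprintf("g%d", 1:5),
    genome_id = c("A", "A", "A", "B", "B"),
    family_id = c("F1", "F1", "F2", "F1", "F3")   # F1 has paralogs in A
  )
  expect_error(presence_absence(fam), "at least 15 genomes")
  expect_message(pa <- presence_absence(fam, allow_fewer = TRUE),
                 "explicit override")
  expect_equal(rownames(pa), c("F1", "F2", "F3"))
  expect_equal(colnames(pa), c("A", "B"))
  expect_equal(unname(pa["F1", ]), c(1L, 1L))   # binarised, not counted
  expect_equal(unname(pa["F2", ]), c(1L, 0L))
  expect_equal(sum(pa), 4L)
  wide <- tibble(gene_id = sprintf("g%d", 1:15),
                 genome_id = sprintf("G%02d", 1:15), family_id = "F1")
  expect_silent(presence_absence(wide))
})

test_that("pangenome graph counts genome-level family adjacencies", {
  mk <- function(genome, fams, circular = FALSE) {
    n <- length(fams)
    tibble(gene_id = sprintf("%s_%d", genome, seq_len(n)),
           genome_id = genome, contig_id = "c1",
           start = (seq_len(n) - 1L) * 1000L, circular = circular,
           family_id = fams)
  }
  split_fam <- function(df) list(genes = df %>% select(-family_id),
                                 fam = df %>% select(gene_id, family_id))
  # linear A-B-C: edges A-B and B-C only
  d <- split_fam(mk("g1", c("A", "B", "C")))
  g <- build_pangenome_graph(d$genes, d$fam)
  e <- igraph::as_data_frame(g) %>% arrange(from, to)
  expect_equal(e$from, c("A", "B"))
  expect_equal(e$to, c("B", "C"))
  expect_equal(e$weight, c(1, 1))
  # circular contig closes the loop
  d <- split_fam(mk("g1", c("A", "B", "C"), circular = TRUE))
  g <- build_pangenome_graph(d$genes, d$fam)
  expect_equal(igraph::ecount(g), 3)
  # tandem duplication: no self loop
  d <- split_fam(mk("g1", c("A", "A", "B")))
  g <- build_pangenome_graph(d$genes, d$fam)
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e$from, e$to), c("A", "B"))
  # each genome contributes at most 1 per edge, genomes accumulate
  rep1 <- mk("g1", c("A", "B", "A", "B"))
  rep2 <- mk("g2", c("A", "B"))
  genes <- bind_rows(rep1, rep2)
  d <- split_fam(genes)
  g <- build_pangenome_graph(d$genes, d$fam)
  e <- igraph::as_data_frame(g)
  expect_equal(e$weight, 2)
  # unassigned gene is an error
  expect_error(build_pangenome_graph(d$genes, d$fam[-1, ]),
               "without family assignment")
})

test_that("strict core requires presence in every genome", {
  pa <- matrix(c(1, 1, 1, 1, 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("F1", "F2"), c("A", "B", "C")))
  sc <- strict_components(pa)
  expect_equal(sc$component[sc$family_id == "F1"], "core")
  expect_equal(sc$component[sc$family_id == "F2"], "variable")
})

test_that("one EM iteration reproduces a hand Bayes computation", {
  pa <- matrix(c(1, 1, 1, 1,
                 1, 0, 1, 0,
                 0, 0, 0, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("F1", "F2", "F3"), LETTERS[1:4]))
  fit <- partition_em(pa, graph = NULL, beta = 0, max_iter = 1, tol = 0)
  # E-step by hand: flat priors cancel, eps rows start at 0.9/0.5/0.1
  lik <- function(x, e) prod(e^x * (1 - e)^(1 - x))
  r <- t(apply(pa, 1, function(x) {
    l <- c(lik(x, rep(0.9, 4)), lik(x, rep(0.5, 4)), lik(x, rep(0.1, 4)))
    l / sum(l)
  }))
  # M-step by hand
  ck <- colSums(r)
  eps <- sweep(t(r) %*% pa, 1, ck, "/")
  eps <- pmin(pmax(eps, 1e-3), 1 - 1e-3)
  ord <- order(-rowMeans(eps))
  r_ord <- r[, ord]
  colnames(r_ord) <- c("persistent", "shell", "cloud")
  expect_equal(unclass(fit$responsibilities), r_ord, tolerance = 1e-12)
  expect_equal(unname(fit$pi),
               unname((ck / 3)[ord] / sum(ck / 3)), tolerance = 1e-12)
  expect_equal(unname(unclass(fit$eps)), unname(eps[ord, ]),
               tolerance = 1e-12)
  labels <- c("persistent", "shell", "cloud")[max.col(r_ord,
                                                      ties.method = "first")]
  expect_equal(as.character(fit$partition$partition), labels)
  expect_equal(fit$iterations, 1L)
})

test_that("at beta = 0 the log-likelihood never decreases", {
  pa <- withr::with_seed(13, {
    m <- matrix(rbinom(50 * 20, 1, runif(50)), nrow = 50)
    dimnames(m) <- list(sprintf("F%02d", 1:50), sprintf("G%02d", 1:20))
    m
  })
  fit <- partition_em(pa, graph = NULL, beta = 0, max_iter = 200,
                      tol = 1e-12)
  expect_true(all(diff(fit$objective) >= -1e-8))
  expect_true(fit$converged)
})

test_that("the smoothed EM recovers planted partitions on a simulation", {
  spec <- simulation_spec(n_genomes = 16, n_persistent = 60, n_shell = 60,
                          n_cloud = 80, shell_block_size = 20, seed = 7)
  sim <- simulate_pangenome(spec, with_dna = FALSE, with_proteins = FALSE)
  fam <- sim$truth$families %>%
    left_join(sim$genes %>% select(gene_id, genome_id), by = "gene_id")
  pa <- presence_absence(fam)
  graph <- build_pangenome_graph(sim$genes, sim$truth$families)
  fit <- partition_em(pa, graph, beta = 0.5)
  expect_gte(partition_accuracy(fit, sim$truth$partitions), 0.95)
  expect_true(fit$converged)
  # relabeling invariant: persistent rows have the highest mean presence
  expect_true(mean(fit$eps["persistent", ]) >= mean(fit$eps["shell", ]))
  expect_true(mean(fit$eps["shell", ]) >= mean(fit$eps["cloud", ]))
})

test_that("partitions are invariant to row and column permutations", {
  pa <- withr::with_seed(29, {
    m <- matrix(rbinom(30 * 18, 1, rep(c(0.95, 0.5, 0.05), each = 10 * 18)),
                nrow = 30, byrow = TRUE)
    dimnames(m) <- list(sprintf("F%02d", 1:30), sprintf("G%02d", 1:18))
    m
  })
  fit <- partition_em(pa, beta = 0)
  perm <- withr::with_seed(1, list(r = sample(30), c = sample(18)))
  fit2 <- partition_em(pa[perm$r, perm$c], beta = 0)
  t1 <- tidy(fit) %>% arrange(family_id)
  t2 <- tidy(fit2) %>% arrange(family_id)
  expect_equal(t2$partition, t1$partition)
  expect_equal(t2$n_genomes_present, t1$n_genomes_present)
})

test_that("tidy, glance and summaries are mutually consistent", {
  pa <- matrix(c(rep(1L, 8), 1L, 0L, 1L, 0L, rep(0L, 3), 1L),
               nrow = 4, byrow = TRUE,
               dimnames = list(sprintf("F%d", 1:4), LETTERS[1:4]))
  fit <- partition_em(pa, beta = 0)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(gl$n_families, 4L)
  expect_equal(gl$n_persistent + gl$n_shell + gl$n_cloud, 4L)
  expect_true(all(abs(td$r_persistent + td$r_shell + td$r_cloud - 1) < 1e-9))
  fam <- tibble(gene_id = sprintf("x%d", 1:6),
                family_id = c("F1", "F1", "F2", "F3", "F4", "F4"))
  s <- pangenome_summary(fit, fam)
  expect_equal(sum(s$n_families), 4L)
  expect_equal(sum(s$n_genes), 6L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "pangenome_partition")
})
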
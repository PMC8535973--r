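test_that("fpkm_to_tpm normalizes columns to 1e6 and is scale-invariant", {
  m <- make_expr(matrix(c(5, 10, 5), 3, 1), scale = "linear")
  expect_equal(unname(fpkm_to_tpm(m)$values[, 1]), c(250000, 500000, 250000))

  set.seed(1)
  v <- matrix(runif(50 * 3, 0.1, 100), 50, 3)
  m <- make_expr(v, scale = "linear")
  m2 <- make_expr(2 * v, scale = "linear")
  expect_equal(fpkm_to_tpm(m)$values, fpkm_to_tpm(m2)$values)

  # element-wise formula oracle on a random column
  tpm <- fpkm_to_tpm(m)$values
  for (j in 1:3) {
    expect_equal(tpm[, j], v[, j] / sum(v[, j]) * 1e6,
                 ignore_attr = TRUE)
  }
  expect_equal(colSums(tpm), rep(1e6, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("fpkm_to_tpm rejects degenerate input", {
  v <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  m <- expression_matrix(v, scale = "linear")
  expect_error(fpkm_to_tpm(m), "s2")
  expect_error(expression_matrix(matrix(-1, 1, 1,
    dimnames = list("A", "s1")), scale = "linear"), "non-negative")
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1, 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(expression_matrix(v, "linear"), "duplicate gene")
  v <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("s1", "s1")))
  expect_error(expression_matrix(v, "linear"), "duplicate sample")
  v <- matrix(c(1, NA, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(expression_matrix(v, "linear"), "missing")
})

test_that("filter_samples applies the 30-day and event-completeness rules", {
  cl <- data.frame(sample_id = paste0("s", 1:4),
                   time = c(10, 29, 30, 400), event = c(1, 0, 1, 0))
  out <- filter_samples(cl)
  expect_equal(out$sample_id, c("s3", "s4"))
  expect_equal(attr(out, "removed"), c("s1", "s2"))

  cl$event[4] <- NA
  expect_equal(filter_samples(cl)$sample_id, "s3")

  cl2 <- data.frame(sample_id = c("a", "b"), time = c(5, 100), event = c(1, 1))
  expect_equal(filter_samples(cl2, min_days = 0)$sample_id, c("a", "b"))
})

test_that("merge_cohorts intersects genes and preserves cohorts", {
  m1 <- make_expr(matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("x1", "x2"))),
                  cohort = "c1")
  m2 <- make_expr(matrix(1:6, 3, 2,
                         dimnames = list(c("A", "B", "C"), c("y1", "y2"))),
                  cohort = "c2")
  mg <- merge_cohorts(list(m1, m2))
  expect_setequal(gene_ids(mg), c("A", "B"))
  expect_equal(sample_ids(mg), c("x1", "x2", "y1", "y2"))
  expect_equal(unname(mg$cohort), c("c1", "c1", "c2", "c2"))

  expect_equal(merge_cohorts(list(m1))$values, m1$values)

  # set-intersection oracle over random gene subsets, plus associativity
  set.seed(4)
  universe <- sprintf("G%02d", 1:20)
  mats <- lapply(1:3, function(i) {
    gs <- sort(sample(universe, sample(10:18, 1)))
    v <- matrix(rnorm(length(gs) * 3), length(gs), 3,
                dimnames = list(gs, paste0("c", i, "_s", 1:3)))
    expression_matrix(v, "log2", cohort = paste0("c", i))
  })
  merged <- merge_cohorts(mats)
  expect_setequal(gene_ids(merged),
                  Reduce(intersect, lapply(mats, gene_ids)))
  two_step <- merge_cohorts(list(merge_cohorts(mats[1:2]), mats[[3]]))
  expect_setequal(gene_ids(two_step), gene_ids(merged))
  expect_equal(two_step$values[gene_ids(merged), ],
               merged$values[gene_ids(merged), ])
})

test_that("merge_cohorts rejects duplicates and empty intersections", {
  m1 <- make_expr(matrix(1:2, 1, 2, dimnames = list("A", c("s1", "s2"))))
  m2 <- make_expr(matrix(1:2, 1, 2, dimnames = list("A", c("s2", "s3"))))
  expect_error(merge_cohorts(list(m1, m2)), "duplicate sample")
  m3 <- make_expr(matrix(1:2, 1, 2, dimnames = list("B", c("t1", "t2"))))
  expect_error(merge_cohorts(list(m1, m3)), "intersection")
})

test_that("correct_batch equalizes per-cohort gene moments and is idempotent", {
  set.seed(5)
  v <- matrix(rnorm(40 * 12, 6), 40, 12)
  coh <- rep(c("a", "b"), each = 6)
  v[, coh == "b"] <- v[, coh == "b"] * 1.7 + 2.5
  m <- make_expr(v, cohort = coh)
  adj <- correct_batch(m)
  for (g in 1:40) {
    expect_equal(mean(adj$values[g, coh == "a"]),
                 mean(adj$values[g, coh == "b"]), tolerance = 1e-9)
  }
  # within-cohort ordering preserved
  expect_equal(order(adj$values[1, coh == "a"]), order(v[1, coh == "a"]))
  # idempotency
  twice <- correct_batch(adj)
  expect_equal(twice$values, adj$values, tolerance = 1e-9)
})

test_that("correct_batch removes simulated batch structure (<1% between-cohort variance)", {
  sim <- simulate_study(sim_config(seed = 21, n_signature_genes = 50,
                                   n_noise_genes = 150, n_cohorts = 3,
                                   n_per_pattern = 40))
  adj <- correct_batch(sim$expression)
  coh <- factor(adj$cohort)
  # between-cohort fraction of per-gene variance via one-way decomposition
  frac <- apply(adj$values, 1, function(x) {
    gm <- tapply(x, coh, mean)
    nb <- tabulate(coh)
    between <- sum(nb * (gm - mean(x))^2)
    total <- sum((x - mean(x))^2)
    between / total
  })
  expect_lt(mean(frac), 0.01)
})

test_that("correct_batch error and degenerate paths", {
  m <- rand_expr(5, 4, seed = 6)
  expect_error(correct_batch(m), "single cohort")
  m2 <- rand_expr(5, 3, seed = 7, cohort = c("a", "a", "b"))
  expect_error(correct_batch(m2), "fewer than 2")
  v <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), paste0("s", 1:4)))
  v[1, 1:2] <- 3  # zero variance in cohort a for gene A
  m3 <- expression_matrix(v, "log2", cohort = c("a", "a", "b", "b"))
  expect_warning(adj <- correct_batch(m3), "zero variance")
  expect_equal(mean(adj$values[1, 1:2]), mean(adj$values[1, 3:4]),
               tolerance = 1e-9)
})

test_that("GMT parsing, validation and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tA", f)
  expect_warning(gs <- read_gene_sets(f), "duplicate")
  expect_equal(gs$S1, c("A", "B"))

  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), f)
  expect_error(read_gene_sets(f), "duplicate set")
  writeLines("S1\tonlytwo", f)
  expect_error(read_gene_sets(f), "line 1")
  writeLines(character(0), f)
  expect_error(read_gene_sets(f), "empty")

  set.seed(8)
  coll <- gene_sets(lapply(stats::setNames(1:5, paste0("set", 1:5)),
                           function(i) sample(LETTERS, sample(3:10, 1))))
  write_gene_sets(coll, f)
  back <- read_gene_sets(f)
  expect_equal(unclass(back), unclass(coll), ignore_attr = TRUE)
})

test_that("expression/clinical/mutation/CNV TSV readers validate input", {
  d <- withr::local_tempdir()
  ef <- file.path(d, "e.tsv")
  write.table(data.frame(gene_id = c("A", "B"), s1 = c(1, 2), s2 = c(3, 4)),
              ef, sep = "\t", row.names = FALSE, quote = FALSE)
  cf <- file.path(d, "c.tsv")
  write.table(data.frame(sample_id = c("s1", "s2"), cohort = c("x", "y")),
              cf, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- read_expression(ef, cf, scale = "linear")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m$cohort), c("x", "y"))

  mf <- file.path(d, "m.tsv")
  write.table(data.frame(Tumor_Sample_Barcode = "s1", Hugo_Symbol = "A",
                         Variant_Classification = "Bad_Class"),
              mf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_mutations(mf), "vocabulary")

  vf <- file.path(d, "v.tsv")
  write.table(data.frame(gene = "A", sample = "s1", state = 5),
              vf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cnv(vf), "state")
})

test_that("to_log2 declares the analysis scale", {
  m <- rand_expr(4, 3, scale = "linear", seed = 9)
  lg <- to_log2(m)
  expect_equal(lg$scale, "log2")
  expect_equal(lg$values, log2(m$values + 1))
  expect_identical(to_log2(lg), lg)
})
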
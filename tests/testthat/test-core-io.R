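test_that("expression matrix TSV round-trip preserves ids and values", {
  vals <- matrix(c(1.5, 2.25, 100, 0.125), 2, 2,
                 dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
  m <- expression_matrix(vals, scale = "raw")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  m2 <- read_expression_matrix(path, scale = "raw")
  # decimal-representable inputs survive bit-exactly
  expect_identical(m2$values, m$values)
  expect_identical(feature_ids(m2), c("miR-a", "miR-b"))
  expect_identical(sample_ids(m2), c("s1", "s2"))
})

test_that("malformed expression inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "miR-a\t1\t2", "miR-a\t3\t4"), path)
  expect_error(read_expression_matrix(path, "raw"), "miR-a")
  writeLines(c("feature\ts1\ts2", "miR-a\t1\toops"), path)
  expect_error(read_expression_matrix(path, "raw"), "oops")
  vals <- matrix(c(1, -2, 3, 4), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(vals, "raw"), "positive")
  expect_silent(expression_matrix(vals, "log10"))
})

test_that("log10 transform matches definition and round-trips", {
  vals <- matrix(c(100, 1, 10, 1000), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- log10_transform(expression_matrix(vals, "raw"))
  expect_equal(m$values[1, 1], 2)
  expect_equal(m$values[2, 1], 0)
  expect_identical(m$scale, "log10")
  expect_error(log10_transform(m), "twice")

  set.seed(42)
  raw <- matrix(10^stats::runif(60, -3, 3), 6, 10,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  tr <- log10_transform(expression_matrix(raw, "raw"))
  expect_equal(10^tr$values, raw, tolerance = 1e-12)
})

test_that("neglog10_ic50 maps censored samples to the minimum and reverses ranks", {
  ic50 <- named_vec(c(1e-6, 5e-7, 1e-5, 2e-6))
  p <- drug_response("d", ic50, max_conc = 1e-5)
  v <- neglog10_ic50(p)
  expect_equal(unname(v["s01"]), 6)
  expect_equal(unname(v["s03"]), -log10(1e-5))
  expect_equal(min(v), unname(v["s03"]))  # at-max sample sits at the floor
  expect_identical(rank(v), rank(-rank(ic50)))
  expect_error(drug_response("d", named_vec(c(-1, 1e-6)), 1e-5), "positive")
})

test_that("at-max detection uses a relative tolerance", {
  ic50 <- named_vec(c(1e-5 * (1 - 1e-12), 1e-5 * (1 - 1e-3), 1e-6))
  p <- drug_response("d", ic50, max_conc = 1e-5)
  expect_identical(unname(at_max(p)), c(TRUE, FALSE, FALSE))
})

test_that("IC50 table round-trips through TSV including missing values", {
  ic1 <- named_vec(c(1e-7, NA, 1e-5, 3e-6))
  ic2 <- named_vec(c(2e-6, 1e-6, 1e-6, 1e-6))
  drugs <- list(A = drug_response("A", ic1, 1e-5),
                B = drug_response("B", ic2, 2e-6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ic50_table(drugs, path)
  back <- read_ic50_table(path)
  expect_identical(names(back), c("A", "B"))
  expect_equal(back$A$ic50, ic1)
  expect_equal(back$B$max_conc, 2e-6)
})

test_that("uncentered correlation distance has the metric properties", {
  x <- c(1, 2, 3, 4)
  vals <- cbind(s1 = x, s2 = x, s3 = -x, s4 = c(4, 3, 2, 1))
  rownames(vals) <- paste0("f", 1:4)
  m <- toy_expr(vals)
  d <- as.matrix(uncentered_cor_dist(m))
  expect_equal(d["s1", "s2"], 0)              # identical profiles
  expect_equal(d["s1", "s3"], 2)              # negated profile
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
  expect_equal(diag(d), stats::setNames(rep(0, 4), colnames(d)))
})

test_that("well-separated templates cluster purely", {
  set.seed(11)
  templates <- list(c(10, 1, 1, 1, 1), c(1, 10, 1, 1, 1), c(1, 1, 10, 1, 1))
  cols <- do.call(cbind, lapply(rep(1:3, each = 3), function(k)
    templates[[k]] + stats::rnorm(5, sd = 0.05)))
  dimnames(cols) <- list(paste0("f", 1:5), paste0("s", 1:9))
  cl <- cluster_subtypes(toy_expr(cols), k = 3)
  expect_identical(length(unique(cl)), 3L)
  # each template's 3 replicates land in one cluster
  expect_true(all(tapply(cl, rep(1:3, each = 3),
                         function(g) length(unique(g))) == 1))
  expect_error(cluster_subtypes(toy_expr(cols), k = 10), "clusters")
})

test_that("GMT files round-trip and validate", {
  gsc <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = c("g3")), "toy")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_identical(back$sets, gsc$sets)
  expect_error(gene_set_collection(list(S1 = character())), "empty")
  expect_error(gene_set_collection(list(c("g1")), "x"))
})

test_that("subtype labels validate and round-trip", {
  lab <- subtype_labels(c("a", "b", "c"), c("basal", "luminal", "normal-like"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subtype_labels(lab, path)
  expect_identical(as.character(read_subtype_labels(path)), as.character(lab))
  expect_error(subtype_labels(c("a", "b"), c("basal", "HER2")), "HER2")
})
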
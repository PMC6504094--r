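rand_groups <- function(n_genes, n_samples, n1 = floor(n_samples / 2),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  y <- rep(0, n_samples); y[sample(n_samples, n1)] <- 1
  list(X = X, y = y)
}

test_that("quartile grouping sorts, floors and breaks ties by sample id", {
  x <- stats::setNames(1:12, sprintf("s%02d", 1:12))
  qg <- quartile_groups(x)
  expect_equal(qg$group_size, 3L)
  expect_identical(qg$bottom_ids, c("s01", "s02", "s03"))
  expect_identical(qg$top_ids, c("s10", "s11", "s12"))
  expect_equal(quartile_groups(stats::setNames(stats::rnorm(8),
                                               letters[1:8]))$group_size, 2L)
  tied <- stats::setNames(rep(1, 8), c("h", "g", "f", "e", "d", "c", "b", "a"))
  expect_identical(quartile_groups(tied)$bottom_ids, c("a", "b"))
  expect_error(quartile_groups(stats::setNames(1:3, letters[1:3])), "group size")
})

test_that("global test Q matches the dense quadratic-form oracle", {
  set.seed(40)
  for (i in 1:20) {
    g <- rand_groups(sample(1:30, 1), sample(6:20, 1))
    expect_equal(global_test_q(g$X, g$y), oracle_global_q(g$X, g$y),
                 tolerance = 1e-10)
  }
  # constant genes carry no signal
  expect_equal(global_test_q(matrix(5, 4, 6), rep(0:1, 3)), 0)
})

test_that("a single gene equal to the centered labels gives the hand-computed Q", {
  y <- c(1, 1, 0, 0)
  yc <- y - 0.5
  X <- matrix(yc, 1, 4)
  # Q = (x . yc)^2 / (m * s2) with x already centered; s2 = 1/4
  expect_equal(global_test_q(X, y), (sum(yc * yc))^2 / (1 * 0.25))
})

test_that("Q is invariant to label swap, gene order and additive shifts", {
  set.seed(41)
  for (i in 1:10) {
    g <- rand_groups(12, 14)
    q <- global_test_q(g$X, g$y)
    expect_equal(global_test_q(g$X, 1 - g$y), q, tolerance = 1e-10)
    expect_equal(global_test_q(g$X[sample(12), ], g$y), q, tolerance = 1e-10)
    expect_equal(global_test_q(g$X + 7, g$y + 3), q, tolerance = 1e-10)
  }
})

test_that("closed-form permutation moments agree with exhaustive enumeration", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(6:11, 1)
    n1 <- sample(2:(n - 2), 1)
    g <- rand_groups(sample(2:15, 1), n, n1 = n1)
    k <- mirdrug:::.gt_kernel(g$X, g$y)
    closed <- mirdrug:::.gt_perm_moments(k$A, n1, enum_limit = 0)
    qs <- oracle_q_enum(g$X, g$y)
    expect_equal(closed$mean, mean(qs), tolerance = 1e-9)
    expect_equal(closed$var, mean(qs^2) - mean(qs)^2, tolerance = 1e-9)
  }
})

test_that("permutation p respects its floor and matches enumeration at n = 6", {
  g <- rand_groups(5, 6, n1 = 3, seed = 43)
  p_any <- permutation_p(g$X, g$y, n_perm = 50, seed = 1)
  expect_gte(p_any, 1 / 51)
  # Monte Carlo converges to the exact enumeration tail probability
  exact <- mean(oracle_q_enum(g$X, g$y) >= oracle_global_q(g$X, g$y) - 1e-12)
  mc <- permutation_p(g$X, g$y, n_perm = 4000, seed = 2)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1 / 4001)
  # observed Q below every permuted Q gives p = 1
  X0 <- matrix(0, 3, 6)
  expect_equal(permutation_p(X0, g$y, n_perm = 20, seed = 3), 1)
})

test_that("approx_p tracks the exact enumeration p on a 3-vs-3 toy", {
  set.seed(44)
  for (i in 1:10) {
    g <- rand_groups(8, 6, n1 = 3)
    exact <- mean(oracle_q_enum(g$X, g$y) >= oracle_global_q(g$X, g$y) - 1e-12)
    expect_lt(abs(approx_p(g$X, g$y) - exact), 0.05)
  }
})

test_that("approx_p is approximately uniform under the null and small under signal", {
  set.seed(45)
  ps <- replicate(400, {
    g <- rand_groups(10, 18, n1 = 9)
    approx_p(g$X, g$y)
  })
  ks <- stats::ks.test(ps, "punif")$statistic
  expect_lt(unname(ks), 0.1)

  # strong separation on many informative genes
  y <- rep(0:1, each = 9)
  X <- matrix(stats::rnorm(50 * 18), 50, 18) +
    matrix(rep(y * 3, each = 50), 50, 18)
  expect_lt(approx_p(X, y), 1e-3)
})

test_that("pathway screen finds planted sets, drops absent genes, pools BH per miRNA", {
  set.seed(46)
  n <- 36
  samples <- sprintf("s%02d", 1:n)
  mir_vals <- matrix(stats::rnorm(2 * n, 2, 0.5), 2, n,
                     dimnames = list(c("miR-A", "miR-B"), samples))
  mirna <- toy_expr(mir_vals)
  genes <- sprintf("g%03d", 1:120)
  G <- matrix(stats::rnorm(120 * n), 120, n, dimnames = list(genes, samples))
  z <- as.numeric(scale(mir_vals["miR-A", ]))
  G[1:20, ] <- matrix(z, 20, n, byrow = TRUE) * 1.2 +
    matrix(stats::rnorm(20 * n), 20, n)
  mrna <- toy_expr(G)
  sets <- gene_set_collection(list(
    PLANTED = c(genes[1:20], "missing-gene"),
    NULL1 = genes[41:60], NULL2 = genes[61:80], NULL3 = genes[81:100]))
  res <- pathway_screen(mrna, sets, mirna, c("miR-A", "miR-B"),
                        n_perm = 300, seed = 5)
  planted <- res[res$mirna == "miR-A" & res$set_name == "PLANTED", ]
  expect_true(planted$significant)
  expect_equal(planted$n_genes_used, 20L)
  expect_false(any(res$significant[res$mirna == "miR-B" &
                                     res$set_name == "PLANTED"]))

  # BH pooled per miRNA: dropping the other miRNA changes nothing
  res_a <- pathway_screen(mrna, sets, mirna, "miR-A", n_perm = 300, seed = 5)
  expect_equal(res_a$p_bh, res$p_bh[res$mirna == "miR-A"])
  expect_equal(res_a$p_approx, res$p_approx[res$mirna == "miR-A"])
})

test_that("sets with no genes in the matrix are reported as untestable", {
  set.seed(47)
  n <- 16
  samples <- sprintf("s%02d", 1:n)
  mirna <- toy_expr(matrix(stats::rnorm(n), 1, n,
                           dimnames = list("miR-A", samples)))
  mrna <- toy_expr(matrix(stats::rnorm(5 * n), 5, n,
                          dimnames = list(paste0("g", 1:5), samples)))
  sets <- gene_set_collection(list(GONE = c("x1", "x2"), OK = c("g1", "g2")))
  res <- pathway_screen(mrna, sets, mirna, "miR-A", n_perm = 50, seed = 1)
  gone <- res[res$set_name == "GONE", ]
  expect_true(is.na(gone$Q) && is.na(gone$significant))
  expect_equal(gone$n_genes_used, 0L)
})
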
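test_that("Spearman correlation matches the rank-Pearson formula and t p-value", {
  expect_equal(spearman_assoc(1:5, c(2, 4, 6, 8, 10))[c("rho", "p_value")],
               list(rho = 1, p_value = 0))
  expect_equal(spearman_assoc(1:5, c(10, 8, 6, 4, 2))$rho, -1)

  sp <- spearman_assoc(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(sp$rho, 0.6)
  t_oracle <- 0.6 * sqrt((4 - 2) / (1 - 0.36))
  expect_equal(sp$p_value, 2 * stats::pt(-t_oracle, df = 2))

  # independent route: base R's rho estimate on tied data
  set.seed(1)
  x <- sample(rep(1:6, 2)); y <- stats::rnorm(12)
  expect_equal(spearman_assoc(x, y)$rho,
               stats::cor(x, y, method = "spearman"))
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
})

test_that("Spearman rho is invariant under monotone transforms and flips under -log10", {
  set.seed(2)
  for (i in 1:20) {
    x <- stats::rnorm(15)
    y <- 10^stats::runif(15, -8, -4)
    rho <- spearman_assoc(x, y)$rho
    expect_equal(spearman_assoc(exp(x), y^3)$rho, rho, tolerance = 1e-12)
    expect_equal(spearman_assoc(x, -log10(y))$rho, -rho, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney p equals full labeling enumeration (tie-free)", {
  mw <- mann_whitney_assoc(c(4, 5, 6, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(mw$U, 9)       # n1 * n2: complete separation
  expect_equal(mw$p_value, 0.1)
  expect_identical(mw$direction, "resistance")

  interleaved <- mann_whitney_assoc(c(1, 3, 5, 2, 4, 6),
                                    rep(c(TRUE, FALSE), each = 3))
  expect_gt(interleaved$p_value, 0.5)

  set.seed(3)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    n1 <- sample(seq_len(n - 1), 1)
    vals <- sample(seq_len(n))   # tie-free ranks
    grp <- seq_len(n) %in% sample(n, n1)
    mw <- mann_whitney_assoc(vals, grp)
    expect_equal(mw$p_value, oracle_mw_enum_p(vals, grp))
  }
})

test_that("Mann-Whitney handles ties and large samples like the reference test", {
  expect_equal(mann_whitney_assoc(c(1, 2, 3, 1, 2, 3),
                                  rep(c(TRUE, FALSE), each = 3))$U, 4.5)
  set.seed(4)
  for (i in 1:20) {
    n1 <- sample(8:20, 1); n2 <- sample(8:20, 1)
    vals <- c(stats::rnorm(n1, 0.3), stats::rnorm(n2))
    if (i %% 2 == 0) vals <- round(vals)  # force ties
    grp <- rep(c(TRUE, FALSE), c(n1, n2))
    mw <- mann_whitney_assoc(vals, grp)
    use_exact <- !any(duplicated(vals)) && (n1 + n2) <= 20
    ref <- suppressWarnings(stats::wilcox.test(vals[grp], vals[!grp],
                                               exact = use_exact,
                                               correct = TRUE))
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_assoc(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("two-step analysis screens then confirms planted censored effects", {
  set.seed(7)
  n <- 36
  mirna <- named_vec(stats::rnorm(n, 2, 0.5))
  # strong monotone effect + elevated miRNA in censored samples
  neglog <- 6 + 1.5 * (mirna - 2) + stats::rnorm(n, 0, 0.3)
  resist <- rank(-neglog) <= 8          # 8 most resistant lines
  mirna[resist] <- mirna[resist] - 1.5  # resistance goes with low miRNA here
  neglog2 <- 6 + 1.5 * (mirna - 2) + stats::rnorm(n, 0, 0.3)
  p <- censored_profile(neglog2, n_at_max = 8)
  expect_identical(classify_profile(p)$branch, "two_step")
  ts <- two_step_assoc(p, mirna)
  expect_true(ts$screened)
  expect_lt(ts$step2$p_value, 0.05)
  expect_equal(ts$final_p, ts$step2$p_value)

  # branch mismatch is an error
  p_lin <- censored_profile(named_vec(stats::rnorm(36, 6, 1)), 0)
  expect_error(two_step_assoc(p_lin, mirna), "two_step")
})

test_that("null miRNAs rarely pass the two-step screen", {
  set.seed(8)
  n <- 36
  neglog <- named_vec(stats::rnorm(n, 6, 1))
  p <- censored_profile(neglog, n_at_max = 8)
  screened <- replicate(200, {
    two_step_assoc(p, named_vec(stats::rnorm(n, 2, 0.5)))$screened
  })
  expect_gte(mean(!screened), 0.9)
})

test_that("a degenerate step-1 response is reported as not screenable", {
  neglog <- named_vec(c(rep(6, 26), seq(5.9, 5.5, length.out = 10)))
  p <- censored_profile(neglog, n_at_max = 0)
  # force two_step by censoring below: build 8 at max, 28 variable all equal
  neglog <- named_vec(c(rep(6, 28), seq(4, 4.5, length.out = 8)))
  p <- censored_profile(neglog, n_at_max = 8)
  ts <- two_step_assoc(p, named_vec(stats::rnorm(36)))
  expect_false(ts$screenable)
  expect_false(ts$screened)
})

test_that("associate_all routes branches, finds planted pairs and calls direction", {
  set.seed(9)
  n <- 36
  samples <- sprintf("s%02d", 1:n)
  X <- matrix(stats::rnorm(51 * n, 2, 0.5), 51, n,
              dimnames = list(sprintf("m%02d", 1:51), samples))
  neglog <- 6 + 1.2 * (X[1, ] - 2) + stats::rnorm(n, 0, 0.3)
  drug <- censored_profile(neglog, 0, drug = "lin")
  names(drug$ic50) <- samples
  res <- associate_all(toy_expr(X), list(lin = drug))
  expect_equal(nrow(res), 51L)
  expect_identical(unique(res$branch), "spearman")
  expect_identical(res$mirna[which.min(res$p_value)], "m01")
  expect_identical(res$direction[res$mirna == "m01"], "sensitivity")

  # negative association -> resistance
  drug2 <- censored_profile(stats::setNames(6 - 1.2 * (X[2, ] - 2) +
                                              stats::rnorm(n, 0, 0.3), samples),
                            0, drug = "neg")
  res2 <- associate_all(toy_expr(X), list(neg = drug2))
  expect_identical(res2$direction[res2$mirna == "m02"], "resistance")
  expect_lt(res2$p_value[res2$mirna == "m02"], 0.001)
})

test_that("associate_all requires log10 miRNA data and shared samples", {
  X <- matrix(stats::runif(8, 1, 2), 2, 4,
              dimnames = list(c("a", "b"), sprintf("s%02d", 1:4)))
  raw <- expression_matrix(X, "raw")
  p <- censored_profile(named_vec(stats::rnorm(4, 6)), 0)
  expect_error(associate_all(raw, list(p)), "log10")
  other <- drug_response("x", stats::setNames(10^-c(6, 7), c("z1", "z2")), 1e-5)
  expect_error(associate_all(log10_transform(raw), list(other)), "shared")
})
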
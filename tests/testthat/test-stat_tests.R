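test_that("rank-sum test handles symmetry, separation and ties", {
  r <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # complete separation: U equals n1 * n2, counted by brute force
  r2 <- wilcoxon_test(c(3, 4, 5), c(1, 2))
  expect_equal(attr(r2, "U"), 6)
  expect_equal(attr(r2, "U"), oracle_u(c(3, 4, 5), c(1, 2)))
  expect_equal(attr(r2, "auc"), 1)

  # tie correction shrinks the variance, so |z_on| >= |z_off|
  x <- c(0, 0, 1, 1, 2); y <- c(0, 1, 1, 2, 2)
  z_on <- wilcoxon_test(x, y, tie_correct = TRUE)$statistic
  z_off <- wilcoxon_test(x, y, tie_correct = FALSE)$statistic
  expect_gte(abs(z_on), abs(z_off))
  expect_equal(z_on, oracle_wilcoxon_z(x, y, TRUE), tolerance = 1e-12)
  expect_equal(z_off, oracle_wilcoxon_z(x, y, FALSE), tolerance = 1e-12)

  # all values identical with tie correction: degenerate contract
  r3 <- wilcoxon_test(c(2, 2), c(2, 2, 2), tie_correct = TRUE)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
})

test_that("rank-sum statistics match the pair-counting oracle on random draws", {
  set.seed(101)
  for (i in 1:50) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- sample(0:4, n1, replace = TRUE)
    y <- sample(0:4, n2, replace = TRUE)
    r <- wilcoxon_test(x, y, tie_correct = TRUE)
    expect_equal(attr(r, "U"), oracle_u(x, y))
    expect_equal(attr(r, "auc"), oracle_u(x, y) / (n1 * n2))
    expect_equal(r$statistic, oracle_wilcoxon_z(x, y, TRUE),
                 tolerance = 1e-10)
    # group swap flips the statistic, p unchanged
    rs <- wilcoxon_test(y, x, tie_correct = TRUE)
    expect_equal(rs$statistic, -r$statistic, tolerance = 1e-10)
    expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  }
})

test_that("t statistics match the reference implementation", {
  set.seed(7)
  x <- rnorm(8, 1); y <- rnorm(13)
  w <- welch_t_test(x, y)
  ref <- t.test(x, y)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)

  s <- student_t_test(x, y)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(s$statistic, unname(ref2$statistic), tolerance = 1e-10)
  expect_equal(s$df, length(x) + length(y) - 2)
  expect_equal(s$p_value, ref2$p.value, tolerance = 1e-10)

  # equal group sizes: Welch and Student statistics coincide (df differ)
  x2 <- rnorm(9); y2 <- rnorm(9, 0.5)
  expect_equal(welch_t_test(x2, y2)$statistic,
               student_t_test(x2, y2)$statistic, tolerance = 1e-12)

  # identical groups: degenerate contract
  expect_equal(welch_t_test(c(1, 1, 2), c(1, 1, 2))$statistic, 0)
  expect_equal(welch_t_test(c(1, 1, 2), c(1, 1, 2))$p_value, 1)
  # zero spread, unequal means: capped statistic
  expect_equal(abs(welch_t_test(c(2, 2), c(1, 1))$statistic), 1e3)
})

test_that("overestimated variance replaces the rest-group size by n1", {
  set.seed(8)
  x <- rnorm(5, 1); y <- rnorm(40)
  r <- welch_t_test(x, y, overestim_var = TRUE)
  n1 <- 5
  a1 <- var(x) / n1; a2 <- var(y) / n1
  expect_equal(r$statistic, (mean(x) - mean(y)) / sqrt(a1 + a2),
               tolerance = 1e-12)
  expect_equal(r$df, (a1 + a2)^2 / (a1^2 / (n1 - 1) + a2^2 / (n1 - 1)),
               tolerance = 1e-12)
  # inflated standard error: weaker statistic than plain Welch here
  expect_lt(abs(r$statistic), abs(welch_t_test(x, y)$statistic))
})

test_that("detection test reproduces the exact conditional p-value", {
  # 5/5 vs 0/5 detected: enumeration gives 2 / choose(10, 5)
  r <- detection_test(c(1, 2, 1, 3, 1), c(0, 0, 0, 0, 0))
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)

  # equal detection proportions with identical n: p = 1
  expect_equal(detection_test(c(1, 1, 0, 0), c(2, 5, 0, 0))$p_value, 1)

  # symmetric in group swap
  x <- c(1, 0, 1, 1, 0, 1); y <- c(0, 0, 1, 0, 0, 0, 1)
  expect_equal(detection_test(x, y)$p_value, detection_test(y, x)$p_value,
               tolerance = 1e-12)

  # cross-check against the reference exact test on random tables
  set.seed(33)
  for (i in 1:40) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rbinom(n1, 1, 0.5); y <- rbinom(n2, 1, 0.2)
    ref <- fisher.test(matrix(c(sum(x), n1 - sum(x),
                                sum(y), n2 - sum(y)), 2))$p.value
    expect_equal(detection_test(x, y)$p_value, ref, tolerance = 1e-9)
  }
})

test_that("logistic LRT obeys likelihood identities and a grid oracle", {
  # constant expression: no information, deviance difference 0
  r0 <- logistic_lrt(rep(1, 5), rep(1, 7))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # duplicating every cell doubles the deviance difference
  x <- c(0, 0.5, 2, 3); y <- c(0, 0, 0.5, 1, 1)
  r1 <- logistic_lrt(x, y)
  r2 <- logistic_lrt(rep(x, 2), rep(y, 2))
  expect_equal(r2$statistic, 2 * r1$statistic, tolerance = 1e-6)

  # grid-search maximum likelihood oracle
  grid_dev <- function(x, y) {
    resp <- c(rep(1, length(x)), rep(0, length(y)))
    ex <- c(x, y)
    best <- -Inf
    for (b0 in seq(-6, 6, by = 0.02)) {
      for (b1 in seq(-6, 6, by = 0.02)) {
        eta <- b0 + b1 * ex
        ll <- sum(resp * eta - log1p(exp(eta)))
        if (ll > best) best <- ll
      }
    }
    n1 <- length(x); n <- length(resp)
    ll0 <- n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n)
    2 * (best - ll0)
  }
  expect_equal(r1$statistic, grid_dev(x, y), tolerance = 0.05)
})

test_that("Poisson two-group test has closed-form rates and matches an optimizer", {
  # rate MLE: counts {2, 4} with unit library sizes
  r <- poisson_two_group(c(2, 4), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(attr(r, "lambda")[1], 3)

  # exactly equal rates: statistic 0
  r0 <- poisson_two_group(c(2, 2), c(4), c(1, 1), c(2))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)

  # both groups all zero
  expect_equal(poisson_two_group(c(0, 0), c(0, 0), c(1, 1), c(1, 1))$p_value,
               1)

  # numerical likelihood optimization oracle on a random instance
  set.seed(4)
  x <- rpois(6, 3); y <- rpois(9, 1)
  lx <- runif(6, 0.5, 2); ly <- runif(9, 0.5, 2)
  nll <- function(lam, cts, lib) -sum(dpois(cts, lam * lib, log = TRUE))
  opt1 <- optimize(nll, c(1e-6, 50), cts = x, lib = lx)
  opt2 <- optimize(nll, c(1e-6, 50), cts = y, lib = ly)
  opt0 <- optimize(nll, c(1e-6, 50), cts = c(x, y), lib = c(lx, ly))
  ref <- 2 * (opt0$objective - opt1$objective - opt2$objective)
  expect_equal(poisson_two_group(x, y, lx, ly)$statistic, ref,
               tolerance = 1e-5)
})

test_that("AUC equals the brute-force pair fraction and bounds", {
  expect_equal(auc_statistic(c(1, 2), c(1, 2))$statistic, 0.5)
  expect_equal(attr(auc_statistic(c(1, 2), c(1, 2)), "power"), 0)
  expect_equal(auc_statistic(c(5, 6), c(1, 2))$statistic, 1)
  set.seed(12)
  for (i in 1:30) {
    x <- sample(0:3, 7, replace = TRUE)
    y <- sample(0:3, 5, replace = TRUE)
    expect_equal(auc_statistic(x, y)$statistic, oracle_u(x, y) / 35)
  }
})

test_that("Cohen's d is scale invariant with documented degenerate caps", {
  x <- c(1, 2, 3, 6); y <- c(2, 4, 1)
  expect_equal(cohens_d(x, y), oracle_cohens_d(x, y), tolerance = 1e-12)
  expect_equal(cohens_d(3 * x + 2, 3 * y + 2), cohens_d(x, y),
               tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2), c(2, 1)), 0)
  # means 2 vs 1, both SD exactly 1
  a <- 2 + c(-1, 1) * sqrt(2) / 2
  b <- 1 + c(-1, 1) * sqrt(2) / 2
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)
  expect_equal(cohens_d(c(2, 2), c(1, 1)), 1e3)
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
})

test_that("detection log fold-change follows its pseudo-counted formula", {
  expect_equal(detection_lfc(c(1, 0, 1), c(2, 0, 3)), 0)
  expect_equal(detection_lfc(rep(1, 10), rep(0, 10)),
               log2(10.5 / 11) - log2(0.5 / 11), tolerance = 1e-12)
  x <- c(1, 1, 0, 0, 1); y <- c(0, 1, 0)
  expect_equal(detection_lfc(x, y), -detection_lfc(y, x))
})

test_that("cosine score hits its closed forms", {
  ind <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(cosine_score(c(3, 3, 0, 0, 0, 0), ind), 1)
  expect_equal(cosine_score(rep(4, 6), ind), sqrt(2 / 6), tolerance = 1e-12)
  expect_equal(cosine_score(rep(0, 6), ind), 0)
})

test_that("the two log fold-change dialects agree and diverge as documented", {
  set.seed(21)
  x <- abs(rnorm(9)); y <- abs(rnorm(6))
  expect_equal(lfc_seurat(x, y), oracle_lfc_seurat(x, y), tolerance = 1e-12)
  expect_equal(lfc_scanpy(x, y), oracle_lfc_scanpy(x, y), tolerance = 1e-12)
  expect_equal(lfc_seurat(x, x), 0)
  expect_equal(lfc_scanpy(x, x), 0)

  # de-log-then-average: group at ln 2 against zeros gives exactly 1
  expect_equal(lfc_seurat(rep(log(2), 4), rep(0, 5)), 1, tolerance = 1e-12)

  # zero-expression blow-up of the average-then-de-log formula
  g1 <- c(0, 2); g2 <- rep(0, 10)
  expect_equal(lfc_scanpy(g1, g2), 30.67832, tolerance = 1e-4)
  expect_equal(lfc_seurat(g1, g2), 2.068508, tolerance = 1e-4)
})

test_that("|z| ordering equals p ordering for z-based tests", {
  set.seed(55)
  d <- make_random_dataset(n_genes = 200, n_cells = 60, K = 2, seed = 55)
  i1 <- which(d$clusters$labels == "k1")
  i2 <- which(d$clusters$labels == "k2")
  r <- markerbench:::mat_wilcoxon(d$lognorm$values, i1, i2, TRUE)
  expect_identical(order(-abs(r$statistic), seq_along(r$statistic)),
                   order(r$log_p, -abs(r$statistic),
                         seq_along(r$statistic)))
})

test_that("Welch p-values can disagree with |t| order across differing df", {
  # t = 2.1 at nu = 2 versus t = 2.0 at nu = 200
  x1 <- c(0, 1); y1 <- c(0, 1) - 2.1 * sqrt(0.5)
  a <- welch_t_test(x1, y1)
  expect_equal(a$statistic, 2.1, tolerance = 1e-10)
  expect_equal(a$df, 2, tolerance = 1e-10)
  expect_equal(a$p_value, 2 * pt(-2.1, 2), tolerance = 1e-10)
  expect_equal(a$p_value, 0.1706, tolerance = 1e-2)

  b0 <- as.numeric(scale(1:101))
  x2 <- b0 + 2 * sqrt(2 / 101); y2 <- b0
  b <- welch_t_test(x2, y2)
  expect_equal(b$statistic, 2, tolerance = 1e-10)
  expect_equal(b$df, 200, tolerance = 1e-8)
  expect_equal(b$p_value, 2 * pt(-2, 200), tolerance = 1e-10)
  expect_equal(b$p_value, 0.0470, tolerance = 1e-2)

  expect_gt(a$statistic, b$statistic)
  expect_gt(a$p_value, b$p_value)  # discordant pair
})
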
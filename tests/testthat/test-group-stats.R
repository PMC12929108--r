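test_that("covariate adjustment equals closed-form OLS residuals", {
  set.seed(71)
  n <- 40
  cov_df <- data.frame(age = rnorm(n, 60, 8), gender = rbinom(n, 1, 0.5))

  # orthogonal covariates reduce to centering
  y <- rnorm(n)
  r0 <- covariate_adjust(y, NULL)
  expect_equal(r0, y - mean(y))

  # outcome exactly linear in age: residuals vanish
  y_lin <- 3 + 0.5 * cov_df$age
  expect_lt(max(abs(covariate_adjust(y_lin, cov_df["age"]))), 1e-10)

  # random data vs normal-equations oracle
  y <- rnorm(n)
  x <- cbind(1, as.matrix(cov_df))
  beta <- solve(t(x) %*% x, t(x) %*% y)
  expect_equal(covariate_adjust(y, cov_df), as.vector(y - x %*% beta),
               tolerance = 1e-10)

  # collinear design rejected with the offending column named
  bad <- data.frame(age = cov_df$age, age2 = 2 * cov_df$age)
  expect_error(covariate_adjust(y, bad), "collinear")
})

test_that("permutation test degenerate and saturated cases", {
  g <- rep(c("a", "b"), each = 15)
  expect_equal(permutation_test(rep(2, 30), g, n_perm = 99,
                                seed = 1)$p_value, 1)

  set.seed(72)
  y <- c(rnorm(15), rnorm(15, 5))  # 5 SD separation
  res <- permutation_test(y, g, n_perm = 500, seed = 2)
  expect_equal(res$p_value, 1 / 501)

  expect_error(permutation_test(rnorm(4), c("a", "a", "a", "b"),
                                n_perm = 9),
               ">= 2 subjects")
})

test_that("permutation p-values are invariant to affine rescaling", {
  set.seed(73)
  y <- rnorm(24)
  g <- rep(c("a", "b"), 12)
  cov_df <- data.frame(age = rnorm(24))
  p1 <- permutation_test(y, g, cov_df, n_perm = 200, seed = 3)$p_value
  p2 <- permutation_test(10 * y + 7, g, cov_df, n_perm = 200,
                         seed = 3)$p_value
  expect_equal(p1, p2)
})

test_that("covariate-adjusted permutation test is calibrated under the null", {
  # type-I error at alpha = 0.05 over null simulations
  set.seed(74)
  n_sim <- 400
  n <- 30
  g <- rep(c("a", "b"), each = 15)
  rejections <- vapply(seq_len(n_sim), function(i) {
    cov_df <- data.frame(age = rnorm(n, 60, 8), gender = rbinom(n, 1, 0.5))
    y <- rnorm(n) + 0.3 * scale(cov_df$age)[, 1]
    permutation_test(y, g, cov_df, n_perm = 200,
                     seed = 1000 + i)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

test_that("BH adjustment follows the step-up rule", {
  r <- fdr_bh(c(0.01, 0.02, 0.5), q = 0.05)
  expect_equal(r$p_adj, c(0.03, 0.03, 0.5))
  expect_equal(r$reject, c(TRUE, TRUE, FALSE))

  r <- fdr_bh(rep(1, 5))
  expect_equal(r$p_adj, rep(1, 5))
  expect_false(any(r$reject))

  r <- fdr_bh(0.03)
  expect_equal(r$p_adj, 0.03)
})

test_that("BH agrees with a brute-force threshold search", {
  # oracle: reject the largest set {p_(i) <= i q / m}; adjusted p_i is the
  # smallest q at which p_i would be rejected
  set.seed(75)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    adj <- fdr_bh(p)$p_adj
    ord <- order(p)
    oracle <- numeric(m)
    for (j in seq_len(m)) {
      cand <- vapply(seq_len(m), function(i2) {
        m * sort(p)[i2] / i2
      }, numeric(1))
      oracle[ord[j]] <- min(1, min(cand[j:m]))
    }
    expect_equal(adj, oracle, tolerance = 1e-12)
  }
})

test_that("spearman partial correlation reduces and matches the formula oracle", {
  set.seed(76)
  n <- 30
  x <- rnorm(n)
  y <- rnorm(n)

  # no covariate influence: equals ordinary Spearman
  r0 <- spearman_partial(x, y, NULL)
  expect_equal(r0$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)

  # strictly increasing transform: rho = 1
  r1 <- spearman_partial(x, exp(x), NULL)
  expect_equal(r1$rho, 1)

  # recursive partial-correlation formula oracle with one covariate
  cv <- rnorm(n)
  got <- spearman_partial(x, y, data.frame(cv = cv))
  rx <- rank(x); ry <- rank(y); rc <- rank(cv)
  rxy <- cor(rx, ry); rxc <- cor(rx, rc); ryc <- cor(ry, rc)
  oracle <- (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  expect_equal(got$rho, oracle, tolerance = 1e-10)

  expect_error(spearman_partial(rep(1, 10), rnorm(10), NULL),
               "zero residual variance")
})

test_that("spearman partial rank-transforms before residualizing", {
  # a monotone nonlinear covariate effect is removed on the rank scale
  set.seed(77)
  n <- 40
  cv <- runif(n, 1, 3)
  x <- cv^3 + rnorm(n, sd = 0.1)
  y <- -cv^3 + rnorm(n, sd = 0.1)
  adj <- spearman_partial(x, y, data.frame(cv = rank(cv)))
  raw <- cor(x, y, method = "spearman")
  expect_lt(abs(adj$rho), abs(raw))
})

test_that("nbs finds planted components and respects component structure", {
  set.seed(78)
  n_nodes <- 10
  m <- n_nodes * (n_nodes - 1) / 2
  n_sub <- 30
  g <- rep(c("pat", "ctl"), each = 15)

  # single strong edge -> one component of size 1
  y <- matrix(rnorm(n_sub * m), n_sub, m)
  y[g == "pat", 3] <- y[g == "pat", 3] + 4
  res <- nbs(y, g, n_iter = 100, seed = 4)
  expect_equal(nrow(res$components), 1)
  expect_equal(res$components$n_edges, 1)
  expect_equal(which(!is.na(res$edges$component)), 3)

  # null data: typically no suprathreshold edges, empty result is valid
  y0 <- matrix(rnorm(n_sub * m), n_sub, m)
  res0 <- nbs(y0, g, n_iter = 50, seed = 5)
  expect_s3_class(res0$components, "tbl_df")

  # corrected p monotone in component size under the shared null
  y2 <- matrix(rnorm(n_sub * m), n_sub, m)
  y2[g == "pat", 1:2] <- y2[g == "pat", 1:2] + 3    # edges (1,2),(1,3)
  y2[g == "pat", m] <- y2[g == "pat", m] + 3        # edge (9,10)
  res2 <- nbs(y2, g, n_iter = 100, seed = 6)
  if (nrow(res2$components) >= 2) {
    big <- which.max(res2$components$n_edges)
    expect_true(all(res2$components$p_corrected[big] <=
                      res2$components$p_corrected))
  }
})

test_that("nbs recovers a planted 8-edge connected effect", {
  set.seed(79)
  n_nodes <- 12
  m <- n_nodes * (n_nodes - 1) / 2
  g <- rep(c("pat", "ctl"), each = 15)
  # a connected 8-edge star-like subgraph on nodes 1..5
  edge_id <- function(i, j, n) {
    # row-major upper-triangle index
    (i - 1) * n - i * (i - 1) / 2 + (j - i)
  }
  planted <- c(edge_id(1, 2, 12), edge_id(1, 3, 12), edge_id(1, 4, 12),
               edge_id(1, 5, 12), edge_id(2, 3, 12), edge_id(2, 4, 12),
               edge_id(3, 5, 12), edge_id(4, 5, 12))
  y <- matrix(rnorm(30 * m), 30, m)
  y[g == "pat", planted] <- y[g == "pat", planted] + 2.5
  cov_df <- data.frame(age = rnorm(30, 60, 8), gender = rbinom(30, 1, 0.5))
  res <- nbs(y, g, cov_df, n_iter = 200, seed = 7)
  expect_gte(nrow(res$components), 1)
  big <- which.max(res$components$n_edges)
  expect_lt(res$components$p_corrected[big], 0.05)
  found <- res$edges$edge[!is.na(res$edges$component) &
                            res$edges$component == big]
  expect_gte(length(intersect(found, planted)), 6)
})

test_that("demographics tests match hand computation on printed-style tables", {
  # gender chi-square on counts 14/13, 18/19, 10/8 vs hand formula
  manifest <- tibble::tibble(
    group = rep(c("HC", "HZ", "PHN"), times = c(27, 37, 18)),
    gender = c(rep(1, 14), rep(0, 13), rep(1, 18), rep(0, 19),
               rep(1, 10), rep(0, 8)),
    age = rnorm(82, 60, 8))
  out <- demographics_tests(manifest)
  obs <- matrix(c(14, 13, 18, 19, 10, 8), 2, 3)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_equal(out$statistic[out$test == "chisq_gender"], chi2,
               tolerance = 1e-10)
  expect_equal(out$df[out$test == "chisq_gender"], 2)

  # identical samples: Mann-Whitney finds no shift
  manifest$nrs <- NA_real_
  manifest$nrs[manifest$group == "HZ"] <- rep(1:5, length.out = 37)
  manifest$nrs[manifest$group == "PHN"] <- rep(1:5, length.out = 18)
  out2 <- demographics_tests(manifest, score = "nrs")
  expect_gt(out2$p_value[out2$test == "mann_whitney_nrs"], 0.5)

  expect_error(demographics_tests(manifest[, "age", drop = FALSE]),
               "must contain")
})

test_that("demographics p-values are near-uniform under identical groups", {
  set.seed(80)
  ps <- vapply(1:100, function(i) {
    manifest <- tibble::tibble(
      group = rep(c("A", "B", "C"), each = 15),
      age = rnorm(45, 60, 8),
      gender = rbinom(45, 1, 0.5))
    # sparse gender tables occasionally trigger the chi-square
    # small-expected-count warning; irrelevant to the age test here
    suppressWarnings(demographics_tests(manifest)$p_value[1])
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)  # roughly uniform mean 0.5
})

test_that("adjusted and unadjusted tests agree when covariates are inert", {
  set.seed(81)
  n <- 24
  g <- rep(c("a", "b"), each = 12)
  rates <- vapply(1:150, function(i) {
    y <- rnorm(n)
    cov_df <- data.frame(age = rnorm(n))
    c(permutation_test(y, g, cov_df, n_perm = 100,
                       seed = 2000 + i)$p_value < 0.05,
      permutation_test(y, g, NULL, n_perm = 100,
                       seed = 2000 + i)$p_value < 0.05)
  }, logical(2))
  expect_lt(abs(mean(rates[1, ]) - mean(rates[2, ])), 0.06)
})

test_that("group contrasts table wires permutation tests to FDR", {
  set.seed(82)
  d <- tibble::tibble(
    group = rep(c("A", "B", "C"), each = 10),
    age = rnorm(30, 60, 5), gender = rbinom(30, 1, 0.5),
    m1 = rnorm(30), m2 = c(rnorm(10), rnorm(10, 4), rnorm(10)))
  out <- group_contrasts(d, c("m1", "m2"), n_perm = 200, seed = 9)
  expect_equal(nrow(out), 2 * 3)
  expect_true(all(out$p_adj >= out$p_raw - 1e-12))
  ab <- out$metric == "m2" & out$group_1 == "A" & out$group_2 == "B"
  expect_true(out$reject[ab])
})
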
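test_that("Grafen branch lengths match hand derivations", {
  # 2-tip cherry: both branches length 1
  t2 <- grafen_branch_lengths(ape::read.tree(text = "(A,B);"))
  expect_equal(sort(t2$edge.length), c(1, 1))

  # 3-tip caterpillar ((A,B),C): inner node height 0.5
  t3 <- grafen_branch_lengths(ape::read.tree(text = "((A,B),C);"))
  depths <- ape::node.depth.edgelength(t3)
  expect_equal(depths[1:3], rep(1, 3))  # ultrametric, root height 1
  tip_edge <- t3$edge.length[match(1:3, t3$edge[, 2])]
  names(tip_edge) <- t3$tip.label
  expect_equal(unname(tip_edge[c("A", "B")]), c(0.5, 0.5))
  expect_equal(unname(tip_edge["C"]), 1)

  # generated trees are ultrametric after Grafen assignment
  for (i in 1:5) {
    tr <- generate_phylogeny(paste0("s", 1:12), seed = i)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
})

test_that("the Brownian phylogenetic covariance has the path structure", {
  t3 <- grafen_branch_lengths(ape::read.tree(text = "((A,B),C);"))
  C <- phylo_covariance(t3)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))

  # star tree: no shared history
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(phylo_covariance(star), diag(4), ignore_attr = TRUE)

  # PSD for generated trees
  for (i in 1:5) {
    C <- phylo_covariance(generate_phylogeny(paste0("s", 1:15), seed = i))
    expect_gte(min(eigen(C, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("PGLS reduces to OLS under identity and interpolates exact data", {
  set.seed(91)
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  f <- pgls(y ~ x, d)
  ols <- lm(y ~ x, d)
  expect_equal(coef(f), coef(ols), tolerance = 1e-12)
  expect_equal(f$se, summary(ols)$coefficients[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)

  # exact linear data: slope 2, zero residual, any valid C
  tree <- generate_phylogeny(paste0("s", 1:10), seed = 2)
  C <- phylo_covariance(tree)
  d2 <- data.frame(species = rownames(C), x = 1:10, y = 2 * (1:10))
  f2 <- pgls(y ~ x, d2, C)
  expect_equal(unname(coef(f2)), c(0, 2), tolerance = 1e-10)
  expect_lt(f2$rss, 1e-16)
  expect_error(pgls(y ~ x, data.frame(x = rep(1, 10), y = 1:10)),
               "singular")
})

test_that("PGLS agrees with the nlme Brownian-correlation route", {
  tree <- generate_phylogeny(paste0("s", 1:25), seed = 3)
  C <- phylo_covariance(tree)
  set.seed(92)
  x <- rnorm(25)
  y <- 1 + 0.8 * x + as.numeric(t(chol(C)) %*% rnorm(25)) * 0.5
  d <- data.frame(species = rownames(C), x = x, y = y)
  f <- pgls(y ~ x, d, C)
  rownames(d) <- d$species
  g <- nlme::gls(y ~ x, d,
                 correlation = ape::corBrownian(1, tree, form = ~species))
  expect_equal(coef(f), coef(g), tolerance = 1e-8)
  expect_equal(f$se, sqrt(diag(stats::vcov(g))), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PGLS recovers a known slope under Brownian noise", {
  tree <- generate_phylogeny(paste0("s", 1:40), seed = 4)
  C <- phylo_covariance(tree)
  L <- t(chol(C))
  slopes <- numeric(10)
  for (i in 1:10) {
    set.seed(400 + i)
    x <- runif(40, -1, 3)
    y <- 0.5 + 1.3 * x + as.numeric(L %*% rnorm(40)) * 0.25
    slopes[i] <- coef(pgls(y ~ x, data.frame(species = rownames(C),
                                             x = x, y = y), C))[2]
  }
  expect_lt(abs(mean(slopes) - 1.3), 0.1)
})

test_that("bias-model comparison selects the generating form", {
  tree <- generate_phylogeny(paste0("s", 1:30), seed = 5)
  C <- phylo_covariance(tree)
  set.seed(93)
  x <- runif(30, -1, 3)

  # constant bias: intercept-only wins
  y0 <- 45 + rnorm(30, sd = 2)
  m0 <- fit_bias_models(y0, x, C, species = rownames(C))
  expect_equal(m0$selected, "intercept")

  # linear decline (slope about -4): linear wins
  y1 <- 47 - 4 * x + rnorm(30, sd = 2)
  m1 <- fit_bias_models(y1, x, C, species = rownames(C))
  expect_equal(m1$selected, "linear")
  expect_lt(coef(m1$fits$linear$fit)[2], 0)

  # selected model attains the minimum QAICc by construction
  expect_equal(min(m1$table$qaicc), m1$fits[[m1$selected]]$qaicc,
               ignore_attr = TRUE)
  expect_error(fit_bias_models(y1[1:5], x[1:5]), "at least 8")
})

test_that("superlinearity requires the CI lower bound to exceed 1", {
  tree <- generate_phylogeny(paste0("s", 1:40), seed = 6)
  C <- phylo_covariance(tree)
  L <- t(chol(C))
  set.seed(94)
  x <- runif(40, -1, 3)
  d_strong <- data.frame(species = rownames(C), x = x,
                         y = 1.5 * x + as.numeric(L %*% rnorm(40)) * 0.1)
  ts <- test_superlinearity(pgls(y ~ x, d_strong, C))
  expect_true(ts$superlinear)
  expect_gt(ts$excess_ci[1], 0)

  d_lin <- data.frame(species = rownames(C), x = x,
                      y = 1.0 * x + as.numeric(L %*% rnorm(40)) * 0.3)
  expect_false(test_superlinearity(pgls(y ~ x, d_lin, C))$superlinear)

  # exact b = 1: zero-width CI at the boundary is not superlinear
  d_exact <- data.frame(x = 1:10, y = 1:10)
  expect_false(test_superlinearity(pgls(y ~ x, d_exact))$superlinear)
})

test_that("HRcorrect converts underestimation into a multiplicative factor", {
  expect_equal(underestimation_from_ratio(2), 0.5)
  expect_equal(underestimation_from_ratio(1), 0)
  expect_error(underestimation_from_ratio(-1), "positive")

  # constant-bias fits: factor = 1 / (1 - u)
  x <- runif(20, -1, 3)
  for (u_true in c(0.136, 0.46)) {
    m <- fit_bias_models(rep(u_true, 20) + rnorm(20, sd = 1e-6), x)
    expect_equal(unname(hrcorrect_factor(10, m)), 1 / (1 - u_true),
                 tolerance = 1e-3)
  }
  # unbiased: factor 1 (negative predictions clamp to no correction)
  m0 <- fit_bias_models(rnorm(20, 0, 1e-6), x)
  expect_equal(unname(hrcorrect_factor(10, m0)), 1, tolerance = 1e-3)
  # impossible underestimation >= 1 errors
  m1 <- fit_bias_models(rep(1.2, 20) + rnorm(20, sd = 1e-6), x)
  expect_error(hrcorrect_factor(10, m1), ">= 1")
})
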
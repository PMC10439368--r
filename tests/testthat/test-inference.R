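test_that("univariate two-group pseudo-F equals the classical ANOVA F", {
  set.seed(1)
  x <- matrix(c(rnorm(12, 0), rnorm(15, 0.8)), ncol = 1)
  g <- rep(c("a", "b"), c(12, 15))
  fit <- permanova(x, g, n_perm = 49, seed = 1)
  ref <- anova(lm(x ~ g))
  expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$R2, ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-10)

  # and for >2 groups / multivariate data against the vegan oracle
  skip_if_not_installed("vegan")
  X <- matrix(rnorm(60 * 4), 60, 4)
  g3 <- rep(c("a", "b", "c"), each = 20)
  fit3 <- permanova(X, g3, n_perm = 49, seed = 1)
  ref3 <- vegan::adonis2(dist(X) ~ g3, permutations = 49)
  expect_equal(fit3$F, ref3$F[1], tolerance = 1e-8)
  expect_equal(fit3$R2, ref3$R2[1], tolerance = 1e-8)
})

test_that("widely separated clusters reach the minimal attainable p", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20 * 2), 20, 2),
             matrix(rnorm(20 * 2, mean = 50), 20, 2))
  g <- rep(c("a", "b"), each = 20)
  fit <- permanova(X, g, n_perm = 199, seed = 3)
  expect_equal(fit$p, 1 / 200)
})

test_that("PERMANOVA is reproducible and invariant to consistent relabeling", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3)
  g <- rep(c("a", "b", "c"), each = 10)
  f1 <- permanova(X, g, n_perm = 99, seed = 7)
  f2 <- permanova(X, g, n_perm = 99, seed = 7)
  expect_identical(f1$p, f2$p)
  perm <- sample(30)
  f3 <- permanova(X[perm, ], g[perm], n_perm = 99, seed = 7)
  expect_equal(f3$F, f1$F, tolerance = 1e-10)

  expect_error(permanova(X, rep("a", 30)), "2 groups")
  expect_error(permanova(X[1:11, ], c(rep("a", 10), "b")), "fewer than 2")
})

test_that("pairwise tables have k(k-1)/2 rows and adjusted p >= raw p", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  g <- rep(c("a", "b", "c", "d"), each = 10)
  fit <- pairwise_permanova(X, g, n_perm = 99, seed = 1)
  expect_equal(nrow(fit$pairwise), 6)
  expect_true(all(fit$pairwise$p_adj >= fit$pairwise$p))
  expect_true(all(fit$pairwise$p_adj <= 1))
})

test_that("only pairs involving truly shifted groups are significant", {
  set.seed(6)
  n_per <- 15
  X <- rbind(
    matrix(rnorm(n_per * 3), n_per, 3),           # a: null
    matrix(rnorm(n_per * 3), n_per, 3),           # b: null
    matrix(rnorm(n_per * 3, mean = 4), n_per, 3), # c: shifted
    matrix(rnorm(n_per * 3, mean = -4), n_per, 3) # d: shifted opposite
  )
  g <- rep(c("a", "b", "c", "d"), each = n_per)
  fit <- pairwise_permanova(X, g, n_perm = 199, seed = 2)
  tab <- fit$pairwise
  shifted <- tab$group1 %in% c("c", "d") | tab$group2 %in% c("c", "d")
  expect_true(all(tab$p_adj[shifted] < 0.05))
  expect_true(all(tab$p_adj[!shifted] > 0.05))
})

test_that("PGLS at lambda 0 reproduces OLS exactly", {
  ds <- simulate_traits(sim_config(n_tips = 40, p = 4, seed = 21))
  cov <- brownian_covariance(ds$tree)
  set.seed(2)
  dat <- data.frame(y = rnorm(40), x = rnorm(40),
                    row.names = cov$tip_order)
  fit <- pgls(y ~ x, dat, cov, lambda = 0)
  ref <- lm(y ~ x, dat)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$coef_table$se, unname(coef(summary(ref))[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$coef_table$p, unname(coef(summary(ref))[, 4]),
               tolerance = 1e-10)
  expect_equal(unname(residuals(fit)), unname(residuals(ref)),
               tolerance = 1e-10)
})

test_that("a noiseless linear response is fitted perfectly", {
  ds <- simulate_traits(sim_config(n_tips = 24, p = 4, seed = 22))
  cov <- brownian_covariance(ds$tree)
  x <- rnorm(24)
  dat <- data.frame(y = 2 + 3 * x, x = x, row.names = cov$tip_order)
  fit <- pgls(y ~ x, dat, cov, lambda = 0.5)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-8)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("ML lambda agrees with the nlme corPagel oracle", {
  skip_if_not_installed("nlme")
  tree <- simulate_tree(64, seed = 31)
  cov <- brownian_covariance(tree)
  set.seed(31)
  Clam <- lambda_transform(cov, 0.7)$C
  y <- drop(t(chol(Clam)) %*% rnorm(64))
  x <- rnorm(64)
  dat <- data.frame(y = y + 0.5 * x, x = x, species = cov$tip_order,
                    row.names = cov$tip_order)
  fit <- pgls(y ~ x, dat, cov, lambda = "ML")
  ref <- nlme::gls(y ~ x, dat, method = "ML",
                   correlation = ape::corPagel(0.5, tree, form = ~ species))
  # corPagel uses the same profile; estimates agree to grid resolution
  ref_lam <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$lambda, ref_lam, tolerance = 0.02)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("profile likelihood at the optimum dominates the grid endpoints", {
  tree <- simulate_tree(32, seed = 33)
  cov <- brownian_covariance(tree)
  set.seed(33)
  y <- drop(t(chol(lambda_transform(cov, 0.5)$C)) %*% rnorm(32))
  dat <- data.frame(y = y, row.names = cov$tip_order)
  fit <- pgls(y ~ 1, dat, cov, lambda = "ML")
  prof <- fit$profile
  ll_hat <- max(prof$logLik)
  expect_gte(ll_hat, prof$logLik[1])
  expect_gte(ll_hat, prof$logLik[nrow(prof)])
  expect_equal(fit$df_residual, fit$n - 1)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * (1 + 2))
})

test_that("model selection ranks by AIC with declaration-order ties", {
  tree <- simulate_tree(48, seed = 35)
  cov <- brownian_covariance(tree)
  set.seed(35)
  x1 <- rnorm(48)
  dat <- data.frame(y = x1 + rnorm(48, sd = 0.3), x1 = x1,
                    x2 = rnorm(48), row.names = cov$tip_order)
  sel <- select_model(list(first = y ~ x1, dup = y ~ x1, both = y ~ x1 + x2),
                      dat, cov)
  expect_equal(nrow(sel$table), 3)
  expect_true(sel$table$best[1])
  # identical candidates tie; the first declared wins
  expect_equal(sel$table$model[1], "first")
  expect_equal(sel$table$AIC[1], sel$table$AIC[2])
  expect_error(select_model(list(y ~ x1), dat, cov), "at least 2")
})
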
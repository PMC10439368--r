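sim_classes <- function(n_per = 20, k = 3, p = 4, shift = 3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(g) {
    mu <- rep(0, p)
    mu[1 + (g - 1) %% p] <- shift * (g - 1)
    matrix(rnorm(n_per * p), n_per, p) + rep(mu, each = n_per)
  }))
  colnames(X) <- paste0("v", seq_len(p))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  list(X = X, g = factor(rep(letters[seq_len(k)], each = n_per)))
}

test_that("two separated 1-D classes split at the prior-weighted midpoint", {
  X <- matrix(c(rep(0, 10) + rnorm(10, sd = 1e-3),
                rep(10, 10) + rnorm(10, sd = 1e-3)), ncol = 1)
  g <- rep(c("lo", "hi"), each = 10)
  fit <- lda_fit(X, g)
  pr <- predict(fit)
  expect_equal(as.character(pr$class), g) # 100% training accuracy
  # equal priors: boundary at the midpoint; a point just below classifies lo
  expect_equal(as.character(predict(fit, matrix(4.99))$class), "lo")
  expect_equal(as.character(predict(fit, matrix(5.01))$class), "hi")
})

test_that("LDA matches the MASS oracle for predictions and trace shares", {
  skip_if_not_installed("MASS")
  d <- sim_classes(n_per = 25, k = 4, p = 5, shift = 1.5, seed = 3)
  fit <- lda_fit(d$X, d$g)
  ref <- MASS::lda(d$X, d$g)
  ref_pred <- predict(ref)
  mine <- predict(fit)
  expect_equal(as.character(mine$class), as.character(ref_pred$class))
  expect_equal(unname(mine$posterior),
               unname(ref_pred$posterior[, fit$levels]), tolerance = 1e-8)
  expect_equal(fit$prop_trace, 100 * ref$svd^2 / sum(ref$svd^2),
               tolerance = 1e-6)
  expect_equal(unname(fit$priors), unname(ref$prior), tolerance = 1e-12)
})

test_that("posteriors sum to one and respond monotonically to priors", {
  d <- sim_classes(seed = 5)
  fit <- lda_fit(d$X, d$g)
  pr <- predict(fit)
  expect_equal(unname(rowSums(pr$posterior)), rep(1, nrow(d$X)),
               tolerance = 1e-10)
  # raising class "a" prior never lowers its posterior anywhere
  fit2 <- lda_fit(d$X, d$g, priors = c(0.6, 0.2, 0.2))
  pr2 <- predict(fit2)
  expect_true(all(pr2$posterior[, "a"] >= pr$posterior[, "a"] - 1e-12))
})

test_that("LDA is invariant to invertible affine transforms", {
  d <- sim_classes(n_per = 15, k = 3, p = 4, seed = 7)
  base <- predict(lda_fit(d$X, d$g))
  set.seed(8)
  for (rep_i in 1:3) {
    A <- matrix(rnorm(16), 4, 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
    b <- rnorm(4)
    Xt <- d$X %*% A + rep(b, each = nrow(d$X))
    got <- predict(lda_fit(Xt, d$g))
    expect_equal(as.character(got$class), as.character(base$class))
    expect_equal(got$posterior, base$posterior, tolerance = 1e-6)
  }
})

test_that("training accuracy rises with regime effect size", {
  accs <- vapply(c(0, 0.5, 1.5, 4), function(shift) {
    d <- sim_classes(n_per = 20, k = 3, p = 4, shift = shift, seed = 11)
    cm <- confusion(as.character(d$g),
                    as.character(predict(lda_fit(d$X, d$g))$class))
    cm$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("degenerate classes and covariances are rejected", {
  d <- sim_classes(seed = 13)
  expect_error(lda_fit(d$X, replace(as.character(d$g), 1, "solo")),
               "fewer than 2")
  Xbad <- cbind(d$X, dup = d$X[, 1])
  expect_error(lda_fit(Xbad, d$g), "singular")
})

test_that("confusion matrices count, percentage and score correctly", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(cm$counts["a", "b"], 1)
  expect_equal(cm$accuracy, 75)
  expect_equal(unname(rowSums(cm$row_pct)), c(100, 100))
  expect_error(confusion(c("a", "b"), c("a", "c"), levels = c("a", "b")),
               "outside")
  # perfect prediction gives an identity count matrix
  cmp <- confusion(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(cmp$counts, diag(3), ignore_attr = TRUE)
  expect_equal(cmp$accuracy, 100)
  # overall accuracy equals the row-n-weighted mean of row accuracies
  acc_rows <- diag(cm$row_pct)
  expect_equal(cm$accuracy, sum(acc_rows * cm$n) / sum(cm$n))
})

test_that("pFDA at lambda 0 on a unit tree is exactly LDA", {
  ds <- simulate_traits(sim_config(n_tips = 60, p = 6, seed = 17,
                                   delta_scale = 0.4))
  sh <- mosimann_shape(ds$measurements,
                       setdiff(attr(ds$measurements, "variable_set"),
                               "iliac_angle"))
  X <- shape_coordinates(shape_matrix(sh))
  g <- setNames(ds$measurements$locomotor_mode, ds$measurements$species_id)
  cov <- brownian_covariance(ds$tree)
  lda_m <- lda_fit(X[cov$tip_order, ], g[cov$tip_order])
  pfda_m <- pfda_fit(X[cov$tip_order, ], g[cov$tip_order], cov, lambda = 0)
  pl <- predict(lda_m)
  pf <- predict(pfda_m)
  expect_equal(as.character(pf$class), as.character(pl$class))
  expect_equal(pf$posterior, pl$posterior, tolerance = 1e-6)
  cm_l <- confusion(as.character(lda_m$labels), as.character(pl$class))
  cm_f <- confusion(as.character(pfda_m$labels), as.character(pf$class))
  expect_equal(cm_f$counts, cm_l$counts)
  expect_equal(pfda_m$prop_trace, lda_m$prop_trace, tolerance = 1e-6)
})

test_that("strong regime effects under full Brownian structure classify well", {
  # strong, phylogenetically labile regime effects: pFDA whitening keeps
  # the class signal only where a tip's regime differs from its ancestry,
  # so the regimes must churn fast for resubstitution accuracy to be high
  ds <- simulate_traits(sim_config(n_tips = 100, p = 8, seed = 19,
                                   delta_scale = 2, q = 20, lambda = 1))
  sh <- mosimann_shape(ds$measurements,
                       setdiff(attr(ds$measurements, "variable_set"),
                               "iliac_angle"))
  X <- shape_coordinates(shape_matrix(sh))
  g <- setNames(ds$measurements$locomotor_mode, ds$measurements$species_id)
  cov <- brownian_covariance(ds$tree)
  fit <- pfda_fit(X[cov$tip_order, ], g[cov$tip_order], cov, lambda = 1)
  cm <- confusion(as.character(fit$labels),
                  as.character(predict(fit)$class))
  expect_gt(cm$accuracy, 90)
})

test_that("optimal lambda recovers the generating phylogenetic signal", {
  reps <- 12
  lam_bm <- lam_star <- numeric(reps)
  for (i in seq_len(reps)) {
    ds <- simulate_traits(sim_config(n_tips = 96, p = 6, seed = 100 + i,
                                     lambda = 1, delta_scale = 0.2,
                                     noise_sd = 0.01))
    sh <- mosimann_shape(ds$measurements,
                         setdiff(attr(ds$measurements, "variable_set"),
                                 "iliac_angle"))
    X <- shape_coordinates(shape_matrix(sh))
    g <- setNames(ds$measurements$locomotor_mode,
                  ds$measurements$species_id)
    cov <- brownian_covariance(ds$tree)
    lam_bm[i] <- optimal_lambda(X[cov$tip_order, ], g[cov$tip_order], cov,
                                grid_step = 0.05)$lambda

    ds0 <- simulate_traits(sim_config(n_tips = 96, p = 6, seed = 200 + i,
                                      lambda = 0, delta_scale = 0.2,
                                      sigma2_size = 0, noise_sd = 0.01))
    sh0 <- mosimann_shape(ds0$measurements,
                          setdiff(attr(ds0$measurements, "variable_set"),
                                  "iliac_angle"))
    X0 <- shape_coordinates(shape_matrix(sh0))
    g0 <- setNames(ds0$measurements$locomotor_mode,
                   ds0$measurements$species_id)
    cov0 <- brownian_covariance(ds0$tree)
    lam_star[i] <- optimal_lambda(X0[cov0$tip_order, ], g0[cov0$tip_order],
                                  cov0, grid_step = 0.05)$lambda
  }
  expect_gte(mean(lam_bm >= 0.8), 0.85)
  expect_gte(mean(lam_star <= 0.2), 0.85)

  expect_error(optimal_lambda(matrix(1, 10, 2), rep(c("a", "b"), 5),
                              brownian_covariance(simulate_tree(10, 1))),
               "degenerate")
})

test_that("held-out tips are classified via conditional whitening", {
  # a held-out tip duplicating a training tip on a star tree inherits its
  # class
  n <- 30
  star_nwk <- paste0("(", paste0("t", 1:n, ":1", collapse = ","), ");")
  tree <- read_newick(star_nwk)
  d <- sim_classes(n_per = 10, k = 3, p = 4, shift = 4, seed = 23)
  X <- d$X[1:27, ]
  rownames(X) <- paste0("t", 1:27)
  g <- setNames(d$g[1:27], rownames(X))
  cov_full <- brownian_covariance(tree)
  cov_tr <- brownian_covariance(prune_to_taxa(tree, rownames(X)))
  fit <- pfda_fit(X[cov_tr$tip_order, ], g[cov_tr$tip_order], cov_tr,
                  lambda = 0)
  X_new <- X[c(3, 15), , drop = FALSE]
  rownames(X_new) <- c("t28", "t29")
  got <- predict_unlabeled_tips(fit, X_new, cov_full)
  expect_equal(as.character(got$class),
               as.character(g[c("t3", "t15")]))
  expect_equal(got$species_id, c("t28", "t29"))

  # empty held-out set gives empty results
  empty <- predict_unlabeled_tips(fit, X[0, , drop = FALSE], cov_full)
  expect_length(empty$class, 0)

  bad <- X_new
  rownames(bad) <- c("nope", "t29")
  expect_error(predict_unlabeled_tips(fit, bad, cov_full), "nope")
})

test_that("simulated basal-like hold-outs return to the basal class", {
  ds <- simulate_traits(sim_config(n_tips = 80, p = 6, seed = 29,
                                   delta_scale = 0.8, n_neo = 0))
  tab <- ds$measurements
  sh <- mosimann_shape(tab, setdiff(attr(tab, "variable_set"),
                                    "iliac_angle"))
  X <- shape_coordinates(shape_matrix(sh))
  g <- setNames(tab$locomotor_mode, tab$species_id)
  cov_full <- brownian_covariance(ds$tree)
  # hold out a third of one regime's tips; their trait values carry that
  # regime's shift, so most should be predicted back into it
  target <- names(g)[g == "TJ"]
  skip_if(length(target) < 6)
  held <- target[seq_len(max(3, length(target) %/% 3))]
  train <- setdiff(names(g), held)
  cov_tr <- brownian_covariance(prune_to_taxa(ds$tree, train))
  fit <- pfda_fit(X[cov_tr$tip_order, ], g[cov_tr$tip_order], cov_tr,
                  lambda = 1)
  got <- predict_unlabeled_tips(fit, X[held, , drop = FALSE], cov_full)
  expect_gt(mean(as.character(got$class) == "TJ"), 0.5)
})

test_that("case-wise reports count planted agreement patterns", {
  pred <- list(class = factor(c("a", "b", "a", "c"),
                              levels = c("a", "b", "c")),
               posterior = matrix(1 / 3, 4, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  truth <- c("a", "a", "a", "b")
  cw <- casewise_predictions(pred, truth,
                             species_id = paste0("s", 1:4),
                             secondary = c(NA, "b", NA, NA),
                             proxy = c(TRUE, FALSE, FALSE, FALSE))
  rep1 <- casewise_report(cw)
  expect_equal(rep1$primary_correct, 2)
  expect_equal(rep1$alternative_correct, 1)  # s2: wrong primary, secondary hit
  expect_equal(rep1$proxy_correct, 1)        # s1 correct via proxy label
  expect_equal(rep1$misclassified_despite_certainty, 1) # s4

  # all-correct predictions have zero alternative-correct
  pred2 <- list(class = factor(truth, levels = c("a", "b", "c")),
                posterior = pred$posterior)
  cw2 <- casewise_predictions(pred2, truth, paste0("s", 1:4))
  expect_equal(casewise_report(cw2)$alternative_correct, 0)

  # identical prediction sets agree 100%
  expect_equal(casewise_report(cw, cw)$agreement_pct, 100)
  cw3 <- cw2
  cw3$species_id <- paste0("x", 1:4)
  expect_error(casewise_report(cw, cw3), "mismatch")
})

test_that("cross-validated accuracy is honest where resubstitution is not", {
  # strong separation: CV and resubstitution both near perfect
  d <- sim_classes(n_per = 20, k = 3, p = 4, shift = 5, seed = 31)
  cv <- lda_cv(d$X, d$g)
  expect_gt(cv$accuracy, 95)
  expect_length(cv$class, nrow(d$X))
  # no separation: resubstitution is optimistic, CV hugs chance
  d0 <- sim_classes(n_per = 20, k = 3, p = 8, shift = 0, seed = 32)
  fit <- lda_fit(d0$X, d0$g)
  resub <- confusion(as.character(d0$g),
                     as.character(predict(fit)$class))$accuracy
  cv0 <- lda_cv(d0$X, d0$g, folds = 10, seed = 1)
  expect_lt(cv0$accuracy, resub)
  expect_lt(abs(cv0$accuracy - 100 / 3), 3 * 100 * sqrt((1/3) * (2/3) / 60))
})
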
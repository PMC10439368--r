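test_that("Newick reading validates structure and round-trips", {
  tree <- toy_tree()
  expect_equal(ape::Ntip(tree), 3)
  d <- ape::node.depth.edgelength(tree)
  expect_equal(d[match("A", tree$tip.label)], 2)

  expect_error(read_newick("((A:1,A:1):1);"), "duplicate tip")
  expect_error(read_newick("((A:1,B:1:1,C:2);"), "parse")

  rt <- read_newick(write_newick(tree))
  expect_equal(rt$tip.label, tree$tip.label)
  expect_equal(rt$edge.length, tree$edge.length)

  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  expect_equal(read_newick(f)$edge.length, tree$edge.length)
})

test_that("pruning preserves root-to-tip and pairwise shared path lengths", {
  tree <- toy_tree()
  pr <- prune_to_taxa(tree, c("A", "C"))
  d <- ape::node.depth.edgelength(pr)
  expect_equal(sort(d[1:2]), c(2, 2))

  keep_all <- prune_to_taxa(tree, tree$tip.label)
  expect_equal(ape::Ntip(keep_all), 3)

  expect_error(prune_to_taxa(tree, c("A", "Z")), "Z")

  # 50-tip simulated tree, random 20 kept: all pairwise MRCA path lengths
  # among kept tips unchanged (checked against the full covariance)
  big <- simulate_tree(50, seed = 9)
  set.seed(1)
  keep <- sample(big$tip.label, 20)
  C_before <- brownian_covariance(big)$C[keep, keep]
  C_after <- brownian_covariance(prune_to_taxa(big, keep))$C[keep, keep]
  expect_equal(C_after, C_before, tolerance = 1e-12)
})

test_that("tip substitution relabels without touching branch lengths", {
  tree <- toy_tree()
  sub <- substitute_tip(tree, "A", "X")
  expect_setequal(sub$tip.label, c("X", "B", "C"))
  expect_equal(sub$edge.length, tree$edge.length)
  C1 <- brownian_covariance(tree)$C
  C2 <- brownian_covariance(sub)$C
  dimnames(C1) <- lapply(dimnames(C1), function(x) sub("A", "X", x, fixed = TRUE))
  expect_equal(C2[rownames(C1), colnames(C1)], C1)

  # substitute then prune behaves as if the new label was always there
  pr <- prune_to_taxa(substitute_tip(tree, "A", "X"), c("X", "C"))
  pr2 <- prune_to_taxa(tree, c("A", "C"))
  expect_equal(pr$edge.length, pr2$edge.length)

  expect_error(substitute_tip(tree, "Z", "Y"), "not found")
  expect_error(substitute_tip(tree, "A", "B"), "already present")
})

test_that("Brownian covariance equals shared path sums", {
  tree <- toy_tree()
  cov <- brownian_covariance(tree, tip_order = c("A", "B", "C"))
  expect_equal(cov$C,
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

  star <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(brownian_covariance(star)$C, diag(4), ignore_attr = TRUE)

  # simulated trees: independent path-sum oracle plus ape cross-check
  for (seed in 1:3) {
    tr <- simulate_tree(12, seed = seed)
    C <- brownian_covariance(tr)$C
    expect_equal(C, path_sum_vcv(tr), tolerance = 1e-12)
    expect_equal(C, ape::vcv(tr)[rownames(C), colnames(C)],
                 tolerance = 1e-12)
    expect_equal(diag(C), rep(1, 12), tolerance = 1e-9,
                 ignore_attr = TRUE) # unit height, constant diagonal
    expect_silent(chol(C)) # positive definite
  }
})

test_that("lambda transform scales off-diagonals linearly and composes", {
  cov <- brownian_covariance(toy_tree())
  expect_equal(lambda_transform(cov, 1)$C, cov$C)
  expect_equal(lambda_transform(cov, 0)$C, diag(diag(cov$C)),
               ignore_attr = TRUE)
  expect_equal(lambda_transform(cov, 0.5)$C["A", "B"], 0.5)
  expect_error(lambda_transform(cov, -0.1), "non-negative")

  # composition: sequential transforms equal the product transform
  c1 <- lambda_transform(lambda_transform(cov, 0.6), 0.5)
  c2 <- lambda_transform(cov, 0.3)
  expect_equal(c1$C, c2$C)
  expect_equal(c1$lambda, 0.3)

  # diagonal never changes
  tr <- simulate_tree(20, seed = 4, ultrametric = FALSE)
  cc <- brownian_covariance(tr)
  expect_equal(diag(lambda_transform(cc, 0.73)$C), diag(cc$C))
})

test_that("lambda_max reaches the PSD bound near 1 for ultrametric trees", {
  # the exact positive-definiteness bound sits at or slightly above 1 for
  # ultrametric trees; it is never clamped, so estimates above 1 stay
  # possible whenever the bound allows them
  cov_u <- brownian_covariance(simulate_tree(24, seed = 2))
  lm_u <- lambda_max(cov_u)
  expect_gte(lm_u, 1 - 1e-3)
  expect_lt(lm_u, 1.2)
  cov_n <- brownian_covariance(simulate_tree(24, seed = 2,
                                             ultrametric = FALSE))
  expect_gt(lambda_max(cov_n), 1)
})

test_that("ancestral states solve the Brownian GLS problem", {
  # symmetric 2-tip case: root midway
  tr2 <- read_newick("(A:1,B:1);")
  expect_equal(unname(ancestral_states(tr2, c(A = 0, B = 2))), 1)

  # constant tips give constant nodes
  tr <- simulate_tree(10, seed = 3)
  est <- ancestral_states(tr, setNames(rep(3.5, 10), tr$tip.label))
  expect_equal(unname(est), rep(3.5, tr$Nnode), tolerance = 1e-10)

  # star tree root equals the arithmetic mean
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 1, B = 2, C = 4, D = 9)
  expect_equal(unname(ancestral_states(star, x)), mean(x))

  expect_error(ancestral_states(tr2, c(A = 1)), "missing tip")
})

test_that("3-tip ancestral states match a grid-search likelihood oracle", {
  tree <- toy_tree() # ((A:1,B:1):1,C:2)
  x <- c(A = 0.3, B = 1.1, C = -0.7)
  est <- ancestral_states(tree, x)
  # joint ML over (root r, AB-node m): minimise the edge-wise quadratic
  # (m-r)^2/1 + (x_A-m)^2/1 + (x_B-m)^2/1 + (x_C-r)^2/2
  obj <- function(r, m) {
    (m - r)^2 + (x["A"] - m)^2 + (x["B"] - m)^2 + (x["C"] - r)^2 / 2
  }
  grid <- seq(-2, 2, by = 0.001)
  vals <- outer(grid, grid, obj)
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_equal(unname(est[1]), grid[best[1]], tolerance = 2e-3) # root
  expect_equal(unname(est[2]), grid[best[2]], tolerance = 2e-3) # AB node
})

test_that("singular covariances are jittered with a message", {
  # zero-length terminal branches duplicate rows of C
  tr <- read_newick("((A:0,B:0):1,C:1);")
  cov <- brownian_covariance(tr)
  x <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  expect_message(ppca(x, cov), "jitter")
})
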
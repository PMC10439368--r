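## PERMANOVA: one-way permutational multivariate ANOVA on a distance
## matrix (Anderson's pseudo-F from the Gower-centred partition), with
## pairwise group contrasts and multiplicity adjustment.

# Pseudo-F for a label permutation given the squared-distance matrix.
# SS_total = sum_{i<j} d2 / n ; SS_within = sum_g sum_{i<j in g} d2 / n_g.
permanova_F <- function(D2, groups, level_tab) {
  n <- nrow(D2)
  k <- length(level_tab$levels)
  U <- level_tab$indicator(groups)
  within_pairs <- colSums(U * (D2 %*% U)) / 2 # sum_g u_g' D2 u_g / 2
  ss_within <- sum(within_pairs / level_tab$sizes(groups))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  c(F = f, R2 = ss_between / ss_total)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance of a species ×
#' variables matrix (Euclidean distance on the supplied data, normally
#' log-shape variables) against a single categorical grouping. The
#' pseudo-F statistic comes from the Gower-centred partition of squared
#' distances; significance from free permutation of row labels, with
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param X Numeric matrix/data.frame (species × variables), or a `dist`
#'   object.
#' @param groups Group labels, one per row; every group needs ≥ 2 members.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `permanova`: list with `grouping` sizes,
#'   `F`, `R2`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(X, groups, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be positive")
  D <- if (inherits(X, "dist")) X else stats::dist(as.matrix(X))
  D2 <- as.matrix(D)^2
  groups <- as.character(groups)
  n <- nrow(D2)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  levels <- names(sizes)
  level_tab <- list(
    levels = levels,
    indicator = function(g) {
      outer(g, levels, `==`) + 0
    },
    sizes = function(g) as.numeric(table(factor(g, levels = levels)))
  )
  obs <- permanova_F(D2, groups, level_tab)
  if (!is.null(seed)) set.seed(seed)
  perm_f <- vapply(seq_len(n_perm), function(i) {
    permanova_F(D2, groups[sample.int(n)], level_tab)[["F"]]
  }, numeric(1))
  p <- (1 + sum(perm_f >= obs[["F"]])) / (1 + n_perm)
  structure(
    list(sizes = sizes, F = obs[["F"]], R2 = obs[["R2"]], p = p,
         n_perm = n_perm, seed = seed),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, " permutations)\n", sep = "")
  cat("Groups:", paste0(names(x$sizes), " (", x$sizes, ")", collapse = ", "),
      "\n")
  cat(sprintf("pseudo-F = %.4g, R2 = %.4g, p = %.4g\n", x$F, x$R2, x$p))
  if (!is.null(x$pairwise)) {
    cat("\nPairwise contrasts (", x$adjust, "-adjusted):\n", sep = "")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' PERMANOVA with pairwise group contrasts
#'
#' Runs the overall test, then re-runs the PERMANOVA on every pair of
#' groups and adjusts the pairwise p-values across the k(k−1)/2
#' comparisons.
#'
#' @inheritParams permanova
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`; `"holm"` and `"BH"` are the usual
#'   alternatives).
#' @return A `permanova` object with an extra `pairwise` data.frame
#'   (columns `group1`, `group2`, `F`, `R2`, `p`, `p_adj`) and the
#'   adjustment method.
#' @export
pairwise_permanova <- function(X, groups, n_perm = 999,
                               adjust = "bonferroni", seed = NULL) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  overall <- permanova(X, groups, n_perm = n_perm, seed = seed)
  levels <- names(overall$sizes)
  pairs <- utils::combn(levels, 2)
  rows <- apply(pairs, 2, function(pr) {
    sel <- groups %in% pr
    fit <- permanova(X[sel, , drop = FALSE], groups[sel],
                     n_perm = n_perm, seed = seed)
    data.frame(group1 = pr[1], group2 = pr[2], F = fit$F, R2 = fit$R2,
               p = fit$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
  overall$pairwise <- tab
  overall$adjust <- adjust
  overall
}
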
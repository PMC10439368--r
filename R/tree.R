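## Phylogeny handling: Newick I/O, pruning, tip substitution, Brownian
## covariance, Pagel's lambda transform, and GLS ancestral states.
## Trees are `ape::phylo` objects throughout; matrix-producing operations
## take and record an explicit tip order.

#' Read a rooted phylogeny from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. Accepts a Newick
#' string or a file path. Unlabelled internal nodes are allowed; duplicate
#' tip labels and unparseable input are errors.
#'
#' @param source Newick text (contains "(") or path to a file.
#' @param missing_lengths `"error"` (default) rejects trees with absent
#'   branch lengths; `"zero"` substitutes 0.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(source, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  is_text <- grepl("(", source, fixed = TRUE)
  tree <- tryCatch(
    if (is_text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) stop("failed to parse Newick: ", conditionMessage(e)),
    warning = function(w) stop("failed to parse Newick: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("failed to parse Newick (unbalanced parentheses?)")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error") stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (missing_lengths == "error") stop("tree has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree `phylo` object.
#' @param file Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths (default 10).
#' @return Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Prune a tree to a set of tips
#'
#' Retains only the listed tips, collapsing degree-2 internal nodes with
#' branch lengths summed, so root-to-tip distances and all pairwise shared
#' path lengths among retained tips are unchanged.
#'
#' @param tree `phylo` object.
#' @param keep Tip labels to retain.
#' @return Pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  absent <- setdiff(keep, tree$tip.label)
  if (length(absent) > 0L) {
    stop("tip(s) not in tree: ", paste(absent, collapse = ", "))
  }
  ape::keep.tip(tree, keep)
}

#' Replace one tip label, preserving topology and branch lengths
#'
#' Used to substitute a species by its closest congener already placed in a
#' reference tree, inheriting that taxon's branch lengths.
#'
#' @param tree `phylo` object.
#' @param old Existing tip label.
#' @param new Replacement label (must not already be present).
#' @return Relabelled `phylo`.
#' @export
substitute_tip <- function(tree, old, new) {
  i <- match(old, tree$tip.label)
  if (is.na(i)) stop("tip '", old, "' not found")
  if (new %in% tree$tip.label) stop("tip '", new, "' already present")
  tree$tip.label[i] <- new
  tree
}

#' Brownian-motion covariance of a rooted tree
#'
#' Builds the expected among-tip covariance under Brownian motion:
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j, and
#' `C[i, i]` the root-to-tip distance. Computed from node depths and MRCA
#' lookups; no ultrametricity is assumed (the diagonal is free to vary for
#' substitutions-per-site trees).
#'
#' @param tree Rooted `phylo` object.
#' @param tip_order Permutation of the tip labels fixing row/column order;
#'   defaults to the tree's own order.
#' @return Object of class `phylo_cov`: list with `C` (named matrix),
#'   `tip_order`, `lambda` (1, untransformed) and `height` (max root-to-tip
#'   distance).
#' @export
brownian_covariance <- function(tree, tip_order = NULL) {
  if (is.null(tree$edge) || length(tree$tip.label) < 2) {
    stop("tree must be a rooted phylogeny with at least 2 tips")
  }
  n <- length(tree$tip.label)
  if (is.null(tip_order)) tip_order <- tree$tip.label
  if (!setequal(tip_order, tree$tip.label) || length(tip_order) != n) {
    stop("tip_order must be a permutation of the tip labels")
  }
  depth <- ape::node.depth.edgelength(tree) # root-to-node path lengths
  mrca_idx <- ape::mrca(tree)               # tips x tips node numbers
  C <- matrix(depth[mrca_idx], n, n, dimnames = dimnames(mrca_idx))
  diag(C) <- depth[seq_len(n)]
  C <- C[tip_order, tip_order]
  structure(
    list(C = C, tip_order = tip_order, lambda = 1,
         height = max(depth[seq_len(n)])),
    class = "phylo_cov"
  )
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance:", length(x$tip_order), "tips, lambda =",
      format(x$lambda), ", height =", format(x$height), "\n")
  invisible(x)
}

#' Pagel's lambda transform
#'
#' Multiplies the off-diagonal entries of a Brownian covariance by
#' `lambda`, leaving the diagonal unchanged. `lambda = 1` is the full
#' Brownian structure, `lambda = 0` the star-phylogeny limit.
#'
#' @param cov A `phylo_cov`.
#' @param lambda Non-negative multiplier. Values above the positive
#'   semi-definiteness bound are accepted here (downstream solvers fail);
#'   use [lambda_max()] for the bound.
#' @return Transformed `phylo_cov` with `lambda` recorded as the product
#'   of transforms applied.
#' @export
lambda_transform <- function(cov, lambda) {
  if (!inherits(cov, "phylo_cov")) stop("cov must be a phylo_cov")
  if (lambda < 0) stop("lambda must be non-negative")
  d <- diag(cov$C)
  cov$C <- cov$C * lambda
  diag(cov$C) <- d
  cov$lambda <- cov$lambda * lambda
  cov
}

#' Largest lambda keeping the covariance positive definite
#'
#' Binary search for the largest `lambda` (up to `cap`) for which the
#' lambda-transformed covariance admits a Cholesky factorisation. For
#' ultrametric trees the bound sits at or just above 1; for
#' substitutions-per-site trees it can be considerably larger. The bound
#' is never clamped at 1.
#'
#' @param cov A `phylo_cov` (untransformed, `lambda = 1`).
#' @param cap Upper search bound (default 2).
#' @param tol Search tolerance (default 1e-4).
#' @return Numeric lambda bound.
#' @export
lambda_max <- function(cov, cap = 2, tol = 1e-4) {
  ok <- function(lam) {
    !inherits(try(chol(lambda_transform(cov, lam)$C), silent = TRUE),
              "try-error")
  }
  if (ok(cap)) return(cap)
  lo <- 0
  hi <- cap
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Cholesky with the package's jitter policy: zero-length terminal branches
# (or duplicated rows) can make C singular; a diagonal jitter of
# 1e-8 * height is applied only when the plain factorisation fails, with a
# message so runs are auditable.
chol_cov <- function(C, height = max(diag(C))) {
  U <- try(chol(C), silent = TRUE)
  if (inherits(U, "try-error")) {
    jit <- 1e-8 * height
    message("covariance singular; adding diagonal jitter ", format(jit))
    U <- chol(C + diag(jit, nrow(C)))
  }
  U
}

# Solve C x = b via Cholesky (never an explicit inverse).
cov_solve <- function(U, b) backsolve(U, forwardsolve(t(U), b))

#' GLS ancestral states of a continuous trait under Brownian motion
#'
#' Maximum-likelihood estimates of internal-node states given tip values:
#' the root estimate is the phylogenetic GLS mean
#' `a = (1' C^-1 1)^-1 1' C^-1 x`, and every internal node is the
#' conditional expectation `a + C_nt C_tt^-1 (x - a)`, where `C_nt` holds
#' shared path lengths between internal nodes and tips.
#'
#' @param tree Rooted `phylo`.
#' @param tip_values Named numeric vector, one value per tip.
#' @return Named numeric vector of estimates for the internal nodes
#'   (names are ape node numbers as characters; the root is node
#'   `n_tips + 1`).
#' @export
ancestral_states <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (is.null(names(tip_values))) {
    if (length(tip_values) != n) stop("tip_values must cover every tip")
    names(tip_values) <- tree$tip.label
  }
  absent <- setdiff(tree$tip.label, names(tip_values))
  if (length(absent) > 0L) {
    stop("missing tip value(s): ", paste(absent, collapse = ", "))
  }
  x <- tip_values[tree$tip.label]
  depth <- ape::node.depth.edgelength(tree)
  full_mrca <- ape::mrca(tree, full = TRUE) # (n+m) x (n+m) node numbers
  Cfull <- matrix(depth[full_mrca], n + m, n + m)
  tips <- seq_len(n)
  nodes <- n + seq_len(m)
  Ctt <- Cfull[tips, tips, drop = FALSE]
  diag(Ctt) <- depth[tips]
  Cnt <- Cfull[nodes, tips, drop = FALSE]
  U <- chol_cov(Ctt, height = max(depth[tips]))
  Cinv1 <- cov_solve(U, rep(1, n))
  a <- sum(Cinv1 * x) / sum(Cinv1)
  est <- as.numeric(a + Cnt %*% cov_solve(U, x - a))
  names(est) <- as.character(nodes)
  est
}
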
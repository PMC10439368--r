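## Ordination: phylogenetic PCA under Brownian motion and shape PCA in
## isometry-free shape space, with PCA ratio spectra and allometry spectra
## (bootstrap percentile intervals).

# Fix eigenvector signs so the largest-magnitude loading of each column is
# positive; makes results reproducible across LAPACK builds.
fix_signs <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, `*`)
}

#' Phylogenetic principal component analysis
#'
#' PCA of among-species (log-shape) data with respect to the covariance
#' expected under Brownian motion on a phylogeny. The phylogenetic mean is
#' `a = (1' C^-1 1)^-1 1' C^-1 X`, the evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`; loadings and eigenvalues come
#' from the eigen-decomposition of `R` (covariance mode by default) and
#' scores are `(X - 1a) %*% loadings`. With `C = I` (star phylogeny) this
#' reduces to ordinary covariance PCA on column-centred data.
#'
#' Percent variance per axis is taken from the eigenvalues of `R`, i.e. the
#' evolutionary-covariance convention (score variances follow a different
#' convention and are not used).
#'
#' @param X Species × variables numeric matrix, rows in `cov$tip_order`.
#' @param cov A `phylo_cov` ([brownian_covariance()], optionally
#'   lambda-transformed).
#' @param mode `"cov"` (default) or `"cor"` (decomposes the evolutionary
#'   correlation matrix).
#' @return Object of class `ppca` (inherits `ordination`): eigenvalues,
#'   loadings (orthonormal columns), scores, percent variance, the
#'   phylogenetic mean `a` and evolutionary covariance `R`.
#' @export
ppca <- function(X, cov, mode = c("cov", "cor")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!inherits(cov, "phylo_cov")) stop("cov must be a phylo_cov")
  if (nrow(X) != length(cov$tip_order)) {
    stop("dimension mismatch: ", nrow(X), " rows vs ",
         length(cov$tip_order), " tips")
  }
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), cov$tip_order)) {
      stop("row names of X do not match the covariance tip order")
    }
    X <- X[cov$tip_order, , drop = FALSE]
  }
  n <- nrow(X)
  U <- chol_cov(cov$C, height = cov$height)
  Cinv1 <- cov_solve(U, rep(1, n))
  a <- drop(crossprod(Cinv1, X)) / sum(Cinv1)
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, cov_solve(U, Xc)) / (n - 1)
  R <- (R + t(R)) / 2
  D <- if (mode == "cor") stats::cov2cor(R) else R
  e <- eigen(D, symmetric = TRUE)
  V <- fix_signs(e$vectors)
  scores <- Xc %*% V
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  rownames(scores) <- cov$tip_order
  structure(
    list(method = "pPCA", mode = mode, variables = colnames(X),
         eigenvalues = e$values, loadings = V, scores = scores,
         percent = 100 * e$values / sum(e$values),
         mean = a, R = R, lambda = cov$lambda),
    class = c("ppca", "ordination")
  )
}

#' Shape PCA in isometry-free shape space
#'
#' Ordinary covariance PCA of log-measurements after projecting each
#' specimen orthogonally to the isometric size direction (the equal-loading
#' vector), i.e. after row-centring — identical to PCA of log-Mosimann
#' shape variables. The isometry direction carries no shape information, so
#' at most p−1 eigenvalues are nonzero.
#'
#' @param Y Species × variables matrix of log-measurements (strictly
#'   positive measurements, logged), or a `shape_table` in log
#'   representation.
#' @return Object of class `spca` (inherits `ordination`): eigenvalues,
#'   loadings, scores, percent variance, and the unit isometric vector.
#' @export
spca <- function(Y) {
  if (inherits(Y, "shape_table")) {
    if (attr(Y, "representation") != "log") {
      stop("shape_table must hold log-shape values")
    }
    Y <- shape_matrix(Y)
  }
  Y <- as.matrix(Y)
  if (nrow(Y) < 3) stop("need at least 3 species")
  if (any(apply(Y, 2, stats::sd) == 0)) stop("constant column in input")
  Z <- Y - rowMeans(Y) # project out isometric size
  S <- stats::cov(Z)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values
  tiny <- abs(vals) < 1e-12 * max(abs(vals), 1e-300)
  vals[tiny] <- pmax(vals[tiny], 0)
  V <- fix_signs(e$vectors)
  Zc <- sweep(Z, 2, colMeans(Z))
  scores <- Zc %*% V
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(Y)
  rownames(scores) <- rownames(Y)
  structure(
    list(method = "SPCA", variables = colnames(Y),
         eigenvalues = vals, loadings = V, scores = scores,
         percent = if (sum(vals) > 0) 100 * vals / sum(vals)
                   else rep(NA_real_, length(vals)), # no shape variance

         isometric = rep(1 / sqrt(ncol(Y)), ncol(Y))),
    class = c("spca", "ordination")
  )
}

#' @export
print.ordination <- function(x, n_axes = 5, ...) {
  cat(x$method, "of", length(x$variables), "variables,",
      nrow(x$scores), "species\n")
  k <- min(n_axes, length(x$eigenvalues))
  tab <- data.frame(
    axis = paste0("PC", seq_len(k)),
    eigenvalue = signif(x$eigenvalues[seq_len(k)], 4),
    percent = round(x$percent[seq_len(k)], 1)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ordination <- function(object, ...) {
  data.frame(
    axis = paste0("PC", seq_along(object$eigenvalues)),
    eigenvalue = object$eigenvalues,
    percent = object$percent,
    cumulative = cumsum(object$percent)
  )
}

# Align a bootstrap replicate's loadings to the point estimate: pick the
# replicate axis with maximal |dot product| (axis swapping), then flip the
# sign to match. Returns the aligned loading vector and whether a swap
# happened.
align_axis <- function(V_rep, point) {
  dots <- drop(crossprod(V_rep, point))
  j <- which.max(abs(dots))
  v <- V_rep[, j] * sign(dots[j])
  list(loading = v, swapped = j)
}

#' PCA ratio spectrum with bootstrap confidence intervals
#'
#' Orders one shape-PC's loadings into a spectrum: the difference between
#' two variables' loadings approximates how much of that component's
#' variance the corresponding log-ratio explains, so the variables at
#' opposite ends form the dominant ratio. Uncertainty comes from
#' resampling species (rows) with replacement, recomputing the SPCA,
#' aligning each replicate axis to the point estimate by maximal absolute
#' dot product (sign flipped to match; swaps are counted), and taking the
#' central percentile interval per variable.
#'
#' @param Y Log-measurement matrix (or `shape_table`), as for [spca()].
#' @param axis PC index (must be ≤ p−1).
#' @param n_boot Bootstrap replicates (default 999).
#' @param ci Central coverage of the percentile interval (default 0.68).
#' @param seed Optional RNG seed for reproducibility.
#' @return Object of class `ratio_spectrum`: data.frame columns
#'   `variable`, `point`, `lower`, `upper` (ordered by point value), with
#'   attributes `axis`, `dominant` (the two end variables), `n_boot`,
#'   `n_swapped`, `n_degenerate`, `ci`, `seed`.
#' @export
ratio_spectrum <- function(Y, axis = 1, n_boot = 999, ci = 0.68,
                           seed = NULL) {
  if (inherits(Y, "shape_table")) Y <- shape_matrix(Y)
  Y <- as.matrix(Y)
  p <- ncol(Y)
  if (axis > p - 1) stop("axis must be at most p-1 = ", p - 1)
  if (n_boot < 1) stop("n_boot must be positive")
  if (!is.null(seed)) set.seed(seed)
  point_fit <- spca(Y)
  point <- point_fit$loadings[, axis]
  reps <- matrix(NA_real_, n_boot, p)
  n_swapped <- 0L
  n_degenerate <- 0L
  draws <- 0L
  i <- 1L
  while (i <= n_boot && draws < 10L * n_boot) {
    draws <- draws + 1L
    idx <- sample.int(nrow(Y), replace = TRUE)
    fit <- try(spca(Y[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(fit, "try-error")) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    al <- align_axis(fit$loadings, point)
    if (al$swapped != axis) n_swapped <- n_swapped + 1L
    reps[i, ] <- al$loading
    i <- i + 1L
  }
  if (i <= n_boot) stop("too many degenerate bootstrap resamples")
  alpha <- (1 - ci) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  # percentile interval, widened (rarely needed) to bracket the point so
  # every spectrum bar passes through its point estimate
  out <- data.frame(variable = names(point), point = as.numeric(point),
                    lower = pmin(qs[1, ], as.numeric(point)),
                    upper = pmax(qs[2, ], as.numeric(point)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$point), ]
  rownames(out) <- NULL
  structure(out,
            axis = paste0("PC", axis),
            dominant = c(high = names(point)[which.max(point)],
                         low = names(point)[which.min(point)]),
            n_boot = n_boot, n_swapped = n_swapped,
            n_degenerate = n_degenerate, ci = ci, seed = seed,
            class = c("ratio_spectrum", "data.frame"))
}

#' Allometry ratio spectrum
#'
#' Per-variable allometric coefficients: the regression slope of each
#' variable's log-shape value (log-measurement minus the specimen's row
#' mean) on log isometric size (the row mean). Under perfect isometry all
#' coefficients are zero. Bootstrap intervals as in [ratio_spectrum()].
#' Shape is judged uncorrelated with size when every pairwise coefficient
#' difference has an interval covering zero.
#'
#' @inheritParams ratio_spectrum
#' @return A `ratio_spectrum` with attribute `axis = "allometry"`.
#' @export
allometry_spectrum <- function(Y, n_boot = 999, ci = 0.68, seed = NULL) {
  if (inherits(Y, "shape_table")) Y <- shape_matrix(Y)
  Y <- as.matrix(Y)
  if (!is.null(seed)) set.seed(seed)
  coef_fun <- function(M) {
    s <- rowMeans(M)
    if (stats::var(s) == 0) stop("zero variance in size")
    sh <- M - s
    drop(crossprod(sh, s - mean(s))) / sum((s - mean(s))^2)
  }
  point <- coef_fun(Y)
  reps <- matrix(NA_real_, n_boot, ncol(Y))
  n_degenerate <- 0L
  draws <- 0L
  i <- 1L
  while (i <= n_boot && draws < 10L * n_boot) {
    draws <- draws + 1L
    idx <- sample.int(nrow(Y), replace = TRUE)
    cf <- try(coef_fun(Y[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(cf, "try-error")) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    reps[i, ] <- cf
    i <- i + 1L
  }
  if (i <= n_boot) stop("too many degenerate bootstrap resamples")
  alpha <- (1 - ci) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(variable = colnames(Y), point = as.numeric(point),
                    lower = pmin(qs[1, ], as.numeric(point)),
                    upper = pmax(qs[2, ], as.numeric(point)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$point), ]
  rownames(out) <- NULL
  structure(out,
            axis = "allometry",
            dominant = c(high = colnames(Y)[which.max(point)],
                         low = colnames(Y)[which.min(point)]),
            n_boot = n_boot, n_swapped = 0L,
            n_degenerate = n_degenerate, ci = ci, seed = seed,
            class = c("ratio_spectrum", "data.frame"))
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat("Ratio spectrum (", attr(x, "axis"), "), ", attr(x, "n_boot"),
      " bootstrap replicates, ", round(100 * attr(x, "ci")),
      "% intervals\n", sep = "")
  dom <- attr(x, "dominant")
  cat("Dominant ratio:", dom["high"], "/", dom["low"], "\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
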
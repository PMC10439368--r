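## Discriminant analysis: Gaussian LDA with shared covariance, and
## phylogenetic flexible discriminant analysis (pFDA): optimal scoring
## after whitening predictors and class indicators by the inverse
## Cholesky factor of the lambda-transformed Brownian covariance.

declared_levels <- function(labels) {
  if (is.factor(labels)) levels(droplevels(labels)) else unique(as.character(labels))
}

indicator_matrix <- function(labels, levels) {
  out <- outer(as.character(labels), levels, `==`) + 0
  colnames(out) <- levels
  out
}

resolve_priors <- function(priors, labels, levels) {
  if (identical(priors, "proportional")) {
    as.numeric(table(factor(labels, levels = levels))) / length(labels)
  } else if (identical(priors, "uniform")) {
    rep(1 / length(levels), length(levels))
  } else {
    stopifnot(is.numeric(priors), length(priors) == length(levels))
    priors / sum(priors)
  }
}

# Shared-covariance Gaussian classification in a feature space Z.
# Posterior_g proportional to prior_g * N(z; m_g, W). Ties in the argmax go
# to the first class in declared level order (which.max's convention).
gaussian_classify <- function(Z, means, W, priors, levels) {
  Uw <- chol(W)
  Zs <- t(backsolve(Uw, t(Z), transpose = TRUE))   # whiten by W^{-1/2}
  Ms <- t(backsolve(Uw, t(means), transpose = TRUE))
  logpost <- sapply(seq_along(levels), function(g) {
    -0.5 * rowSums(sweep(Zs, 2, Ms[g, ])^2) + log(priors[g])
  })
  if (is.null(dim(logpost))) logpost <- matrix(logpost, nrow = 1)
  colnames(logpost) <- levels
  lp <- logpost - apply(logpost, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  cls <- levels[apply(post, 1, which.max)]
  list(class = factor(cls, levels = levels), posterior = post)
}

#' Linear discriminant analysis with shared covariance
#'
#' Gaussian LDA: class means, pooled within-class covariance
#' (denominator n − k), priors defaulting to observed class frequencies.
#' Discriminant directions are the eigenvectors of `W^-1 B` with `B` the
#' between-class scatter of the (frequency-weighted) class means;
#' proportion-of-trace is the normalised eigenvalue share per direction.
#'
#' @param X Species × variables numeric matrix.
#' @param labels Class labels (factor level order fixes tie-breaking).
#' @param priors `"proportional"` (default), `"uniform"`, or a numeric
#'   vector over the class levels.
#' @return Object of class `discrim` with method `"LDA"`.
#' @export
lda_fit <- function(X, labels, priors = "proportional") {
  X <- as.matrix(X)
  levels <- declared_levels(labels)
  labels <- factor(as.character(labels), levels = levels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  n <- nrow(X)
  k <- length(levels)
  p <- ncol(X)
  pri <- resolve_priors(priors, labels, levels)
  means <- do.call(rbind, lapply(levels, function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  rownames(means) <- levels
  Xc <- X - means[as.integer(labels), , drop = FALSE]
  W <- crossprod(Xc) / (n - k)
  Uw <- try(chol(W), silent = TRUE)
  if (inherits(Uw, "try-error")) {
    zero_var <- colnames(X)[diag(W) < 1e-12 * max(diag(W))]
    stop("singular pooled within-class covariance",
         if (length(zero_var)) paste0(" (constant within classes: ",
                                      paste(zero_var, collapse = ", "), ")"))
  }
  gm <- colSums(means * as.numeric(sizes)) / n
  Mc <- sweep(means, 2, gm)
  B <- crossprod(Mc * sqrt(as.numeric(sizes)))
  # eigenproblem of W^-1 B via symmetric form in the W-whitened space
  Bs <- backsolve(Uw, t(backsolve(Uw, t(B), transpose = TRUE)),
                  transpose = TRUE)
  e <- eigen((Bs + t(Bs)) / 2, symmetric = TRUE)
  r <- min(p, k - 1)
  ev <- pmax(e$values[seq_len(r)], 0)
  dirs <- backsolve(Uw, e$vectors[, seq_len(r), drop = FALSE])
  dirs <- fix_signs(dirs)
  colnames(dirs) <- paste0("LD", seq_len(r))
  rownames(dirs) <- colnames(X)
  structure(
    list(method = "LDA", levels = levels, priors = stats::setNames(pri, levels),
         counts = as.integer(sizes), means = means, cov = W,
         scaling = dirs, svd2 = ev,
         prop_trace = 100 * ev / sum(ev),
         variables = colnames(X), X = X, labels = labels),
    class = "discrim"
  )
}

#' Phylogenetic flexible discriminant analysis
#'
#' Whitens the predictor matrix and the class-indicator matrix by the
#' inverse Cholesky factor of the lambda-transformed Brownian covariance
#' `C(lambda)`, then fits flexible discriminant analysis by optimal
#' scoring on the whitened system (with a linear regression basis this is
#' LDA in the whitened space): after residualising against the whitened
#' intercept, discriminant directions come from the canonical correlations
#' between whitened predictors and whitened indicators. Cases are
#' classified by the shared-covariance Gaussian rule on the discriminant
#' variates. With `lambda = 0` on a unit-height ultrametric tree the
#' whitening is the identity and the model coincides with [lda_fit()].
#'
#' @param X Species × variables matrix, rows aligned to `cov$tip_order`.
#' @param labels Class labels.
#' @param cov A `phylo_cov` (untransformed; the lambda transform is
#'   applied internally).
#' @param lambda `"optimal"` (grid-search via [optimal_lambda()]) or a
#'   fixed value in `[0, lambda_max]`.
#' @param priors As in [lda_fit()].
#' @param grid_step Grid step for the lambda search.
#' @return Object of class `discrim` with method `"pFDA"`; carries the
#'   lambda used, the tip order of the whitening factor, and (for
#'   `"optimal"`) the full lambda-search trace.
#' @export
pfda_fit <- function(X, labels, cov, lambda = "optimal",
                     priors = "proportional", grid_step = 0.01) {
  X <- as.matrix(X)
  if (!inherits(cov, "phylo_cov")) stop("cov must be a phylo_cov")
  if (nrow(X) != length(cov$tip_order)) stop("rows of X must match cov tips")
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), cov$tip_order)) {
      stop("row names of X do not match the covariance tip order")
    }
    ord <- match(cov$tip_order, rownames(X))
    X <- X[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  levels <- declared_levels(labels)
  labels <- factor(as.character(labels), levels = levels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  trace <- NULL
  if (identical(lambda, "optimal")) {
    opt <- optimal_lambda(X, labels, cov, grid_step = grid_step)
    lambda <- opt$lambda
    trace <- opt$trace
  }
  n <- nrow(X)
  k <- length(levels)
  p <- ncol(X)
  pri <- resolve_priors(priors, labels, levels)

  V <- lambda_transform(cov, lambda)$C
  Lt <- t(chol_cov(V, height = cov$height))
  ones_w <- forwardsolve(Lt, rep(1, n))
  Xw <- forwardsolve(Lt, X)
  Yw <- forwardsolve(Lt, indicator_matrix(labels, levels)[, -1, drop = FALSE])
  # residualise against the whitened intercept (phylogenetic mean removal)
  gamma <- drop(crossprod(ones_w, Xw)) / sum(ones_w^2)
  Xt <- Xw - tcrossprod(ones_w, gamma)
  gamma_y <- drop(crossprod(ones_w, Yw)) / sum(ones_w^2)
  Yt <- Yw - tcrossprod(ones_w, gamma_y)

  qrX <- qr(Xt)
  if (qrX$rank < p) stop("whitened predictor matrix is rank deficient")
  Yhat <- qr.fitted(qrX, Yt)
  Syy <- crossprod(Yt)
  Ucy <- chol(Syy)
  Tm <- crossprod(Yt, Yhat)
  M1 <- backsolve(Ucy, t(backsolve(Ucy, t(Tm), transpose = TRUE)),
                  transpose = TRUE)
  e <- eigen((M1 + t(M1)) / 2, symmetric = TRUE)
  r <- min(p, k - 1)
  rho2 <- pmin(pmax(e$values[seq_len(r)], 0), 1)
  theta <- backsolve(Ucy, e$vectors[, seq_len(r), drop = FALSE])
  beta <- qr.coef(qrX, Yt %*% theta)
  beta <- fix_signs(beta)
  colnames(beta) <- paste0("pFDA", seq_len(r))
  rownames(beta) <- colnames(X)

  Z <- Xt %*% beta
  means_z <- do.call(rbind, lapply(levels, function(g) {
    colMeans(Z[labels == g, , drop = FALSE])
  }))
  rownames(means_z) <- levels
  Zc <- Z - means_z[as.integer(labels), , drop = FALSE]
  Wz <- crossprod(Zc) / (n - k)

  ratio <- rho2 / pmax(1 - rho2, 1e-12) # between/within share per axis
  structure(
    list(method = "pFDA", levels = levels,
         priors = stats::setNames(pri, levels),
         counts = as.integer(sizes),
         lambda = lambda, tip_order = cov$tip_order, trace = trace,
         scaling = beta, gamma = gamma, rho2 = rho2,
         prop_trace = 100 * ratio / sum(ratio),
         means_z = means_z, cov_z = Wz,
         variables = colnames(X), X = X, labels = labels,
         Z = Z),
    class = "discrim"
  )
}

#' Grid search for the discriminant Pagel's lambda
#'
#' Scores each lambda on a grid over `[0, lambda_max]` by the exact
#' Gaussian log-likelihood of the whitened multivariate regression of the
#' traits on the class indicators — the GLS operationalisation of
#' "maximising the correlation between the categories and the
#' morphology". The log-likelihood includes the `-p/2 log|C(lambda)|`
#' term so that different lambdas are compared on the original data
#' scale. The full trace is returned for audit.
#'
#' @inheritParams pfda_fit
#' @param grid_step Grid resolution (default 0.01).
#' @return List with `lambda` (argmax) and `trace` (data.frame of lambda
#'   and logLik over the grid).
#' @export
optimal_lambda <- function(X, labels, cov, grid_step = 0.01) {
  X <- as.matrix(X)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate input: constant trait column")
  }
  levels <- declared_levels(labels)
  D <- cbind(1, indicator_matrix(labels, levels)[, -1, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  lam_hi <- lambda_max(cov)
  grid <- seq(0, lam_hi, by = grid_step)
  ll <- vapply(grid, function(lam) {
    V <- lambda_transform(cov, lam)$C
    U <- try(chol(V), silent = TRUE)
    if (inherits(U, "try-error")) return(-Inf)
    Lt <- t(U)
    Dw <- forwardsolve(Lt, D)
    Xw <- forwardsolve(Lt, X)
    fit <- stats::lm.fit(Dw, Xw)
    rss <- colSums(as.matrix(fit$residuals)^2)
    if (any(rss <= 0)) return(-Inf)
    logdet <- 2 * sum(log(diag(U)))
    sum(-n / 2 * (log(2 * pi * rss / n) + 1)) - p / 2 * logdet
  }, numeric(1))
  list(lambda = grid[which.max(ll)],
       trace = data.frame(lambda = grid, logLik = ll))
}

#' @export
print.discrim <- function(x, ...) {
  cat(x$method, "with", length(x$levels), "classes:",
      paste(x$levels, collapse = ", "), "\n")
  if (x$method == "pFDA") cat("lambda =", format(x$lambda), "\n")
  cat("Priors:", paste(sprintf("%s=%.3f", x$levels, x$priors),
                       collapse = ", "), "\n")
  cat("Proportion of trace (%):",
      paste(round(x$prop_trace, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes and posteriors from a discriminant model
#'
#' For LDA, posteriors come from Gaussian class-conditional densities with
#' the pooled covariance times the priors, normalised. For pFDA, cases
#' must lie in the training set (resubstitution; classification happens on
#' the stored discriminant variates) — held-out tips go through
#' [predict_unlabeled_tips()], which conditions the whitening on the
#' training tips.
#'
#' @param object A `discrim` model.
#' @param newdata Optional matrix with the training variables as columns
#'   (LDA only); defaults to the training data.
#' @param ... Unused.
#' @return List with `class` (factor) and `posterior` (matrix, rows sum
#'   to 1).
#' @export
predict.discrim <- function(object, newdata = NULL, ...) {
  if (object$method == "LDA") {
    X <- if (is.null(newdata)) object$X else as.matrix(newdata)
    if (ncol(X) != ncol(object$means) ||
        (!is.null(colnames(X)) && !is.null(object$variables) &&
         !identical(colnames(X), object$variables))) {
      stop("columns of newdata must match the training variables")
    }
    gaussian_classify(X, object$means, object$cov, object$priors,
                      object$levels)
  } else {
    if (!is.null(newdata)) {
      stop("pFDA predictions for new tips require predict_unlabeled_tips()")
    }
    gaussian_classify(object$Z, object$means_z, object$cov_z,
                      object$priors, object$levels)
  }
}

#' Classify held-out tips with a pFDA model
#'
#' Whitens the held-out rows using the full-tree covariance conditioned on
#' the training tips: the stacked (training + held-out) covariance is
#' lambda-transformed and Cholesky-factorised with training tips first, so
#' forward substitution whitens each held-out row given the training
#' block. The training residualisation (`gamma`) and discriminant
#' directions are then applied and cases classified by the trained
#' Gaussian rule.
#'
#' @param model A pFDA `discrim` model.
#' @param X_new Matrix of held-out cases (rownames are tip labels present
#'   in `cov_full`).
#' @param cov_full `phylo_cov` over training plus held-out tips
#'   (untransformed).
#' @return List with `class`, `posterior` and `species_id`; empty inputs
#'   give empty results.
#' @export
predict_unlabeled_tips <- function(model, X_new, cov_full) {
  if (model$method != "pFDA") stop("model must be a pFDA fit")
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L) {
    return(list(class = factor(character(0), levels = model$levels),
                posterior = matrix(numeric(0), 0, length(model$levels),
                                   dimnames = list(NULL, model$levels)),
                species_id = character(0)))
  }
  new_ids <- rownames(X_new)
  if (is.null(new_ids)) stop("X_new must carry tip labels as rownames")
  absent <- setdiff(new_ids, cov_full$tip_order)
  if (length(absent) > 0L) {
    stop("held-out tip(s) absent from tree: ", paste(absent, collapse = ", "))
  }
  train <- model$tip_order
  ord <- c(train, new_ids)
  C <- lambda_transform(cov_full, model$lambda)$C[ord, ord]
  Lt <- t(chol_cov(C, height = cov_full$height))
  D <- cbind(1, rbind(model$X, X_new))
  Dw <- forwardsolve(Lt, D)
  idx_new <- length(train) + seq_along(new_ids)
  ones_w_new <- Dw[idx_new, 1]
  Xw_new <- Dw[idx_new, -1, drop = FALSE]
  Xt_new <- Xw_new - tcrossprod(ones_w_new, model$gamma)
  Z_new <- Xt_new %*% model$scaling
  res <- gaussian_classify(Z_new, model$means_z, model$cov_z,
                           model$priors, model$levels)
  res$species_id <- new_ids
  res
}

#' Cross-validated LDA classification
#'
#' K-fold (default leave-one-out) cross-validation of [lda_fit()].
#' Resubstitution on the training data remains the headline metric of the
#' confusion tables; cross-validation is reported separately as the
#' honest generalisation estimate.
#'
#' @inheritParams lda_fit
#' @param folds Number of folds (default `nrow(X)`, leave-one-out).
#' @param seed RNG seed for the fold assignment (unused for
#'   leave-one-out).
#' @return List with `class` (held-out predictions, one per row),
#'   `accuracy` (percent) and `folds`.
#' @export
lda_cv <- function(X, labels, priors = "proportional",
                   folds = nrow(X), seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- min(folds, n)
  levels <- declared_levels(labels)
  labels <- factor(as.character(labels), levels = levels)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- if (folds == n) seq_len(n) else sample(rep_len(seq_len(folds), n))
  pred <- factor(rep(NA_character_, n), levels = levels)
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    fit <- lda_fit(X[!hold, , drop = FALSE], droplevels(labels[!hold]),
                   priors = priors)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])$class
  }
  list(class = pred,
       accuracy = 100 * mean(as.character(pred) == as.character(labels)),
       folds = folds)
}

#' Confusion matrix with row percentages and overall accuracy
#'
#' Either cross-tabulates true against predicted labels, or accepts an
#' already tabulated k × k count matrix (rows = true classes, columns =
#' predicted) such as a published classification table.
#'
#' @param truth True labels, or a square count matrix (then `predicted`
#'   is ignored).
#' @param predicted Predicted labels.
#' @param levels Optional shared level set (defaults to the union, in
#'   declared order of `truth`).
#' @return Object of class `confusion_matrix`: `counts`, `row_pct`
#'   (rows sum to 100), `accuracy` (percent, `100 * trace / total`),
#'   `n` per true class.
#' @export
confusion <- function(truth, predicted = NULL, levels = NULL) {
  if (is.matrix(truth) || is.data.frame(truth)) {
    counts <- as.matrix(truth)
    if (nrow(counts) != ncol(counts)) stop("count matrix must be square")
    if (is.null(rownames(counts))) {
      rownames(counts) <- colnames(counts) <-
        if (!is.null(levels)) levels else paste0("class", seq_len(nrow(counts)))
    }
  } else {
    truth <- as.character(truth)
    predicted <- as.character(predicted)
    stopifnot(length(truth) == length(predicted))
    if (is.null(levels)) levels <- unique(c(truth, predicted))
    unseen <- setdiff(c(truth, predicted), levels)
    if (length(unseen) > 0L) {
      stop("label(s) outside the level set: ", paste(unseen, collapse = ", "))
    }
    counts <- table(factor(truth, levels = levels),
                    factor(predicted, levels = levels))
    counts <- matrix(as.integer(counts), nrow = length(levels),
                     dimnames = list(levels, levels))
  }
  n_row <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(n_row == 0, 1, n_row)
  structure(
    list(levels = rownames(counts), counts = counts, row_pct = row_pct,
         n = n_row, accuracy = 100 * sum(diag(counts)) / sum(counts)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%% (%d / %d)\n",
              x$accuracy, sum(diag(x$counts)), sum(x$counts)))
  cat("\nCounts (rows = true, columns = predicted):\n")
  print(cbind(x$counts, Total = x$n))
  cat("\nRow percentages:\n")
  print(round(x$row_pct, 1))
  invisible(x)
}

#' Case-wise prediction table
#'
#' Assembles per-species predictions with posteriors and agreement flags:
#' `correct` (predicted equals the primary label), `matches_alternative`
#' (predicted equals a secondary label, where one exists), and
#' `proxy_label_used` passed through for species whose primary label was
#' taken from a proxy taxon.
#'
#' @param pred Output of [predict.discrim()] or
#'   [predict_unlabeled_tips()].
#' @param truth Primary labels (named by species or aligned to `pred`).
#' @param species_id Species identifiers (defaults to `pred$species_id`
#'   or names of `truth`).
#' @param secondary Optional secondary labels (NA where none).
#' @param proxy Optional logical flags: label borrowed from a proxy
#'   taxon.
#' @return `data.frame` of class `casewise`: one row per case with
#'   posterior columns `post.<level>`.
#' @export
casewise_predictions <- function(pred, truth, species_id = NULL,
                                 secondary = NULL, proxy = NULL) {
  n <- length(pred$class)
  if (is.null(species_id)) {
    species_id <- if (!is.null(pred$species_id)) pred$species_id
                  else if (!is.null(names(truth))) names(truth)
                  else as.character(seq_len(n))
  }
  truth <- as.character(truth)
  predicted <- as.character(pred$class)
  out <- data.frame(species_id = species_id, true = truth,
                    predicted = predicted,
                    correct = predicted == truth,
                    stringsAsFactors = FALSE)
  out$matches_alternative <- if (is.null(secondary)) FALSE else {
    !is.na(secondary) & predicted == as.character(secondary)
  }
  out$proxy_label_used <- if (is.null(proxy)) FALSE else as.logical(proxy)
  post <- as.data.frame(pred$posterior)
  names(post) <- paste0("post.", colnames(pred$posterior))
  out <- cbind(out, post)
  class(out) <- c("casewise", "data.frame")
  out
}

#' Summarise agreement of case-wise predictions
#'
#' Counts primary-correct, alternative-correct (secondary label matched
#' when the primary was missed), proxy-correct (correct among
#' proxy-labelled cases) and misclassified-despite-certainty (wrong with
#' no secondary label and no proxy). When a second prediction set over
#' the same species is supplied, the cross-method agreement rate is
#' reported.
#'
#' @param predictions A `casewise` table.
#' @param predictions2 Optional second `casewise` table over the same
#'   species.
#' @return List of counts (and `agreement_pct` when two sets given).
#' @export
casewise_report <- function(predictions, predictions2 = NULL) {
  stopifnot(inherits(predictions, "casewise"))
  out <- list(
    n = nrow(predictions),
    primary_correct = sum(predictions$correct),
    alternative_correct = sum(!predictions$correct &
                                predictions$matches_alternative),
    proxy_correct = sum(predictions$correct & predictions$proxy_label_used),
    misclassified_despite_certainty = sum(
      !predictions$correct & !predictions$matches_alternative &
        !predictions$proxy_label_used
    )
  )
  if (!is.null(predictions2)) {
    m <- match(predictions$species_id, predictions2$species_id)
    if (anyNA(m)) stop("species_id mismatch between prediction sets")
    out$agreement_pct <- 100 * mean(
      predictions$predicted == predictions2$predicted[m]
    )
  }
  out
}
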
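## Phylogenetic generalized least squares with maximum-likelihood Pagel's
## lambda, and AIC-based model selection across candidate predictor sets.

pgls_loglik <- function(lam, y, Xd, cov) {
  V <- lambda_transform(cov, lam)$C
  U <- try(chol(V), silent = TRUE)
  if (inherits(U, "try-error")) return(-Inf)
  yw <- forwardsolve(t(U), y)
  Xw <- forwardsolve(t(U), Xd)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  logdet <- 2 * sum(log(diag(U)))
  -0.5 * (n * log(2 * pi * rss / n) + logdet + n)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `formula` by GLS with error covariance `C(lambda)`, the
#' lambda-transformed Brownian covariance of the phylogeny. For fixed
#' lambda, `beta = (X' V^-1 X)^-1 X' V^-1 y` with `V = C(lambda)`;
#' `sigma^2` and the log-likelihood are evaluated at the ML optimum.
#' `lambda = "ML"` maximises the profile log-likelihood over
#' `[0, lambda_max]` by a grid (step `grid_step`) followed by local
#' refinement; `lambda_max` is the positive-definiteness bound of the
#' covariance, so estimates above 1 are possible on non-ultrametric trees.
#' All solves go through the Cholesky factor of `V`.
#'
#' Coefficient standard errors use the unbiased residual variance
#' `RSS / (n - k)`; the reported log-likelihood and AIC use the ML
#' variance, with `AIC = -2 logLik + 2 (k + 2)` counting the coefficients
#' plus `sigma^2` and `lambda`.
#'
#' Factor predictors follow R's standard treatment coding via
#' `model.matrix`; for single-coefficient designs pass pre-coded numeric
#' scores (see [code_levels()]).
#'
#' @param formula Model formula.
#' @param data Data frame with rows named by (or ordered as) the
#'   covariance tip order.
#' @param cov A `phylo_cov`.
#' @param lambda `"ML"` (default) or a fixed non-negative number.
#' @param grid_step Grid resolution of the profile-likelihood search
#'   (default 0.01).
#' @return Object of class `pgls`: coefficients, SEs, t and p values,
#'   `lambda`, `lambda_max`, `sigma2` (ML), `logLik`, `AIC`, residuals,
#'   fitted values, profile trace, and a convergence note when the
#'   optimum sits on the search boundary.
#' @export
pgls <- function(formula, data, cov, lambda = "ML", grid_step = 0.01) {
  if (!inherits(cov, "phylo_cov")) stop("cov must be a phylo_cov")
  data <- as.data.frame(data)
  if (!is.null(rownames(data)) &&
      all(cov$tip_order %in% rownames(data))) {
    data <- data[cov$tip_order, , drop = FALSE]
  } else if (nrow(data) != length(cov$tip_order)) {
    stop("data rows do not match covariance tips")
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  Xd <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  k <- ncol(Xd)
  if (qr(Xd)$rank < k) stop("singular design matrix")

  boundary <- NULL
  if (identical(lambda, "ML")) {
    lam_hi <- lambda_max(cov)
    grid <- seq(0, lam_hi, by = grid_step)
    if (grid[length(grid)] < lam_hi) grid <- c(grid, lam_hi)
    ll <- vapply(grid, pgls_loglik, numeric(1), y = y, Xd = Xd, cov = cov)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(pgls_loglik, c(lo, hi), maximum = TRUE,
                           y = y, Xd = Xd, cov = cov, tol = 1e-6)
    lam_hat <- if (ll[i] >= opt$objective) grid[i] else opt$maximum
    stopifnot(pgls_loglik(lam_hat, y, Xd, cov) >= ll[1] - 1e-8,
              pgls_loglik(lam_hat, y, Xd, cov) >= ll[length(ll)] - 1e-8)
    if (abs(lam_hat - lam_hi) < 1e-6 || lam_hat == 0) {
      boundary <- paste0("lambda at search boundary (", signif(lam_hat, 4), ")")
    }
    trace <- data.frame(lambda = grid, logLik = ll)
  } else {
    if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0 or 'ML'")
    lam_hat <- lambda
    lam_hi <- NA_real_
    trace <- NULL
  }

  V <- lambda_transform(cov, lam_hat)$C
  U <- chol_cov(V, height = cov$height)
  yw <- forwardsolve(t(U), y)
  Xw <- forwardsolve(t(U), Xd)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  sigma2_ub <- rss / (n - k)
  XtVX_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(diag(XtVX_inv) * sigma2_ub)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  logdet <- 2 * sum(log(diag(U)))
  ll_hat <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  fitted <- drop(Xd %*% beta)
  structure(
    list(call = match.call(), formula = formula,
         coefficients = beta,
         coef_table = data.frame(
           estimate = beta, se = se, t = tval, p = pval,
           row.names = colnames(Xd)
         ),
         lambda = lam_hat, lambda_max = lam_hi, lambda_input = lambda,
         sigma2 = sigma2_ml, logLik = ll_hat,
         AIC = -2 * ll_hat + 2 * (k + 2),
         n = n, df_residual = n - k,
         fitted = fitted, residuals = y - fitted,
         profile = trace, boundary = boundary,
         tip_order = cov$tip_order),
    class = "pgls"
  )
}

#' Integer-code a factor by a declared level order
#'
#' Produces the single-coefficient numeric coding used in compact PGLS
#' designs: level i of `order` maps to the integer i. The order is
#' configuration, not inference, and is recorded as an attribute.
#'
#' @param x Factor or character vector.
#' @param order Level order (defaults to factor levels).
#' @return Integer vector with attribute `level_order`.
#' @export
code_levels <- function(x, order = NULL) {
  x <- as.character(x)
  if (is.null(order)) order <- unique(x)
  unknown <- setdiff(unique(x), order)
  if (length(unknown) > 0L) {
    stop("value(s) outside declared order: ", paste(unknown, collapse = ", "))
  }
  structure(match(x, order), level_order = order)
}

#' @export
print.pgls <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("lambda = %.4g (%s), sigma2 = %.4g, logLik = %.4g, AIC = %.4g\n",
              x$lambda,
              if (identical(x$lambda_input, "ML")) "ML" else "fixed",
              x$sigma2, x$logLik, x$AIC))
  if (!is.null(x$boundary)) cat("note:", x$boundary, "\n")
  print(signif(as.matrix(x$coef_table), 4))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  object$coef_table
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(stats::terms(object$formula))
  mf <- stats::model.frame(tt, as.data.frame(newdata))
  Xd <- stats::model.matrix(tt, mf)
  drop(Xd %*% object$coefficients)
}

#' Rank candidate PGLS designs by AIC
#'
#' Fits every candidate formula with ML lambda on the same data and
#' covariance, and ranks the fits by AIC. Exact ties keep declaration
#' order (stable sort), which is reported in the table.
#'
#' @param formulas Named (or unnamed) list of model formulas sharing the
#'   same response.
#' @param data Data frame aligned to `cov$tip_order`.
#' @param cov A `phylo_cov`.
#' @param ... Passed to [pgls()].
#' @return Object of class `pgls_select`: ranking table (`model`,
#'   `lambda`, `logLik`, `AIC`, `dAIC`, `best`) and the list of fits in
#'   declaration order.
#' @export
select_model <- function(formulas, data, cov, ...) {
  if (length(formulas) < 2) stop("need at least 2 candidate designs")
  nm <- names(formulas)
  if (is.null(nm)) nm <- rep("", length(formulas))
  nm[nm == ""] <- vapply(formulas[nm == ""], function(f) {
    paste(deparse(f), collapse = "")
  }, character(1))
  fits <- lapply(formulas, pgls, data = data, cov = cov, ...)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  ord <- order(aic) # stable: equal AICs keep declaration order
  tab <- data.frame(
    model = nm[ord],
    lambda = vapply(fits, `[[`, numeric(1), "lambda")[ord],
    logLik = vapply(fits, `[[`, numeric(1), "logLik")[ord],
    AIC = aic[ord],
    dAIC = aic[ord] - min(aic),
    stringsAsFactors = FALSE
  )
  tab$best <- seq_len(nrow(tab)) == 1L
  structure(list(table = tab, fits = stats::setNames(fits, nm)),
            class = "pgls_select")
}

#' @export
print.pgls_select <- function(x, ...) {
  cat("PGLS model selection (ML lambda, ranked by AIC)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
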
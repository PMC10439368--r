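## Mosimann shape variables: isometric size removal by the per-specimen
## geometric mean of the length measurements.

#' Mosimann shape variables
#'
#' Removes isometric size from a measurement table by dividing each
#' specimen's length measurements by their geometric mean. Size is
#' `size_i = (prod_j x_ij)^(1/p)` over the p selected length variables;
#' shape is either the dimensionless ratio `x_ij / size_i` or its natural
#' log. Internally computed as log-then-row-centre, which is algebraically
#' identical to divide-then-log but numerically stabler for small
#' measurements. Angle columns (degrees) are never entered into the
#' geometric mean; when present among `variables` they are dropped with a
#' message.
#'
#' @param table A `measurement_table` (or plain data.frame with the
#'   columns).
#' @param variables Length-measurement columns to use; defaults to the
#'   table's active variable set (attribute `variable_set`) minus angle
#'   columns.
#' @param log Return log-shape (default) or raw Mosimann ratios.
#' @return Object of class `shape_table`: data.frame with `species_id`,
#'   `size` (cm, geometric mean), and one shape column per variable.
#'   Attributes: `representation` ("log" or "ratio"), `variable_set`.
#'   Every row satisfies sum(log-shape) = 0, equivalently prod(ratio) = 1.
#' @examples
#' tab <- data.frame(species_id = "sp1", a = 1, b = 2, c = 4)
#' sh <- mosimann_shape(tab, variables = c("a", "b", "c"), log = FALSE)
#' sh$size      # 2  (cube root of 8)
#' sh[, c("a", "b", "c")]  # 0.5, 1, 2
#' @export
mosimann_shape <- function(table, variables = NULL, log = TRUE) {
  if (is.null(variables)) {
    variables <- attr(table, "variable_set")
    if (is.null(variables)) {
      variables <- names(table)[vapply(table, is.numeric, logical(1))]
    }
  }
  dropped <- intersect(variables, angle_variables)
  if (length(dropped) > 0L) {
    message("excluding angle column(s) from shape computation: ",
            paste(dropped, collapse = ", "))
    variables <- setdiff(variables, angle_variables)
  }
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols) > 0L) {
    stop("missing variable(s): ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(table)[variables])
  if (!is.numeric(X)) stop("selected variables must be numeric")
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)
    stop("non-positive value(s), e.g. column '", variables[bad[1, 2]],
         "' row ", bad[1, 1], "; geometric mean undefined")
  }
  logX <- base::log(X)
  log_size <- rowMeans(logX)
  shape <- logX - log_size # log-shape: rows sum to zero by construction
  if (!log) shape <- exp(shape)
  ids <- if ("species_id" %in% names(table)) table$species_id else rownames(table)
  out <- data.frame(species_id = ids, size = exp(log_size),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[variables] <- as.data.frame(shape)
  rownames(out) <- ids
  attr(out, "representation") <- if (log) "log" else "ratio"
  attr(out, "variable_set") <- variables
  class(out) <- c("shape_table", "data.frame")
  out
}

#' Full-rank coordinates of shape space
#'
#' Log-shape variables satisfy a sum-to-zero constraint per row, so the p
#' shape columns span only p−1 dimensions and their pooled covariance is
#' singular — discriminant analysis cannot run on them directly. This
#' projects the shape matrix onto a fixed orthonormal (Helmert) basis of
#' the isometry-free subspace, yielding p−1 full-rank coordinates that
#' preserve all pairwise Euclidean distances. Classifiers are affine
#' invariant, so results do not depend on the particular basis.
#'
#' @param X Log-shape matrix (species × p), rows summing to 0.
#' @return Species × (p−1) matrix with columns `SC1..SC(p-1)`.
#' @export
shape_coordinates <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  H <- stats::contr.helmert(p)
  H <- H %*% diag(1 / sqrt(colSums(H^2)), p - 1)
  out <- X %*% H
  colnames(out) <- paste0("SC", seq_len(p - 1))
  rownames(out) <- rownames(X)
  out
}

#' Extract the shape matrix from a shape table
#'
#' @param x A `shape_table`.
#' @return Numeric matrix (species × variables) of shape values with
#'   species ids as rownames.
#' @export
shape_matrix <- function(x) {
  vars <- attr(x, "variable_set")
  m <- as.matrix(as.data.frame(x)[vars])
  rownames(m) <- x$species_id
  m
}
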
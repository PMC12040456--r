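#' Describe a dimensionality-reduction branch
#'
#' A branch is applied after standardization and refitted inside every
#' training fold: `"none"` passes features through, `"pca"` projects onto
#' the first `k` principal components (k constrained to the explored range
#' 5–15), `"select"` keeps the `k` features most correlated with the
#' target.
#'
#' @param type One of `"none"`, `"pca"`, `"select"`.
#' @param k Number of components/features (required for pca and select).
#' @return A `reduction_branch`.
#' @export
reduction_branch <- function(type = c("none", "pca", "select"), k = NULL) {
  type <- match.arg(type)
  if (type != "none") {
    if (is.null(k)) stop("branch '", type, "' requires k", call. = FALSE)
    if (type == "pca" && (k < 5 || k > 15)) {
      stop("pca branch explores k between 5 and 15", call. = FALSE)
    }
  }
  structure(list(type = type, k = k), class = "reduction_branch")
}

branch_label <- function(branch) {
  if (branch$type == "none") "none" else paste0(branch$type, "(", branch$k, ")")
}

#' Principal-component reduction with explained-variance accounting
#'
#' Computes principal components of an already-standardized matrix and
#' either keeps the first `k` or, in threshold mode, the smallest number of
#' components whose cumulative explained-variance fraction reaches
#' `variance_threshold`. Components are ordered by decreasing explained
#' variance.
#'
#' @param x Numeric matrix (standardized) or an `encoded_matrix`.
#' @param k Number of components to retain.
#' @param variance_threshold Alternative to `k`: cumulative
#'   explained-variance target in (0, 1].
#' @return A `pca_reduction`: list with `x` (reduced matrix), `rotation`,
#'   `explained` (variance fractions of all components) and `k`.
#' @export
pca_reduce <- function(x, k = NULL, variance_threshold = NULL) {
  if (inherits(x, "encoded_matrix")) x <- x$x
  if (is.null(k) && is.null(variance_threshold)) {
    stop("supply k or variance_threshold", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(k)) {
    k <- which(cumsum(explained) >= variance_threshold)[1]
    if (is.na(k)) k <- length(explained)
  }
  if (k > ncol(x)) {
    stop("k = ", k, " exceeds the ", ncol(x), " available columns",
         call. = FALSE)
  }
  structure(list(x = pc$x[, seq_len(k), drop = FALSE],
                 rotation = pc$rotation, explained = explained, k = k),
            class = "pca_reduction")
}

#' Project new data onto a fitted principal-component reduction
#'
#' @param reduction A `pca_reduction` fitted on training data.
#' @param x New (standardized) matrix with the training columns.
#' @return Reduced matrix with `reduction$k` columns.
#' @export
apply_pca <- function(reduction, x) {
  if (inherits(x, "encoded_matrix")) x <- x$x
  x %*% reduction$rotation[, seq_len(reduction$k), drop = FALSE]
}

# top-k features by absolute Pearson correlation with the target;
# zero-variance columns score 0; ties resolved by column order
select_features <- function(x, y, k) {
  if (k > ncol(x)) stop("k exceeds the number of columns", call. = FALSE)
  scores <- apply(x, 2, function(col) {
    if (stats::sd(col) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps) {
      return(0)
    }
    abs(stats::cor(col, y))
  })
  sort(order(-scores)[seq_len(k)])
}

# Fit a branch on training data; returns list(transform = function(matrix))
fit_branch <- function(branch, x_train, y_train) {
  if (branch$type == "none") {
    list(transform = function(x) x)
  } else if (branch$type == "pca") {
    red <- pca_reduce(x_train, k = min(branch$k, ncol(x_train)))
    list(transform = function(x) apply_pca(red, x))
  } else {
    idx <- select_features(x_train, y_train, min(branch$k, ncol(x_train)))
    list(transform = function(x) x[, idx, drop = FALSE])
  }
}
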
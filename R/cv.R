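#' Seeded k-fold assignment
#'
#' Randomly partitions `n` observations into `k` folds whose sizes differ
#' by at most one; identical seeds give identical folds.
#'
#' @param n Number of observations.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer RNG seed.
#' @return Integer vector of fold labels (1..k) of length `n`.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  withr::with_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    fold
  })
}

#' Cross-validate one model candidate
#'
#' Seeded k-fold cross-validation of one (family, hyperparameters, branch)
#' candidate on one response. Standardization and the reduction branch are
#' refitted inside every training fold and applied unchanged to the held-out
#' fold, so no fold ever informs its own preprocessing.
#'
#' @param spec A `model_spec`.
#' @param table An experiment table.
#' @param response Response column to predict.
#' @param k Number of folds (the study setting is fivefold).
#' @param seed Integer seed driving both the fold assignment and any
#'   stochastic model fits.
#' @param branch A `reduction_branch`.
#' @param design The `factor_design` used for feature encoding.
#' @return Tibble of per-fold metric sets (`fold`, `r2_train`, `r2_val`,
#'   `mae`, `rmse`, `mse`, `w_new`).
#' @export
cross_validate <- function(spec, table, response, k = 5, seed,
                           branch = reduction_branch("none"),
                           design = build_design()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!response %in% names(table)) {
    stop("unknown response: ", response, call. = FALSE)
  }
  em <- encode_features(table, design)
  y <- table[[response]]
  folds <- make_folds(nrow(table), k, seed)
  out <- lapply(seq_len(k), function(i) {
    tr <- folds != i
    em_train <- standardize(list_as_encoded(em$x[tr, , drop = FALSE],
                                            em$column_map))
    em_val <- standardize(list_as_encoded(em$x[!tr, , drop = FALSE],
                                          em$column_map),
                          fit_stats = em_train$scaling_stats)
    br <- fit_branch(branch, em_train$x, y[tr])
    x_train <- br$transform(em_train$x)
    x_val <- br$transform(em_val$x)
    fit <- fit_model(spec, x_train, y[tr], seed = seed + i)
    dplyr::mutate(evaluate_fit(fit, x_train, y[tr], x_val, y[!tr]),
                  fold = i, .before = 1)
  })
  dplyr::bind_rows(out)
}

list_as_encoded <- function(x, column_map) {
  structure(list(x = x, column_map = column_map, scaling_stats = NULL),
            class = "encoded_matrix")
}
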
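#' Default hyperparameter grids for the roster
#'
#' One data frame of grid points per family (rows in lexicographic
#' exploration order). Defaults are intentionally compact; the
#' random-forest grid spans the commonly explored forest sizes.
#'
#' @return Named list of data frames keyed by family.
#' @export
default_grids <- function() {
  list(
    knn = data.frame(k = c(3, 5)),
    elastic_net = expand.grid(alpha = 0.5, lambda = c(0.01, 0.1)),
    linear = data.frame(row.names = 1),
    svr = data.frame(cost = 1, epsilon = 0.1),
    nusvr = data.frame(cost = 1, nu = 0.5),
    decision_tree = data.frame(maxdepth = 10, minsplit = 5, cp = 0.01),
    gradient_boosting = data.frame(nrounds = 100, eta = 0.1, max_depth = 3),
    random_forest = expand.grid(num_trees = c(100, 300), max_depth = 10,
                                min_node_size = 5),
    adaboost = data.frame(nrounds = 50, maxdepth = 4),
    xgboost = data.frame(nrounds = 100, eta = 0.3, max_depth = 6)
  )
}

grid_rows <- function(grid) {
  n <- max(nrow(grid), 1)
  lapply(seq_len(n), function(i) {
    if (ncol(grid) == 0) list() else as.list(grid[i, , drop = FALSE])
  })
}

#' Grid search over the model roster by the composite score
#'
#' Evaluates every (family, grid point, reduction branch) candidate by
#' seeded k-fold cross-validation, scores each candidate with one
#' [w_new()] computed from its fold-mean metrics, and returns the argmax.
#' Ties are broken by roster order, then by lexicographic grid order, then
#' by branch order. The winner is additionally refitted on a seeded 70/30
#' split of the table and its split metric set is reported alongside the
#' cross-validation folds.
#'
#' @param table An experiment table.
#' @param response Response column to predict.
#' @param roster Character vector of family ids (subset of
#'   [roster_families()]), in tie-break priority order.
#' @param grids Named list of per-family grid data frames; families absent
#'   from the list use their single default grid point.
#' @param k Number of CV folds.
#' @param seed Integer seed for folds, stochastic fits and the 70/30 split.
#' @param branches List of `reduction_branch` objects to explore.
#' @param design The `factor_design` for feature encoding.
#' @return A `selection_result`: list with `best` (family, params, branch),
#'   `leaderboard` (one row per candidate: fold-mean metrics + `w_new`),
#'   `cv_metrics` (per-fold metrics of the winner) and `split_metrics`
#'   (winner's metric set on the 70/30 split).
#' @export
grid_search <- function(table, response, roster = roster_families(),
                        grids = default_grids(), k = 5, seed,
                        branches = list(reduction_branch("none")),
                        design = build_design()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(roster) == 0) stop("roster must be non-empty", call. = FALSE)
  unknown <- setdiff(roster, roster_families())
  if (length(unknown) > 0) {
    stop("unknown roster famil(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  failures <- character(0)
  for (family in roster) {
    grid <- grids[[family]]
    if (is.null(grid)) grid <- as.data.frame(default_params(family))
    for (gp in grid_rows(grid)) {
      for (branch in branches) {
        spec <- make_model(family, gp)
        res <- tryCatch({
          folds <- cross_validate(spec, table, response, k = k, seed = seed,
                                  branch = branch, design = design)
          means <- colMeans(folds[c("r2_train", "r2_val", "mae", "rmse",
                                    "mse")])
          tibble::tibble(
            family = family,
            params = paste(names(gp), unlist(gp), sep = "=", collapse = ";"),
            branch = branch_label(branch),
            r2_train = means[["r2_train"]], r2_val = means[["r2_val"]],
            mae = means[["mae"]], rmse = means[["rmse"]],
            mse = means[["mse"]],
            w_new = w_new(means[["r2_train"]], means[["r2_val"]],
                          means[["mae"]], means[["rmse"]], means[["mse"]])
          )
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) {
          failures <- c(failures, paste0(family, ": ", res))
        } else {
          rows[[length(rows) + 1]] <- res
        }
      }
    }
  }
  if (length(rows) == 0) {
    stop("every candidate failed:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  }
  leaderboard <- dplyr::bind_rows(rows)
  best_i <- which.max(leaderboard$w_new)  # first max: iteration order breaks ties
  best <- leaderboard[best_i, ]
  best_params <- parse_params(best$params)
  best_branch <- parse_branch(best$branch)
  best_spec <- make_model(best$family, best_params)

  cv_metrics <- cross_validate(best_spec, table, response, k = k, seed = seed,
                               branch = best_branch, design = design)
  split_metrics <- holdout_metrics(best_spec, table, response, seed,
                                   best_branch, design)
  structure(list(best = list(family = best$family, params = best_params,
                             branch = best_branch),
                 leaderboard = leaderboard, cv_metrics = cv_metrics,
                 split_metrics = split_metrics),
            class = "selection_result")
}

parse_params <- function(s) {
  if (s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    num <- suppressWarnings(as.numeric(x[2]))
    if (is.na(num)) x[2] else num
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

parse_branch <- function(label) {
  if (label == "none") return(reduction_branch("none"))
  type <- sub("\\(.*", "", label)
  k <- as.integer(sub(".*\\((\\d+)\\)", "\\1", label))
  reduction_branch(type, k)
}

# metric set of one candidate on a seeded 70/30 train/test split
holdout_metrics <- function(spec, table, response, seed, branch, design) {
  sp <- split_experiment(table, 0.7, seed)
  em_train <- standardize(encode_features(sp$train, design))
  em_test <- standardize(encode_features(sp$test, design),
                         fit_stats = em_train$scaling_stats)
  y_train <- sp$train[[response]]
  y_test <- sp$test[[response]]
  br <- fit_branch(branch, em_train$x, y_train)
  x_train <- br$transform(em_train$x)
  x_test <- br$transform(em_test$x)
  fit <- fit_model(spec, x_train, y_train, seed = seed)
  evaluate_fit(fit, x_train, y_train, x_test, y_test)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> best: ", x$best$family,
      " (", branch_label(x$best$branch), "), w_new = ",
      sprintf("%.3f", max(x$leaderboard$w_new)), "\n", sep = "")
  invisible(x)
}
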
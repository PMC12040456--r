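#' @keywords internal
experiment_columns <- function() {
  c("genus", "varied_factor", "replicate",
    "co2_pct", "temperature_C", "light_colour", "light_intensity_lux", "pH",
    response_names())
}

#' Read and write the experiment-table CSV
#'
#' The on-disk format is plain comma-separated UTF-8 with a header naming
#' every column of the experiment table exactly (`genus`, `varied_factor`,
#' `replicate`, the five factor columns, the nine response columns) and "."
#' as the decimal mark. Reading validates the schema: missing columns,
#' non-numeric factor or response cells, and negative responses are errors.
#' An empty file with a valid header yields an empty table.
#'
#' @param path File path.
#' @param table An experiment table as produced by [generate_experiment()]
#'   or [read_experiment_csv()].
#' @return `read_experiment_csv()` returns the experiment tibble;
#'   `write_experiment_csv()` returns `path` invisibly.
#' @export
read_experiment_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(experiment_columns(), names(tab))
  if (length(missing_cols) > 0) {
    stop("experiment CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[experiment_columns()]
  numeric_cols <- c("replicate", "co2_pct", "temperature_C",
                    "light_intensity_lux", "pH", response_names())
  for (cn in numeric_cols) {
    if (nrow(tab) > 0 && !is.numeric(tab[[cn]])) {
      stop("column '", cn, "' contains non-numeric values", call. = FALSE)
    }
    if (nrow(tab) == 0) tab[[cn]] <- as.numeric(tab[[cn]])
  }
  for (rn in response_names()) {
    if (any(tab[[rn]] < 0, na.rm = TRUE)) {
      stop("negative values in response column '", rn, "'", call. = FALSE)
    }
  }
  tab
}

#' @rdname read_experiment_csv
#' @export
write_experiment_csv <- function(table, path) {
  missing_cols <- setdiff(experiment_columns(), names(table))
  if (length(missing_cols) > 0) {
    stop("table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[experiment_columns()], path, progress = FALSE)
  invisible(path)
}

#' Encode factor columns as a numeric feature matrix
#'
#' Drops the metadata columns (`genus`, `varied_factor`, `replicate`) and
#' the responses, passes the four numeric factors through, and one-hot
#' encodes light colour into one indicator column per design level (no
#' reference level is dropped: the downstream tree ensembles need every
#' level, and importance aggregation pools the indicators back into one
#' factor).
#'
#' @param table An experiment table.
#' @param design The `factor_design` defining the level sets.
#' @return An `encoded_matrix`: list with elements `x` (numeric matrix),
#'   `column_map` (named character vector, encoded column -> source factor)
#'   and `scaling_stats` (`NULL` until [standardize()] is applied).
#' @export
encode_features <- function(table, design = build_design()) {
  if (nrow(table) == 0) stop("table must be non-empty", call. = FALSE)
  fx <- design_factors(design)
  cols <- list()
  column_map <- character(0)
  for (f in fx) {
    kind <- design$kind[match(f, design$factor)]
    if (kind == "numeric") {
      cols[[f]] <- as.numeric(table[[f]])
      column_map[f] <- f
    } else {
      lv <- design_levels(design, f)
      unknown <- setdiff(unique(table[[f]]), lv)
      if (length(unknown) > 0) {
        stop("unknown level(s) in '", f, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      for (l in lv) {
        cn <- paste0(f, "_", l)
        cols[[cn]] <- as.numeric(table[[f]] == l)
        column_map[cn] <- f
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  structure(list(x = x, column_map = column_map, scaling_stats = NULL),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", nrow(x$x), " x ", ncol(x$x),
      if (!is.null(x$scaling_stats)) " (standardized)", "\n", sep = "")
  invisible(x)
}

#' Split an experiment table into train and test partitions
#'
#' Seeded random row-level split. The train partition receives
#' `round(n * train_fraction)` rows; the partitions are disjoint and their
#' union is the input. The split unit is the row, not the replicate triplet,
#' so replicates of one condition can land on both sides — a deliberate,
#' documented leakage risk of the row-level convention.
#'
#' @param table An experiment table (n >= 2 rows).
#' @param train_fraction Fraction of rows assigned to training (0 < f < 1).
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`.
#' @export
split_experiment <- function(table, train_fraction = 0.7, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_train <- round(n * train_fraction)
  n_train <- min(max(n_train, 1), n - 1)
  idx <- withr::with_seed(seed, sample.int(n))
  list(train = table[sort(idx[seq_len(n_train)]), ],
       test = table[sort(idx[(n_train + 1):n]), ])
}

#' Standardize an encoded matrix to zero mean and unit variance
#'
#' Centres each column to mean zero and scales to unit variance using the
#' population (1/n) convention. Constant columns are centred only (scale
#' fixed at 1). When `fit_stats` is supplied (e.g. statistics fitted on the
#' training partition), it is applied unchanged — test data never updates
#' the stored statistics.
#'
#' @param em An `encoded_matrix`.
#' @param fit_stats Optional scaling statistics (list with `center` and
#'   `scale` vectors) from a previous `standardize()` call.
#' @return The `encoded_matrix` with standardized `x` and populated
#'   `scaling_stats`.
#' @export
standardize <- function(em, fit_stats = NULL) {
  x <- em$x
  if (nrow(x) == 0) stop("matrix must be non-empty", call. = FALSE)
  if (is.null(fit_stats)) {
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2, center)^2))
    scale[scale < .Machine$double.eps] <- 1
    fit_stats <- list(center = center, scale = scale)
  }
  em$x <- sweep(sweep(x, 2, fit_stats$center), 2, fit_stats$scale, "/")
  em$scaling_stats <- fit_stats
  em
}
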
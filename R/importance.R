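#' Aggregate encoded-column impurity importances to design factors
#'
#' Takes raw per-encoded-column impurity-reduction totals (from a fitted
#' tree ensemble via [importance_values()], or supplied directly as a named
#' vector) and produces a per-factor profile: indicator columns are pooled
#' into their source factor first (so light colour is one factor, not four
#' columns), then the pooled scores are normalized to sum to one. A
#' degenerate fit with no impurity reduction anywhere (constant target)
#' yields an all-zero profile flagged `no_signal` rather than a fabricated
#' uniform ranking.
#'
#' @param fit A `model_fit` with impurity support, or a named numeric
#'   vector of raw column importances.
#' @param column_map Named character vector mapping encoded column names to
#'   source factor names; must cover every column.
#' @param genus,response Labels attached to the profile.
#' @return An `importance_profile`: list with `genus`, `response`,
#'   `scores` (named numeric per factor, sum 1 or all 0) and `no_signal`.
#' @export
impurity_importance <- function(fit, column_map, genus = NA_character_,
                                response = NA_character_) {
  raw <- if (inherits(fit, "model_fit")) importance_values(fit) else fit
  if (is.null(names(raw))) {
    stop("raw importances must be named by encoded column", call. = FALSE)
  }
  uncovered <- setdiff(names(raw), names(column_map))
  if (length(uncovered) > 0) {
    stop("column_map does not cover: ", paste(uncovered, collapse = ", "),
         call. = FALSE)
  }
  factors <- unique(unname(column_map))
  pooled <- vapply(factors, function(f) {
    sum(raw[names(raw) %in% names(column_map)[column_map == f]])
  }, numeric(1))
  total <- sum(pooled)
  no_signal <- total < .Machine$double.eps
  scores <- if (no_signal) pooled * 0 else pooled / total
  structure(list(genus = genus, response = response,
                 scores = scores, no_signal = no_signal),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("<importance_profile> ", x$genus, " / ", x$response,
      if (x$no_signal) " (no signal)", "\n", sep = "")
  print(round(x$scores, 3))
  invisible(x)
}

#' Environmental-factor importance for one genus and response
#'
#' Convenience wrapper for the full importance stage: filters the table to
#' one genus, encodes the factors (unreduced feature space — importances
#' are reported per original factor, which is incompatible with component
#' space), standardizes, fits a tree-ensemble family and aggregates its
#' impurity importances with [impurity_importance()].
#'
#' @param table An experiment table.
#' @param genus Genus to analyse.
#' @param response Response column.
#' @param spec A `model_spec` with impurity support; defaults to the tuned
#'   random forest.
#' @param seed Integer seed for the ensemble fit.
#' @param design The `factor_design`.
#' @return An `importance_profile`.
#' @export
factor_importance <- function(table, genus, response,
                              spec = make_model("random_forest"), seed,
                              design = build_design()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sub <- table[table$genus == genus, ]
  if (nrow(sub) == 0) stop("unknown genus: ", genus, call. = FALSE)
  if (!response %in% names(sub)) {
    stop("unknown response: ", response, call. = FALSE)
  }
  em <- standardize(encode_features(sub, design))
  fit <- fit_model(spec, em$x, sub[[response]], seed = seed)
  impurity_importance(fit, em$column_map, genus = genus, response = response)
}

#' Top factor per importance profile
#'
#' Identifies, for every profile, the factor with the highest importance
#' score; exact ties go to the earlier factor in design order (the order of
#' the profile's score vector).
#'
#' @param profiles List of `importance_profile` objects.
#' @return Tibble with columns `genus`, `response`, `top_factor`, `score`.
#' @export
rank_factors <- function(profiles) {
  if (length(profiles) == 0) stop("profiles must be non-empty", call. = FALSE)
  purrr::map_dfr(profiles, function(p) {
    i <- which.max(p$scores)
    tibble::tibble(genus = p$genus, response = p$response,
                   top_factor = names(p$scores)[i],
                   score = unname(p$scores[i]))
  })
}

#' Average importance profiles across genera
#'
#' Element-wise arithmetic mean of per-genus profiles for one response,
#' re-normalized to sum to one, labelled genus `"average"`.
#'
#' @param profiles List of `importance_profile` objects sharing one
#'   response.
#' @return An `importance_profile` with genus `"average"`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("profiles must be non-empty", call. = FALSE)
  responses <- unique(vapply(profiles, `[[`, character(1), "response"))
  if (length(responses) != 1) {
    stop("profiles mix responses: ", paste(responses, collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, lapply(profiles, `[[`, "scores"))
  avg <- colMeans(mat)
  total <- sum(avg)
  no_signal <- total < .Machine$double.eps
  structure(list(genus = "average", response = responses,
                 scores = if (no_signal) avg * 0 else avg / total,
                 no_signal = no_signal),
            class = "importance_profile")
}

#' Tidy importance table over all genera and responses
#'
#' Runs [factor_importance()] for every (genus, response) pair plus the
#' cross-genus average profile per response.
#'
#' @inheritParams factor_importance
#' @return List with `profiles` (tidy tibble: genus, response, factor,
#'   score) and `top_factors` (tibble from [rank_factors()], including the
#'   `"average"` genus).
#' @export
importance_report <- function(table, spec = make_model("random_forest"),
                              seed, design = build_design()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  genera <- sort(unique(table$genus))
  all_profiles <- list()
  for (rn in response_names()) {
    per_genus <- lapply(genera, function(g) {
      factor_importance(table, g, rn, spec = spec,
                        seed = seed + match(g, genera), design = design)
    })
    all_profiles <- c(all_profiles, per_genus,
                      list(average_profiles(per_genus)))
  }
  tidy <- purrr::map_dfr(all_profiles, function(p) {
    tibble::tibble(genus = p$genus, response = p$response,
                   factor = names(p$scores), score = unname(p$scores))
  })
  list(profiles = tidy, top_factors = rank_factors(all_profiles))
}

#' Locate the best-performing cultivation condition
#'
#' Groups one genus's observations by the full factor combination and
#' returns the combination with the highest mean response; exact ties go
#' to the smallest combination in design-order lexicographic terms
#' (factors in design order, levels in their design order).
#'
#' @param table An experiment table.
#' @param response Response column.
#' @param genus Genus to analyse.
#' @param design The `factor_design`.
#' @return One-row tibble: `genus`, `response`, one column per factor,
#'   `mean_response`, `n_obs`.
#' @export
find_optimal_conditions <- function(table, response, genus,
                                    design = build_design()) {
  sub <- table[table$genus == genus, ]
  if (nrow(sub) == 0) stop("unknown genus: ", genus, call. = FALSE)
  if (!response %in% names(sub)) {
    stop("unknown response: ", response, call. = FALSE)
  }
  fx <- design_factors(design)
  grouped <- dplyr::summarise(
    dplyr::group_by(sub, dplyr::across(dplyr::all_of(fx))),
    mean_response = mean(.data[[response]]), n_obs = dplyr::n(),
    .groups = "drop"
  )
  ord <- condition_order(grouped[fx], design)
  grouped <- grouped[ord, ]
  best <- grouped[which.max(grouped$mean_response), ]
  dplyr::bind_cols(tibble::tibble(genus = genus, response = response), best)
}
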
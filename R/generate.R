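#' Generate a synthetic OFAT cultivation experiment
#'
#' Simulates the one-factor-at-a-time layout: for every genus, every factor
#' is varied over its levels while the remaining factors sit at their
#' baselines, with `replicates` observations per treatment condition. Each
#' of the nine responses is the noiseless surface value plus Gaussian
#' replicate noise, clipped to the declared response bounds. Generation is
#' fully deterministic given `seed`.
#'
#' @param design A `factor_design`.
#' @param surfaces List of `genus_surface` objects built on `design`.
#' @param replicates Number of replicates per condition (>= 1); the study
#'   layout uses triplicates.
#' @param seed Integer RNG seed (required).
#' @return An experiment table: a tibble with columns `genus`,
#'   `varied_factor`, `replicate`, the five factor columns and the nine
#'   response columns.
#' @examples
#' tab <- generate_experiment(replicates = 3, seed = 1)
#' dim(tab)  # 300 rows: 20 conditions x 3 replicates x 5 genera
#' @export
generate_experiment <- function(design = build_design(),
                                surfaces = default_surfaces(design),
                                replicates = 3, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  for (s in surfaces) {
    if (!identical(design_factors(s$design), design_factors(design))) {
      stop("surface for genus '", s$genus, "' does not match the design",
           call. = FALSE)
    }
    for (f in design_factors(design)) {
      if (!all(design_levels(s$design, f) %in% design_levels(design, f))) {
        stop("surface for genus '", s$genus,
             "' references levels absent from the design", call. = FALSE)
      }
    }
  }
  base <- design_baseline(design)
  fx <- design_factors(design)
  resp <- response_names()

  withr::with_seed(seed, {
    rows <- list()
    for (surface in surfaces) {
      for (f in fx) {
        for (l in design_levels(design, f)) {
          cond <- base
          cond[[f]] <- l
          vals <- lapply(resp, function(rn) {
            rs <- surface$responses[[rn]]
            v <- surface_value(surface, rn, cond) +
              stats::rnorm(replicates, 0, rs$noise_sd)
            pmin(pmax(v, rs$bounds[1]), rs$bounds[2])
          })
          names(vals) <- resp
          rows[[length(rows) + 1]] <- tibble::tibble(
            genus = surface$genus, varied_factor = f,
            replicate = seq_len(replicates), !!!cond, !!!vals
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
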
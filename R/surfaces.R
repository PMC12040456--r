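#' Construct a genus response surface
#'
#' A genus surface describes, for one algal genus, how each of the nine
#' biochemical responses depends on the five cultivation factors. Numeric
#' factors contribute a quadratic peak centred on a planted optimum level;
#' the categorical light-colour factor contributes additive per-level
#' offsets. The surface value at a condition is
#' `base + sum of factor effects`, and replicate observations add Gaussian
#' noise truncated at the response bounds.
#'
#' @param genus Genus name.
#' @param design A `factor_design` the surface refers to.
#' @param responses Named list (one entry per response name) of lists with
#'   elements:
#'   * `base`: response value when every factor effect is zero;
#'   * `effects`: named list per design factor — for a numeric factor a
#'     `list(optimum =, amplitude =)` (quadratic peak, zero at the level
#'     farthest from the optimum); for a categorical factor a named numeric
#'     vector of per-level offsets;
#'   * `noise_sd`: replicate noise standard deviation (response units, >= 0);
#'   * `bounds`: length-2 numeric `c(min, max)` with `min < max`.
#'
#' @return A `genus_surface` object.
#' @seealso [default_surfaces()], [generate_experiment()], [planted_truth()]
#' @export
genus_surface <- function(genus, design, responses) {
  stopifnot(is.character(genus), length(genus) == 1)
  fx <- design_factors(design)
  for (rn in names(responses)) {
    rs <- responses[[rn]]
    if (!is.numeric(rs$noise_sd) || rs$noise_sd < 0) {
      stop("noise_sd of response '", rn, "' must be >= 0", call. = FALSE)
    }
    if (length(rs$bounds) != 2 || rs$bounds[1] >= rs$bounds[2]) {
      stop("bounds of response '", rn, "' must satisfy min < max", call. = FALSE)
    }
    if (!setequal(names(rs$effects), fx)) {
      stop("effects of response '", rn, "' must cover exactly the design factors",
           call. = FALSE)
    }
    for (f in fx) {
      ef <- rs$effects[[f]]
      kind <- design$kind[match(f, design$factor)]
      lv <- design_levels(design, f)
      if (kind == "numeric") {
        if (!ef$optimum %in% lv) {
          stop("planted optimum of '", f, "' for response '", rn,
               "' is not a design level", call. = FALSE)
        }
        if (ef$amplitude < 0) {
          stop("amplitude of '", f, "' for response '", rn,
               "' must be >= 0", call. = FALSE)
        }
      } else {
        if (!setequal(names(ef), as.character(lv))) {
          stop("offsets of '", f, "' for response '", rn,
               "' must name exactly the design levels", call. = FALSE)
        }
      }
    }
  }
  structure(list(genus = genus, design = design, responses = responses),
            class = "genus_surface")
}

#' @export
print.genus_surface <- function(x, ...) {
  cat("<genus_surface> ", x$genus, ": ", length(x$responses),
      " responses over ", nrow(x$design), " factors\n", sep = "")
  invisible(x)
}

# Effect of one factor at one level (scalar).
factor_effect <- function(surface, response, factor, level) {
  ef <- surface$responses[[response]]$effects[[factor]]
  kind <- surface$design$kind[match(factor, surface$design$factor)]
  if (kind == "numeric") {
    lv <- design_levels(surface$design, factor)
    w <- max(abs(lv - ef$optimum))
    if (w == 0) return(ef$amplitude)
    ef$amplitude * max(0, 1 - ((level - ef$optimum) / w)^2)
  } else {
    unname(ef[[as.character(level)]])
  }
}

#' Noiseless surface value at a cultivation condition
#'
#' @param surface A `genus_surface`.
#' @param response Response name.
#' @param condition Named list/vector with one level per design factor.
#' @return The noiseless response value (base plus all factor effects).
#' @export
surface_value <- function(surface, response, condition) {
  rs <- surface$responses[[response]]
  if (is.null(rs)) stop("unknown response: ", response, call. = FALSE)
  val <- rs$base
  for (f in design_factors(surface$design)) {
    val <- val + factor_effect(surface, response, f, condition[[f]])
  }
  val
}

# Peak-to-trough effect amplitude of one factor over the design levels.
effect_amplitude <- function(surface, response, factor) {
  lv <- design_levels(surface$design, factor)
  vals <- vapply(lv, function(l) factor_effect(surface, response, factor, l),
                 numeric(1))
  max(vals) - min(vals)
}

#' Default genus surfaces for the five-genus study design
#'
#' Builds surfaces for *Chlorella*, *Botryococcus*, *Chlamydomonas*,
#' *Tetraselmis* and *Closterium* with the structure the analysis stages
#' assume: each (genus, response) has one dominant factor whose effect
#' amplitude is three times that of the remaining factors (0.30 vs 0.10 of
#' the response range), planted optima at the joint optimum (CO2 9%,
#' 30 deg C, 3000 lux, pH 7, white light — red light for protein and lipid,
#' CO2 7% for fibre), and replicate noise of 1.5% of the response range.
#' Per-genus biomass peak values reflect the spread reported for these
#' genera (roughly 1.5–2.0 g/l).
#'
#' @param design A `factor_design`; defaults to [build_design()].
#' @return Named list of five `genus_surface` objects.
#' @export
default_surfaces <- function(design = build_design()) {
  bounds <- list(
    biomass = c(0.2, 2.1), lipid = c(7.2, 24.5), protein = c(8, 49.5),
    fibre = c(1, 11), ash = c(0.5, 18), moisture = c(2, 12.5),
    nfe = c(10, 70), na = c(7, 14), k = c(0.4, 22)
  )
  genera <- c("Chlorella", "Botryococcus", "Chlamydomonas", "Tetraselmis",
              "Closterium")
  # fraction of the response range at which the planted optimum sits
  opt_frac <- c(Chlorella = 0.84, Botryococcus = 0.80, Chlamydomonas = 0.90,
                Tetraselmis = 0.78, Closterium = 0.76)
  biomass_peak <- c(Chlorella = 1.782, Botryococcus = 1.66,
                    Chlamydomonas = 2.00, Tetraselmis = 1.52,
                    Closterium = 1.485)
  dominant_default <- c(
    biomass = "co2_pct", lipid = "co2_pct", protein = "co2_pct",
    fibre = "pH", ash = "co2_pct", moisture = "pH", nfe = "pH",
    na = "light_colour", k = "co2_pct"
  )
  dominant_by_genus <- list(
    Chlorella = c(protein = "pH"),
    Botryococcus = c(protein = "pH"),
    Chlamydomonas = c(biomass = "light_intensity_lux"),
    Tetraselmis = c(protein = "pH"),
    Closterium = c(protein = "pH")
  )
  red_optimal <- c("protein", "lipid")
  fx <- design_factors(design)
  colour_levels <- design_levels(design, "light_colour")
  numeric_optima <- list(co2_pct = 9, temperature_C = 30,
                         light_intensity_lux = 3000, pH = 7)

  surfaces <- lapply(genera, function(g) {
    responses <- lapply(response_names(), function(rn) {
      b <- bounds[[rn]]
      rng <- diff(b)
      dominant <- dominant_default[[rn]]
      override <- dominant_by_genus[[g]]
      if (!is.null(override) && rn %in% names(override)) {
        dominant <- override[[rn]]
      }
      amp <- function(f) if (f == dominant) 0.30 * rng else 0.10 * rng
      effects <- lapply(fx, function(f) {
        if (f == "light_colour") {
          opt_colour <- if (rn %in% red_optimal) "red" else "white"
          a <- amp(f)
          # offsets in design level order, optimum first then decreasing
          others <- setdiff(colour_levels, opt_colour)
          off <- stats::setNames(c(a, a * c(0.3, 0.15, 0)),
                                 c(opt_colour, others))
          off[colour_levels]
        } else {
          opt <- numeric_optima[[f]]
          if (rn == "fibre" && f == "co2_pct") opt <- 7
          list(optimum = opt, amplitude = amp(f))
        }
      })
      names(effects) <- fx
      peak <- if (rn == "biomass") biomass_peak[[g]] else b[1] + opt_frac[[g]] * rng
      total_amp <- 0.30 * rng + 4 * 0.10 * rng
      list(base = peak - total_amp, effects = effects,
           noise_sd = 0.015 * rng, bounds = b)
    })
    names(responses) <- response_names()
    genus_surface(g, design, responses)
  })
  stats::setNames(surfaces, genera)
}

#' Enumerate the distinct OFAT conditions of a design
#'
#' Each treatment series varies one factor over its levels with all other
#' factors at baseline; conditions identical across series (the all-baseline
#' condition) are collapsed.
#'
#' @param design A `factor_design`.
#' @return Tibble with one factor column per design factor, one row per
#'   distinct condition.
#' @export
ofat_conditions <- function(design) {
  base <- design_baseline(design)
  rows <- list()
  for (f in design_factors(design)) {
    for (l in design_levels(design, f)) {
      cond <- base
      cond[[f]] <- l
      rows[[length(rows) + 1]] <- tibble::as_tibble(cond)
    }
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Ground truth planted in a set of genus surfaces
#'
#' For every (genus, response) pair, reports the dominant factor (largest
#' peak-to-trough effect amplitude; ties broken by design factor order) and
#' the optimum cultivation condition — the argmax of the noiseless surface
#' over the OFAT conditions the design produces, with design-order
#' lexicographic tie-breaking — together with the noiseless response value
#' there.
#'
#' @param surfaces Non-empty list of `genus_surface` objects.
#' @return Tibble with columns `genus`, `response`, `dominant_factor`, one
#'   column per design factor (the optimum level) and `optimum_value`.
#' @export
planted_truth <- function(surfaces) {
  if (length(surfaces) == 0) stop("surfaces must be non-empty", call. = FALSE)
  out <- list()
  for (surface in surfaces) {
    design <- surface$design
    fx <- design_factors(design)
    conds <- ofat_conditions(design)
    for (rn in names(surface$responses)) {
      amps <- vapply(fx, function(f) effect_amplitude(surface, rn, f),
                     numeric(1))
      dominant <- fx[which.max(amps)]  # which.max takes the first on ties
      vals <- vapply(seq_len(nrow(conds)), function(i) {
        surface_value(surface, rn, as.list(conds[i, ]))
      }, numeric(1))
      ord <- condition_order(conds, design)
      best <- ord[which.max(vals[ord])]
      out[[length(out) + 1]] <- tibble::tibble(
        genus = surface$genus, response = rn, dominant_factor = dominant,
        !!!as.list(conds[best, ]), optimum_value = vals[best]
      )
    }
  }
  dplyr::bind_rows(out)
}

# Row order of a condition table under design-order lexicographic sorting
# (factors in design order; levels in their design order).
condition_order <- function(conds, design) {
  keys <- lapply(design_factors(design), function(f) {
    match(conds[[f]], design_levels(design, f))
  })
  do.call(order, keys)
}
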
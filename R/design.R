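#' Build the OFAT factor design
#'
#' Constructs the five-factor cultivation design used throughout the package:
#' CO2 concentration (%), temperature (deg C), light colour, light intensity
#' (lux) and pH, each at four levels. Every treatment series varies one factor
#' across its levels while the remaining factors sit at their baseline values
#' (one-factor-at-a-time layout). Default baselines are CO2 9%, 30 deg C,
#' white light, 3000 lux and pH 7.
#'
#' @param overrides Optional named list keyed by factor name. Each entry is a
#'   list with optional elements `levels` and `baseline` replacing the
#'   defaults for that factor. At least one level must remain, and the
#'   baseline must be a member of the level set.
#'
#' @return A `factor_design` object: a tibble with one row per factor and
#'   columns `factor`, `kind` ("numeric" or "categorical"), `unit`,
#'   `levels` (list-column) and `baseline` (list-column), in design order.
#'
#' @examples
#' design <- build_design()
#' design_levels(design, "co2_pct")
#' build_design(overrides = list(pH = list(levels = 7, baseline = 7)))
#' @export
build_design <- function(overrides = NULL) {
  defaults <- list(
    co2_pct = list(kind = "numeric", unit = "%",
                   levels = c(5, 7, 9, 11), baseline = 9),
    temperature_C = list(kind = "numeric", unit = "degC",
                         levels = c(10, 20, 30, 40), baseline = 30),
    light_colour = list(kind = "categorical", unit = "",
                        levels = c("white", "red", "green", "blue"),
                        baseline = "white"),
    light_intensity_lux = list(kind = "numeric", unit = "lux",
                               levels = c(2000, 2500, 3000, 3500),
                               baseline = 3000),
    pH = list(kind = "numeric", unit = "",
              levels = c(5, 7, 9, 11), baseline = 7)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("`overrides` must be a named list keyed by factor name", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown factor(s) in overrides: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(names(overrides))) {
      stop("duplicate factor names in overrides", call. = FALSE)
    }
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      if (!is.null(ov$levels)) {
        if (length(ov$levels) < 1) {
          stop("factor '", nm, "' must keep at least one level", call. = FALSE)
        }
        if (anyDuplicated(ov$levels)) {
          stop("factor '", nm, "' has duplicated levels", call. = FALSE)
        }
        defaults[[nm]]$levels <- ov$levels
        # keep the baseline valid if it was dropped by the override
        if (!defaults[[nm]]$baseline %in% ov$levels) {
          defaults[[nm]]$baseline <- ov$levels[[1]]
        }
      }
      if (!is.null(ov$baseline)) defaults[[nm]]$baseline <- ov$baseline
    }
  }
  design <- tibble::tibble(
    factor = names(defaults),
    kind = vapply(defaults, `[[`, character(1), "kind"),
    unit = vapply(defaults, `[[`, character(1), "unit"),
    levels = lapply(defaults, `[[`, "levels"),
    baseline = lapply(defaults, `[[`, "baseline")
  )
  validate_design(design)
  structure(design, class = c("factor_design", class(tibble::tibble())))
}

validate_design <- function(design) {
  if (anyDuplicated(design$factor)) {
    stop("duplicate factor names in design", call. = FALSE)
  }
  for (i in seq_len(nrow(design))) {
    lv <- design$levels[[i]]
    if (length(lv) < 1) {
      stop("factor '", design$factor[i], "' has an empty level set", call. = FALSE)
    }
    if (!design$baseline[[i]] %in% lv) {
      stop("baseline of factor '", design$factor[i],
           "' is not a member of its level set", call. = FALSE)
    }
  }
  invisible(design)
}

#' Design accessors
#'
#' @param design A `factor_design` from [build_design()].
#' @param factor A factor name present in the design.
#' @return `design_factors()` returns the factor names in design order;
#'   `design_levels()` the level vector of one factor; `design_baseline()`
#'   a named list with the baseline level of every factor.
#' @export
design_factors <- function(design) design$factor

#' @rdname design_factors
#' @export
design_levels <- function(design, factor) {
  i <- match(factor, design$factor)
  if (is.na(i)) stop("unknown factor: ", factor, call. = FALSE)
  design$levels[[i]]
}

#' @rdname design_factors
#' @export
design_baseline <- function(design) {
  stats::setNames(design$baseline, design$factor)
}

#' Names of the nine biochemical response variables
#'
#' Biomass (g/l), lipid, protein, fibre, ash, moisture and nitrogen-free
#' extract (all % dry weight), and sodium and potassium (mg/100 g).
#'
#' @return Character vector of the nine response column names.
#' @export
response_names <- function() {
  c("biomass", "lipid", "protein", "fibre", "ash", "moisture", "nfe", "na", "k")
}

#' @export
print.factor_design <- function(x, ...) {
  cat("<factor_design> ", nrow(x), " factors\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-20s [%s] levels: %s | baseline: %s\n",
                x$factor[i], x$kind[i],
                paste(x$levels[[i]], collapse = ", "),
                x$baseline[[i]]))
  }
  invisible(x)
}
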
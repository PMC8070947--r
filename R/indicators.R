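# Indicator hierarchy: objectives (exposure / sensitivity / adaptability),
# elements B1..B8, indicators C1..C23. The element -> objective membership is
# structural, not configurable.

ELEMENT_OBJECTIVE <- c(
  B1 = "exposure", B2 = "exposure",
  B3 = "sensitivity", B4 = "sensitivity",
  B5 = "adaptability", B6 = "adaptability",
  B7 = "adaptability", B8 = "adaptability"
)

OBJECTIVE_ELEMENTS <- split(names(ELEMENT_OBJECTIVE), ELEMENT_OBJECTIVE)

#' Declare one assessment indicator
#'
#' An indicator is a measurable layer with a fixed position in the
#' three-level hierarchy (objective > element > indicator), a polarity, a
#' within-element weight, a spatial mode, and a standardization rule.
#'
#' Polarity follows the usual convention for vulnerability indices: for a
#' *negative* indicator larger raw values mean a more vulnerable ecosystem
#' and the standardized score is `C/S`; for a *positive* indicator larger
#' values mean less vulnerable and the score is `S/C`, where `S` is the
#' indicator's standard (reference) value.
#'
#' @param id Short code, e.g. `"C4"` or `"npp"`; must be unique in a config.
#' @param element Element code `B1`..`B8`; fixes the objective (B1-B2
#'   exposure, B3-B4 sensitivity, B5-B8 adaptability).
#' @param name Human-readable name.
#' @param polarity `"negative"` or `"positive"`.
#' @param weight Within-element weight in (0, 1].
#' @param spatial_mode `"heterogeneous"` (a raster layer) or `"uniform"`
#'   (one island-wide value, materialized as a constant raster).
#' @param standard Either the string `"regional_mean"` (the standard value is
#'   the mean of the raw layer over the study domain) or a single positive
#'   number (a fixed standard value). `NA` marks a standard that must be
#'   supplied before use, e.g. an environmental-quality grade threshold.
#' @param objective Optional; if given it must agree with `element`.
#' @return An object of class `indicator_spec`.
#' @export
indicator_spec <- function(id, element, name = id,
                           polarity = c("negative", "positive"),
                           weight = 1,
                           spatial_mode = c("heterogeneous", "uniform"),
                           standard = "regional_mean",
                           objective = NULL) {
  polarity <- match.arg(polarity)
  spatial_mode <- match.arg(spatial_mode)
  if (!element %in% names(ELEMENT_OBJECTIVE)) {
    stop_config("unknown element '", element, "' (expected B1..B8)")
  }
  obj <- ELEMENT_OBJECTIVE[[element]]
  if (!is.null(objective) && objective != obj) {
    stop_config("indicator ", id, ": objective '", objective,
                "' is inconsistent with element ", element, " (", obj, ")")
  }
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0 || weight > 1) {
    stop_config("indicator ", id, ": weight must lie in (0, 1]")
  }
  fixed <- NA_real_
  rule <- "regional_mean"
  if (is.numeric(standard)) {
    rule <- "fixed"
    fixed <- as.numeric(standard)
  } else if (identical(standard, "regional_mean")) {
    rule <- "regional_mean"
  } else if (is.na(standard)) {
    rule <- "fixed"
  } else {
    stop_config("indicator ", id, ": standard must be 'regional_mean' or a number")
  }
  structure(
    list(id = id, name = name, element_id = element, objective = obj,
         polarity = polarity, weight = weight, spatial_mode = spatial_mode,
         standard_rule = rule, standard_value = fixed),
    class = "indicator_spec"
  )
}

#' @export
print.indicator_spec <- function(x, ...) {
  std <- if (x$standard_rule == "regional_mean") "regional mean"
         else if (is.na(x$standard_value)) "fixed (unset)"
         else paste0("fixed ", x$standard_value)
  cat(sprintf("<indicator_spec> %s (%s): %s, %s, w=%.2f, %s, standard = %s\n",
              x$id, x$name, x$element_id, x$objective, x$weight,
              x$spatial_mode, std))
  invisible(x)
}

#' Assemble an assessment configuration
#'
#' Bundles the indicator set with the classification breaks of the final
#' index. Validates that indicator ids are unique, each element's weights
#' sum to 1 within a printing tolerance of 0.02 (published weight tables are
#' rounded to two decimals, so element sums of 0.99-1.01 are legal and are
#' renormalized at aggregation time), and the class breaks are strictly
#' increasing.
#'
#' @param indicators List of [indicator_spec()] objects.
#' @param class_breaks Increasing numeric breaks for the five vulnerability
#'   classes; defaults to `c(0.6, 0.7, 0.9, 1.0)`.
#' @return An object of class `index_config`.
#' @export
index_config <- function(indicators, class_breaks = c(0.6, 0.7, 0.9, 1.0)) {
  if (!length(indicators) || !all(vapply(indicators, inherits, TRUE, "indicator_spec"))) {
    stop_config("indicators must be a non-empty list of indicator_spec objects")
  }
  ids <- vapply(indicators, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_config("duplicate indicator ids: ",
                                      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(indicators) <- ids
  el <- vapply(indicators, `[[`, "", "element_id")
  for (e in unique(el)) {
    s <- sum(vapply(indicators[el == e], `[[`, 1, "weight"))
    if (abs(s - 1) > 0.02) {
      stop_config("element ", e, ": weights sum to ", signif(s, 4),
                  ", outside the 1 +/- 0.02 tolerance")
    }
  }
  if (any(diff(class_breaks) <= 0)) stop_config("class_breaks must be strictly increasing")
  structure(list(indicators = indicators, class_breaks = as.numeric(class_breaks)),
            class = "index_config")
}

#' @export
print.index_config <- function(x, ...) {
  el <- vapply(x$indicators, `[[`, "", "element_id")
  ob <- vapply(x$indicators, `[[`, "", "objective")
  cat(sprintf("<index_config> %d indicators in %d elements (%s)\n",
              length(x$indicators), length(unique(el)),
              paste(sprintf("%s: %d", names(table(ob)), table(ob)), collapse = ", ")))
  cat("class breaks:", paste(x$class_breaks, collapse = ", "), "\n")
  invisible(x)
}

#' The published 23-indicator configuration
#'
#' The full high-intensity-development island indicator system: 23
#' indicators in 8 elements under the three E-S-A objectives, with the
#' expert-survey (Delphi) weights shipped as constants. Element weight sums
#' reflect the published two-decimal rounding (e.g. B1 sums to 1.01) and are
#' renormalized during aggregation. Environmental-quality standards (C13-C16)
#' and the stepwise area-class standard (C4) have no universal numeric value
#' and are shipped unset; supply them per study area before use.
#'
#' @return An [index_config()].
#' @export
default_index_config <- function() {
  s <- function(...) indicator_spec(...)
  index_config(list(
    s("C1",  "B1", "Impact of typical natural disasters",      "negative", 0.34, "uniform"),
    s("C2",  "B1", "Island area change rate",                  "negative", 0.24, "uniform"),
    s("C3",  "B1", "Change rate of island shoreline",          "negative", 0.23, "uniform"),
    s("C4",  "B1", "Proportion of steep slope area",           "negative", 0.20, "heterogeneous", NA),
    s("C5",  "B2", "Population density of residents",          "negative", 0.14, "uniform"),
    s("C6",  "B2", "Tourism population pressure",              "negative", 0.15, "uniform"),
    s("C7",  "B2", "Impact of man-made environmental disturbance", "negative", 0.17, "uniform"),
    s("C8",  "B2", "Island land development impact",           "negative", 0.20, "heterogeneous"),
    s("C9",  "B2", "Shoreline development impact",             "negative", 0.18, "heterogeneous"),
    s("C10", "B2", "Impact of surrounding sea area development", "negative", 0.15, "heterogeneous"),
    s("C11", "B3", "Net primary productivity of vegetation",   "negative", 0.56, "heterogeneous"),
    s("C12", "B3", "Primary productivity of surrounding sea",  "negative", 0.44, "heterogeneous"),
    s("C13", "B4", "Groundwater environmental quality",        "negative", 0.25, "heterogeneous", NA),
    s("C14", "B4", "Soil environmental quality",               "negative", 0.29, "heterogeneous", NA),
    s("C15", "B4", "Sea water environmental quality",          "negative", 0.28, "heterogeneous", NA),
    s("C16", "B4", "Marine sediments environmental quality",   "negative", 0.19, "heterogeneous", NA),
    s("C17", "B5", "Island area",                              "positive", 0.54, "uniform"),
    s("C18", "B5", "Island shape complexity",                  "negative", 0.46, "uniform"),
    s("C19", "B6", "Income level of residents",                "positive", 0.28, "uniform"),
    s("C20", "B6", "Science and technology support capacity",  "positive", 0.37, "uniform"),
    s("C21", "B6", "Education level of residents",             "positive", 0.35, "uniform"),
    s("C22", "B7", "Treatment capacity of main pollutants",    "positive", 1.00, "uniform", 0.9),
    s("C23", "B8", "Management effectiveness",                 "positive", 1.00, "uniform")
  ))
}

#' Read an assessment configuration from a YAML file
#'
#' The file holds one block per indicator under `indicators:`, with keys
#' `id, element, name, polarity, weight, spatial_mode, standard`, an
#' optional `class_breaks` list, and optional `leveling:` blocks mapping
#' variable ids to discretization breaks.
#'
#' @param path YAML file path.
#' @return A list with components `config` (an [index_config()]) and
#'   `leveling` (a named list of [leveling_rule()] or `NULL`).
#' @export
read_index_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$indicators)) stop_config("config has no 'indicators' section")
  specs <- lapply(y$indicators, function(b) {
    if (is.null(b$id) || is.null(b$element)) {
      stop_config("each indicator block needs at least 'id' and 'element'")
    }
    std <- b$standard %||% "regional_mean"
    if (identical(std, "NA") || (length(std) == 1 && is.na(std))) std <- NA
    indicator_spec(
      id = b$id, element = b$element, name = b$name %||% b$id,
      polarity = b$polarity %||% "negative",
      weight = b$weight %||% 1,
      spatial_mode = b$spatial_mode %||% "heterogeneous",
      standard = std
    )
  })
  cfg <- index_config(specs,
                      class_breaks = as.numeric(y$class_breaks %||% c(0.6, 0.7, 0.9, 1.0)))
  lev <- NULL
  if (!is.null(y$leveling)) {
    lev <- lapply(names(y$leveling), function(v) {
      leveling_rule(v, as.numeric(y$leveling[[v]]))
    })
    names(lev) <- names(y$leveling)
  }
  list(config = cfg, leveling = lev)
}
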
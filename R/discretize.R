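# Discretization of continuous assessment layers into ordinal states for
# the conditional-probability stage.

#' Declare a discretization (leveling) rule
#'
#' `m - 1` strictly increasing thresholds define `m` contiguous intervals.
#' Intervals are left-closed / right-open: state 1 is `(-Inf, b1)`, state k
#' is `[b_{k-1}, b_k)`, and the top state is `[b_{m-1}, Inf)`, so a value
#' exactly on a break belongs to the upper interval.
#'
#' @param variable_id Variable code the rule applies to.
#' @param breaks Strictly increasing numeric thresholds.
#' @return An object of class `leveling_rule`.
#' @export
leveling_rule <- function(variable_id, breaks) {
  if (!length(breaks) || any(!is.finite(breaks)) || any(diff(breaks) <= 0)) {
    stop_config("breaks must be a strictly increasing finite vector")
  }
  structure(list(variable_id = variable_id, breaks = as.numeric(breaks),
                 n_states = length(breaks) + 1L),
            class = "leveling_rule")
}

#' @export
print.leveling_rule <- function(x, ...) {
  cat(sprintf("<leveling_rule> %s: %d states, breaks {%s}\n",
              x$variable_id, x$n_states, paste(x$breaks, collapse = ", ")))
  invisible(x)
}

#' Default three-level rules for standardized assessment layers
#'
#' Every variable (each standardized indicator and the final index) is split
#' into 3 levels at 0.6 and 0.7, except soil environmental quality, whose
#' standardized values concentrate in a much narrower band and which is
#' split at 0.24 and 0.25.
#'
#' @param variables Character vector of variable ids to cover.
#' @param soil_id Id of the soil variable (default `"soil"`; also applied to
#'   the published code `"C14"`).
#' @return Named list of [leveling_rule()] objects.
#' @export
default_leveling_rules <- function(variables, soil_id = "soil") {
  rules <- lapply(variables, function(v) {
    if (v %in% c(soil_id, "C14")) leveling_rule(v, c(0.24, 0.25))
    else leveling_rule(v, c(0.6, 0.7))
  })
  names(rules) <- variables
  rules
}

#' Discretize a continuous raster into ordinal states
#'
#' Applies a [leveling_rule()] cell-wise. The mapping covers the whole real
#' line (every finite value gets exactly one state) and is monotone
#' nondecreasing; invalid cells stay invalid.
#'
#' @param values An [iev_raster()].
#' @param rule A [leveling_rule()].
#' @return A [categorical_raster()] carrying the rule's `variable_id`.
#' @examples
#' g <- iev_grid(1, 3, 30)
#' r <- iev_raster(c(0.55, 0.65, 0.75), g)
#' discretize(r, leveling_rule("x", c(0.6, 0.7)))$levels
#' @export
discretize <- function(values, rule) {
  stopifnot(inherits(values, "iev_raster"), inherits(rule, "leveling_rule"))
  lv <- matrix(NA_integer_, values$grid$n_rows, values$grid$n_cols)
  v <- values$values[values$valid]
  st <- rep(1L, length(v))
  for (b in rule$breaks) st <- st + (v >= b)
  lv[values$valid] <- st
  categorical_raster(lv, rule$n_states, values$grid, values$valid,
                     id = rule$variable_id)
}
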
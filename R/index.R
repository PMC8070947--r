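# E-S-A index computation: per-indicator standardization, weighted element
# aggregation, equal-weight objective aggregation, geometric-mean IEVI,
# five-level classification.

#' Standardize a raw indicator layer
#'
#' Computes the single-factor score `RC` of an indicator: `C/S` for a
#' negative indicator (larger raw value = more vulnerable) and `S/C` for a
#' positive one, where `S` is the standard value — either fixed in the spec
#' or the regional mean of the raw layer over the analysis domain. A
#' uniform-mode indicator may be supplied as a single number and yields a
#' constant raster over the domain.
#'
#' @param raw An [iev_raster()], or a single number for a uniform indicator.
#' @param spec The indicator's [indicator_spec()].
#' @param domain Optional [region_mask()] restricting the analysis (and the
#'   regional-mean standard). Required when `raw` is a bare number.
#' @return An `iev_raster` of standardized scores, valid on
#'   `domain` intersected with the raw layer's valid cells.
#' @export
standardize <- function(raw, spec, domain = NULL) {
  stopifnot(inherits(spec, "indicator_spec"))
  if (is_scalar_number(raw)) {
    if (is.null(domain)) stop_config("a scalar uniform indicator needs a domain mask for its grid")
    raw <- constant_raster(raw, domain$grid, domain)
  }
  stopifnot(inherits(raw, "iev_raster"))
  member <- domain_member(domain, raw$grid)
  valid <- raw$valid & member
  if (!any(valid)) stop_data("indicator ", spec$id, ": no valid cells inside the domain")
  s <- if (spec$standard_rule == "regional_mean") {
    mean(raw$values[valid])
  } else {
    spec$standard_value
  }
  if (is.na(s)) {
    stop_config("indicator ", spec$id, ": fixed standard value is unset")
  }
  if (s <= 0) stop_data("indicator ", spec$id, ": standard value must be positive (got ", s, ")")
  v <- raw$values
  if (spec$polarity == "negative") {
    if (any(valid & v < 0)) stop_data("indicator ", spec$id, ": negative raw values")
    rc <- v / s
  } else {
    if (any(valid & v <= 0)) {
      stop_data("indicator ", spec$id, ": positive indicator requires raw values > 0")
    }
    rc <- s / v
  }
  iev_raster(rc, raw$grid, valid)
}

#' Aggregate standardized indicators into an element score
#'
#' Per-cell weighted sum `RB = sum(RC_i * W_i)` over the element's
#' indicators. Published weights are rounded, so the weight vector is
#' renormalized to sum exactly 1 (with a warning when the printed sum
#' deviates from 1 by more than 1e-9); sums outside 1 +/- 0.02 are rejected.
#'
#' @param standardized List of standardized `iev_raster` layers.
#' @param weights Numeric weights, one per layer.
#' @return An `iev_raster`; a cell is valid only where every input is valid.
#'   The (pre-normalization) weight sum is attached as attribute
#'   `"weight_sum"`.
#' @export
aggregate_element <- function(standardized, weights) {
  if (!length(standardized)) stop_config("empty indicator collection")
  if (length(weights) != length(standardized)) {
    stop_config("need exactly one weight per standardized layer")
  }
  g <- do.call(check_aligned, standardized)
  ws <- sum(weights)
  if (abs(ws - 1) > 0.02) {
    stop_config("element weights sum to ", signif(ws, 4),
                ", outside the 1 +/- 0.02 tolerance")
  }
  if (abs(ws - 1) > 1e-9) {
    warning("element weights sum to ", signif(ws, 6), "; renormalizing to 1",
            call. = FALSE)
  }
  w <- weights / ws
  acc <- matrix(0, g$n_rows, g$n_cols)
  valid <- matrix(TRUE, g$n_rows, g$n_cols)
  for (k in seq_along(standardized)) {
    r <- standardized[[k]]
    valid <- valid & r$valid
    vv <- r$values
    vv[!r$valid] <- 0
    acc <- acc + w[k] * vv
  }
  out <- iev_raster(acc, g, valid)
  attr(out, "weight_sum") <- ws
  out
}

#' Aggregate element scores into an objective score
#'
#' The three objectives use fixed equal weights so that assessments remain
#' comparable across study areas: exposure is the mean of its two elements
#' (B1, B2), sensitivity of its two (B3, B4), adaptability of its four
#' (B5-B8). The element count is enforced, not configurable.
#'
#' @param elements List of element `iev_raster` layers, in element order.
#' @param objective `"exposure"`, `"sensitivity"` or `"adaptability"`.
#' @return An `iev_raster` of the objective score.
#' @export
aggregate_objective <- function(elements,
                                objective = c("exposure", "sensitivity", "adaptability")) {
  objective <- match.arg(objective)
  need <- length(OBJECTIVE_ELEMENTS[[objective]])
  if (length(elements) != need) {
    stop_config(objective, " requires exactly ", need, " element layers, got ",
                length(elements))
  }
  g <- do.call(check_aligned, elements)
  acc <- matrix(0, g$n_rows, g$n_cols)
  valid <- matrix(TRUE, g$n_rows, g$n_cols)
  for (r in elements) {
    valid <- valid & r$valid
    vv <- r$values
    vv[!r$valid] <- 0
    acc <- acc + vv
  }
  iev_raster(acc / need, g, valid)
}

#' Island Ecological Vulnerability Index
#'
#' The per-cell geometric mean of the three objective scores,
#' `IEVI = (RE * RS * RA)^(1/3)`. All inputs must be nonnegative at valid
#' cells; the result is bounded between the cell-wise minimum and maximum of
#' the three objectives.
#'
#' @param re,rs,ra Exposure, sensitivity and adaptability `iev_raster`s on a
#'   shared grid.
#' @return An `iev_raster` of index values.
#' @export
compute_ievi <- function(re, rs, ra) {
  g <- check_aligned(re, rs, ra)
  valid <- re$valid & rs$valid & ra$valid
  for (r in list(re, rs, ra)) {
    if (any(valid & r$values < 0)) stop_data("objective scores must be nonnegative")
  }
  prod <- re$values * rs$values * ra$values
  iev_raster(prod^(1 / 3), g, valid)
}

IEVI_LABELS <- c("non-vulnerable", "near vulnerable", "slightly vulnerable",
                 "moderate vulnerable", "severe vulnerable")

#' Classify index values into the five vulnerability levels
#'
#' Maps the continuous index onto the five-level scale using left-open /
#' right-closed intervals: level 1 is `IEVI <= b1`, level k is
#' `(b_{k-1}, b_k]`, and the top level is `IEVI > b4`. The default breaks
#' `0.6, 0.7, 0.9, 1.0` give non-vulnerable, near vulnerable, slightly
#' vulnerable, moderate vulnerable and severe vulnerable.
#'
#' @param ievi An `iev_raster` of index values.
#' @param breaks Strictly increasing numeric breaks (default the five-level
#'   standard).
#' @return An [categorical_raster()] with `length(breaks) + 1` states and
#'   level labels attached (for the default five-level scale).
#' @export
classify_ievi <- function(ievi, breaks = c(0.6, 0.7, 0.9, 1.0)) {
  stopifnot(inherits(ievi, "iev_raster"))
  if (any(diff(breaks) <= 0)) stop_config("breaks must be strictly increasing")
  lv <- matrix(NA_integer_, ievi$grid$n_rows, ievi$grid$n_cols)
  v <- ievi$values[ievi$valid]
  st <- rep(1L, length(v))
  for (b in breaks) st <- st + (v > b)
  lv[ievi$valid] <- st
  labels <- if (length(breaks) == 4) IEVI_LABELS else NULL
  categorical_raster(lv, length(breaks) + 1L, ievi$grid, ievi$valid,
                     id = "result", labels = labels)
}

#' Area fraction of each vulnerability class
#'
#' @param classes A [categorical_raster()] of class levels.
#' @param domain Optional [region_mask()]; fractions are over the valid
#'   cells inside it and always sum to 1.
#' @return A data frame with columns `state`, `label`, `cells`, `fraction`.
#' @export
class_area_fractions <- function(classes, domain = NULL) {
  stopifnot(inherits(classes, "iev_categorical"))
  member <- domain_member(domain, classes$grid)
  sel <- classes$valid & member
  if (!any(sel)) stop_data("no valid cells inside the domain")
  counts <- tabulate(classes$levels[sel], classes$n_states)
  data.frame(
    state = seq_len(classes$n_states),
    label = classes$labels %||% paste0("state ", seq_len(classes$n_states)),
    cells = counts,
    fraction = counts / sum(counts)
  )
}

#' Run the full E-S-A vulnerability assessment
#'
#' Drives the whole index computation for one study area: standardizes every
#' configured indicator, aggregates indicators into elements by their
#' weights, elements into the three objectives with equal weights, combines
#' the objectives into the geometric-mean index, and classifies it.
#'
#' @param layers Named list mapping indicator id to either an
#'   [iev_raster()] (heterogeneous indicators) or a single number (uniform
#'   indicators).
#' @param config An [index_config()]; defaults to the published 23-indicator
#'   system.
#' @param domain A [region_mask()] for the assessment scope (island land
#'   plus buffered surrounding waters).
#' @return An object of class `iev_assessment` with components `rc`
#'   (standardized layers), `rb` (element layers), `objectives` (named list
#'   `exposure`/`sensitivity`/`adaptability`), `ievi`, `classes`,
#'   `fractions`, `config`, `domain`, and `notes` (renormalization log).
#' @examples
#' sc <- scenario_presets(seed = 1)$two_islands
#' sim <- simulate_island(sc)
#' fit <- ievi_assess(sim$layers, synthetic_index_config(), sim$study_area)
#' fit
#' @export
ievi_assess <- function(layers, config = default_index_config(), domain) {
  stopifnot(inherits(config, "index_config"), inherits(domain, "iev_mask"))
  ids <- names(config$indicators)
  missing <- setdiff(ids, names(layers))
  if (length(missing)) {
    stop_config("no layer supplied for indicator(s): ", paste(missing, collapse = ", "))
  }
  notes <- character()
  rc <- lapply(ids, function(id) {
    standardize(layers[[id]], config$indicators[[id]], domain)
  })
  names(rc) <- ids
  el_of <- vapply(config$indicators, `[[`, "", "element_id")
  rb <- list()
  for (e in unique(el_of)) {
    sub <- ids[el_of == e]
    w <- vapply(config$indicators[sub], `[[`, 1, "weight")
    rb[[e]] <- withCallingHandlers(
      aggregate_element(rc[sub], w),
      warning = function(wrn) {
        notes <<- c(notes, conditionMessage(wrn))
        invokeRestart("muffleWarning")
      }
    )
  }
  objectives <- list()
  for (obj in c("exposure", "sensitivity", "adaptability")) {
    els <- intersect(OBJECTIVE_ELEMENTS[[obj]], names(rb))
    objectives[[obj]] <- aggregate_objective(rb[els], obj)
  }
  ievi <- compute_ievi(objectives$exposure, objectives$sensitivity,
                       objectives$adaptability)
  classes <- classify_ievi(ievi, config$class_breaks)
  structure(
    list(rc = rc, rb = rb, objectives = objectives, ievi = ievi,
         classes = classes,
         fractions = class_area_fractions(classes, domain),
         config = config, domain = domain, notes = notes),
    class = "iev_assessment"
  )
}

#' @export
print.iev_assessment <- function(x, ...) {
  v <- x$ievi$values[x$ievi$valid]
  cat("Island ecological vulnerability assessment\n")
  cat(sprintf("  grid: %d x %d cells (%g m); %d assessed cells\n",
              x$ievi$grid$n_rows, x$ievi$grid$n_cols, x$ievi$grid$cell_size,
              length(v)))
  cat(sprintf("  IEVI range: %.2f - %.2f\n", min(v), max(v)))
  f <- x$fractions[x$fractions$cells > 0, ]
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-20s %5.1f%%\n", f$label[i], 100 * f$fraction[i]))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.iev_assessment <- function(object, ...) {
  rng <- function(r) {
    v <- r$values[r$valid]
    c(min = min(v), max = max(v))
  }
  out <- list(
    ievi = rng(object$ievi),
    objectives = lapply(object$objectives, rng),
    elements = lapply(object$rb, rng),
    fractions = object$fractions,
    notes = object$notes
  )
  class(out) <- "summary.iev_assessment"
  out
}

#' @export
print.summary.iev_assessment <- function(x, ...) {
  cat("IEVI range:", sprintf("%.3f - %.3f", x$ievi[1], x$ievi[2]), "\n")
  cat("Objectives:\n")
  for (n in names(x$objectives)) {
    cat(sprintf("  %-13s %.3f - %.3f\n", n, x$objectives[[n]][1], x$objectives[[n]][2]))
  }
  cat("Elements:\n")
  for (n in names(x$elements)) {
    cat(sprintf("  %-4s %.3f - %.3f\n", n, x$elements[[n]][1], x$elements[[n]][2]))
  }
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' @export
plot.iev_assessment <- function(x, what = c("ievi", "classes", "exposure",
                                            "sensitivity", "adaptability"), ...) {
  what <- match.arg(what)
  r <- switch(what,
              ievi = x$ievi,
              classes = NULL,
              x$objectives[[what]])
  if (what == "classes") {
    m <- x$classes$levels
    image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
          col = grDevices::hcl.colors(x$classes$n_states, "RdYlGn", rev = TRUE),
          main = "vulnerability level", ...)
  } else {
    m <- r$values
    image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
          col = grDevices::hcl.colors(64, "viridis"), main = what, ...)
  }
  invisible(x)
}
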
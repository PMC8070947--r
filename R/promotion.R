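# Spatial-pattern promotion regions: cells whose key-indicator states
# support a better vulnerability level than the one currently attained.

#' Declare promotion rules over the key indicators
#'
#' The first-level rule marks cells whose key-indicator states give the
#' highest probability of the best (level-1) result but whose current result
#' is *not* level 1; if no cell satisfies the strict subset, an optional
#' relaxed fallback subset is applied instead and the provenance recorded.
#' The second-level rule marks cells whose key-indicator states favor a
#' level-2 result while the current result is level 3; second-level cells
#' never overlap first-level cells.
#'
#' @param first_level [state_subset()] over the key indicators for the
#'   first tier.
#' @param second_level [state_subset()] for the second tier.
#' @param fallback_first_level Optional relaxed [state_subset()] used when
#'   the strict first-level region is empty.
#' @param first_excludes_result Result level a first-tier cell must *not*
#'   have (default 1).
#' @param second_requires_result Result level a second-tier cell must have
#'   (default 3).
#' @return An object of class `iev_promotion_rules`.
#' @export
promotion_rules <- function(first_level, second_level,
                            fallback_first_level = NULL,
                            first_excludes_result = 1L,
                            second_requires_result = 3L) {
  stopifnot(inherits(first_level, "iev_state_subset"),
            inherits(second_level, "iev_state_subset"))
  if (!is.null(fallback_first_level)) {
    stopifnot(inherits(fallback_first_level, "iev_state_subset"))
  }
  structure(list(first_level = first_level, second_level = second_level,
                 fallback_first_level = fallback_first_level,
                 first_excludes_result = as.integer(first_excludes_result),
                 second_requires_result = as.integer(second_requires_result)),
            class = "iev_promotion_rules")
}

#' Default promotion rules for a pair of key indicators
#'
#' The standard construction for two key indicators: strict first level
#' requires both at state 1, fallback relaxes both to states 1 or 2, second
#' level pairs the first key indicator at state 3 with the second at
#' state 1.
#'
#' @param key_ids Character vector of exactly two key-indicator ids, in the
#'   order (productivity-type, slope-type) used by the second-level rule.
#' @return An [promotion_rules()] object.
#' @export
default_promotion_rules <- function(key_ids) {
  if (length(key_ids) != 2) stop_config("default rules expect exactly two key indicators")
  a <- key_ids[1]; b <- key_ids[2]
  promotion_rules(
    first_level = state_subset(stats::setNames(list(1L, 1L), c(a, b)),
                               label = "first level (strict)"),
    second_level = state_subset(stats::setNames(list(3L, 1L), c(a, b)),
                                label = "second level"),
    fallback_first_level = state_subset(stats::setNames(list(c(1L, 2L), c(1L, 2L)), c(a, b)),
                                        label = "first level (relaxed)")
  )
}

#' Derive promotion rules from a probability graph
#'
#' Reproduces the rule-construction procedure on any fitted graph: the
#' strict first-level subset assigns each key indicator the state
#' maximizing `P(result = 1 | X = s)`; the second-level subset the state
#' maximizing `P(result = 2 | X = s)`; the fallback relaxes each
#' first-level assignment to the two best states for a level-1 result.
#' States with zero support are never selected.
#'
#' @param g An [probability_graph()] whose result variable has at least 3
#'   states.
#' @param key_ids Ids of the key indicators (non-result variables of `g`).
#' @return An [promotion_rules()] object.
#' @export
promotion_rules_from_graph <- function(g, key_ids) {
  stopifnot(inherits(g, "iev_probability_graph"))
  missing <- setdiff(key_ids, setdiff(g$variables, g$result_var))
  if (length(missing)) {
    stop_config("key indicator(s) absent from the graph: ",
                paste(missing, collapse = ", "))
  }
  best_states <- function(target, k) {
    out <- list()
    for (v in key_ids) {
      p <- g$cpts[[paste0(g$result_var, "|", v)]]$probs[target, ]
      ord <- order(-ifelse(is.na(p), -Inf, p), seq_along(p))
      out[[v]] <- sort(ord[seq_len(min(k, sum(!is.na(p))))])
    }
    out
  }
  promotion_rules(
    first_level = state_subset(best_states(1, 1), "first level (strict)"),
    second_level = state_subset(best_states(2, 1), "second level"),
    fallback_first_level = state_subset(best_states(1, 2),
                                        "first level (relaxed)")
  )
}

#' Identify promotion regions and account their areas
#'
#' Applies the promotion rules to the discretized key-indicator stack and
#' the result layer. The first-level mask holds cells matching the
#' first-level subset whose result differs from the excluded level; if it is
#' empty and a fallback subset exists, the fallback is used and
#' `provenance = "fallback"` recorded. The second-level mask holds cells
#' matching the second-level subset at the required result level, minus any
#' first-level cells, so the two tiers are disjoint.
#'
#' @param stack Named list of [categorical_raster()] key-indicator layers
#'   (may contain more variables than the rules reference).
#' @param result Result [categorical_raster()].
#' @param rules An [promotion_rules()] object.
#' @param domain Optional [region_mask()].
#' @param zones Optional [categorical_raster()] zone layer (e.g. one state
#'   per island) for a per-zone area breakdown.
#' @return An object of class `iev_promotion` with fields `first_mask`,
#'   `second_mask`, `areas` (data frame: tier, zone, hectares, rule), and
#'   `provenance` (`"strict"` or `"fallback"`).
#' @export
promotion_regions <- function(stack, result, rules, domain = NULL, zones = NULL) {
  stopifnot(inherits(rules, "iev_promotion_rules"),
            inherits(result, "iev_categorical"))
  check_aligned(result, stack[[1]])
  member <- domain_member(domain, result$grid)
  res_ok <- result$valid & member

  first <- match_subset(stack, rules$first_level, domain)
  first$member <- first$member & res_ok &
    (result$levels != rules$first_excludes_result) & !is.na(result$levels)
  provenance <- "strict"
  if (!any(first$member) && !is.null(rules$fallback_first_level)) {
    first <- match_subset(stack, rules$fallback_first_level, domain)
    first$member <- first$member & res_ok &
      (result$levels != rules$first_excludes_result) & !is.na(result$levels)
    provenance <- "fallback"
  }

  second <- match_subset(stack, rules$second_level, domain)
  second$member <- second$member & res_ok &
    (result$levels == rules$second_requires_result) & !is.na(result$levels) &
    !first$member

  area_rows <- function(mask, tier, rule) {
    if (is.null(zones)) {
      data.frame(tier = tier, zone = "total",
                 hectares = region_area(mask), rule = rule)
    } else {
      per <- region_area(mask, zones)
      data.frame(tier = tier, zone = per$zone, hectares = per$hectares,
                 rule = rule)
    }
  }
  areas <- rbind(
    area_rows(first, "first", provenance),
    area_rows(second, "second", "strict")
  )
  structure(list(first_mask = first, second_mask = second, areas = areas,
                 provenance = provenance),
            class = "iev_promotion")
}

#' @export
print.iev_promotion <- function(x, ...) {
  cat(sprintf("Promotion regions (first-level rule: %s)\n", x$provenance))
  cat(sprintf("  first level:  %d cells, %.1f ha\n",
              sum(x$first_mask$member), region_area(x$first_mask)))
  cat(sprintf("  second level: %d cells, %.1f ha\n",
              sum(x$second_mask$member), region_area(x$second_mask)))
  if (length(unique(x$areas$zone)) > 1) print(x$areas, row.names = FALSE)
  invisible(x)
}

#' Area of a region mask in hectares
#'
#' Exact accounting: member-cell count times `cell_size^2 / 1e4`. With a
#' zone layer the area is split by zone state and the per-zone areas sum to
#' the total.
#'
#' @param mask A [region_mask()] with metric cell size.
#' @param zones Optional aligned [categorical_raster()] of zone states.
#' @return Hectares (a number), or with `zones` a data frame with columns
#'   `zone` and `hectares`.
#' @export
region_area <- function(mask, zones = NULL) {
  stopifnot(inherits(mask, "iev_mask"))
  ha_per_cell <- mask$grid$cell_size^2 / 1e4
  if (is.null(zones)) return(sum(mask$member) * ha_per_cell)
  stopifnot(inherits(zones, "iev_categorical"))
  check_aligned(mask, zones)
  sel <- mask$member & zones$valid
  counts <- tabulate(zones$levels[sel], zones$n_states)
  out <- data.frame(zone = zones$labels %||% paste0("zone ", seq_len(zones$n_states)),
                    hectares = counts * ha_per_cell)
  leftover <- sum(mask$member) - sum(counts)
  if (leftover > 0) {
    out <- rbind(out, data.frame(zone = "(unzoned)",
                                 hectares = leftover * ha_per_cell))
  }
  out
}
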
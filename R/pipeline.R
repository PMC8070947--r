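# File-based orchestration of the four-stage workflow: simulate -> assess ->
# conditional-probability analysis -> entropy ranking -> promotion mapping.
# Each stage reads and writes files under a run directory, so stages are
# independently re-runnable and deterministic given their inputs. A run
# manifest logs every interpretation decision actually exercised (weight
# renormalizations, argmax ties, fallback subsets).

#' @noRd
manifest_append <- function(dir, lines) {
  if (length(lines)) {
    cat(paste0(lines, "\n"), file = file.path(dir, "manifest.txt"), append = TRUE)
  }
}

#' Generate and write a synthetic island layer set
#'
#' Writes `land.asc`, `study_area.asc`, one `raw_<id>.asc` per indicator and
#' `latent.asc` (the generator's ground truth, for inspection only) to
#' `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset Name of a [scenario_presets()] entry, or an
#'   [island_scenario()] object.
#' @param seed Seed used when `preset` is a name.
#' @return Invisibly, the layer file paths.
#' @export
run_simulate <- function(out_dir, preset = "two_islands", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario <- if (inherits(preset, "island_scenario")) preset
              else scenario_presets(seed = seed)[[preset]]
  if (is.null(scenario)) stop_config("unknown preset '", preset, "'")
  sim <- simulate_island(scenario)
  paths <- c(land = file.path(out_dir, "land.asc"),
             study_area = file.path(out_dir, "study_area.asc"),
             latent = file.path(out_dir, "latent.asc"))
  write_asc(sim$land, paths["land"])
  write_asc(sim$study_area, paths["study_area"])
  write_asc(sim$latent, paths["latent"])
  for (id in names(sim$layers)) {
    p <- file.path(out_dir, paste0("raw_", id, ".asc"))
    write_asc(sim$layers[[id]], p)
    paths[id] <- p
  }
  manifest_append(out_dir, sprintf("simulate: preset with seed %d, %d layers",
                                   scenario$seed, length(sim$layers)))
  invisible(paths)
}

#' Run the assessment stage from files
#'
#' Reads the raw indicator layers and the study-area mask, runs
#' [ievi_assess()], and writes one `.asc` per standardized indicator
#' (`rc_<id>`), element (`rb_<el>`), objective, plus `ievi.asc`,
#' `ievi_class.asc` and `class_fractions.csv`.
#'
#' @param in_dir Directory holding `raw_<id>.asc` layers and
#'   `study_area.asc` (as written by [run_simulate()], or assembled by
#'   hand).
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param config An [index_config()].
#' @return The `iev_assessment`, invisibly.
#' @export
run_assess <- function(in_dir, out_dir = in_dir,
                       config = synthetic_index_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  domain <- read_mask(file.path(in_dir, "study_area.asc"))
  ids <- names(config$indicators)
  layers <- list()
  missing <- character()
  for (id in ids) {
    p <- file.path(in_dir, paste0("raw_", id, ".asc"))
    if (file.exists(p)) layers[[id]] <- read_asc(p) else missing <- c(missing, id)
  }
  if (length(missing)) {
    stop_config("missing raster file for indicator(s): ",
                paste(missing, collapse = ", "))
  }
  fit <- ievi_assess(layers, config, domain)
  for (id in names(fit$rc)) write_asc(fit$rc[[id]], file.path(out_dir, paste0("rc_", id, ".asc")))
  for (e in names(fit$rb)) write_asc(fit$rb[[e]], file.path(out_dir, paste0("rb_", e, ".asc")))
  for (o in names(fit$objectives)) {
    write_asc(fit$objectives[[o]], file.path(out_dir, paste0(o, ".asc")))
  }
  write_asc(fit$ievi, file.path(out_dir, "ievi.asc"))
  write_asc(fit$classes, file.path(out_dir, "ievi_class.asc"))
  utils::write.csv(fit$fractions, file.path(out_dir, "class_fractions.csv"),
                   row.names = FALSE)
  manifest_append(out_dir, c(sprintf("assess: %d indicators", length(ids)),
                             fit$notes))
  invisible(fit)
}

#' @noRd
read_bn_stack <- function(in_dir, variables, rules) {
  stack <- list()
  for (v in variables) {
    p <- file.path(in_dir, paste0("rc_", v, ".asc"))
    if (!file.exists(p)) stop_data("missing standardized layer: ", p)
    stack[[v]] <- discretize(read_asc(p), rules[[v]])
  }
  ievi_p <- file.path(in_dir, "ievi.asc")
  if (!file.exists(ievi_p)) stop_data("missing ievi.asc (run the assess stage first)")
  stack[["result"]] <- discretize(read_asc(ievi_p), rules[["result"]])
  stack
}

#' Run the conditional-probability stage from files
#'
#' Discretizes the standardized indicator layers and the index with
#' three-level rules, builds the pairwise [probability_graph()], and writes
#' `probability_graph.csv` (the long-format probability matrix), one
#' `css_<r>.txt` per supported result level, `optimal.txt`, and a
#' `match_css_<r>.asc` / `match_optimal.asc` mask for each subset.
#'
#' @param in_dir Directory with `rc_<id>.asc`, `ievi.asc`,
#'   `study_area.asc`.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param variables Indicator ids to analyze (default the five synthetic
#'   heterogeneous indicators).
#' @param rules Named list of [leveling_rule()] covering `variables` and
#'   `"result"`; defaults to [default_leveling_rules()].
#' @return The `iev_probability_graph`, invisibly.
#' @export
run_bn <- function(in_dir, out_dir = in_dir,
                   variables = c("steep_slope", "land_dev", "npp",
                                 "groundwater", "soil"),
                   rules = default_leveling_rules(c(variables, "result"))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  domain <- read_mask(file.path(in_dir, "study_area.asc"))
  stack <- read_bn_stack(in_dir, variables, rules)
  g <- probability_graph(stack, "result", domain)
  utils::write.csv(as.data.frame(g), file.path(out_dir, "probability_graph.csv"),
                   row.names = FALSE)
  notes <- character()
  for (r in seq_len(stack$result$n_states)) {
    if (g$marginals$result[r] <= 0) next
    css <- conditional_state_subset(g, r)
    write_subset(css, file.path(out_dir, sprintf("css_%d.txt", r)))
    write_asc(match_subset(stack, css, domain),
              file.path(out_dir, sprintf("match_css_%d.asc", r)))
    if (any(css$ties)) {
      notes <- c(notes, sprintf("bn: CSS %d tie on %s (lowest state kept)", r,
                                paste(names(which(css$ties)), collapse = ", ")))
    }
  }
  opt <- optimal_state_subset(g, 1)
  write_subset(opt, file.path(out_dir, "optimal.txt"))
  write_asc(match_subset(stack, opt, domain), file.path(out_dir, "match_optimal.asc"))
  if (any(opt$ties)) {
    notes <- c(notes, paste("bn: optimal-subset tie on",
                            paste(names(which(opt$ties)), collapse = ", ")))
  }
  manifest_append(out_dir, c(sprintf("bn: %d variables over %d cells",
                                     length(g$variables), g$n_cells), notes))
  invisible(g)
}

#' Run the entropy-ranking stage from files
#'
#' Writes `entropy_report.csv` with one row per indicator (ascending
#' entropy difference, key flag).
#'
#' @inheritParams run_bn
#' @param threshold Key-indicator cutoff on V (default 1.0).
#' @return The `iev_entropy_report`, invisibly.
#' @export
run_entropy <- function(in_dir, out_dir = in_dir,
                        variables = c("steep_slope", "land_dev", "npp",
                                      "groundwater", "soil"),
                        rules = default_leveling_rules(c(variables, "result")),
                        threshold = 1.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  domain <- read_mask(file.path(in_dir, "study_area.asc"))
  stack <- read_bn_stack(in_dir, variables, rules)
  rep <- rank_key_indicators(stack$result, stack[variables], domain,
                             threshold = threshold)
  utils::write.csv(rep$table, file.path(out_dir, "entropy_report.csv"),
                   row.names = FALSE)
  manifest_append(out_dir, sprintf("entropy: key = {%s} at threshold %g",
                                   paste(rep$table$indicator[rep$table$key],
                                         collapse = ", "), threshold))
  invisible(rep)
}

#' Run the promotion stage from files
#'
#' Derives the key indicators from `entropy_report.csv` (the two
#' lowest-entropy-difference indicators), derives the promotion rule set
#' from the conditional-probability graph with
#' [promotion_rules_from_graph()], and writes `promotion_first.asc`,
#' `promotion_second.asc` and `promotion_areas.csv`.
#'
#' @inheritParams run_bn
#' @return The `iev_promotion`, invisibly.
#' @export
run_promote <- function(in_dir, out_dir = in_dir,
                        variables = c("steep_slope", "land_dev", "npp",
                                      "groundwater", "soil"),
                        rules = default_leveling_rules(c(variables, "result"))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_path <- file.path(in_dir, "entropy_report.csv")
  if (!file.exists(rep_path)) stop_data("missing entropy_report.csv (run the entropy stage first)")
  tab <- utils::read.csv(rep_path)
  keys <- tab$indicator[seq_len(2)]
  domain <- read_mask(file.path(in_dir, "study_area.asc"))
  stack <- read_bn_stack(in_dir, variables, rules)
  g <- probability_graph(stack, "result", domain)
  prules <- promotion_rules_from_graph(g, keys)
  prom <- promotion_regions(stack[variables], stack$result, prules, domain)
  write_asc(prom$first_mask, file.path(out_dir, "promotion_first.asc"))
  write_asc(prom$second_mask, file.path(out_dir, "promotion_second.asc"))
  utils::write.csv(prom$areas, file.path(out_dir, "promotion_areas.csv"),
                   row.names = FALSE)
  manifest_append(out_dir, sprintf(
    "promote: keys = {%s}, first rule %s, %.1f / %.1f ha",
    paste(keys, collapse = ", "), prom$provenance,
    region_area(prom$first_mask), region_area(prom$second_mask)))
  invisible(prom)
}
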
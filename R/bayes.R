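# Pairwise conditional-probability machinery over categorical rasters:
# contingency tables, conditional probability tables (CPTs), the complete
# pairwise probability graph, and conditional / optimal state subsets.
#
# The structure is deliberately what the underlying method uses and nothing
# more: empirical CPTs from raster co-occurrence counts, with no structure
# learning and no smoothing.

#' Joint state counts of two categorical layers
#'
#' Counts co-occurrences of states over the cells that are valid in both
#' layers and inside the domain. The count total equals the number of such
#' cells.
#'
#' @param a,b Aligned [categorical_raster()] layers.
#' @param domain Optional [region_mask()].
#' @param var_a,var_b Variable ids; default to the layers' own ids.
#' @return An object of class `iev_contingency` with fields `var_a`,
#'   `var_b`, `counts` (an `m_a` x `m_b` integer matrix) and `n`.
#' @export
joint_counts <- function(a, b, domain = NULL, var_a = NULL, var_b = NULL) {
  stopifnot(inherits(a, "iev_categorical"), inherits(b, "iev_categorical"))
  g <- check_aligned(a, b)
  member <- domain_member(domain, g)
  sel <- a$valid & b$valid & member
  if (!any(sel)) stop_data("no cells valid in both layers inside the domain")
  counts <- table(factor(a$levels[sel], levels = seq_len(a$n_states)),
                  factor(b$levels[sel], levels = seq_len(b$n_states)))
  counts <- matrix(as.integer(counts), a$n_states, b$n_states)
  structure(list(var_a = var_a %||% a$id %||% "A",
                 var_b = var_b %||% b$id %||% "B",
                 counts = counts, n = sum(counts)),
            class = "iev_contingency")
}

#' Column-normalize a contingency table into a CPT
#'
#' Entry (i, j) of the result is `P(A = i | B = j)`, the count share within
#' column j. Columns with zero support are flagged undefined (`NA`) rather
#' than divided; every supported column sums to 1.
#'
#' @param t An [joint_counts()] result.
#' @return An object of class `iev_cpt` with fields `var_a`, `var_b`,
#'   `probs`, `support` (count per conditioning state) and `undefined`
#'   (logical per column).
#' @export
conditional_probability <- function(t) {
  stopifnot(inherits(t, "iev_contingency"))
  support <- colSums(t$counts)
  probs <- t$counts
  storage.mode(probs) <- "double"
  for (j in seq_along(support)) {
    probs[, j] <- if (support[j] > 0) probs[, j] / support[j] else NA_real_
  }
  structure(list(var_a = t$var_a, var_b = t$var_b, probs = probs,
                 support = support, undefined = support == 0),
            class = "iev_cpt")
}

#' @export
print.iev_cpt <- function(x, digits = 3, ...) {
  cat(sprintf("P(%s | %s), support n = %d\n", x$var_a, x$var_b, sum(x$support)))
  m <- round(x$probs, digits)
  dimnames(m) <- list(paste0(x$var_a, "=", seq_len(nrow(m))),
                      paste0(x$var_b, "=", seq_len(ncol(m))))
  print(m)
  invisible(x)
}

#' Build the complete pairwise conditional-probability graph
#'
#' For a stack of discretized layers (the analyzed indicators plus the
#' designated result variable) computes, over the cells valid in *every*
#' layer inside the domain, the marginal state distribution of each variable
#' and the CPT of every ordered variable pair. Because all tables share one
#' joint support, the Bayes identity
#' `P(A=i|B=j) P(B=j) = P(B=j|A=i) P(A=i)` holds exactly.
#'
#' @param stack Named list of aligned [categorical_raster()] layers.
#' @param result Name of the result (ecological vulnerability) variable in
#'   `stack`.
#' @param domain Optional [region_mask()].
#' @return An object of class `iev_probability_graph` with fields
#'   `variables`, `result_var`, `n_states` (named integer), `marginals`
#'   (named list of probability vectors), `cpts` (named `"A|B"` list of
#'   [conditional_probability()] tables), and `n_cells`.
#' @export
probability_graph <- function(stack, result, domain = NULL) {
  if (is.null(names(stack)) || any(!nzchar(names(stack)))) {
    stop_config("stack must be a fully named list of categorical rasters")
  }
  if (anyDuplicated(names(stack))) stop_config("duplicate variable ids in the stack")
  if (length(stack) < 2) stop_config("need at least two variables")
  if (!result %in% names(stack)) stop_config("result variable '", result, "' not in the stack")
  g <- do.call(check_aligned, unname(stack))
  member <- domain_member(domain, g)
  common <- Reduce(`&`, lapply(stack, `[[`, "valid"), member)
  if (!any(common)) stop_data("no cells valid in every layer inside the domain")
  common_mask <- region_mask(common, g)
  vars <- names(stack)
  n_states <- vapply(stack, `[[`, 1L, "n_states")
  marginals <- lapply(stack, function(x) {
    counts <- tabulate(x$levels[common], x$n_states)
    counts / sum(counts)
  })
  cpts <- list()
  for (a in vars) for (b in vars) {
    if (a == b) next
    cpts[[paste0(a, "|", b)]] <- conditional_probability(
      joint_counts(stack[[a]], stack[[b]], common_mask, var_a = a, var_b = b)
    )
  }
  structure(list(variables = vars, result_var = result, n_states = n_states,
                 marginals = marginals, cpts = cpts, n_cells = sum(common)),
            class = "iev_probability_graph")
}

#' @export
print.iev_probability_graph <- function(x, ...) {
  cat(sprintf("<iev_probability_graph> %d variables over %d cells (result: %s)\n",
              length(x$variables), x$n_cells, x$result_var))
  for (v in x$variables) {
    cat(sprintf("  %-14s P = (%s)\n", v,
                paste(sprintf("%.3f", x$marginals[[v]]), collapse = ", ")))
  }
  cat(sprintf("  %d ordered-pair conditional probability tables\n", length(x$cpts)))
  invisible(x)
}

#' Flatten a probability graph to a long table
#'
#' One row per CPT entry: `var_a`, `state_a`, `var_b`, `state_b`,
#' `p_a_given_b`, `support`. This is the export format for the
#' probability-matrix figure style (rows = conditioned variable states,
#' columns = conditioning variable states).
#'
#' @param x An [probability_graph()] result.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.iev_probability_graph <- function(x, ...) {
  rows <- lapply(names(x$cpts), function(key) {
    cpt <- x$cpts[[key]]
    expand <- expand.grid(state_a = seq_len(nrow(cpt$probs)),
                          state_b = seq_len(ncol(cpt$probs)))
    data.frame(var_a = cpt$var_a, state_a = expand$state_a,
               var_b = cpt$var_b, state_b = expand$state_b,
               p_a_given_b = cpt$probs[cbind(expand$state_a, expand$state_b)],
               support = cpt$support[expand$state_b])
  })
  do.call(rbind, rows)
}

#' Construct a state subset by hand
#'
#' A state subset assigns each listed variable a required state or set of
#' admissible states, e.g. `list(npp = c(1, 2), steep_slope = 1)`.
#'
#' @param assignments Named list; each entry an integer vector of admissible
#'   states for that variable.
#' @param label Free-text label.
#' @return An object of class `iev_state_subset`.
#' @export
state_subset <- function(assignments, label = "subset") {
  if (length(assignments) && (is.null(names(assignments)) || any(!nzchar(names(assignments))))) {
    stop_config("assignments must be a named list")
  }
  assignments <- lapply(assignments, function(s) sort(unique(as.integer(s))))
  if (any(vapply(assignments, function(s) any(s < 1), TRUE))) {
    stop_config("states must be positive integers")
  }
  structure(list(assignments = assignments, label = label,
                 ties = logical(0), probs = numeric(0)),
            class = "iev_state_subset")
}

#' @export
print.iev_state_subset <- function(x, ...) {
  cat(sprintf("<iev_state_subset> %s\n", x$label))
  if (!length(x$assignments)) {
    cat("  (empty: matches the whole domain)\n")
    return(invisible(x))
  }
  for (v in names(x$assignments)) {
    tie <- if (isTRUE(x$ties[v])) "  [tie, lowest state kept]" else ""
    p <- if (length(x$probs) && !is.na(x$probs[v])) sprintf("  (p = %.4f)", x$probs[v]) else ""
    cat(sprintf("  %s = %s%s%s\n", v,
                paste(x$assignments[[v]], collapse = " | "), p, tie))
  }
  invisible(x)
}

#' @noRd
argmax_lowest <- function(p) {
  ok <- !is.na(p)
  if (!any(ok)) stop_data("all candidate states have undefined probability")
  mx <- max(p[ok])
  hits <- which(ok & p >= mx - 1e-12)
  list(state = hits[1], tie = length(hits) > 1, p = p[hits[1]])
}

#' Conditional state subset for a result level
#'
#' For each non-result variable X, the state s maximizing
#' `P(X = s | result = r)`: the combination of indicator states most
#' probable in cells attaining result level r. Ties are broken toward the
#' lowest state index and recorded.
#'
#' @param g An [probability_graph()].
#' @param result_level Result state r (must have support > 0).
#' @return An [state_subset()] labeled `"CSS r"`, with the winning
#'   conditional probabilities and tie flags attached.
#' @export
conditional_state_subset <- function(g, result_level) {
  stopifnot(inherits(g, "iev_probability_graph"))
  res <- g$result_var
  if (result_level < 1 || result_level > g$n_states[[res]]) {
    stop_config("result_level outside the result variable's states")
  }
  if (g$marginals[[res]][result_level] <= 0) {
    stop_data("result level ", result_level, " has zero support")
  }
  vars <- setdiff(g$variables, res)
  out <- state_subset(stats::setNames(as.list(rep(1L, length(vars))), vars),
                      label = paste("CSS", result_level))
  ties <- stats::setNames(logical(length(vars)), vars)
  probs <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    col <- g$cpts[[paste0(v, "|", res)]]$probs[, result_level]
    pick <- argmax_lowest(col)
    out$assignments[[v]] <- pick$state
    ties[v] <- pick$tie
    probs[v] <- pick$p
  }
  out$ties <- ties
  out$probs <- probs
  out
}

#' Optimal state subset for reaching a target result level
#'
#' For each non-result variable X, the state s maximizing
#' `P(result = target | X = s)`: the per-indicator condition under which the
#' best (level-1) assessment outcome is most probable. States of X with zero
#' support are excluded; ties go to the lowest state and are recorded.
#'
#' @param g An [probability_graph()].
#' @param target_level Desired result state (default 1, the least
#'   vulnerable).
#' @return An [state_subset()] labeled `"optimal"`.
#' @export
optimal_state_subset <- function(g, target_level = 1) {
  stopifnot(inherits(g, "iev_probability_graph"))
  res <- g$result_var
  if (g$marginals[[res]][target_level] <= 0) {
    stop_data("target level ", target_level, " has zero support")
  }
  vars <- setdiff(g$variables, res)
  out <- state_subset(stats::setNames(as.list(rep(1L, length(vars))), vars),
                      label = "optimal")
  ties <- stats::setNames(logical(length(vars)), vars)
  probs <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    row <- g$cpts[[paste0(res, "|", v)]]$probs[target_level, ]
    pick <- argmax_lowest(row)
    out$assignments[[v]] <- pick$state
    ties[v] <- pick$tie
    probs[v] <- pick$p
  }
  out$ties <- ties
  out$probs <- probs
  out
}

#' Map a state subset onto the grid
#'
#' Returns the cells (valid in every referenced layer and inside the
#' domain) whose states satisfy every assignment of the subset; state-sets
#' are satisfied by membership. An empty subset matches the whole valid
#' domain; a subset requiring an absent state legally yields an empty mask.
#'
#' @param stack Named list of [categorical_raster()] layers.
#' @param subset An [state_subset()].
#' @param domain Optional [region_mask()].
#' @return A [region_mask()].
#' @export
match_subset <- function(stack, subset, domain = NULL) {
  stopifnot(inherits(subset, "iev_state_subset"))
  missing <- setdiff(names(subset$assignments), names(stack))
  if (length(missing)) {
    stop_config("subset references absent variable(s): ", paste(missing, collapse = ", "))
  }
  g <- do.call(check_aligned, unname(stack))
  ok <- domain_member(domain, g)
  for (v in names(subset$assignments)) {
    layer <- stack[[v]]
    ok <- ok & layer$valid & matrix(layer$levels %in% subset$assignments[[v]],
                                    g$n_rows, g$n_cols)
  }
  if (!length(subset$assignments)) {
    for (layer in stack) ok <- ok & layer$valid
  }
  region_mask(ok, g)
}

#' Write a state subset as a small structured-text document
#'
#' @param subset An [state_subset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subset <- function(subset, path) {
  lines <- c(paste("label:", subset$label),
             vapply(names(subset$assignments), function(v) {
               paste0(v, ": ", paste(subset$assignments[[v]], collapse = " | "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
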
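# Entropy-difference ranking of indicators against the assessment result.
#
# All entropies are Shannon entropies in bits (log base 2) of empirical
# (maximum-likelihood) state frequencies; empty joint cells contribute 0 and
# no smoothing is applied.

#' Shannon entropy of a probability vector
#'
#' `-sum(p * log2(p))` with the `0 * log2(0) = 0` convention.
#'
#' @param p Nonnegative probabilities summing to 1 (tolerance 1e-9).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # 1 bit
#' shannon_entropy(c(1, 0, 0))    # 0 bits
#' @export
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) stop_data("probabilities must be finite and nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop_data("probabilities must sum to 1 (got ", sum(p), ")")
  entropy_from_counts(p)
}

#' @noRd
pair_joint_counts <- function(e, i, domain) {
  joint_counts(e, i, domain, var_a = e$id %||% "result", var_b = i$id %||% "indicator")
}

#' Joint entropy of the result and an indicator
#'
#' Shannon entropy (bits) of the empirical joint state distribution of the
#' two layers over the cells valid in both and inside the domain.
#'
#' @param e Result [categorical_raster()].
#' @param i Indicator [categorical_raster()], aligned with `e`.
#' @param domain Optional [region_mask()].
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(e, i, domain = NULL) {
  entropy_from_counts(pair_joint_counts(e, i, domain)$counts)
}

#' Entropy difference between an indicator and the result
#'
#' The default (`method = "conditional"`) is the nonnegative difference
#' between the joint entropy and the result's marginal entropy,
#' `V(I) = S(E, I) - S(E)` — equivalently the conditional entropy of the
#' indicator given the result. `V = 0` when the indicator is a function of
#' the result (maximal association) and `V = S(I)` under empirical
#' independence, so *smaller V means stronger association*.
#'
#' `method = "mutual_information"` instead returns
#' `S(E) + S(I) - S(E, I)`, the mutual information, for which *larger*
#' values mean stronger association; it is provided as a named alternative
#' reading of the same ingredients.
#'
#' @param e Result [categorical_raster()].
#' @param i Indicator [categorical_raster()].
#' @param domain Optional [region_mask()].
#' @param method `"conditional"` (default) or `"mutual_information"`.
#' @return V value in bits.
#' @export
entropy_difference <- function(e, i, domain = NULL,
                               method = c("conditional", "mutual_information")) {
  method <- match.arg(method)
  counts <- pair_joint_counts(e, i, domain)$counts
  s_joint <- entropy_from_counts(counts)
  s_e <- entropy_from_counts(rowSums(counts))
  if (method == "conditional") {
    abs(s_joint - s_e)
  } else {
    s_i <- entropy_from_counts(colSums(counts))
    s_e + s_i - s_joint
  }
}

#' Rank indicators by entropy difference and flag key indicators
#'
#' Computes `V(I)` for every indicator against the result layer, sorts
#' ascending (strongest association first) and flags as *key* the
#' indicators with `V` strictly below the threshold (default 1 bit).
#'
#' @param result Result [categorical_raster()].
#' @param indicators Named list of aligned [categorical_raster()] layers.
#' @param domain Optional [region_mask()].
#' @param threshold Key-indicator cutoff on V (default 1.0).
#' @param method Passed to [entropy_difference()]; the key rule applies to
#'   the conditional reading.
#' @return An object of class `iev_entropy_report`: a list with
#'   `result_entropy`, `threshold`, `method` and `table`, a data frame with
#'   columns `indicator`, `joint_entropy`, `entropy_difference`, `key`.
#' @export
rank_key_indicators <- function(result, indicators, domain = NULL,
                                threshold = 1.0,
                                method = c("conditional", "mutual_information")) {
  method <- match.arg(method)
  if (!length(indicators)) stop_config("need at least one indicator layer")
  if (is.null(names(indicators)) || any(!nzchar(names(indicators)))) {
    stop_config("indicators must be a named list")
  }
  rows <- lapply(names(indicators), function(v) {
    counts <- pair_joint_counts(result, indicators[[v]], domain)$counts
    data.frame(indicator = v,
               joint_entropy = entropy_from_counts(counts),
               entropy_difference = {
                 sj <- entropy_from_counts(counts)
                 se <- entropy_from_counts(rowSums(counts))
                 si <- entropy_from_counts(colSums(counts))
                 if (method == "conditional") abs(sj - se) else se + si - sj
               })
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$entropy_difference,
                   decreasing = (method == "mutual_information")), ]
  rownames(tab) <- NULL
  tab$key <- if (method == "conditional") tab$entropy_difference < threshold
             else tab$entropy_difference > threshold
  member <- domain_member(domain, result$grid)
  se <- entropy_from_counts(tabulate(result$levels[result$valid & member],
                                     result$n_states))
  structure(list(result_entropy = se, threshold = threshold, method = method,
                 table = tab),
            class = "iev_entropy_report")
}

#' @export
print.iev_entropy_report <- function(x, ...) {
  cat(sprintf("Entropy-difference ranking (%s, bits); S(result) = %.4f\n",
              x$method, x$result_entropy))
  tab <- x$table
  tab$entropy_difference <- round(tab$entropy_difference, 4)
  tab$joint_entropy <- round(tab$joint_entropy, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("key indicators (V %s %g): %s\n",
              if (x$method == "conditional") "<" else ">", x$threshold,
              paste(tab$indicator[tab$key], collapse = ", ") |>
                (\(s) if (nzchar(s)) s else "none")()))
  invisible(x)
}

#' @export
as.data.frame.iev_entropy_report <- function(x, ...) x$table
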
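# independent brute-force oracles: plain loops over count tables and cells,
# sharing no code with the package internals

oracle_entropy <- function(p) {
  total <- 0
  for (x in p) if (x > 0) total <- total - x * log2(x)
  total
}

oracle_joint_entropy <- function(counts) {
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    p <- counts[i, j] / n
    if (p > 0) total <- total - p * log2(p)
  }
  total
}

oracle_marginal_entropy_rows <- function(counts) {
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    p <- sum(counts[i, ]) / n
    if (p > 0) total <- total - p * log2(p)
  }
  total
}

oracle_entropy_difference <- function(counts) {
  abs(oracle_joint_entropy(counts) - oracle_marginal_entropy_rows(counts))
}

# joint counts of two categorical layers by explicit cell scan
oracle_joint_counts <- function(a, b, member = NULL) {
  nr <- a$grid$n_rows; nc <- a$grid$n_cols
  if (is.null(member)) member <- matrix(TRUE, nr, nc)
  counts <- matrix(0L, a$n_states, b$n_states)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (member[i, j] && a$valid[i, j] && b$valid[i, j]) {
      counts[a$levels[i, j], b$levels[i, j]] <- counts[a$levels[i, j], b$levels[i, j]] + 1L
    }
  }
  counts
}

# per-variable argmax of P(X = s | result = r) by direct count scan,
# lowest state on ties
oracle_css <- function(stack, result_name, r) {
  res <- stack[[result_name]]
  out <- list()
  for (v in setdiff(names(stack), result_name)) {
    counts <- oracle_joint_counts(stack[[v]], res)
    col <- counts[, r]
    best <- 1; bestval <- col[1]
    for (s in seq_along(col)) if (col[s] > bestval) { best <- s; bestval <- col[s] }
    out[[v]] <- best
  }
  out
}

# per-variable argmax of P(result = target | X = s), skipping zero-support
# states, lowest state on ties
oracle_optimal <- function(stack, result_name, target) {
  res <- stack[[result_name]]
  out <- list()
  for (v in setdiff(names(stack), result_name)) {
    counts <- oracle_joint_counts(res, stack[[v]])
    best <- NA; bestval <- -1
    for (s in seq_len(ncol(counts))) {
      support <- sum(counts[, s])
      if (support == 0) next
      p <- counts[target, s] / support
      if (p > bestval + 1e-12) { best <- s; bestval <- p }
    }
    out[[v]] <- best
  }
  out
}

# per-cell scan applying the promotion rules directly
oracle_promotion <- function(stack, result, first, second, fallback = NULL) {
  nr <- result$grid$n_rows; nc <- result$grid$n_cols
  sat <- function(subset, i, j) {
    for (v in names(subset)) {
      lay <- stack[[v]]
      if (!lay$valid[i, j] || !(lay$levels[i, j] %in% subset[[v]])) return(FALSE)
    }
    TRUE
  }
  scan_first <- function(subset) {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (result$valid[i, j] && result$levels[i, j] != 1 && sat(subset, i, j)) {
        m[i, j] <- TRUE
      }
    }
    m
  }
  fm <- scan_first(first)
  used_fallback <- FALSE
  if (!any(fm) && !is.null(fallback)) {
    fm <- scan_first(fallback)
    used_fallback <- TRUE
  }
  sm <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (result$valid[i, j] && result$levels[i, j] == 3 && sat(second, i, j) &&
        !fm[i, j]) {
      sm[i, j] <- TRUE
    }
  }
  list(first = fm, second = sm, fallback = used_fallback)
}
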
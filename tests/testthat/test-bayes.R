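test_that("joint counts conserve cells and match a brute-force scan", {
  lv <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  a <- mk_cat(lv, n_states = 2, id = "a")
  t_aa <- joint_counts(a, a)
  expect_equal(t_aa$counts, matrix(c(50L, 0L, 0L, 50L), 2, 2))

  set.seed(21)
  b <- rand_cat(10, 10, 3, id = "b")
  tab <- joint_counts(a, b)
  expect_equal(sum(tab$counts), 100)
  expect_equal(tab$counts, oracle_joint_counts(a, b))

  # independent checkerboards give uniform counts
  chk1 <- mk_cat(outer(1:8, 1:8, function(i, j) 1L + (i + j) %% 2L), n_states = 2)
  chk2 <- mk_cat(outer(1:8, 1:8, function(i, j) 1L + ((i + j) %/% 2) %% 2L), n_states = 2)
  expect_true(all(joint_counts(chk1, chk2)$counts == 16))

  empty <- mk_mask(matrix(FALSE, 10, 10))
  expect_error(joint_counts(a, b, empty), "no cells")
})

test_that("conditional probabilities column-normalize and flag zero support", {
  ct <- structure(list(var_a = "A", var_b = "B",
                       counts = matrix(c(30L, 10L, 10L, 30L), 2, 2), n = 80L),
                  class = "iev_contingency")
  cpt <- conditional_probability(ct)
  expect_equal(cpt$probs[1, 1], 0.75)
  expect_equal(cpt$probs[2, 2], 0.75)
  expect_equal(colSums(cpt$probs), c(1, 1))

  diag_ct <- structure(list(var_a = "A", var_b = "B",
                            counts = diag(c(5L, 7L)), n = 12L),
                       class = "iev_contingency")
  expect_equal(conditional_probability(diag_ct)$probs, diag(2))

  zc <- structure(list(var_a = "A", var_b = "B",
                       counts = matrix(c(3L, 1L, 0L, 0L), 2, 2), n = 4L),
                  class = "iev_contingency")
  cpt0 <- conditional_probability(zc)
  expect_true(all(is.na(cpt0$probs[, 2])))
  expect_true(cpt0$undefined[2])
  expect_equal(cpt0$probs[, 1], c(0.75, 0.25))
})

test_that("the probability graph has all ordered pairs and is Bayes-consistent", {
  set.seed(31)
  two <- list(x = rand_cat(6, 6, 3, "x"), result = rand_cat(6, 6, 3, "result"))
  g2 <- probability_graph(two, "result")
  expect_length(g2$cpts, 2)
  expect_length(g2$marginals, 2)

  six <- c(lapply(1:5, function(i) rand_cat(9, 9, 3)), list(rand_cat(9, 9, 3)))
  names(six) <- c(paste0("v", 1:5), "result")
  for (n in names(six)) six[[n]]$id <- n
  g6 <- probability_graph(six, "result")
  expect_length(g6$cpts, 30)

  for (a in g6$variables) for (b in g6$variables) {
    if (a == b) next
    p_ab <- g6$cpts[[paste0(a, "|", b)]]$probs
    p_ba <- g6$cpts[[paste0(b, "|", a)]]$probs
    pa <- g6$marginals[[a]]; pb <- g6$marginals[[b]]
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      lhs <- if (is.na(p_ab[i, j])) 0 else p_ab[i, j] * pb[j]
      rhs <- if (is.na(p_ba[j, i])) 0 else p_ba[j, i] * pa[i]
      expect_lt(abs(lhs - rhs), 1e-9)
    }
    # marginal consistency: P(A=i) = sum_j P(A=i|B=j) P(B=j)
    recon <- sapply(seq_along(pa), function(i) {
      sum(ifelse(is.na(p_ab[i, ]), 0, p_ab[i, ]) * pb)
    })
    expect_true(all(abs(recon - pa) < 1e-9))
  }

  expect_error(probability_graph(six, "missing"), "not in the stack")
  expect_error(probability_graph(six[1], "v1"), "two variables")
})

test_that("state subsets equal the brute-force argmax, ties to the lowest state", {
  # deterministic dependence: indicator states equal the result state
  set.seed(41)
  lv <- matrix(sample(1:3, 64, TRUE), 8, 8)
  det <- list(a = mk_cat(lv, 3, "a"), b = mk_cat(lv, 3, "b"),
              result = mk_cat(lv, 3, "result"))
  g <- probability_graph(det, "result")
  for (r in 1:3) {
    css <- conditional_state_subset(g, r)
    expect_equal(unname(unlist(css$assignments)), c(r, r))
  }
  opt <- optimal_state_subset(g, 1)
  expect_equal(unname(unlist(opt$assignments)), c(1, 1))

  # random graphs vs the exhaustive oracle
  for (rep in 1:40) {
    n_cells <- sample(c(12, 30, 60), 1)  # small counts provoke ties
    nr <- 3; nc <- n_cells / 3
    stack <- lapply(1:4, function(i) rand_cat(nr, nc, 3))
    names(stack) <- c(paste0("v", 1:3), "result")
    for (n in names(stack)) stack[[n]]$id <- n
    gg <- probability_graph(stack, "result")
    for (r in which(gg$marginals$result > 0)) {
      want <- oracle_css(stack, "result", r)
      got <- conditional_state_subset(gg, r)$assignments
      expect_equal(got[names(want)], want)
    }
    want_opt <- oracle_optimal(stack, "result", 1)
    got_opt <- optimal_state_subset(gg, 1)$assignments
    expect_equal(got_opt[names(want_opt)], want_opt)
  }
})

test_that("full independence yields a tie resolved to state 1 and flagged", {
  # exact independence by construction: a full crossing of state cycles
  resm <- matrix(rep(rep(1:2, each = 3), 6), 6, 6)
  indm <- matrix(rep(1:3, 12), 6, 6)
  stack <- list(result = mk_cat(resm, 2, "result"), x = mk_cat(indm, 3, "x"))
  gg <- probability_graph(stack, "result")
  css <- conditional_state_subset(gg, 1)
  expect_equal(css$assignments$x, 1L)
  expect_true(css$ties["x"])
})

test_that("match_subset selects exactly the satisfying cells", {
  set.seed(51)
  a <- rand_cat(8, 8, 3, "a")
  b <- rand_cat(8, 8, 3, "b")
  stack <- list(a = a, b = b)

  empty <- state_subset(list())
  expect_equal(match_subset(stack, empty)$member, a$valid & b$valid)

  m40 <- mk_cat(matrix(c(rep(2L, 40), rep(1L, 24)), 8, 8), 3, "a")
  expect_equal(sum(match_subset(list(a = m40), state_subset(list(a = 2)))$member), 40)

  absent <- state_subset(list(a = 3L, b = 3L))
  only12 <- list(a = mk_cat(matrix(rep(1:2, 32), 8, 8), 3, "a"), b = b)
  expect_equal(sum(match_subset(only12, absent)$member), 0)

  # conjunction property for disjoint-variable subsets
  s1 <- state_subset(list(a = c(1L, 2L)))
  s2 <- state_subset(list(b = 2L))
  s12 <- state_subset(list(a = c(1L, 2L), b = 2L))
  expect_equal(match_subset(stack, s12)$member,
               match_subset(stack, s1)$member & match_subset(stack, s2)$member)

  expect_error(match_subset(stack, state_subset(list(zzz = 1))), "absent")
})
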
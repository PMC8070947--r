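test_that("shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0.0)
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log2(3), tolerance = 1e-15)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
})

# layers realizing the joint count table [[2,1],[1,2]] over 6 cells
joint_2112 <- function() {
  e <- mk_cat(matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 1, 6), 2, "e")
  i <- mk_cat(matrix(c(1L, 1L, 2L, 1L, 2L, 2L), 1, 6), 2, "i")
  list(e = e, i = i)
}

test_that("joint entropy matches enumeration on known tables", {
  p <- joint_2112()
  # counts (2,1,1,2)/6: H = (2/3) log2 3 + (1/3) log2 6
  expect_equal(joint_entropy(p$e, p$i), 1.9182958340544896, tolerance = 1e-12)

  # identical uniform binary layers: joint = marginal = 1 bit
  e <- mk_cat(matrix(rep(1:2, 8), 4, 4), 2, "e")
  expect_equal(joint_entropy(e, e), 1.0)

  # independent uniform binaries: additivity
  a <- mk_cat(matrix(rep(c(1L, 1L, 2L, 2L), 4), 4, 4), 2, "a")
  b <- mk_cat(matrix(rep(1:2, 8), 4, 4), 2, "b")
  expect_equal(joint_entropy(a, b), 2.0)
})

test_that("entropy difference behaves as conditional entropy of the indicator", {
  p <- joint_2112()
  expect_equal(entropy_difference(p$e, p$i), 0.9182958340544896, tolerance = 1e-12)

  # duplicate layer: V = 0 (maximal association)
  e <- mk_cat(matrix(rep(1:2, 8), 4, 4), 2, "e")
  expect_equal(entropy_difference(e, e), 0.0)

  # exact empirical independence: V = S(I) = log2 3
  resm <- matrix(rep(rep(1:2, each = 3), 6), 6, 6)
  indm <- matrix(rep(1:3, 12), 6, 6)
  ev <- mk_cat(resm, 2, "e"); iv <- mk_cat(indm, 3, "i")
  expect_equal(entropy_difference(ev, iv), log2(3), tolerance = 1e-12)

  # mutual-information reading is zero there and symmetric in general
  expect_equal(entropy_difference(ev, iv, method = "mutual_information"), 0,
               tolerance = 1e-12)
  expect_equal(entropy_difference(p$e, p$i, method = "mutual_information"),
               entropy_difference(p$i, p$e, method = "mutual_information"))
})

test_that("entropy operations agree with enumeration oracles on random tables", {
  set.seed(61)
  for (rep in 1:100) {
    ma <- sample(2:4, 1); mb <- sample(2:4, 1)
    counts <- matrix(rpois(ma * mb, 3), ma, mb)
    if (sum(counts) == 0) counts[1, 1] <- 1
    # materialize layers with exactly these joint counts
    lv_a <- integer(0); lv_b <- integer(0)
    for (i in seq_len(ma)) for (j in seq_len(mb)) {
      lv_a <- c(lv_a, rep(i, counts[i, j]))
      lv_b <- c(lv_b, rep(j, counts[i, j]))
    }
    n <- length(lv_a)
    a <- mk_cat(matrix(lv_a, 1, n), ma, "a")
    b <- mk_cat(matrix(lv_b, 1, n), mb, "b")
    expect_equal(joint_entropy(a, b), oracle_joint_entropy(counts), tolerance = 1e-9)
    expect_equal(entropy_difference(a, b), oracle_entropy_difference(counts),
                 tolerance = 1e-9)
  }
})

test_that("V is invariant under state relabeling and count duplication", {
  set.seed(71)
  lv_e <- sample(1:2, 40, TRUE); lv_i <- sample(1:3, 40, TRUE)
  e <- mk_cat(matrix(lv_e, 1, 40), 2, "e")
  i <- mk_cat(matrix(lv_i, 1, 40), 3, "i")
  v0 <- entropy_difference(e, i)

  # relabel indicator states by a permutation
  perm <- c(3L, 1L, 2L)
  i2 <- mk_cat(matrix(perm[lv_i], 1, 40), 3, "i")
  expect_equal(entropy_difference(e, i2), v0, tolerance = 1e-12)

  # duplicating every cell leaves the empirical joint unchanged
  e2 <- mk_cat(matrix(c(lv_e, lv_e), 1, 80), 2, "e")
  i3 <- mk_cat(matrix(c(lv_i, lv_i), 1, 80), 3, "i")
  expect_equal(entropy_difference(e2, i3), v0, tolerance = 1e-12)
})

test_that("ranking recovers a planted noisy copy and flags no independent keys", {
  set.seed(81)
  res_lv <- sample(1:3, 400, TRUE)
  copy_lv <- res_lv
  flip <- sample(400, 20)  # 5% corruption
  copy_lv[flip] <- sample(1:3, 20, TRUE)
  stack <- list(
    copy = mk_cat(matrix(copy_lv, 20, 20), 3, "copy"),
    noise1 = rand_cat(20, 20, 3, "noise1"),
    noise2 = rand_cat(20, 20, 3, "noise2")
  )
  res <- mk_cat(matrix(res_lv, 20, 20), 3, "result")
  rep_ <- rank_key_indicators(res, stack)
  expect_equal(rep_$table$indicator[1], "copy")
  expect_true(rep_$table$key[1])
  expect_true(all(rep_$table$entropy_difference ==
                    sort(rep_$table$entropy_difference)))

  # independent near-uniform 3-state indicators carry V near log2 3 > 1
  indep <- rank_key_indicators(res, stack[c("noise1", "noise2")])
  expect_false(any(indep$table$key))
})
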
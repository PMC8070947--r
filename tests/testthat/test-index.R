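spec_neg <- indicator_spec("x", "B1", polarity = "negative", standard = 0.25)
spec_pos <- indicator_spec("x", "B1", polarity = "positive", standard = 0.25)

test_that("standardization is the ratio against the standard, by polarity", {
  r <- mk_raster(matrix(0.5, 3, 3))
  expect_equal(unique(standardize(r, spec_neg)$values[TRUE]), 2.0)
  expect_equal(unique(standardize(r, spec_pos)$values[TRUE]), 0.5)

  # C = S is a fixed point for both polarities
  r2 <- mk_raster(matrix(0.25, 3, 3))
  expect_equal(unique(standardize(r2, spec_neg)$values[TRUE]), 1.0)
  expect_equal(unique(standardize(r2, spec_pos)$values[TRUE]), 1.0)
})

test_that("regional-mean standards are computed over the domain", {
  m <- matrix(c(1, 1, 3, 3), 2, 2)
  r <- mk_raster(m)
  sp <- indicator_spec("x", "B1", polarity = "negative")
  expect_equal(standardize(r, sp)$values, m / 2)
  # restricting the domain changes the mean
  dom <- mk_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  out <- standardize(r, sp, dom)
  expect_equal(out$values[, 1], c(1, 1))
  expect_false(any(out$valid[, 2]))
})

test_that("standardization is monotone in the raw value", {
  v <- sort(runif(20, 0.1, 3))
  rcn <- standardize(mk_raster(v), spec_neg)$values[1, ]
  rcp <- standardize(mk_raster(v), spec_pos)$values[1, ]
  expect_true(all(diff(rcn) > 0))
  expect_true(all(diff(rcp) < 0))
})

test_that("standardization rejects degenerate inputs", {
  expect_error(standardize(mk_raster(c(0, 1)), spec_pos), "> 0")
  zero_std <- indicator_spec("x", "B1", standard = 0)
  expect_error(standardize(mk_raster(c(1, 2)), zero_std), "positive")
  unset <- indicator_spec("x", "B1", standard = NA)
  expect_error(standardize(mk_raster(c(1, 2)), unset), "unset")
  # uniform scalar needs a domain
  expect_error(standardize(0.5, spec_neg), "domain")
})

test_that("element aggregation is the renormalized weighted sum", {
  rc <- list(mk_raster(matrix(2, 3, 3)), mk_raster(matrix(1, 3, 3)))
  out <- aggregate_element(rc, c(0.6, 0.4))
  expect_equal(unique(out$values[TRUE]), 1.6)
  expect_equal(attr(out, "weight_sum"), 1.0)

  # single indicator with weight 1 is the identity
  one <- aggregate_element(rc[1], 1)
  expect_equal(one$values, rc[[1]]$values)

  # published rounded weights summing to 1.01 are renormalized, with warning
  rcs <- lapply(c(2, 1, 4, 0.5), function(x) mk_raster(matrix(x, 2, 2)))
  w <- c(0.34, 0.24, 0.23, 0.20)
  expect_warning(out2 <- aggregate_element(rcs, w), "renormalizing")
  expect_equal(unique(out2$values[TRUE]),
               sum(c(2, 1, 4, 0.5) * w / 1.01))
  expect_error(aggregate_element(rcs, c(0.5, 0.2, 0.2, 0.2)), "tolerance")
  expect_error(aggregate_element(list(), numeric()), "empty")
})

test_that("element aggregation is permutation invariant", {
  set.seed(5)
  vals <- lapply(1:3, function(i) mk_raster(matrix(runif(9), 3, 3)))
  w <- c(0.5, 0.3, 0.2)
  a <- aggregate_element(vals, w)
  perm <- c(3, 1, 2)
  b <- aggregate_element(vals[perm], w[perm])
  expect_equal(a$values, b$values)
})

test_that("objective aggregation uses fixed equal weights and element counts", {
  consts <- function(x) lapply(x, function(v) mk_raster(matrix(v, 2, 2)))
  ra <- aggregate_objective(consts(c(0.18, 0.97, 0.98, 0.40)), "adaptability")
  expect_equal(unique(ra$values[TRUE]), 0.6325)
  expect_equal(round(unique(ra$values[TRUE]), 2), 0.63)
  expect_equal(unique(aggregate_objective(consts(c(1, 1)), "exposure")$values[TRUE]), 1)
  expect_equal(unique(aggregate_objective(consts(c(0.62, 0.10)), "sensitivity")$values[TRUE]), 0.36)
  expect_error(aggregate_objective(consts(c(1, 1, 1)), "exposure"), "exactly 2")
  expect_error(aggregate_objective(consts(c(1, 1)), "adaptability"), "exactly 4")
})

test_that("the index is the geometric mean of the three objectives", {
  one <- mk_raster(matrix(1, 2, 2))
  expect_equal(unique(compute_ievi(one, one, one)$values[TRUE]), 1)
  out <- compute_ievi(mk_raster(matrix(1.45, 2, 2)), mk_raster(matrix(0.62, 2, 2)),
                      mk_raster(matrix(0.63, 2, 2)))
  expect_equal(unique(out$values[TRUE]), 0.82737059217751696, tolerance = 1e-15)
  zero <- mk_raster(matrix(0, 2, 2))
  expect_equal(unique(compute_ievi(zero, one, one)$values[TRUE]), 0)
  neg <- mk_raster(matrix(-0.1, 2, 2))
  expect_error(compute_ievi(neg, one, one), "nonnegative")
})

test_that("the index lies between the cell-wise min and max objective", {
  set.seed(9)
  for (rep in 1:5) {
    re <- mk_raster(matrix(runif(25, 0, 2), 5, 5))
    rs <- mk_raster(matrix(runif(25, 0, 2), 5, 5))
    ra <- mk_raster(matrix(runif(25, 0, 2), 5, 5))
    iv <- compute_ievi(re, rs, ra)$values
    lo <- pmin(re$values, rs$values, ra$values)
    hi <- pmax(re$values, rs$values, ra$values)
    expect_true(all(iv >= lo - 1e-12 & iv <= hi + 1e-12))
  }
})

test_that("classification maps the five levels with right-closed intervals", {
  vals <- c(0.39, 0.65, 0.75, 0.95, 1.2, 0.6, 0.7, 0.9, 1.0)
  got <- classify_ievi(mk_raster(vals))$levels[1, ]
  expect_equal(got, c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L, 4L))
  expect_error(classify_ievi(mk_raster(vals), breaks = c(0.7, 0.6)), "increasing")
})

test_that("classification partitions the real line", {
  v <- c(seq(-1, 2, by = 0.01), 0.6 + 1e-12, 0.7 - 1e-12)
  st <- classify_ievi(mk_raster(v))$levels[1, ]
  expect_true(all(st %in% 1:5))          # exactly one class each
  expect_true(all(diff(st[order(v)]) >= 0))  # monotone in the value
})

test_that("class area fractions are normalized over the domain", {
  k <- mk_cat(matrix(rep(c(1L, 2L), each = 50), 10, 10), n_states = 5)
  f <- class_area_fractions(k)
  expect_equal(f$fraction[1:2], c(0.5, 0.5))
  expect_equal(sum(f$fraction), 1)
  single <- mk_cat(matrix(3L, 4, 4), n_states = 5)
  expect_equal(class_area_fractions(single)$fraction[3], 1)
  empty_dom <- mk_mask(matrix(FALSE, 4, 4))
  expect_error(class_area_fractions(single, empty_dom), "no valid cells")
})

test_that("the assessment driver reproduces the stagewise computation", {
  sc <- scenario_presets(seed = 3)$two_islands
  sim <- simulate_island(sc)
  cfg <- synthetic_index_config()
  fit <- ievi_assess(sim$layers, cfg, sim$study_area)
  expect_s3_class(fit, "iev_assessment")
  # adaptability is spatially constant by construction
  av <- fit$objectives$adaptability$values[fit$objectives$adaptability$valid]
  expect_equal(unique(av), 0.6325)
  # manual recomputation of one cell path: exposure element B1 = steep slope / 2.25
  rc_manual <- standardize(sim$layers$steep_slope, cfg$indicators$steep_slope,
                           sim$study_area)
  expect_equal(fit$rc$steep_slope$values, rc_manual$values)
  expect_equal(sum(fit$fractions$fraction), 1)
  expect_error(ievi_assess(sim$layers[-1], cfg, sim$study_area), "steep_slope")
})

test_that("the shipped 23-indicator configuration is structurally valid", {
  cfg <- default_index_config()
  expect_length(cfg$indicators, 23)
  el <- vapply(cfg$indicators, function(s) s$element_id, "")
  ob <- vapply(cfg$indicators, function(s) s$objective, "")
  expect_setequal(unique(el), paste0("B", 1:8))
  expect_true(all(ob[el %in% c("B1", "B2")] == "exposure"))
  expect_true(all(ob[el %in% c("B3", "B4")] == "sensitivity"))
  expect_true(all(ob[el %in% paste0("B", 5:8)] == "adaptability"))
  for (e in unique(el)) {
    s <- sum(vapply(cfg$indicators[el == e], function(x) x$weight, 1))
    expect_lt(abs(s - 1), 0.02 + 1e-12)
  }
  expect_error(indicator_spec("bad", "B1", objective = "sensitivity"),
               "inconsistent")
})
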
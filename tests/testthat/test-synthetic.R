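test_that("identical scenarios produce bit-identical outputs", {
  sc <- scenario_presets(seed = 5)$two_islands
  a <- simulate_island(sc)
  b <- simulate_island(sc)
  expect_identical(a$land$member, b$land$member)
  expect_identical(lapply(a$layers, `[[`, "values"),
                   lapply(b$layers, `[[`, "values"))
  expect_identical(a$latent$values, b$latent$values)
  # a different seed changes the fields
  sc2 <- scenario_presets(seed = 6)$two_islands
  expect_false(identical(simulate_island(sc2)$latent$values, a$latent$values))
})

test_that("land geometry: buffer containment, two components, analytic area", {
  sc <- scenario_presets(seed = 1)$two_islands
  isl <- generate_island(sc)
  expect_true(all(isl$study_area$member[isl$land$member]))
  expect_equal(n_components(isl$land), 2)

  # rasterized circle of radius 10 cells is within 5% of pi r^2
  circ <- island_scenario(seed = 1, n_rows = 40, n_cols = 40, cell_size = 30,
                          ellipses = list(list(center = c(20, 20),
                                               semi_axes = c(10, 10))))
  n_land <- sum(generate_island(circ)$land$member)
  expect_lt(abs(n_land - pi * 100) / (pi * 100), 0.05)

  # an ellipse poking out of the grid is rejected
  bad <- island_scenario(seed = 1, n_rows = 20, n_cols = 20,
                         ellipses = list(list(center = c(3, 10),
                                              semi_axes = c(6, 6))))
  expect_error(generate_island(bad), "outside the grid")
})

test_that("link strength controls the dependence on the latent field", {
  base <- function(link, L = 3) {
    island_scenario(
      seed = 17, n_rows = 100, n_cols = 100, cell_size = 100,
      ellipses = list(list(center = c(50, 50), semi_axes = c(20, 20))),
      fields = list(x = list(mean = 1.2, sd = 0.3, corr_length = L,
                             link = link, polarity = "negative")),
      latent_corr_length = L
    )
  }
  # link 1: a deterministic monotone transform of the latent field
  f1 <- generate_fields(base(1))
  expect_equal(cor(as.vector(f1$fields$x$values),
                   as.vector(f1$latent$values), method = "spearman"), 1.0)
  # link 0: independent up to sampling noise at 10^4 cells
  f0 <- generate_fields(base(0))
  expect_lt(abs(cor(as.vector(f0$fields$x$values),
                    as.vector(f0$latent$values), method = "spearman")), 0.1)
})

test_that("the correlation length controls neighbor correlation", {
  neighbor_cor <- function(L) {
    sc <- island_scenario(
      seed = 23, n_rows = 100, n_cols = 100, cell_size = 100,
      ellipses = list(list(center = c(50, 50), semi_axes = c(20, 20))),
      fields = list(x = list(mean = 1.2, sd = 0.3, corr_length = L,
                             link = 0, polarity = "negative")),
      latent_corr_length = 1
    )
    v <- generate_fields(sc)$fields$x$values
    cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  expect_lt(abs(neighbor_cor(1)), 0.05)
  expect_gt(neighbor_cor(7), 0.5)
})

test_that("generated fields are strictly positive and full-grid valid", {
  for (p in c("two_islands", "independent", "deterministic")) {
    sim <- simulate_island(scenario_presets(seed = 2)[[p]])
    for (r in sim$layers) {
      expect_true(all(r$valid))
      expect_true(all(r$values > 0))
    }
  }
  expect_error(island_scenario(seed = 1, ellipses = list(),
                               fields = list(x = list(mean = 1, sd = 0,
                                                      corr_length = 1, link = 0))),
               "positive")
  expect_error(island_scenario(seed = 1, ellipses = list(),
                               fields = list(x = list(mean = 1, sd = 1,
                                                      corr_length = 1, link = 2))),
               "link")
})

test_that("preset dependence structure shows in the entropy ranking", {
  vars <- c("steep_slope", "land_dev", "npp", "groundwater", "soil")
  rules <- default_leveling_rules(c(vars, "result"))
  run <- function(preset) {
    sim <- simulate_island(scenario_presets(seed = 7)[[preset]])
    fit <- ievi_assess(sim$layers, synthetic_index_config(), sim$study_area)
    stack <- lapply(vars, function(v) discretize(fit$rc[[v]], rules[[v]]))
    names(stack) <- vars
    rank_key_indicators(discretize(fit$ievi, rules$result), stack,
                        sim$study_area)
  }
  indep <- run("independent")
  expect_false(any(indep$table$key))  # V stays near S(I) > 1 bit

  det <- run("deterministic")
  # every indicator is a monotone transform of the latent field driving the
  # result, so association is strong for all of them
  expect_true(all(det$table$entropy_difference < 1))
  expect_true(all(det$table$entropy_difference <
                    min(indep$table$entropy_difference)))
})
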
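test_that("an orthogonal one-hot code decodes with zero error", {
  res <- 5
  arena <- c(15, 15)
  coords <- gridvar:::decode_coords(arena, res)
  n_pos <- res * res
  maps <- array(0, c(n_pos, n_pos, 3))
  for (j in 1:3) maps[, , j] <- diag(n_pos) # each cell active in one bin
  err <- decode_fold(maps, held_out = 1, coords)
  expect_equal(err, rep(0, n_pos))
})

test_that("a single fixed cell leaves large lattice ambiguity", {
  pop <- tibble::tibble(cell = 1L, lambda = 85, theta = 6, phase_x = 10,
                        phase_y = 20, xmax = 20)
  ideal <- gridvar:::population_map_matrix(pop, c(150, 150), 50)
  stack <- gridvar:::noisy_map_stack(ideal, 10, seed = 5)
  coords <- gridvar:::decode_coords(c(150, 150), 50)
  err <- mean(decode_fold(stack, 1, coords))
  expect_gt(err, 20)
})

test_that("decoding error is invariant to permuting the cells", {
  spec <- grid_population_spec(n = 16)
  pop <- sample_population(spec, seed = 6)
  ideal <- gridvar:::population_map_matrix(pop, spec$arena, 30)
  stack <- gridvar:::noisy_map_stack(ideal, 4, seed = 7)
  coords <- gridvar:::decode_coords(spec$arena, 30)
  set.seed(19)
  perm <- sample(16)
  e1 <- decode_fold(stack, 2, coords)
  e2 <- decode_fold(stack[, perm, , drop = FALSE], 2, coords)
  # permuting cells only reorders floating-point sums; scores at near-tie
  # positions may resolve differently, so compare the error level
  expect_equal(mean(e1), mean(e2), tolerance = 0.01)
  expect_gt(mean(abs(e1 - e2) < 1e-9), 0.99)
})

test_that("shuffled templates decode at chance level", {
  spec <- grid_population_spec(n = 64)
  pop <- sample_population(spec, seed = 8)
  ideal <- gridvar:::population_map_matrix(pop, spec$arena, 50)
  stack <- gridvar:::noisy_map_stack(ideal, 3, seed = 9)
  coords <- gridvar:::decode_coords(spec$arena, 50)
  set.seed(10)
  shuffled <- ideal[sample(nrow(ideal)), ] # destroy the spatial code
  err <- mean(gridvar:::decode_against_template(stack[, , 1], shuffled,
                                                coords))
  expect_lt(abs(err - chance_error(spec$arena)), 5)
})

test_that("more noisy maps average toward lower error", {
  spec <- grid_population_spec(n = 64)
  errs <- vapply(c(2, 10), function(nm) {
    sw <- population_size_sweep(spec, ns = 64, n_noisy_maps = nm,
                                n_populations = 3, resolution = 30,
                                seed = 11)
    sw$summary$mean_error
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("error decreases with population size for variable populations", {
  sw <- population_size_sweep(grid_population_spec(), ns = c(16, 128),
                              n_populations = 3, resolution = 30, seed = 12)
  s <- sw$summary
  expect_lt(s$mean_error[s$n_cells == 128], s$mean_error[s$n_cells == 16])
  expect_equal(sw$chance_error, 0.5214 * 150, tolerance = 1e-3)
  # tidy/glance accessors
  expect_equal(nrow(tidy(sw)), 6)
  expect_equal(glance(sw)$n_cells_max, 128)
})

test_that("the sigma grid at (0, 0) matches the fixed-population sweep", {
  sg <- sigma_grid_search(sigma_lambda_values = 0, sigma_theta_values = 0,
                          n = 16, n_populations = 2, resolution = 30,
                          seed = 13)
  sw <- population_size_sweep(
    grid_population_spec(n = 16, sigma_lambda = 0, sigma_theta = 0),
    ns = 16, n_populations = 2, resolution = 30, seed = 13)
  expect_equal(sg$mean_error[1], sw$summary$mean_error[1])
  expect_s3_class(sg, "sigma_grid")
})

test_that("large variability drives the error toward zero", {
  sg <- sigma_grid_search(sigma_lambda_values = c(0, 5),
                          sigma_theta_values = c(0, 5),
                          n = 128, n_populations = 2, resolution = 30,
                          seed = 14)
  e00 <- sg$mean_error[sg$sigma_lambda == 0 & sg$sigma_theta == 0]
  e55 <- sg$mean_error[sg$sigma_lambda == 5 & sg$sigma_theta == 5]
  expect_lt(e55, e00 / 2)
})

test_that("an empty second module reduces to single-module decoding", {
  spec <- grid_population_spec(n = 16)
  tm <- two_module_decode(spec, ns = 16, fraction_second = 0,
                          n_populations = 2, resolution = 30, seed = 15)
  sw <- population_size_sweep(spec, ns = 16, n_populations = 2,
                              resolution = 30, seed = 15)
  expect_equal(tm$summary$mean_error, sw$summary$mean_error)
})

test_that("two consecutive fixed-property modules decode near zero", {
  spec <- grid_population_spec(sigma_lambda = 0, sigma_theta = 0)
  tm <- two_module_decode(spec, ns = 256, relation = "consecutive",
                          n_populations = 2, resolution = 40, seed = 16)
  one <- population_size_sweep(spec, ns = 256, n_populations = 2,
                               resolution = 40, seed = 16)
  expect_lt(tm$summary$mean_error, one$summary$mean_error / 3)
  expect_lt(tm$summary$mean_error, 10)
})

test_that("skip-module ambiguity is relieved by grid-property variability", {
  fixed <- grid_population_spec(sigma_lambda = 0, sigma_theta = 0)
  vab <- grid_population_spec()
  tm0 <- two_module_decode(fixed, ns = 256, relation = "skip",
                           orientation_offset = 0, n_populations = 2,
                           resolution = 40, seed = 17)
  tm1 <- two_module_decode(vab, ns = 256, relation = "skip",
                           orientation_offset = 0, n_populations = 2,
                           resolution = 40, seed = 17)
  expect_gt(tm0$summary$mean_error, tm1$summary$mean_error)
})

test_that("recorded-session decoding beats chance and caps subpop sizes", {
  rec <- fixture("decode_session", {
    simulate_session(grid_population_spec(n = 6), duration_s = 30 * 60,
                     seed = 81)
  })
  expect_warning(
    res <- decode_recorded(rec, grid_config(), subpop_sizes = c(2, 4, 8),
                           n_splits = 3, n_subpops = 3, seed = 82),
    "capped")
  s <- res$summary
  expect_equal(s$n_cells, c(2, 4, 6))
  expect_lt(min(s$mean_error), res$chance_error)
  expect_true(all(diff(s$mean_error) <= 5)) # error does not blow up with n
})

test_that("normalizing by a shared peak rate leaves decoding unchanged", {
  res <- 10
  coords <- gridvar:::decode_coords(c(30, 30), res)
  set.seed(90)
  test <- matrix(rexp(res^2 * 5), res^2, 5)
  template <- matrix(rexp(res^2 * 5), res^2, 5)
  e1 <- gridvar:::decode_against_template(test, template, coords)
  e2 <- gridvar:::decode_against_template(test / 7, template / 7, coords)
  expect_equal(e1, e2)
})
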
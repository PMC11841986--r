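test_that("split halves are balanced, disjoint, and cover the used bins", {
  rec <- small_session()
  sp <- split_halves(rec, bin_seconds = 30, seed = 3)
  # balance: total occupancy differs by at most one bin's duration
  da <- recording_duration(sp$a)
  db <- recording_duration(sp$b)
  expect_lt(abs(da - db), 30 + 1)
  expect_equal(sum(sp$assignment), sp$n_bins_used / 2)
  # disjoint partition of the used bins
  ta <- sp$a$positions$t
  tb <- sp$b$positions$t
  expect_length(intersect(ta, tb), 0)
  t0 <- rec$positions$t[1]
  used <- rec$positions$t < t0 + sp$n_bins_used * 30
  expect_equal(sort(c(ta, tb)), rec$positions$t[used])
  # spikes split with their bins
  for (u in rec$unit_ids) {
    expect_length(intersect(sp$a$spikes[[u]], sp$b$spikes[[u]]), 0)
  }
})

test_that("a 130-minute recording splits into 260 bins, 130 per half", {
  pos <- data.frame(t = seq(0, 130 * 60, 1), x = 75, y = 75)
  rec <- grid_recording(pos, list(u1 = numeric(0)))
  sp <- split_halves(rec, 30, seed = 1)
  expect_equal(sp$n_bins_used, 260)
  expect_equal(sum(sp$assignment), 130)
})

test_that("recordings shorter than two bins refuse to split", {
  pos <- data.frame(t = seq(0, 40, 0.5), x = 75, y = 75)
  rec <- grid_recording(pos, list(u1 = numeric(0)))
  expect_error(split_halves(rec, 30), "shorter")
})

test_that("cells with identical tuning show within ~ between variability", {
  # two cells, same (lambda, theta, phase): between-cell differences are
  # then exchangeable with within-cell ones
  spec <- grid_population_spec(n = 1, sigma_lambda = 0, sigma_theta = 0)
  traj <- simulate_trajectory(40 * 60, seed = 31)
  par <- list(lambda = 85, theta = 6, px = 40, py = 70, xmax = 12)
  sp1 <- generate_spikes(traj, par$lambda, par$theta, par$px, par$py,
                         par$xmax, seed = 32)
  sp2 <- generate_spikes(traj, par$lambda, par$theta, par$px, par$py,
                         par$xmax, seed = 33)
  rec <- grid_recording(as.data.frame(traj), list(a = sp1, b = sp2))
  vr <- shuffle_analysis(rec, grid_config(n_shuffles = 20), seed = 34)
  cells <- tidy(vr)
  gap_l <- cells$mean_between_dlambda - cells$mean_within_dlambda
  gap_t <- cells$mean_between_dtheta - cells$mean_within_dtheta
  # no systematic excess: gaps are small relative to the within level
  expect_lt(max(abs(gap_l)), 1.5 * max(cells$mean_within_dlambda))
  expect_lt(max(abs(gap_t)), 1.5 * max(cells$mean_within_dtheta))
})

test_that("heterogeneous modules show between > within for most cells", {
  rec <- fixture("var_session_15", {
    simulate_session(grid_population_spec(n = 8), duration_s = 40 * 60,
                     seed = 41)
  })
  vr <- shuffle_analysis(rec, grid_config(n_shuffles = 20), seed = 42)
  cells <- tidy(vr)[tidy(vr)$accepted, ]
  expect_gte(nrow(cells), 5)
  expect_gt(mean(cells$mean_between_dlambda > cells$mean_within_dlambda),
            0.7)
})

test_that("the reliability filter applies a strict poor-fit cap", {
  fake <- structure(
    list(cells = tibble::tibble(
      unit_id = c("ok", "edge", "bad"),
      mean_within_dtheta = 1, mean_between_dtheta = 2,
      mean_within_dlambda = 1, mean_between_dlambda = 2,
      n_poor_fits = c(4, 5, 60), n_shuffles = 100,
      grid_score = 1, accepted = NA),
      config = grid_config(), n_shuffles = 100),
    class = "grid_variability")
  expect_message(kept <- reliability_filter(fake), "1/3")
  expect_identical(kept$unit_id, "ok") # 4% < 5% kept; 5% and 60% rejected
})

test_that("an unstructured cell is rejected by the reliability criterion", {
  traj <- simulate_trajectory(20 * 60, seed = 51)
  dur <- max(traj$t)
  rand_times <- function(s, n) {
    set.seed(s)
    sort(runif(n, 0, dur))
  }
  rec <- grid_recording(as.data.frame(traj),
                        list(noise1 = rand_times(52, 3000),
                             noise2 = rand_times(53, 3000)))
  vr <- shuffle_analysis(rec, grid_config(n_shuffles = 10), seed = 54)
  expect_true(all(!tidy(vr)$accepted))
})

test_that("population summary flags direction and extremes correctly", {
  n <- 12
  set.seed(61)
  cells <- tibble::tibble(
    unit_id = paste0("c", 1:n),
    mean_within_dtheta = runif(n, 0.5, 1.5),
    mean_within_dlambda = runif(n, 1, 3),
    n_poor_fits = 0, n_shuffles = 100, grid_score = runif(n, 0.9, 1.5),
    accepted = TRUE)
  cells$mean_between_dtheta <- cells$mean_within_dtheta + runif(n, 0.2, 1)
  cells$mean_between_dlambda <- cells$mean_within_dlambda + runif(n, 1, 4)
  s <- summarize_variability(cells)
  expect_equal(s$pct_between_gt_within_theta, 100)
  expect_equal(s$pct_between_gt_within_lambda, 100)
  expect_lt(s$p_theta, 0.05)
  expect_lt(s$p_lambda, 0.05)
  # swapping within and between flips the one-sided test
  swapped <- cells
  swapped$mean_between_dlambda <- cells$mean_within_dlambda
  swapped$mean_within_dlambda <- cells$mean_between_dlambda
  s2 <- summarize_variability(swapped)
  expect_gte(s2$p_lambda, 0.5)
  expect_equal(s2$pct_between_gt_within_lambda, 0)
})

test_that("too few accepted cells yield an all-NA summary", {
  cells <- tibble::tibble(
    unit_id = c("a", "b"),
    mean_within_dtheta = 1, mean_between_dtheta = 2,
    mean_within_dlambda = 1, mean_between_dlambda = 2,
    n_poor_fits = 0, n_shuffles = 100, grid_score = 1, accepted = TRUE)
  expect_warning(s <- summarize_variability(cells), "fewer than 5")
  expect_equal(s$n_accepted, 2)
  expect_true(is.na(s$p_lambda))
})

test_that("shuffle substreams make the analysis reproducible", {
  rec <- small_session()
  cfg <- grid_config(n_shuffles = 5)
  v1 <- shuffle_analysis(rec, cfg, seed = 71)
  v2 <- shuffle_analysis(rec, cfg, seed = 71)
  expect_equal(tidy(v1), tidy(v2))
  v3 <- shuffle_analysis(rec, cfg, seed = 72)
  expect_false(isTRUE(all.equal(tidy(v1)$mean_within_dlambda,
                                tidy(v3)$mean_within_dlambda)))
})
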
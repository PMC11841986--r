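# Cross-validated linear template decoding of position from grid-cell
# population activity.

# Bin-centre coordinates (cm, corner origin) of a resolution x resolution
# grid over the arena, row-major in x-fastest order matching matrix
# vectorization of [nx, ny] maps.
decode_coords <- function(arena, resolution) {
  bs_x <- arena[1] / resolution
  bs_y <- arena[2] / resolution
  xc <- (seq_len(resolution) - 0.5) * bs_x
  yc <- (seq_len(resolution) - 0.5) * bs_y
  cbind(x = rep(xc, resolution), y = rep(yc, each = resolution))
}

# Ideal rate maps of a population as a (n_positions x n_cells) matrix on
# the decoder grid.
population_map_matrix <- function(pop, arena, resolution) {
  n_pos <- resolution * resolution
  m <- matrix(0, n_pos, nrow(pop))
  if (nrow(pop) == 0) return(m)
  bs <- arena[1] / resolution
  for (i in seq_len(nrow(pop))) {
    im <- ideal_rate_map(pop$lambda[i], pop$theta[i], pop$phase_x[i],
                         pop$phase_y[i], pop$xmax[i], arena = arena,
                         bin_size = bs)
    m[, i] <- as.vector(im$values)
  }
  m
}

# Poisson noisy map stack: array [n_positions, n_cells, n_maps].
noisy_map_stack <- function(ideal_matrix, n_maps, seed = NULL) {
  with_seed(seed, {
    d <- dim(ideal_matrix)
    draws <- rpois(d[1] * d[2] * n_maps, rep(as.vector(ideal_matrix), n_maps))
    array(as.numeric(draws), c(d[1], d[2], n_maps))
  })
}

#' Mean distance between two uniform points in the arena (chance error)
#'
#' Exact for a square arena (`L * (2 + sqrt(2) + 5 * asinh(1)) / 15`,
#' about `0.5214 * L`); Monte-Carlo otherwise.
#'
#' @param arena `c(Lx, Ly)` in cm.
#' @param n_mc Monte-Carlo sample size for non-square arenas.
#' @return Chance decoding error in cm.
#' @export
chance_error <- function(arena, n_mc = 2e5) {
  if (isTRUE(all.equal(arena[1], arena[2]))) {
    return(arena[1] * (2 + sqrt(2) + 5 * asinh(1)) / 15)
  }
  p <- matrix(runif(4 * n_mc), ncol = 4)
  mean(sqrt(((p[, 1] - p[, 2]) * arena[1])^2 +
              ((p[, 3] - p[, 4]) * arena[2])^2))
}

#' Decode one cross-validation fold
#'
#' The template for each cell is the mean of its non-held-out noisy maps.
#' The activity of the held-out maps at each true position is multiplied
#' against the templates at every candidate position; the decoded position
#' is the candidate with the largest summed product (ties broken by the
#' first index in column-major order), and the error is the Euclidean
#' distance to the true position.
#'
#' @param noisy_maps Array `[n_positions, n_cells, n_maps]` on a common
#'   spatial grid (from the internal stack builder or user-supplied).
#' @param held_out Index of the map used as test data.
#' @param coords `n_positions x 2` matrix of bin-centre coordinates (cm).
#' @return Numeric vector of per-position decoding errors (cm).
#' @export
decode_fold <- function(noisy_maps, held_out, coords) {
  d <- dim(noisy_maps)
  if (nrow(coords) != d[1]) abort("coords do not match the map grid")
  if (d[3] < 2) abort("need at least 2 noisy maps per cell")
  test <- noisy_maps[, , held_out, drop = TRUE]
  if (is.null(dim(test))) test <- matrix(test, d[1], d[2])
  template <- (rowSums(noisy_maps, dims = 2) - test) / (d[3] - 1)
  decode_against_template(test, template, coords)
}

# Shared argmax rule: rows of `test` and `template` index positions,
# columns cells. Returns per-position error (cm).
decode_against_template <- function(test, template, coords) {
  scores <- tcrossprod(test, template) # [true position, candidate]
  decoded <- max.col(scores, ties.method = "first")
  sqrt((coords[, 1] - coords[decoded, 1])^2 +
         (coords[, 2] - coords[decoded, 2])^2)
}

new_decoding_result <- function(results, summary, chance, spec = NULL,
                                config = list()) {
  structure(
    list(results = results, summary = summary, chance_error = chance,
         spec = spec, config = config),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> chance %.1f cm\n", x$chance_error))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decoding_result <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.decoding_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$n_cells), ]
  tibble(n_cells_max = best$n_cells, mean_error = best$mean_error,
         sd_error = best$sd_error, chance_error = x$chance_error,
         n_populations = x$config$n_populations %||% NA_integer_)
}

#' Decoding error as a function of population size
#'
#' For each of `n_populations` independently sampled populations, draws
#' `n_noisy_maps` Poisson maps per cell, runs all leave-one-map-out folds,
#' and averages the decoding error over positions and folds; populations of
#' each size in `ns` are nested subsets of the largest one. The summary
#' reports the mean and SD across populations per size.
#'
#' @param spec A [grid_population_spec()] (its `n` is ignored in favour of
#'   `ns`).
#' @param ns Population sizes, ascending.
#' @param n_noisy_maps Noisy maps per cell.
#' @param n_populations Independent populations.
#' @param resolution Decoder grid bins per arena side.
#' @param seed Integer seed; populations and noise use derived substreams.
#' @return A `decoding_result`; `tidy()` gives per-(population, size) mean
#'   errors, `glance()` the largest-size summary.
#' @export
#' @examples
#' \donttest{
#' res <- population_size_sweep(grid_population_spec(), ns = c(4, 16),
#'                              n_populations = 2, seed = 1)
#' res$summary
#' }
population_size_sweep <- function(spec, ns = 2^(4:10), n_noisy_maps = 10,
                                  n_populations = 25, resolution = 50,
                                  seed = 1L) {
  ns <- sort(as.integer(ns))
  coords <- decode_coords(spec$arena, resolution)
  rows <- vector("list", n_populations * length(ns))
  r <- 0L
  for (p in seq_len(n_populations)) {
    spec_max <- spec
    spec_max$n <- max(ns)
    pop <- sample_population(spec_max, seed = derive_seed(seed, "cells", p))
    ideal <- population_map_matrix(pop, spec$arena, resolution)
    stack <- noisy_map_stack(ideal, n_noisy_maps,
                             seed = derive_seed(seed, "noise", p))
    for (n in ns) {
      sub <- stack[, seq_len(n), , drop = FALSE]
      err <- mean(vapply(seq_len(n_noisy_maps), function(j) {
        mean(decode_fold(sub, j, coords))
      }, numeric(1)))
      r <- r + 1L
      rows[[r]] <- tibble(population = p, n_cells = n, mean_error = err)
    }
  }
  results <- bind_rows(rows)
  summary <- results |>
    group_by(.data$n_cells) |>
    summarise(sd_error = sd(.data$mean_error),
              mean_error = mean(.data$mean_error), .groups = "drop") |>
    select("n_cells", "mean_error", "sd_error")
  new_decoding_result(
    results, summary, chance_error(spec$arena), spec = spec,
    config = list(ns = ns, n_noisy_maps = n_noisy_maps,
                  n_populations = n_populations, resolution = resolution,
                  seed = seed))
}

#' Decoding error over a grid of variability values
#'
#' Runs one decoding experiment (fixed population size) for every pair of
#' spacing / orientation SDs, mirroring the 6 x 6 search over
#' `[0..5 cm] x [0..5 deg]` at `n = 1024`.
#'
#' @param lambda_hat,theta_hat Module means (cm, deg).
#' @param sigma_lambda_values,sigma_theta_values SD grids (cm, deg).
#' @param n Cells per population.
#' @param n_noisy_maps,n_populations,resolution,seed As in
#'   [population_size_sweep()].
#' @param arena `c(Lx, Ly)` cm.
#' @return Tibble with class `"sigma_grid"`: `sigma_lambda`, `sigma_theta`,
#'   `mean_error`, `sd_error` (across populations).
#' @export
sigma_grid_search <- function(lambda_hat = 85, theta_hat = 6,
                              sigma_lambda_values = 0:5,
                              sigma_theta_values = 0:5,
                              n = 1024, n_noisy_maps = 10,
                              n_populations = 25, resolution = 50,
                              arena = c(150, 150), seed = 1L) {
  stopifnot(length(sigma_lambda_values) > 0, length(sigma_theta_values) > 0)
  grid <- tidyr::expand_grid(sigma_lambda = sigma_lambda_values,
                             sigma_theta = sigma_theta_values)
  res <- purrr::pmap(grid, function(sigma_lambda, sigma_theta) {
    spec <- grid_population_spec(
      n = n, lambda_hat = lambda_hat, theta_hat = theta_hat,
      sigma_lambda = sigma_lambda, sigma_theta = sigma_theta, arena = arena)
    sw <- population_size_sweep(spec, ns = n, n_noisy_maps = n_noisy_maps,
                                n_populations = n_populations,
                                resolution = resolution, seed = seed)
    sw$summary[1, c("mean_error", "sd_error")]
  })
  out <- dplyr::bind_cols(grid, bind_rows(res))
  class(out) <- c("sigma_grid", class(out))
  attr(out, "config") <- list(n = n, n_noisy_maps = n_noisy_maps,
                              n_populations = n_populations,
                              resolution = resolution, seed = seed)
  out
}

#' Decoding from two concatenated grid modules
#'
#' Builds a second module whose mean spacing follows the experimentally
#' observed module-scale progression: `consecutive` sets
#' `lambda_hat_2 = sqrt(2) * lambda_hat_1`, `skip` sets
#' `lambda_hat_2 = 2 * lambda_hat_1` (modules two steps apart). The second
#' module's mean orientation is offset by `orientation_offset` degrees.
#' Cells from both modules are concatenated (split
#' `fraction_second` / `1 - fraction_second` at each total size) and
#' decoded as one population. With `fraction_second = 0` this reduces
#' exactly to single-module decoding.
#'
#' @param spec Module-1 [grid_population_spec()].
#' @param ns Total population sizes.
#' @param relation `"consecutive"` or `"skip"`.
#' @param orientation_offset Degrees added to module 2's mean orientation.
#' @param fraction_second Fraction of each population drawn from module 2.
#' @param n_noisy_maps,n_populations,resolution,seed As in
#'   [population_size_sweep()].
#' @return A `decoding_result`.
#' @export
two_module_decode <- function(spec, ns = 2^(4:10),
                              relation = c("consecutive", "skip"),
                              orientation_offset = 15, fraction_second = 0.5,
                              n_noisy_maps = 10, n_populations = 25,
                              resolution = 50, seed = 1L) {
  relation <- match.arg(relation)
  ratio <- if (relation == "consecutive") sqrt(2) else 2
  spec2 <- spec
  spec2$lambda_hat <- spec$lambda_hat * ratio
  spec2$sigma_lambda <- spec$sigma_lambda * ratio
  spec2$theta_hat <- spec$theta_hat + orientation_offset
  ns <- sort(as.integer(ns))
  n2 <- as.integer(round(ns * fraction_second))
  n1 <- ns - n2
  coords <- decode_coords(spec$arena, resolution)
  rows <- vector("list", n_populations * length(ns))
  r <- 0L
  for (p in seq_len(n_populations)) {
    s1 <- spec; s1$n <- max(n1)
    s2 <- spec2; s2$n <- max(n2)
    pop1 <- sample_population(s1, seed = derive_seed(seed, "cells", p))
    pop2 <- sample_population(s2, seed = derive_seed(seed, "cells2", p))
    ideal <- cbind(population_map_matrix(pop1, spec$arena, resolution),
                   population_map_matrix(pop2, spec$arena, resolution))
    stack <- noisy_map_stack(ideal, n_noisy_maps,
                             seed = derive_seed(seed, "noise", p))
    for (i in seq_along(ns)) {
      cols <- c(seq_len(n1[i]),
                if (n2[i] > 0) max(n1) + seq_len(n2[i]) else integer(0))
      sub <- stack[, cols, , drop = FALSE]
      err <- mean(vapply(seq_len(n_noisy_maps), function(j) {
        mean(decode_fold(sub, j, coords))
      }, numeric(1)))
      r <- r + 1L
      rows[[r]] <- tibble(population = p, n_cells = ns[i],
                          n_module1 = n1[i], n_module2 = n2[i],
                          mean_error = err)
    }
  }
  results <- bind_rows(rows)
  summary <- results |>
    group_by(.data$n_cells) |>
    summarise(sd_error = sd(.data$mean_error),
              mean_error = mean(.data$mean_error), .groups = "drop") |>
    select("n_cells", "mean_error", "sd_error")
  new_decoding_result(
    results, summary, chance_error(spec$arena), spec = spec,
    config = list(ns = ns, relation = relation,
                  orientation_offset = orientation_offset,
                  fraction_second = fraction_second,
                  n_noisy_maps = n_noisy_maps,
                  n_populations = n_populations, resolution = resolution,
                  seed = seed))
}

#' Decode position from a recorded (or simulated) session
#'
#' Splits the session into `n_time_bins` contiguous temporal bins and
#' builds one occupancy-normalized rate map per cell per bin, normalized
#' per cell by its maximal activity. For each random subpopulation and each
#' train/test split, half the time bins are averaged into templates and the
#' other half into test maps, and the same argmax rule as for synthetic
#' data is applied over the session's visited bins.
#'
#' @param rec A [grid_recording()].
#' @param config A [grid_config()] (bin size and smoothing).
#' @param subpop_sizes Subpopulation sizes; sizes exceeding the available
#'   cells are capped with a warning.
#' @param units Cells to draw from (default: all units).
#' @param n_time_bins Temporal bins (even).
#' @param n_splits Random train/test splits per subpopulation.
#' @param n_subpops Random subpopulations per size.
#' @param seed Integer seed.
#' @return A `decoding_result` (errors averaged over visited bins, splits
#'   and subpopulations).
#' @export
decode_recorded <- function(rec, config = grid_config(),
                            subpop_sizes = 2^(0:6), units = NULL,
                            n_time_bins = 10, n_splits = 10, n_subpops = 25,
                            seed = 1L) {
  units <- units %||% rec$unit_ids
  n_avail <- length(units)
  subpop_sizes <- sort(unique(as.integer(subpop_sizes)))
  if (any(subpop_sizes > n_avail)) {
    warn(sprintf("subpopulation sizes capped at the %d available cells",
                 n_avail))
    subpop_sizes <- unique(pmin(subpop_sizes, n_avail))
  }
  t <- rec$positions$t
  t0 <- t[1]
  edges <- seq(t0, t[length(t)], length.out = n_time_bins + 1)
  edges[n_time_bins + 1] <- edges[n_time_bins + 1] + 1e-9
  full_occ <- compute_occupancy(rec, config$bin_size_cm)
  visited <- full_occ >= 0.99 * median(rec$positions$dwell)
  vis_idx <- which(as.vector(visited))
  coords_all <- decode_coords(rec$arena,
                              n_bins_for(rec$arena[1], config$bin_size_cm))
  # per cell x time-bin rate maps, flattened to visited bins, max-normalized
  maps <- array(0, c(length(vis_idx), n_avail, n_time_bins))
  for (b in seq_len(n_time_bins)) {
    sub <- subset_recording_time(rec, matrix(edges[c(b, b + 1)], 1))
    for (i in seq_len(n_avail)) {
      rm_b <- compute_rate_map(sub, units[i], config$bin_size_cm,
                               config$ratemap_smooth_sigma_bins)
      v <- as.vector(rm_b$values)[vis_idx]
      v[is.na(v)] <- 0
      maps[, i, b] <- v
    }
  }
  for (i in seq_len(n_avail)) {
    mx <- max(maps[, i, ])
    if (mx > 0) maps[, i, ] <- maps[, i, ] / mx
  }
  coords <- coords_all[vis_idx, , drop = FALSE]
  rows <- vector("list", n_subpops * n_splits * length(subpop_sizes))
  r <- 0L
  for (sp in seq_len(n_subpops)) {
    cells_sp <- with_seed(derive_seed(seed, "subpop", sp),
                          sample.int(n_avail, max(subpop_sizes)))
    for (s in seq_len(n_splits)) {
      train_bins <- with_seed(derive_seed(seed, "split", sp * 1000L + s),
                              sample.int(n_time_bins, n_time_bins %/% 2L))
      test_bins <- setdiff(seq_len(n_time_bins), train_bins)
      for (n in subpop_sizes) {
        idx <- cells_sp[seq_len(n)]
        template <- apply(maps[, idx, train_bins, drop = FALSE], c(1, 2),
                          mean)
        test <- apply(maps[, idx, test_bins, drop = FALSE], c(1, 2), mean)
        err <- mean(decode_against_template(test, template, coords))
        r <- r + 1L
        rows[[r]] <- tibble(subpop = sp, split = s, n_cells = n,
                            mean_error = err)
      }
    }
  }
  results <- bind_rows(rows)
  summary <- results |>
    group_by(.data$n_cells) |>
    summarise(sd_error = sd(.data$mean_error),
              mean_error = mean(.data$mean_error), .groups = "drop") |>
    select("n_cells", "mean_error", "sd_error")
  new_decoding_result(
    results, summary, chance_error(rec$arena),
    config = list(subpop_sizes = subpop_sizes, n_time_bins = n_time_bins,
                  n_splits = n_splits, n_subpops = n_subpops, seed = seed))
}
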
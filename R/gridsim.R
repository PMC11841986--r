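# Synthetic grid-cell populations and recordings with known ground truth.

#' Specification of a synthetic grid-cell population
#'
#' Describes a single module: cell count, the module-mean spacing
#' `lambda_hat` (cm) and orientation `theta_hat` (deg), the within-module
#' standard deviations `sigma_lambda` (cm) and `sigma_theta` (deg), the
#' arena, and the peak-rate distribution. Defaults match the module the
#' heterogeneity analysis is calibrated to: 85 cm spacing, 6 deg
#' orientation, 5 cm / 1 deg variability, a 1.5 m x 1.5 m arena, and peak
#' rates drawn Normal(13, 8) Hz saturated into [2, 30] Hz.
#'
#' @param n Number of cells.
#' @param lambda_hat,sigma_lambda Mean and SD of grid spacing (cm).
#' @param theta_hat,sigma_theta Mean and SD of grid orientation (deg).
#' @param arena `c(Lx, Ly)` in cm.
#' @param xmax_mean,xmax_sd,xmax_clip Peak firing rate distribution (Hz):
#'   Gaussian, with values outside `xmax_clip` set to the nearer bound.
#' @return A list with class `"grid_population_spec"`.
#' @export
grid_population_spec <- function(n = 30, lambda_hat = 85, theta_hat = 6,
                                 sigma_lambda = 5, sigma_theta = 1,
                                 arena = c(150, 150),
                                 xmax_mean = 13, xmax_sd = 8,
                                 xmax_clip = c(2, 30)) {
  stopifnot(n >= 0, lambda_hat > 0, sigma_lambda >= 0, sigma_theta >= 0,
            xmax_clip[1] < xmax_clip[2])
  structure(
    list(n = as.integer(n), lambda_hat = lambda_hat, theta_hat = theta_hat,
         sigma_lambda = sigma_lambda, sigma_theta = sigma_theta,
         arena = as.numeric(arena), xmax_mean = xmax_mean, xmax_sd = xmax_sd,
         xmax_clip = as.numeric(xmax_clip)),
    class = "grid_population_spec"
  )
}

#' @export
print.grid_population_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_population_spec> %d cells; lambda %g +/- %g cm; theta %g +/- %g deg\n",
    x$n, x$lambda_hat, x$sigma_lambda, x$theta_hat, x$sigma_theta))
  invisible(x)
}

#' Sample per-cell grid parameters from a population specification
#'
#' Spacing and orientation are Gaussian with the spec's means and SDs,
#' phases are uniform over the arena, and peak rates are Gaussian saturated
#' at the clip bounds (sampled values outside the range are set to the
#' boundary, leaving point masses at the bounds). Non-positive spacing draws
#' (possible only under extreme `sigma_lambda`) are redrawn.
#'
#' @param spec A [grid_population_spec()].
#' @param seed Optional integer seed (isolated from the global RNG stream).
#' @return Tibble with one row per cell: `cell`, `lambda` (cm), `theta`
#'   (deg), `phase_x`, `phase_y` (cm), `xmax` (Hz).
#' @export
#' @examples
#' pop <- sample_population(grid_population_spec(n = 5), seed = 1)
#' pop
sample_population <- function(spec, seed = NULL) {
  with_seed(seed, {
    n <- spec$n
    if (n == 0L) {
      return(tibble(cell = integer(0), lambda = numeric(0),
                    theta = numeric(0), phase_x = numeric(0),
                    phase_y = numeric(0), xmax = numeric(0)))
    }
    lambda <- rnorm(n, spec$lambda_hat, spec$sigma_lambda)
    bad <- which(lambda <= 0)
    while (length(bad)) {
      lambda[bad] <- rnorm(length(bad), spec$lambda_hat, spec$sigma_lambda)
      bad <- which(lambda <= 0)
    }
    theta <- rnorm(n, spec$theta_hat, spec$sigma_theta)
    xmax <- rnorm(n, spec$xmax_mean, spec$xmax_sd)
    xmax <- pmin(pmax(xmax, spec$xmax_clip[1]), spec$xmax_clip[2])
    tibble(
      cell = seq_len(n),
      lambda = lambda,
      theta = theta,
      phase_x = runif(n, 0, spec$arena[1]),
      phase_y = runif(n, 0, spec$arena[2]),
      xmax = xmax
    )
  })
}

# Rate of the three-plane-wave grid model at centred coordinates (cm).
# Wave vectors have magnitude 4*pi/(sqrt(3)*lambda) and directions at
# theta + 30, theta + 90, theta + 150 deg, which places the lattice axes
# (real-space peak directions) at theta, theta + 60, theta + 120 deg with
# nearest-peak distance exactly lambda.
grid_rate_at <- function(x, y, lambda, theta, phase_x = 0, phase_y = 0,
                         xmax = 1) {
  k <- 4 * pi / (sqrt(3) * lambda)
  ang <- (theta + c(30, 90, 150)) * pi / 180
  s <- 0
  for (j in 1:3) {
    kx <- k * cos(ang[j]); ky <- k * sin(ang[j])
    s <- s + cos(kx * (x + phase_x) + ky * (y + phase_y))
  }
  xmax * (2 / 3) * (s / 3 + 1 / 2)
}

#' Noiseless rate map of an ideal grid cell
#'
#' Evaluates the three-plane-wave grid model on the bin centres of a regular
#' map covering the arena (coordinates centred on the arena middle). The
#' rate peaks at `xmax` on the lattice (at `x = -phase`) and reaches 0 at
#' the lattice minima.
#'
#' @param lambda Grid spacing (cm).
#' @param theta Grid orientation (deg).
#' @param phase_x,phase_y Grid phase (cm).
#' @param xmax Peak firing rate (Hz).
#' @param arena `c(Lx, Ly)` in cm.
#' @param bin_size Bin side (cm).
#' @return A `rate_map` with all bins visited and unit occupancy.
#' @export
ideal_rate_map <- function(lambda, theta, phase_x = 0, phase_y = 0, xmax = 1,
                           arena = c(150, 150), bin_size = 3) {
  nx <- n_bins_for(arena[1], bin_size)
  ny <- n_bins_for(arena[2], bin_size)
  xc <- -arena[1] / 2 + (seq_len(nx) - 0.5) * bin_size
  yc <- -arena[2] / 2 + (seq_len(ny) - 0.5) * bin_size
  xm <- matrix(rep(xc, ny), nx, ny)
  ym <- matrix(rep(yc, each = nx), nx, ny)
  vals <- grid_rate_at(xm, ym, lambda, theta, phase_x, phase_y, xmax)
  vals[vals < 0] <- 0 # guard against float dust below the analytic minimum
  new_rate_map(vals, occupancy = matrix(1, nx, ny), bin_size = bin_size,
               visited = matrix(TRUE, nx, ny), arena = arena)
}

#' Poisson-noisy rate map from an ideal map
#'
#' Draws each bin independently from a Poisson distribution whose mean is
#' the ideal rate times `dwell` (default 1: counts with mean equal to the
#' rate value, matching direct sampling of the rate map).
#'
#' @param ideal A `rate_map` with non-negative values.
#' @param dwell Effective dwell multiplier applied to the mean.
#' @param seed Optional integer seed.
#' @return A `rate_map` of non-negative integer counts.
#' @export
poisson_noisy_map <- function(ideal, dwell = 1, seed = NULL) {
  vals <- ideal$values
  stopifnot(all(vals[ideal$visited] >= 0))
  with_seed(seed, {
    out <- ideal
    draw <- rpois(length(vals), as.vector(vals) * dwell)
    out$values <- matrix(as.numeric(draw), nrow(vals), ncol(vals))
    out$values[!ideal$visited] <- NA_real_
    out
  })
}

#' Simulate a smooth foraging trajectory
#'
#' Ornstein-Uhlenbeck velocity process (independent in x and y) folded into
#' the arena by reflection at the walls; the stationary speed distribution
#' is Rayleigh with mean `speed_cm_s`. Intended only to give roughly uniform
#' arena coverage for rate-map estimation.
#'
#' @param duration_s Duration (s).
#' @param dt_s Sampling interval (s).
#' @param arena `c(Lx, Ly)` in cm.
#' @param speed_cm_s Target mean running speed (cm/s).
#' @param tau_s Velocity correlation time (s).
#' @param seed Optional integer seed.
#' @return Tibble `t`, `x`, `y` with `floor(duration/dt) + 1` rows.
#' @export
simulate_trajectory <- function(duration_s, dt_s = 0.02, arena = c(150, 150),
                                speed_cm_s = 15, tau_s = 0.7, seed = NULL) {
  stopifnot(duration_s > 0, dt_s > 0)
  with_seed(seed, {
    n <- as.integer(floor(duration_s / dt_s)) + 1L
    sv <- speed_cm_s / sqrt(pi / 2) # per-component stationary SD
    a <- exp(-dt_s / tau_s)
    b <- sv * sqrt(1 - a^2)
    step_ou <- function() {
      v0 <- sv * rnorm(1) # stationary start
      as.numeric(stats::filter(b * rnorm(n), a, method = "recursive",
                               init = v0))
    }
    fold <- function(p, len) {
      q <- p %% (2 * len)
      ifelse(q <= len, q, 2 * len - q)
    }
    vx <- step_ou(); vy <- step_ou()
    x <- fold(arena[1] / 2 + cumsum(vx) * dt_s, arena[1])
    y <- fold(arena[2] / 2 + cumsum(vy) * dt_s, arena[2])
    tibble(t = (seq_len(n) - 1L) * dt_s, x = x, y = y)
  })
}

#' Generate an inhomogeneous-Poisson spike train along a trajectory
#'
#' Thins a homogeneous Poisson process of rate `xmax` with acceptance
#' probability `rate(x(t)) / xmax`, where the rate is the ideal grid model
#' evaluated at the (linearly interpolated) animal position in arena-centred
#' coordinates.
#'
#' @param trajectory Tibble `t`, `x`, `y` in corner-origin coordinates.
#' @param lambda,theta,phase_x,phase_y,xmax Grid-cell parameters.
#' @param arena `c(Lx, Ly)` in cm.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
generate_spikes <- function(trajectory, lambda, theta, phase_x = 0,
                            phase_y = 0, xmax = 1, arena = c(150, 150),
                            seed = NULL) {
  if (xmax <= 0) return(numeric(0))
  with_seed(seed, {
    t0 <- trajectory$t[1]
    t1 <- trajectory$t[nrow(trajectory)]
    n_cand <- rpois(1, xmax * (t1 - t0))
    if (n_cand == 0) return(numeric(0))
    tc <- sort(runif(n_cand, t0, t1))
    px <- approx(trajectory$t, trajectory$x, xout = tc)$y - arena[1] / 2
    py <- approx(trajectory$t, trajectory$y, xout = tc)$y - arena[2] / 2
    rate <- grid_rate_at(px, py, lambda, theta, phase_x, phase_y, xmax)
    keep <- runif(n_cand) < pmax(rate, 0) / xmax
    tc[keep]
  })
}

#' Simulate a full synthetic recording session
#'
#' Samples a population, simulates one shared foraging trajectory, and
#' generates one Poisson spike train per cell, yielding a
#' [grid_recording()] in the same structure as a real session. The sampled
#' ground-truth parameters are attached as attribute `"ground_truth"`.
#'
#' Every stochastic stage uses a seed derived deterministically from `seed`
#' (`derive_seed()` in the source), so stages are independently
#' reproducible.
#'
#' @param spec A [grid_population_spec()].
#' @param duration_s Session duration (s); default 130 min.
#' @param dt_s Position sampling interval (s).
#' @param seed Integer seed.
#' @param session_id,module_id Labels for the recording.
#' @return A `grid_recording` with attribute `ground_truth` (the population
#'   tibble).
#' @export
#' @examples
#' rec <- simulate_session(grid_population_spec(n = 2), duration_s = 120,
#'                         seed = 1)
#' vapply(rec$spikes, length, integer(1))
simulate_session <- function(spec, duration_s = 130 * 60, dt_s = 0.02,
                             seed = 1L, session_id = "synthetic",
                             module_id = "m1") {
  pop <- sample_population(spec, seed = derive_seed(seed, "population"))
  traj <- simulate_trajectory(duration_s, dt_s, spec$arena,
                              seed = derive_seed(seed, "trajectory"))
  spikes <- lapply(seq_len(nrow(pop)), function(i) {
    generate_spikes(traj, pop$lambda[i], pop$theta[i], pop$phase_x[i],
                    pop$phase_y[i], pop$xmax[i], arena = spec$arena,
                    seed = derive_seed(seed, "spikes", i))
  })
  names(spikes) <- sprintf("cell%03d", seq_len(nrow(pop)))
  rec <- grid_recording(traj, spikes, arena = spec$arena,
                        module_id = module_id, session_id = session_id)
  attr(rec, "ground_truth") <- mutate(pop, unit_id = names(spikes),
                                      .before = 1)
  rec
}
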
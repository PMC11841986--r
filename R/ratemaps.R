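# Rate maps and spatial autocorrelograms.
#
# A rate map lives on a regular grid of square bins covering the arena,
# indexed from the arena corner with half-open [lo, hi) bins; the first
# matrix dimension runs along x, the second along y. Unvisited bins are NA,
# never 0 Hz.

n_bins_for <- function(length_cm, bin_size) {
  as.integer(ceiling(length_cm / bin_size - 1e-9))
}

# Spatial bin index (1-based, clamped at the top edge so x = Lx falls in the
# last bin) for continuous coordinates.
bin_index <- function(coord, bin_size, n_bins) {
  pmax(1L, pmin(n_bins, as.integer(floor(coord / bin_size)) + 1L))
}

#' Occupancy map of a recording
#'
#' Sums dwell time per spatial bin. Each position sample contributes its
#' following inter-sample interval to the bin containing it (the last sample
#' contributes the median interval), so total occupancy equals total
#' trajectory duration.
#'
#' @param rec A [grid_recording()].
#' @param bin_size Spatial bin side (cm).
#' @return Matrix of seconds, dimensions `n_x x n_y`.
#' @export
#' @examples
#' pos <- data.frame(t = seq(0, 60, 0.5), x = 75, y = 75)
#' occ <- compute_occupancy(grid_recording(pos, list(u1 = numeric(0))), 3)
#' sum(occ) # 60.5 s (121 samples x 0.5 s dwell)
compute_occupancy <- function(rec, bin_size) {
  if (!is.numeric(bin_size) || bin_size <= 0) {
    abort("`bin_size` must be a positive number of cm")
  }
  nx <- n_bins_for(rec$arena[1], bin_size)
  ny <- n_bins_for(rec$arena[2], bin_size)
  ix <- bin_index(rec$positions$x, bin_size, nx)
  iy <- bin_index(rec$positions$y, bin_size, ny)
  flat <- ix + (iy - 1L) * nx
  occ <- numeric(nx * ny)
  agg <- rowsum(rec$positions$dwell, flat)
  occ[as.integer(rownames(agg))] <- agg[, 1]
  matrix(occ, nx, ny)
}

new_rate_map <- function(values, occupancy, bin_size, visited,
                         spike_counts = NULL, arena = NULL) {
  structure(
    list(values = values, occupancy = occupancy, bin_size = bin_size,
         visited = visited, spike_counts = spike_counts, arena = arena),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins of %g cm; peak %.2f Hz; %.0f%% visited\n",
              nrow(x$values), ncol(x$values), x$bin_size,
              max(x$values, na.rm = TRUE), 100 * mean(x$visited)))
  invisible(x)
}

#' Occupancy-normalized, smoothed firing-rate map
#'
#' Bins the unit's spikes by the animal's location at spike time, divides by
#' occupancy, and applies mask-aware Gaussian smoothing (the smoothed map is
#' renormalized by the smoothed visited mask so unvisited bins leak no
#' mass). A bin counts as visited when it holds at least one position
#' sample's dwell.
#'
#' @param rec A [grid_recording()].
#' @param unit Unit id (name in `rec$spikes`).
#' @param bin_size Spatial bin side (cm).
#' @param smooth_sigma_bins Gaussian sigma in bins; 0 disables smoothing.
#' @return A `rate_map` object; zero-spike units yield a valid all-zero map.
#' @export
compute_rate_map <- function(rec, unit, bin_size = 3, smooth_sigma_bins = 1) {
  if (!unit %in% names(rec$spikes)) {
    abort(sprintf("unknown unit '%s'", unit))
  }
  occ <- compute_occupancy(rec, bin_size)
  nx <- nrow(occ); ny <- ncol(occ)
  visited <- occ >= 0.99 * median(rec$positions$dwell)
  st <- rec$spikes[[unit]]
  counts <- matrix(0L, nx, ny)
  if (length(st)) {
    si <- findInterval(st, rec$positions$t, all.inside = TRUE)
    ix <- bin_index(rec$positions$x[si], bin_size, nx)
    iy <- bin_index(rec$positions$y[si], bin_size, ny)
    counts <- matrix(tabulate(ix + (iy - 1L) * nx, nx * ny), nx, ny)
  }
  raw <- matrix(NA_real_, nx, ny)
  raw[visited] <- counts[visited] / occ[visited]
  values <- smooth_masked(raw, smooth_sigma_bins, visited)
  new_rate_map(values, occ, bin_size, visited, counts, rec$arena)
}

# The six masked cross-correlation sums needed for a Pearson SAC, sharing
# the three forward FFTs.
sac_correlations <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  pr <- 2L * nr; pc <- 2L * nc
  padf <- function(m) {
    p <- matrix(0, pr, pc)
    p[1:nr, 1:nc] <- m
    fft(p)
  }
  fw <- padf(w); fx <- padf(x); fx2 <- padf(x * x)
  ridx <- c((pr - nr + 2L):pr, 1L:nr)
  cidx <- c((pc - nc + 2L):pc, 1L:nc)
  backc <- function(fa, fb) {
    cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
    cc[ridx, cidx]
  }
  list(n = backc(fw, fw), sx = backc(fx, fw), sy = backc(fw, fx),
       sxy = backc(fx, fx), sxx = backc(fx2, fw), syy = backc(fw, fx2))
}

new_sac <- function(values, bin_size, center_masked = FALSE,
                    mask_radius_bins = 0L, degenerate = FALSE) {
  structure(
    list(values = values, bin_size = bin_size, center_masked = center_masked,
         mask_radius_bins = mask_radius_bins, degenerate = degenerate),
    class = "grid_sac"
  )
}

#' @export
print.grid_sac <- function(x, ...) {
  cat(sprintf("<grid_sac> %d x %d lags; centre %s; %s\n",
              nrow(x$values), ncol(x$values),
              if (x$center_masked) sprintf("masked (r = %d bins)", x$mask_radius_bins)
              else "unmasked",
              if (x$degenerate) "DEGENERATE" else "ok"))
  invisible(x)
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with a copy of itself displaced by every
#' integer 2-D lag, using only bin pairs where both bins are visited. Lags
#' with fewer than `min_overlap` overlapping pairs are NA. The output has
#' side `2n - 1`, lag (0, 0) at the centre, where the correlation is exactly
#' 1 for any non-degenerate map.
#'
#' @param map A `rate_map`.
#' @param min_overlap Minimum overlapping visited bin pairs per lag.
#' @return A `grid_sac` object; an all-constant map yields a SAC flagged
#'   `degenerate` (correlation undefined everywhere).
#' @export
compute_sac <- function(map, min_overlap = 20) {
  w <- map$visited + 0
  if (sum(w) < 2) abort("rate map must have at least 2 visited bins")
  x <- map$values
  x[!map$visited] <- 0
  s <- sac_correlations(x, w)
  n <- round(s$n)
  num <- n * s$sxy - s$sx * s$sy
  v1 <- n * s$sxx - s$sx^2
  v2 <- n * s$syy - s$sy^2
  tol <- 1e-8 * max(1, max(abs(x))^2) * max(1, max(n))
  den <- sqrt(pmax(v1, 0) * pmax(v2, 0))
  vals <- num / den
  vals[n < min_overlap | v1 <= tol | v2 <= tol] <- NA_real_
  vals[vals > 1] <- 1
  vals[vals < -1] <- -1
  degenerate <- all(is.na(vals))
  if (!degenerate) {
    ctr <- (dim(vals) + 1L) / 2L
    vals[ctr[1], ctr[2]] <- 1
  }
  new_sac(vals, map$bin_size, degenerate = degenerate)
}

#' Mask the central peak of a SAC
#'
#' Marks all lags within `radius_bins` of the centre as missing. The central
#' peak always correlates strongly with itself and would otherwise swamp the
#' six inner lattice peaks. Idempotent.
#'
#' @param sac A `grid_sac`.
#' @param radius_bins Mask radius in lag bins; `NULL` (default) picks the
#'   radius adaptively as the first minimum of the radially averaged SAC
#'   profile, clamped to `[2, 0.3 x half-width]`, so the mask tracks the
#'   module scale.
#' @return The masked `grid_sac` (`center_masked = TRUE`).
#' @export
mask_center <- function(sac, radius_bins = NULL) {
  vals <- sac$values
  half <- (nrow(vals) - 1L) / 2L
  if (is.null(radius_bins)) {
    radius_bins <- first_radial_minimum(vals)
    radius_bins <- max(2L, min(radius_bins, as.integer(0.3 * half)))
  }
  if (radius_bins >= half) {
    warn("centre-mask radius reaches the SAC edge; inner peaks may be masked")
  }
  lg <- lag_grid(dim(vals))
  vals[lg$dr^2 + lg$dc^2 <= radius_bins^2] <- NA_real_
  out <- sac
  out$values <- vals
  out$center_masked <- TRUE
  out$mask_radius_bins <- as.integer(radius_bins)
  out
}

# Radius (bins) of the first local minimum of the radially averaged SAC
# profile; falls back to 2 when the profile is monotone.
first_radial_minimum <- function(vals) {
  half <- (nrow(vals) - 1L) / 2L
  lg <- lag_grid(dim(vals))
  r <- sqrt(lg$dr^2 + lg$dc^2)
  rbin <- as.integer(round(r))
  prof <- vapply(0:half, function(k) {
    v <- vals[rbin == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  for (k in 2:(length(prof) - 1L)) {
    if (!anyNA(prof[(k - 1L):(k + 1L)]) &&
        prof[k] <= prof[k - 1L] && prof[k] < prof[k + 1L]) {
      return(k - 1L) # profile index k corresponds to radius k - 1
    }
  }
  2L
}
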
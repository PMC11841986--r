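# Fitting grid spacing, orientation and grid score from the SAC.
#
# Convention: orientation is the angle (deg, counter-clockwise from the
# x-axis) of the lattice axis nearest the x-axis, 60-degree periodic and
# reported in [0, 60). The three axes are nominally near 0, 60 and 120 deg.

#' Detect candidate peaks in a centre-masked SAC
#'
#' Smooths the SAC with a Gaussian (sigma 1 bin by default), then returns
#' all local maxima (8-neighbour rule) above a correlation threshold,
#' sorted by radial distance from the centre lag. Peak locations are
#' integer lag bins unless `refine = TRUE`, which applies 3x3 quadratic
#' sub-bin refinement.
#'
#' @param sac A centre-masked `grid_sac`.
#' @param smooth_sigma_bins Gaussian sigma (bins) applied before detection.
#' @param threshold Minimum smoothed correlation for a peak.
#' @param refine Logical; sub-bin quadratic refinement (default off).
#' @return Tibble `dr`, `dc` (lag bins from centre), `radius_bins`,
#'   `angle_deg` (in (-180, 180]), `value`; zero rows when nothing is found.
#' @export
find_sac_peaks <- function(sac, smooth_sigma_bins = 1, threshold = 0.1,
                           refine = FALSE) {
  vals <- sac$values
  if (sac$degenerate || all(is.na(vals))) {
    return(tibble(dr = numeric(0), dc = numeric(0), radius_bins = numeric(0),
                  angle_deg = numeric(0), value = numeric(0)))
  }
  sm <- smooth_masked(vals, smooth_sigma_bins)
  pk <- which(local_maxima(sm, threshold), arr.ind = TRUE)
  ctr <- (dim(vals) + 1L) / 2L
  if (nrow(pk) == 0) {
    return(tibble(dr = numeric(0), dc = numeric(0), radius_bins = numeric(0),
                  angle_deg = numeric(0), value = numeric(0)))
  }
  loc <- pk
  if (refine) {
    loc <- t(apply(pk, 1, function(rc) refine_peak_quadratic(sm, rc[1], rc[2])))
  }
  out <- tibble(
    dr = loc[, 1] - ctr[1],
    dc = loc[, 2] - ctr[2],
    value = sm[pk]
  )
  out$radius_bins <- sqrt(out$dr^2 + out$dc^2)
  out$angle_deg <- atan2(out$dc, out$dr) * 180 / pi
  arrange(out[, c("dr", "dc", "radius_bins", "angle_deg", "value")],
          .data$radius_bins)
}

# Reduce a peak angle to its axis representative in [-15, 165) (axes are
# 180-degree periodic; nominal axes sit at 0, 60, 120).
reduce_axis_angle <- function(angle_deg) {
  a <- angle_deg %% 180
  ifelse(a >= 165, a - 180, a)
}

#' Hexagonal-structure inclusion criteria
#'
#' A fit passes only if (1) no two angularly adjacent axis peaks are less
#' than 30 deg apart, (2) none more than 90 deg apart, and (3) the ratio of
#' spacings between any two axis peaks lies strictly inside (0.5, 2). Rules
#' are checked in that order and the first failure is reported.
#'
#' @param axis_angles Three axis orientations (deg).
#' @param axis_spacings Three axis spacings (same units).
#' @return List with `pass` (logical) and `reason` (one of `"none"`,
#'   `"angle_lt_30"`, `"angle_gt_90"`, `"spacing_ratio"`).
#' @export
check_inclusion <- function(axis_angles, axis_spacings) {
  a <- sort(reduce_axis_angle(axis_angles))
  gaps <- diff(a)
  if (any(gaps < 30)) return(list(pass = FALSE, reason = "angle_lt_30"))
  if (any(gaps > 90)) return(list(pass = FALSE, reason = "angle_gt_90"))
  ratio <- max(axis_spacings) / min(axis_spacings)
  if (ratio >= 2) return(list(pass = FALSE, reason = "spacing_ratio"))
  list(pass = TRUE, reason = "none")
}

new_grid_fit <- function(valid, reason, peaks = NULL, axis = NULL,
                         spacing = NA_real_, orientation = NA_real_) {
  structure(
    list(valid = valid, rejection_reason = reason, peaks = peaks,
         axis = axis, spacing = spacing, orientation = orientation),
    class = "grid_fit"
  )
}

#' @export
print.grid_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<grid_fit> lambda = %.1f cm, theta = %.2f deg\n",
                x$spacing, x$orientation))
  } else {
    cat(sprintf("<grid_fit> invalid (%s)\n", x$rejection_reason))
  }
  invisible(x)
}

#' Fit grid spacing and orientation from a SAC
#'
#' Selects the six SAC peaks closest to the centre, reduces their angles to
#' axis representatives and keeps one peak per nominal axis (0/60/120 deg;
#' nearest angle, ties to the larger SAC value). Per-axis spacing is the
#' peak radius in lag bins times the bin size; overall spacing is the
#' arithmetic mean of the three axes. Per-axis orientation is the peak
#' angle; overall orientation is the circular mean of
#' `angle_k - 60 * (k - 1)` on the 60-degree circle. The hexagonal
#' inclusion criteria ([check_inclusion()]) set `valid`/`rejection_reason`.
#'
#' @param sac A centre-masked `grid_sac`.
#' @param smooth_sigma_bins,threshold,refine Passed to [find_sac_peaks()];
#'   sub-bin refinement is on by default so spacing and orientation are not
#'   quantized to integer lag bins.
#' @return A `grid_fit` object: fields `valid`, `rejection_reason`, `peaks`
#'   (the six inner peaks), `axis` (tibble with per-axis spacing and
#'   orientation), `spacing` (cm), `orientation` (deg in `[0, 60)`).
#' @export
fit_grid <- function(sac, smooth_sigma_bins = 1, threshold = 0.1,
                     refine = TRUE) {
  if (sac$degenerate) return(new_grid_fit(FALSE, "degenerate_sac"))
  peaks <- find_sac_peaks(sac, smooth_sigma_bins, threshold, refine)
  if (nrow(peaks) < 3) return(new_grid_fit(FALSE, "too_few_peaks", peaks))
  inner <- head(peaks, 6)
  inner$axis_angle <- reduce_axis_angle(inner$angle_deg)
  nominal <- c(0, 60, 120)
  sel <- vector("list", 3)
  for (k in 1:3) {
    d <- circular_dist_deg(inner$axis_angle, nominal[k], period = 180)
    cand <- inner[d == min(d), , drop = FALSE]
    sel[[k]] <- cand[which.max(cand$value), , drop = FALSE]
  }
  axis <- bind_rows(sel)
  axis$axis <- 1:3
  # the same peak claiming two axes means hexagonal structure is absent
  if (anyDuplicated(axis[, c("dr", "dc")])) {
    return(new_grid_fit(FALSE, "too_few_peaks", inner))
  }
  axis$spacing <- axis$radius_bins * sac$bin_size
  axis$orientation <- axis$axis_angle
  incl <- check_inclusion(axis$axis_angle, axis$spacing)
  spacing <- mean(axis$spacing)
  rel <- axis$axis_angle - 60 * (axis$axis - 1)
  orientation <- circular_mean_deg(rel, period = 60)
  new_grid_fit(incl$pass, incl$reason, peaks = inner,
               axis = as_tibble(axis[, c("axis", "spacing", "orientation",
                                         "radius_bins", "value")]),
               spacing = spacing, orientation = orientation)
}

#' Grid score of a centre-masked SAC
#'
#' Standard rotational-symmetry statistic: the SAC annulus (inner radius at
#' the centre mask, outer radius just beyond the six inner peaks) is
#' correlated with itself rotated by 30, 60, 90, 120 and 150 deg, and the
#' score is `min(r60, r120) - max(r30, r90, r150)`. Hexagonal maps score
#' well above 0; spatially unstructured maps score near 0.
#'
#' @param sac A centre-masked `grid_sac`.
#' @param peaks Optional peak tibble from [find_sac_peaks()] used to set the
#'   outer annulus radius (1.25 x the outermost of the six inner peaks);
#'   detected automatically when `NULL`. With no detectable peaks the outer
#'   radius falls back to 0.7 x the SAC half-width.
#' @return Scalar score, or `NA` (with a warning) for a degenerate annulus.
#' @export
grid_score <- function(sac, peaks = NULL) {
  if (sac$degenerate) {
    warn("degenerate SAC: grid score undefined")
    return(NA_real_)
  }
  if (is.null(peaks)) peaks <- find_sac_peaks(sac)
  half <- (nrow(sac$values) - 1L) / 2L
  inner_r <- max(sac$mask_radius_bins, 2L)
  outer_r <- if (nrow(peaks) >= 1) {
    min(half, 1.25 * max(head(peaks, 6)$radius_bins))
  } else {
    0.7 * half
  }
  if (outer_r <= inner_r + 1) {
    warn("degenerate annulus: grid score undefined")
    return(NA_real_)
  }
  lg <- lag_grid(dim(sac$values))
  r <- sqrt(lg$dr^2 + lg$dc^2)
  annulus <- r > inner_r & r <= outer_r
  rots <- c(30, 60, 90, 120, 150)
  cors <- vapply(rots, function(a) {
    rot <- rotate_matrix(sac$values, a)
    ok <- annulus & !is.na(sac$values) & !is.na(rot)
    if (sum(ok) < 20) return(NA_real_)
    cor(sac$values[ok], rot[ok])
  }, numeric(1))
  if (anyNA(cors)) {
    warn("degenerate annulus: grid score undefined")
    return(NA_real_)
  }
  min(cors[c(2, 4)]) - max(cors[c(1, 3, 5)])
}

#' Grid spacing estimated directly from the rate map
#'
#' Control estimator that avoids boundary-truncated SAC fields: the rate
#' map is smoothed (sigma 1.5 bins), firing-field centres are detected as
#' local maxima, and the spacing is the mean of the three pairwise
#' distances between three field centres near the arena centre. Among the
#' six most central fields, the triple with the most equal pairwise
#' distances (smallest relative spread, ties to the more central triple) is
#' used: on a triangular lattice the three fields nearest an arbitrary
#' point can be nearly collinear, which would make a literal
#' nearest-three rule jump by ~25% with the lattice phase, while the most
#' equilateral central triple is a stable lattice triangle.
#'
#' @param map A `rate_map`.
#' @param smooth_sigma_bins Gaussian sigma (bins) for field detection.
#' @param threshold_rel Fields must exceed this fraction of the map peak.
#' @return Spacing in cm, or `NA` (with a warning) when fewer than three
#'   fields are detectable.
#' @export
spacing_from_ratemap <- function(map, smooth_sigma_bins = 1.5,
                                 threshold_rel = 0.2) {
  sm <- smooth_masked(map$values, smooth_sigma_bins, map$visited)
  if (all(is.na(sm)) || max(sm, na.rm = TRUE) <= 0) {
    warn("rate-map spacing undefined: no firing fields")
    return(NA_real_)
  }
  thr <- threshold_rel * max(sm, na.rm = TRUE)
  pk <- which(local_maxima(sm, thr), arr.ind = TRUE)
  if (nrow(pk) < 3) {
    warn("rate-map spacing undefined: fewer than 3 firing fields")
    return(NA_real_)
  }
  ctr <- (dim(sm) + 1) / 2
  d_ctr <- sqrt((pk[, 1] - ctr[1])^2 + (pk[, 2] - ctr[2])^2)
  near <- pk[order(d_ctr), , drop = FALSE][seq_len(min(6, nrow(pk))), ,
                                           drop = FALSE]
  d_near <- sort(d_ctr)[seq_len(nrow(near))]
  triples <- utils::combn(nrow(near), 3)
  best <- NULL; best_key <- c(Inf, Inf)
  for (j in seq_len(ncol(triples))) {
    tri <- triples[, j]
    dd <- as.vector(stats::dist(near[tri, , drop = FALSE]))
    key <- c(sd(dd) / mean(dd), sum(d_near[tri]))
    if (key[1] < best_key[1] - 1e-9 ||
        (abs(key[1] - best_key[1]) <= 1e-9 && key[2] < best_key[2])) {
      best_key <- key
      best <- dd
    }
  }
  mean(best) * map$bin_size
}

#' Fit every unit of a recording
#'
#' The tidy per-session surface: computes each unit's rate map, SAC, grid
#' fit, grid score and rate-map spacing under one configuration.
#'
#' @param rec A [grid_recording()].
#' @param config A [grid_config()].
#' @param units Unit ids to fit (default: all).
#' @return Tibble, one row per unit: ids, spike count, `grid_score`,
#'   `spacing` / `orientation`, per-axis values, `ratemap_spacing`, `valid`
#'   and `rejection_reason`.
#' @export
#' @examples
#' \donttest{
#' rec <- simulate_session(grid_population_spec(n = 2), duration_s = 600,
#'                         seed = 1)
#' fit_session(rec, grid_config())
#' }
fit_session <- function(rec, config = grid_config(), units = NULL) {
  units <- units %||% rec$unit_ids
  rows <- lapply(units, function(u) {
    map <- compute_rate_map(rec, u, config$bin_size_cm,
                            config$ratemap_smooth_sigma_bins)
    res <- fit_map_pipeline(map, config)
    rms <- suppressWarnings(
      spacing_from_ratemap(map, config$ratemap_spacing_smooth_sigma_bins))
    fit_row(u, res$fit, res$score, rms, n_spikes = length(rec$spikes[[u]]))
  })
  out <- bind_rows(rows)
  out$session_id <- rec$session_id
  out$module_id <- rec$module_id
  out
}

# Shared SAC -> fit -> score pipeline for one rate map.
fit_map_pipeline <- function(map, config, want_score = TRUE) {
  if (sum(map$visited) < 2 ||
      all(map$values[map$visited] == 0, na.rm = TRUE)) {
    return(list(fit = new_grid_fit(FALSE, "degenerate_sac"),
                score = NA_real_))
  }
  sac <- compute_sac(map, config$min_sac_overlap)
  if (sac$degenerate) {
    return(list(fit = new_grid_fit(FALSE, "degenerate_sac"),
                score = NA_real_))
  }
  sac <- mask_center(sac)
  fit <- fit_grid(sac, config$sac_smooth_sigma_bins,
                  config$sac_peak_threshold, config$refine_peaks)
  score <- if (want_score) {
    suppressWarnings(grid_score(sac, peaks = fit$peaks))
  } else {
    NA_real_
  }
  list(fit = fit, score = score, sac = sac)
}

fit_row <- function(unit, fit, score, ratemap_spacing = NA_real_,
                    n_spikes = NA_integer_) {
  ax <- function(k, col) {
    if (is.null(fit$axis) || nrow(fit$axis) < k) NA_real_ else fit$axis[[col]][k]
  }
  tibble(
    unit_id = unit, n_spikes = n_spikes, valid = fit$valid,
    rejection_reason = fit$rejection_reason, grid_score = score,
    spacing = fit$spacing, orientation = fit$orientation,
    axis1_spacing = ax(1, "spacing"), axis2_spacing = ax(2, "spacing"),
    axis3_spacing = ax(3, "spacing"),
    axis1_orientation = ax(1, "orientation"),
    axis2_orientation = ax(2, "orientation"),
    axis3_orientation = ax(3, "orientation"),
    ratemap_spacing = ratemap_spacing
  )
}
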
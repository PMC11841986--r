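# Split-half estimation of within- vs between-cell variability of grid
# spacing and orientation.

# Random permutation with no fixed points (so no cell is compared with
# itself in the between-cell statistic).
derangement <- function(n) {
  if (n < 2) abort("a derangement needs at least 2 elements")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# Orientation differences live on the 60-degree circle; magnitudes in
# [0, 30]. Spacing differences are plain absolute differences.
dtheta <- function(a, b) circular_dist_deg(a, b, period = 60)

#' Split a recording into two balanced random halves
#'
#' Partitions time into consecutive bins of `bin_seconds`, drops the final
#' partial bin (and, if the count is odd, the last complete bin), and
#' randomly assigns exactly half the bins to each block. Positions and
#' spikes are restricted to each block's bins; per-sample dwell times from
#' the full trajectory are kept so the two halves conserve occupancy.
#'
#' @param rec A [grid_recording()].
#' @param bin_seconds Temporal bin length (s).
#' @param seed Optional integer seed.
#' @return List with recordings `a` and `b`, `n_bins_used`, and the logical
#'   `assignment` (TRUE = block A) per used bin.
#' @export
split_halves <- function(rec, bin_seconds = 30, seed = NULL) {
  t <- rec$positions$t
  t0 <- t[1]
  dur <- t[length(t)] - t0
  if (dur < 2 * bin_seconds) {
    abort("recording shorter than two temporal bins; cannot split")
  }
  n_bins <- as.integer(floor(dur / bin_seconds))
  n_used <- if (n_bins %% 2L == 1L) n_bins - 1L else n_bins
  assignment <- with_seed(seed, {
    a <- rep(FALSE, n_used)
    a[sample.int(n_used, n_used %/% 2L)] <- TRUE
    a
  })
  pick <- function(in_a) {
    bins <- which(assignment == in_a)
    cbind(t0 + (bins - 1) * bin_seconds, t0 + bins * bin_seconds)
  }
  list(a = subset_recording_time(rec, pick(TRUE)),
       b = subset_recording_time(rec, pick(FALSE)),
       n_bins_used = n_used, assignment = assignment)
}

#' Split-half shuffle analysis of grid-property variability
#'
#' For each of `n_shuffles` iterations the session is split once into two
#' balanced random halves of `split_bin_seconds` bins (the same split for
#' all simultaneously recorded cells), grid properties are fit on each
#' half, and per cell the within-cell differences
#' `|lambda_A(i) - lambda_B(i)|` and the 60-degree circular distance
#' between `theta_A(i)` and `theta_B(i)` are recorded. Each surviving cell
#' is also paired with a different surviving cell by a fresh random
#' derangement to give the between-cell differences
#' `|lambda_A(i) - lambda_B(j)|` (and likewise for orientation). A cell is
#' "poor" on a shuffle when either half fails the hexagonal inclusion
#' criteria; its per-cell means are taken over the shuffles it survived.
#'
#' @param rec A [grid_recording()] with at least 2 units.
#' @param config A [grid_config()] (bins, smoothing, shuffle count,
#'   reliability cap).
#' @param units Unit ids to analyse (default all).
#' @param seed Integer seed; shuffle k uses a derived substream so it is
#'   reproducible in isolation.
#' @return A `grid_variability` object. `tidy()` returns the per-cell
#'   table (`mean_within_dtheta`, `mean_between_dtheta`,
#'   `mean_within_dlambda`, `mean_between_dlambda`, `n_poor_fits`,
#'   `accepted`, full-session `grid_score`); `glance()` returns the
#'   population summary of [summarize_variability()].
#' @export
shuffle_analysis <- function(rec, config = grid_config(), units = NULL,
                             seed = config$rng_seed) {
  units <- units %||% rec$unit_ids
  if (length(units) < 2) abort("shuffle analysis needs at least 2 cells")
  n_cells <- length(units)
  n_sh <- config$n_shuffles
  bs <- config$split_bin_seconds

  t <- rec$positions$t
  t0 <- t[1]
  dur <- t[length(t)] - t0
  n_bins <- as.integer(floor(dur / bs))
  n_used <- if (n_bins %% 2L == 1L) n_bins - 1L else n_bins
  if (n_used < 2) abort("recording shorter than two temporal bins")

  nx <- n_bins_for(rec$arena[1], config$bin_size_cm)
  ny <- n_bins_for(rec$arena[2], config$bin_size_cm)
  nb <- nx * ny
  ix <- bin_index(rec$positions$x, config$bin_size_cm, nx)
  iy <- bin_index(rec$positions$y, config$bin_size_cm, ny)
  flat <- ix + (iy - 1L) * nx
  dwell <- rec$positions$dwell
  med_dwell <- median(dwell)
  itb <- as.integer(floor((t - t0) / bs)) + 1L
  in_used <- itb <= n_used

  cell_pre <- lapply(units, function(u) {
    st <- rec$spikes[[u]]
    if (!length(st)) {
      return(list(flat = integer(0), itb = integer(0)))
    }
    si <- findInterval(st, t, all.inside = TRUE)
    list(flat = flat[si], itb = as.integer(floor((st - t0) / bs)) + 1L)
  })

  half_fit <- function(in_half) {
    keep <- in_used & in_half[itb]
    occ <- numeric(nb)
    agg <- rowsum(dwell[keep], flat[keep])
    occ[as.integer(rownames(agg))] <- agg[, 1]
    occ <- matrix(occ, nx, ny)
    visited <- occ >= 0.99 * med_dwell
    function(cp) {
      sp_keep <- cp$itb <= n_used & in_half[cp$itb]
      counts <- matrix(tabulate(cp$flat[sp_keep], nb), nx, ny)
      raw <- matrix(NA_real_, nx, ny)
      raw[visited] <- counts[visited] / occ[visited]
      vals <- smooth_masked(raw, config$ratemap_smooth_sigma_bins, visited)
      map <- new_rate_map(vals, occ, config$bin_size_cm, visited,
                         arena = rec$arena)
      fit_map_pipeline(map, config, want_score = FALSE)$fit
    }
  }

  w_th <- matrix(NA_real_, n_cells, n_sh)
  w_la <- matrix(NA_real_, n_cells, n_sh)
  b_th <- matrix(NA_real_, n_cells, n_sh)
  b_la <- matrix(NA_real_, n_cells, n_sh)
  poor <- matrix(TRUE, n_cells, n_sh)
  n_no_between <- 0L

  for (k in seq_len(n_sh)) {
    with_seed(derive_seed(seed, "shuffle", k), {
      in_a <- rep(FALSE, n_used)
      in_a[sample.int(n_used, n_used %/% 2L)] <- TRUE
      fit_a <- half_fit(in_a)
      fit_b <- half_fit(!in_a)
      th_a <- la_a <- th_b <- la_b <- rep(NA_real_, n_cells)
      for (i in seq_len(n_cells)) {
        fa <- fit_a(cell_pre[[i]])
        fb <- fit_b(cell_pre[[i]])
        if (fa$valid && fb$valid) {
          poor[i, k] <- FALSE
          th_a[i] <- fa$orientation; la_a[i] <- fa$spacing
          th_b[i] <- fb$orientation; lb <- fb$spacing
          la_b[i] <- lb
          w_th[i, k] <- dtheta(fa$orientation, fb$orientation)
          w_la[i, k] <- abs(fa$spacing - lb)
        }
      }
      surv <- which(!poor[, k])
      if (length(surv) >= 2) {
        partner <- surv[derangement(length(surv))]
        b_th[surv, k] <- dtheta(th_a[surv], th_b[partner])
        b_la[surv, k] <- abs(la_a[surv] - la_b[partner])
      } else {
        n_no_between <- n_no_between + 1L
      }
    })
  }

  full <- fit_session(rec, config, units)
  cells <- tibble(
    unit_id = units,
    mean_within_dtheta = rowMeans(w_th, na.rm = TRUE),
    mean_between_dtheta = rowMeans(b_th, na.rm = TRUE),
    mean_within_dlambda = rowMeans(w_la, na.rm = TRUE),
    mean_between_dlambda = rowMeans(b_la, na.rm = TRUE),
    n_poor_fits = rowSums(poor),
    n_shuffles = n_sh,
    grid_score = full$grid_score[match(units, full$unit_id)]
  )
  cells$accepted <- cells$n_poor_fits / n_sh < config$reliability_max_poor_frac
  cells[2:5] <- lapply(cells[2:5], function(x) ifelse(is.nan(x), NA_real_, x))

  structure(
    list(cells = cells, config = config, n_shuffles = n_sh,
         split_bin_seconds = bs, n_bins_used = n_used,
         n_shuffles_without_between = n_no_between,
         session_id = rec$session_id, module_id = rec$module_id,
         within_dtheta = w_th, between_dtheta = b_th,
         within_dlambda = w_la, between_dlambda = b_la),
    class = "grid_variability"
  )
}

#' @export
print.grid_variability <- function(x, ...) {
  cat(sprintf(
    "<grid_variability> session %s: %d cells, %d shuffles, %d/%d accepted\n",
    x$session_id, nrow(x$cells), x$n_shuffles, sum(x$cells$accepted),
    nrow(x$cells)))
  invisible(x)
}

#' Reliability filter on a shuffle analysis
#'
#' Keeps only cells whose poor-fit fraction across shuffles is strictly
#' below `max_poor_frac` (a cell poor on 5 of 100 shuffles is rejected at
#' the default 5% cap; one poor on 4 is kept).
#'
#' @param vr A `grid_variability` object.
#' @param max_poor_frac Cap on the poor-fit fraction; defaults to the value
#'   in the object's config.
#' @return The accepted subset of the per-cell table, with the acceptance
#'   percentage reported as a message.
#' @export
reliability_filter <- function(vr, max_poor_frac = NULL) {
  max_poor_frac <- max_poor_frac %||% vr$config$reliability_max_poor_frac
  cells <- vr$cells
  keep <- cells$n_poor_fits / cells$n_shuffles < max_poor_frac
  inform(sprintf("%d/%d cells accepted (%.1f%%)",
                 sum(keep), nrow(cells), 100 * mean(keep)))
  out <- cells[keep, , drop = FALSE]
  out$accepted <- TRUE
  out
}

#' Population summary of within- vs between-cell variability
#'
#' Means of the per-cell within/between variabilities over accepted cells,
#' the percentage of cells with more between- than within-cell variability
#' (orientation and spacing separately), one-sided paired Wilcoxon
#' signed-rank p-values for between > within, and (when grid scores are
#' available) the linear regression of within-cell variability on grid
#' score (R-squared and Wald p).
#'
#' @param vr A `grid_variability` object or a per-cell tibble.
#' @return One-row tibble. With fewer than 5 accepted cells the statistics
#'   are returned as `NA`.
#' @export
summarize_variability <- function(vr) {
  cells <- if (inherits(vr, "grid_variability")) vr$cells else as_tibble(vr)
  acc <- cells[cells$accepted &
                 complete.cases(cells[, c("mean_within_dtheta",
                                          "mean_between_dtheta",
                                          "mean_within_dlambda",
                                          "mean_between_dlambda")]), ]
  n <- nrow(acc)
  if (n < 5) {
    warn("fewer than 5 accepted cells: summary statistics set to NA")
    return(tibble(
      n_accepted = n, mean_within_dtheta = NA_real_,
      mean_between_dtheta = NA_real_, mean_within_dlambda = NA_real_,
      mean_between_dlambda = NA_real_, pct_between_gt_within_theta = NA_real_,
      pct_between_gt_within_lambda = NA_real_, p_theta = NA_real_,
      p_lambda = NA_real_, r2_theta_score = NA_real_,
      p_theta_score = NA_real_, r2_lambda_score = NA_real_,
      p_lambda_score = NA_real_))
  }
  p_one_sided <- function(b, w) {
    suppressWarnings(
      wilcox.test(b, w, paired = TRUE, alternative = "greater",
                  exact = FALSE)$p.value)
  }
  reg <- function(y) {
    if (all(is.na(acc$grid_score))) return(c(NA_real_, NA_real_))
    fit <- lm(y ~ grid_score, data = acc)
    s <- summary(fit)
    c(s$r.squared, coef(s)["grid_score", "Pr(>|t|)"])
  }
  rt <- reg(acc$mean_within_dtheta)
  rl <- reg(acc$mean_within_dlambda)
  tibble(
    n_accepted = n,
    mean_within_dtheta = mean(acc$mean_within_dtheta),
    mean_between_dtheta = mean(acc$mean_between_dtheta),
    mean_within_dlambda = mean(acc$mean_within_dlambda),
    mean_between_dlambda = mean(acc$mean_between_dlambda),
    pct_between_gt_within_theta =
      100 * mean(acc$mean_between_dtheta > acc$mean_within_dtheta),
    pct_between_gt_within_lambda =
      100 * mean(acc$mean_between_dlambda > acc$mean_within_dlambda),
    p_theta = p_one_sided(acc$mean_between_dtheta, acc$mean_within_dtheta),
    p_lambda = p_one_sided(acc$mean_between_dlambda, acc$mean_within_dlambda),
    r2_theta_score = rt[1], p_theta_score = rt[2],
    r2_lambda_score = rl[1], p_lambda_score = rl[2]
  )
}

#' @exportS3Method generics::tidy
tidy.grid_variability <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.grid_variability <- function(x, ...) summarize_variability(x)
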
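# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, quick recording: 20 min, 3 cells, default module parameters.
small_session <- function() {
  fixture("small_session", {
    simulate_session(grid_population_spec(n = 3), duration_s = 20 * 60,
                     seed = 101)
  })
}

# A long single-cell session for rate-map fidelity checks: 130 min.
long_session <- function() {
  fixture("long_session", {
    simulate_session(grid_population_spec(n = 1), duration_s = 130 * 60,
                     seed = 202)
  })
}

# Hand-built recording: constant dt, stationary or scripted path.
scripted_recording <- function(t, x, y, spikes = list(u1 = numeric(0)),
                               arena = c(150, 150)) {
  grid_recording(data.frame(t = t, x = x, y = y), spikes, arena = arena)
}

# Independent direct (non-FFT) masked Pearson autocorrelogram, used as the
# oracle for compute_sac on tiny maps.
brute_sac <- function(vals, visited, min_overlap = 2) {
  nr <- nrow(vals); nc <- ncol(vals)
  out <- matrix(NA_real_, 2 * nr - 1, 2 * nc - 1)
  for (dr in -(nr - 1):(nr - 1)) {
    for (dc in -(nc - 1):(nc - 1)) {
      xs <- c(); ys <- c()
      for (i in 1:nr) for (j in 1:nc) {
        i2 <- i + dr; j2 <- j + dc
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
            visited[i, j] && visited[i2, j2]) {
          xs <- c(xs, vals[i, j]); ys <- c(ys, vals[i2, j2])
        }
      }
      if (length(xs) >= min_overlap && sd(xs) > 1e-12 && sd(ys) > 1e-12) {
        out[dr + nr, dc + nc] <- cor(xs, ys)
      }
    }
  }
  out
}

# Independent local-maximum finder (plain double loop) for lattice checks.
brute_peaks <- function(mat, threshold = -Inf) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- mat[i, j]
    if (is.na(v) || v <= threshold) next
    nb <- mat[(i - 1):(i + 1), (j - 1):(j + 1)]
    nb[2, 2] <- -Inf
    if (all(is.na(nb) | v >= nb)) out <- rbind(out, c(i, j))
  }
  out
}
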
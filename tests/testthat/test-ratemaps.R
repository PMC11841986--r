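test_that("occupancy assigns dwell to the containing bin and is conserved", {
  # stationary: all 60 s in one bin
  rec <- scripted_recording(t = seq(0, 60, 0.5), x = 10, y = 10)
  occ <- compute_occupancy(rec, 3)
  expect_equal(sum(occ), recording_duration(rec))
  expect_equal(sum(occ > 0), 1)
  expect_equal(occ[4, 4], recording_duration(rec)) # bin [9, 12) holds x = 10

  # conservation on a random trajectory
  rec2 <- small_session()
  expect_equal(sum(compute_occupancy(rec2, 3)), recording_duration(rec2))

  expect_error(compute_occupancy(rec, -1), "positive")
})

test_that("uniform sweep over four bins yields 2 s in each", {
  # 2 x 2 bin arena (6 x 6 cm, 3 cm bins); 4 samples x 0.5 s in each bin.
  centres <- rbind(c(1.5, 1.5), c(4.5, 1.5), c(1.5, 4.5), c(4.5, 4.5))
  idx <- rep(1:4, each = 4)
  rec <- scripted_recording(t = seq(0, by = 0.5, length.out = 16),
                            x = centres[idx, 1], y = centres[idx, 2],
                            arena = c(6, 6))
  occ <- compute_occupancy(rec, 3)
  expect_equal(occ, matrix(2, 2, 2))
})

test_that("raw rate is spike count over occupancy; zero spikes give zeros", {
  rec <- scripted_recording(t = seq(0, 2, 0.5), x = 10, y = 10,
                            spikes = list(u1 = c(0.9), u0 = numeric(0)))
  m <- compute_rate_map(rec, "u1", 3, smooth_sigma_bins = 0)
  expect_equal(m$values[4, 4], 1 / sum(m$occupancy)) # 1 spike / 2.5 s
  m0 <- compute_rate_map(rec, "u0", 3, smooth_sigma_bins = 0)
  expect_true(all(m0$values[m0$visited] == 0))
  expect_true(all(is.na(m0$values[!m0$visited])))
  expect_error(compute_rate_map(rec, "nope"), "unknown unit")
})

test_that("smoothed rate matches a direct Gaussian kernel-sum oracle", {
  rec <- small_session()
  m_raw <- compute_rate_map(rec, "cell001", 3, smooth_sigma_bins = 0)
  m_sm <- compute_rate_map(rec, "cell001", 3, smooth_sigma_bins = 1)
  # oracle: explicit truncated-Gaussian weighted average over visited bins,
  # at the interior visited bin with the most occupancy
  occ_int <- m_raw$occupancy
  occ_int[c(1:4, 47:50), ] <- -1
  occ_int[, c(1:4, 47:50)] <- -1
  occ_int[!m_raw$visited] <- -1
  target <- which(occ_int == max(occ_int), arr.ind = TRUE)[1, ]
  r <- 3
  num <- 0; den <- 0
  for (di in -r:r) for (dj in -r:r) {
    i <- target[1] + di; j <- target[2] + dj
    if (m_raw$visited[i, j]) {
      w <- exp(-(di^2) / 2) / sum(exp(-((-r:r)^2) / 2)) *
        exp(-(dj^2) / 2) / sum(exp(-((-r:r)^2) / 2))
      num <- num + w * m_raw$values[i, j]
      den <- den + w
    }
  }
  expect_equal(m_sm$values[target[1], target[2]], num / den,
               tolerance = 1e-10)
})

test_that("SAC matches a direct masked-Pearson oracle on a small map", {
  set.seed(4)
  vals <- matrix(rnorm(64, 5), 8, 8)
  visited <- matrix(TRUE, 8, 8)
  visited[1, 1:3] <- FALSE # a hole, to exercise the masked path
  vals[!visited] <- NA
  map <- gridvar:::new_rate_map(vals, matrix(1, 8, 8), 3, visited)
  sac <- compute_sac(map, min_overlap = 2)
  expect_equal(sac$values, brute_sac(vals, visited, min_overlap = 2),
               tolerance = 1e-8)
})

test_that("SAC has unit centre and point symmetry", {
  m <- compute_rate_map(small_session(), "cell002", 3, 1)
  sac <- compute_sac(m)
  n <- nrow(sac$values)
  expect_equal(sac$values[(n + 1) / 2, (n + 1) / 2], 1)
  flipped <- sac$values[n:1, n:1]
  expect_equal(sac$values, flipped, tolerance = 1e-8)
})

test_that("SAC of an ideal grid shows six inner peaks on the lattice", {
  lam <- 85
  m <- ideal_rate_map(lam, 0, 7, 11, xmax = 8)
  sac <- mask_center(compute_sac(m))
  pk <- find_sac_peaks(sac)
  expect_gte(nrow(pk), 6)
  six <- head(pk, 6)
  expect_equal(six$radius_bins, rep(lam / 3, 6), tolerance = 0.05)
  ang <- sort(six$angle_deg %% 60)
  expect_true(all(pmin(ang, 60 - ang) < 4))
  # three antipodal pairs
  for (i in 1:6) {
    expect_true(any(abs(six$dr + six$dr[i]) < 1e-9 &
                      abs(six$dc + six$dc[i]) < 1e-9))
  }
})

test_that("an all-constant map yields a degenerate SAC, not silent NaNs", {
  vals <- matrix(2, 10, 10)
  map <- gridvar:::new_rate_map(vals, matrix(1, 10, 10), 3,
                                matrix(TRUE, 10, 10))
  sac <- compute_sac(map)
  expect_true(sac$degenerate)
})

test_that("SAC commutes with 90-degree rotation of the map", {
  m <- compute_rate_map(small_session(), "cell001", 3, 1)
  rot_vals <- t(m$values)[ncol(m$values):1, ]
  rot_map <- gridvar:::new_rate_map(rot_vals, t(m$occupancy)[ncol(m$occupancy):1, ],
                                    3, t(m$visited)[ncol(m$visited):1, ])
  s1 <- compute_sac(m)$values
  s2 <- compute_sac(rot_map)$values
  s1_rot <- t(s1)[ncol(s1):1, ]
  expect_equal(s2, s1_rot, tolerance = 1e-8)
})

test_that("centre masking removes exactly the lattice points in the disc", {
  m <- compute_rate_map(small_session(), "cell001", 3, 1)
  sac <- compute_sac(m)
  r <- 5
  masked <- mask_center(sac, r)
  expect_true(masked$center_masked)
  # oracle: count integer lattice points with dr^2 + dc^2 <= r^2
  n_disc <- sum(outer((-r:r)^2, (-r:r)^2, "+") <= r^2)
  newly_na <- is.na(masked$values) & !is.na(sac$values)
  n <- nrow(sac$values)
  ctr <- (n + 1) / 2
  in_disc <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") <= r^2
  expect_equal(sum(in_disc), n_disc)
  expect_true(all(is.na(masked$values[in_disc])))
  # radius 0: only the centre bin changes
  m0 <- mask_center(sac, 0)
  expect_true(is.na(m0$values[ctr, ctr]))
  expect_equal(sum(is.na(m0$values) & !is.na(sac$values)), 1)
  # idempotent
  twice <- mask_center(masked, r)
  expect_equal(twice$values, masked$values)
})
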
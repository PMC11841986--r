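# Internal numerical helpers: separable Gaussian convolution, FFT-based
# masked cross-correlation, local maxima, image rotation, circular means.

# Discrete Gaussian kernel, truncated at ceiling(3*sigma) taps each side.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Banded Toeplitz matrix applying a symmetric 1-D kernel with zero padding.
band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    keep <- idx + off >= 1L & idx + off <= n
    m[cbind(idx[keep], (idx + off)[keep])] <- kernel[j]
  }
  m
}

# Separable 2-D Gaussian blur with zero padding.
conv2_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- gaussian_kernel(sigma)
  b1 <- band_matrix(nrow(mat), k)
  b2 <- band_matrix(ncol(mat), k)
  b1 %*% mat %*% t(b2)
}

# Mask-aware Gaussian smoothing: values outside `mask` carry no weight and
# the result is renormalized by the smoothed mask, so valid bins near holes
# or borders are not biased toward zero. Returns NA outside the mask.
smooth_masked <- function(mat, sigma, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(mat)
  if (sigma <= 0) {
    out <- mat
    out[!mask] <- NA_real_
    return(out)
  }
  x <- mat
  x[!mask] <- 0
  num <- conv2_gauss(x, sigma)
  den <- conv2_gauss(mask + 0, sigma)
  out <- num / den
  out[!mask | den < 1e-12] <- NA_real_
  out
}

# Full 2-D cross-correlation sum_i A[i] * B[i + d] for all integer lags d,
# computed with FFTs on zero-padded arrays. Returns a (2*nr-1) x (2*nc-1)
# matrix whose centre element is lag (0, 0); positive lags in a dimension
# mean B shifted toward larger indices.
xcorr2 <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  stopifnot(nrow(b) == nr, ncol(b) == nc)
  pr <- 2L * nr; pc <- 2L * nc
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[1:nr, 1:nc] <- a
  pb[1:nr, 1:nc] <- b
  cc <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / (pr * pc)
  # lag d in [-(n-1), n-1] lives at index ((d mod p) + 1)
  ridx <- c((pr - nr + 2L):pr, 1L:nr)
  cidx <- c((pc - nc + 2L):pc, 1L:nc)
  cc[ridx, cidx]
}

# Coordinates (in lag units) of each element of a (2n-1)-sided lag matrix.
lag_grid <- function(dim_out) {
  half_r <- (dim_out[1] - 1L) / 2L
  half_c <- (dim_out[2] - 1L) / 2L
  list(
    dr = matrix(rep(-half_r:half_r, dim_out[2]), dim_out[1], dim_out[2]),
    dc = matrix(rep(-half_c:half_c, each = dim_out[1]), dim_out[1], dim_out[2])
  )
}

# Local maxima of a matrix (8-neighbour rule, >= neighbours and above
# threshold). NA bins never qualify and never suppress a neighbour.
local_maxima <- function(mat, threshold = -Inf) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  filled <- mat
  filled[is.na(filled)] <- -Inf
  pad[2:(nr + 1L), 2:(nc + 1L)] <- filled
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_max <- is_max & (filled >= nb)
  }
  is_max & !is.na(mat) & mat > threshold & is.finite(filled)
}

# 3x3 quadratic sub-bin refinement of a peak location: least-squares
# paraboloid (with cross term) through the 9 neighbours; falls back to the
# integer peak when the surface is not concave or the shift exceeds one bin.
refine_peak_quadratic <- function(mat, r, c) {
  if (r <= 1 || r >= nrow(mat) || c <= 1 || c >= ncol(mat)) return(c(r, c))
  v <- mat[(r - 1):(r + 1), (c - 1):(c + 1)]
  if (anyNA(v)) return(c(r, c))
  x <- rep(-1:1, 3)
  y <- rep(-1:1, each = 3)
  z <- as.vector(v)
  # normal equations for z ~ 1 + x + y + x^2 + y^2 + xy on the 3x3 stencil
  b1 <- sum(x * z) / 6
  b2 <- sum(y * z) / 6
  d1 <- (sum(x^2 * z) - 2 / 3 * sum(z)) / 2 # coefficient of x^2
  d2 <- (sum(y^2 * z) - 2 / 3 * sum(z)) / 2
  d3 <- sum(x * y * z) / 4                  # coefficient of xy
  det <- 4 * d1 * d2 - d3^2
  if (!is.finite(det) || d1 >= 0 || d2 >= 0 || det <= 1e-12) return(c(r, c))
  dx <- (-2 * d2 * b1 + d3 * b2) / det
  dy <- (-2 * d1 * b2 + d3 * b1) / det
  if (abs(dx) > 1 || abs(dy) > 1) return(c(r, c))
  c(r + dx, c + dy)
}

# Rotate a matrix by `angle_deg` (counter-clockwise in (row, col) = (x, y)
# coordinates) about its centre, bilinear interpolation, NA outside or where
# any contributing bin is NA.
rotate_matrix <- function(mat, angle_deg) {
  nr <- nrow(mat); nc <- ncol(mat)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  out_r <- matrix(rep(seq_len(nr), nc), nr, nc) - cr
  out_c <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cc
  # inverse mapping: source = R(-th) %*% target
  sr <- co * out_r + si * out_c + cr
  sc <- -si * out_r + co * out_c + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  out <- matrix(NA_real_, nr, nc)
  g <- function(ri, ci) mat[cbind(ri, ci)]
  i <- which(ok)
  v00 <- g(r0[i], c0[i]); v10 <- g(r0[i] + 1, c0[i])
  v01 <- g(r0[i], c0[i] + 1); v11 <- g(r0[i] + 1, c0[i] + 1)
  out[i] <- (1 - fr[i]) * (1 - fc[i]) * v00 + fr[i] * (1 - fc[i]) * v10 +
    (1 - fr[i]) * fc[i] * v01 + fr[i] * fc[i] * v11
  out
}

# Circular mean of angles (degrees) on a circle of the given period.
circular_mean_deg <- function(angles_deg, period = 360) {
  a <- angles_deg * 2 * pi / period
  m <- atan2(mean(sin(a)), mean(cos(a))) * period / (2 * pi)
  m %% period
}

# Absolute circular distance between two angles on a circle of given period;
# result in [0, period/2].
circular_dist_deg <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# Deterministic derivation of stage seeds from one global seed, so pipeline
# stages can be re-run in isolation yet reproducibly. Documented contract:
# seed_stage = (seed * 2654435761 + sum of char codes of the key * 97 + index)
# mod (2^31 - 1).
derive_seed <- function(seed, key, index = 0L) {
  h <- sum(utf8ToInt(key)) * 97
  as.integer((as.numeric(seed) * 2654435761 + h + index) %% (2^31 - 1))
}

# Run `expr` under a local RNG state seeded with `seed` (NULL = use the
# current global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
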
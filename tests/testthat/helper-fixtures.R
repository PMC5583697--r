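# Shared fixtures and independent oracles used across the suite.

# Short uniform axis for fast cube fixtures.
small_axis <- function(n = 32) spectral_axis(seq(550, by = 1, length.out = n))

# Random non-negative cube fixture.
random_cube <- function(nr = 4, nc = 5, axis = small_axis(), seed = 1) {
  set.seed(seed)
  nl <- length(axis$wavelengths_nm)
  vals <- array(runif(nr * nc * nl, 0, 7), c(nr, nc, nl))
  spectral_cube(vals, axis, pixel_size_um = 0.5,
                metadata = list(instrument = instrument_model()))
}

# Closed-form Airy reflectance of a homogeneous film (independent oracle).
airy_reflectance <- function(n0, n1, n2, d_nm, wl_nm) {
  r1 <- (n0 - n1) / (n0 + n1)
  r2 <- (n1 - n2) / (n1 + n2)
  beta <- 2 * pi * n1 * d_nm / wl_nm
  r <- (r1 + r2 * exp(2i * beta)) / (1 + r1 * r2 * exp(2i * beta))
  Mod(r)^2
}

# Brute-force Kapur criterion maximiser (independent of the package path).
kapur_brute <- function(v, bins) {
  edges <- seq(min(v), max(v), length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                     bins), nbins = bins)
  p <- h / sum(h)
  best <- -Inf
  bt <- NA_real_
  for (t in seq_len(bins - 1L)) {
    p0 <- p[1:t]
    p1 <- p[(t + 1):bins]
    w0 <- sum(p0)
    w1 <- sum(p1)
    if (w0 <= 0 || w1 <= 0) next
    q0 <- p0[p0 > 0] / w0
    q1 <- p1[p1 > 0] / w1
    cr <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (cr > best + 1e-12) {
      best <- cr
      bt <- edges[t + 1L]
    }
  }
  bt
}

# Binary image of discs given (row, col, radius) triples, 0-based centres.
disc_image <- function(dim_px, discs) {
  rows <- matrix(0:(dim_px[1] - 1L), dim_px[1], dim_px[2])
  cols <- matrix(0:(dim_px[2] - 1L), dim_px[1], dim_px[2], byrow = TRUE)
  out <- matrix(FALSE, dim_px[1], dim_px[2])
  for (i in seq_len(nrow(discs)))
    out <- out | ((rows - discs[i, 1])^2 + (cols - discs[i, 2])^2 <=
                    discs[i, 3]^2)
  out
}

# Exact two-sided permutation p-value for a difference in means, n=10+10.
perm_p_exact_10_10 <- function(a, b) {
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(20L, 10L)
  tot <- sum(pool)
  ma <- colMeans(matrix(pool[idx], 10L))
  mean(abs(ma - (tot - 10 * ma) / 10) >= obs - 1e-12)
}

# Signed effect size (case minus control direction retained).
signed_effect_size <- function(a, b, ...) {
  effect_size(a, b, ...) * sign(mean(b) - mean(a))
}

# Best per-nucleus IoU of a predicted mask against a ground-truth mask.
per_nucleus_iou <- function(truth, predicted) {
  vapply(seq_len(max(truth$labels)), function(k) {
    gt <- truth$labels == k
    cand <- setdiff(unique(predicted$labels[gt]), 0L)
    if (length(cand) == 0L) return(0)
    max(vapply(cand, function(j) {
      pr <- predicted$labels == j
      sum(gt & pr) / sum(gt | pr)
    }, numeric(1)))
  }, numeric(1))
}
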
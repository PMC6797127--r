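# Independent closed-form and brute-force oracles used across the suite.

# overlap volume of two axis-aligned boxes given as (lo, hi) pairs
box_overlap_volume <- function(lo1, hi1, lo2, hi2) {
  prod(pmax(pmin(hi1, hi2) - pmax(lo1, lo2), 0))
}

# volume of the intersection lens of two spheres (closed form)
sphere_lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

# two-sided exact Mann-Whitney p by full enumeration of group assignments
brute_force_mwu_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  u_all <- apply(idx, 2, function(sel)
    sum(rank(pooled)[sel]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# standard frame landmarks: canonical axes (X lateral, Y anterior,
# Z cranial), CoR at the origin, rim circle of radius `rim_r` in the x = 0
# plane
canonical_landmarks <- function(rim_r = 26, rim_noise = 0, seed = NULL,
                                n_rim = 72) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n_rim + 1)[-(n_rim + 1)]
  rim <- cbind(0, rim_r * sin(th), rim_r * cos(th))
  if (rim_noise > 0)
    rim <- rim + matrix(stats::rnorm(3 * n_rim, 0, rim_noise), ncol = 3)
  list(asis_right = c(112, 30, 10), asis_left = c(-108, 30, 10),
       symphysis = c(2, 30, -80), cor = c(0, 0, 0), acetabular_rim = rim)
}

canonical_frame <- function(...) build_frame(canonical_landmarks(...), "R")

# memoized fixtures shared within a test file (phantom generation is the
# expensive part of the suite)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) assign(key, fn(), .fixture_cache)
  get(key, .fixture_cache)
}
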
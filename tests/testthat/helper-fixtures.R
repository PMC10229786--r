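# Small in-code fixtures shared across the suite.

# Random geometry with generic (tie-free) distances.
random_geometry <- function(m, seed = 1L) {
  coords <- withr::with_seed(seed, matrix(stats::runif(m * 3, 0, 100), m, 3))
  atlas_geometry(sprintf("R%02d", seq_len(m)), coords)
}

# Tiny cohort of pure-noise subjects (z-scored at construction).
noise_cohort <- function(n = 4, m = 6, t = 30, seed = 1L,
                         labels = rep_len(c("a", "b"), n)) {
  signals <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) matrix(stats::rnorm(t * m), t, m))
  })
  new_cohort(sprintf("sub%02d", seq_len(n)), signals, labels)
}

# Brute-force neighbour-set oracle: filter by radius, sort by (distance,
# index), take first k, add the centre.
neighbor_set_oracle <- function(i, geometry, k, r) {
  if (k == 0) return(i)
  d <- geometry$dist[i, ]
  cand <- setdiff(seq_len(geometry$m), i)
  cand <- cand[d[cand] < r * geometry$max_dist]
  cand <- cand[order(d[cand], cand)]
  if (length(cand) > k) cand <- cand[seq_len(k)]
  sort(c(i, cand))
}

# Textbook Pearson correlation of two vectors.
pearson_oracle <- function(a, b) {
  num <- sum((a - mean(a)) * (b - mean(b)))
  num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Outer-product + z-score fusion oracle.
fuse_oracle <- function(s1, s2) {
  v <- numeric(length(s1) * length(s2))
  idx <- 1
  for (a in seq_along(s1)) {
    for (b in seq_along(s2)) {
      v[idx] <- s1[a] * s2[b]
      idx <- idx + 1
    }
  }
  if (stats::sd(v) == 0) return(rep(0, length(v)))
  (v - mean(v)) / stats::sd(v)
}
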
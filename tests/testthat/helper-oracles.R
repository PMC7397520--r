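# Independent brute-force oracles used across the suite.  These deliberately
# use naive per-voxel / per-pair enumeration, never the package's vectorized
# code paths.

# Mean over the ROI's central cross-section in one plane, by looping over
# every voxel of the grid.
brute_plane_mean <- function(counts, spacing, center, diameter, plane,
                             labels = NULL, exclude_cortical = FALSE) {
  ax <- c(sagittal = 1L, coronal = 2L, axial = 3L)[[plane]]
  r2 <- (diameter / 2)^2
  shape <- dim(counts)
  centers <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  slice <- which.min(abs(centers[[ax]] - center[ax]))
  tot <- 0; n <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      idx <- c(i, j, k)
      if (idx[ax] != slice) next
      pt <- c(centers[[1]][i], centers[[2]][j], centers[[3]][k])
      if (sum(((pt - center)[-ax])^2) > r2 + 1e-9) next
      if (exclude_cortical && labels[i, j, k] == 2L) next
      tot <- tot + counts[i, j, k]
      n <- n + 1L
    }
  list(mean = tot / n, n = n)
}

# Mann-Whitney AUC by explicit enumeration of all positive-negative pairs.
brute_pair_auc <- function(scores, outcomes, lower_is_positive = TRUE) {
  pos <- scores[outcomes == "onfh"]
  neg <- scores[outcomes == "union"]
  s <- 0
  for (p in pos) for (q in neg) {
    d <- if (lower_is_positive) q - p else p - q
    s <- s + (d > 0) + 0.5 * (d == 0)
  }
  s / (length(pos) * length(neg))
}

# Mean of a truncated normal by numerical integration (independent of the
# closed-form used in the package).
integrate_tnorm_mean <- function(mu, sigma, lower, upper) {
  z <- pnorm(upper, mu, sigma) - pnorm(lower, mu, sigma)
  stats::integrate(function(x) x * dnorm(x, mu, sigma) / z,
                   lower, upper, rel.tol = 1e-10)$value
}

# Random small voxel fixture with integer counts (so sums are exact in
# double precision and oracle comparisons can be exact).
random_volume_fixture <- function(shape = c(9L, 9L, 9L), spacing = 1,
                                  lambda = 50) {
  counts <- array(rpois(prod(shape), lambda), dim = shape)
  voxel_volume(counts, spacing)
}

# Random score/outcome fixture with ties, guaranteed two classes.
random_roc_fixture <- function(n_max = 50L) {
  n <- sample(4:n_max, 1)
  repeat {
    outcomes <- sample(c("onfh", "union"), n, replace = TRUE)
    if (length(unique(outcomes)) == 2L) break
  }
  scores <- round(rlnorm(n, 0, 0.5), sample(1:2, 1))
  list(scores = scores, outcomes = outcomes)
}

# Correlated paired-marker fixture: two noisy monotone readings of one
# latent perfusion score.
paired_marker_fixture <- function(n = 30L, n_pos = NULL) {
  if (is.null(n_pos)) n_pos <- sample(6:15, 1)
  outcomes <- c(rep("onfh", n_pos), rep("union", n - n_pos))
  latent <- rnorm(n) + ifelse(outcomes == "onfh", -1.2, 0)
  list(scores_a = latent + rnorm(n, sd = 0.6),
       scores_b = latent + rnorm(n, sd = 0.6),
       outcomes = outcomes)
}

# Patient-level bootstrap variance of the Mann-Whitney AUC (rank form).
bootstrap_auc_variance <- function(scores, outcomes, B = 10000L) {
  n <- length(outcomes)
  pos <- outcomes == "onfh"
  aucs <- numeric(B)
  kept <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- pos[idx]
    m <- sum(p)
    if (m == 0L || m == n) next   # degenerate resample: AUC undefined
    r <- rank(-scores[idx])       # lower score = more diseased
    kept <- kept + 1L
    aucs[kept] <- (sum(r[p]) - m * (m + 1) / 2) / (m * (n - m))
  }
  stats::var(aucs[seq_len(kept)])
}

# Small anatomy that keeps test-time phantoms cheap (~64^3 voxels).
small_anatomy <- function() {
  anatomy_model(
    volume_shape = c(64L, 64L, 64L), voxel_spacing = 4.4,
    femoral_head_center_left = c(60, 130, 100),
    femoral_head_center_right = c(190, 130, 100),
    acetabular_dome_center_left = c(80, 130, 128),
    acetabular_dome_center_right = c(170, 130, 128)
  )
}
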
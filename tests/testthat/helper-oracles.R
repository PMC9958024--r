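# Independent brute-force oracles used to freeze expected values.

# Exhaustive Otsu: direct between-class variance at every interior bin edge,
# computed by looping over candidates (no cumulative-sum algebra). Shares
# only the histogram construction with the implementation.
oracle_otsu <- function(v, nbins) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = nbins + 1)
  bin <- findInterval(v, edges, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  best <- -Inf
  best_edge <- NA_real_
  for (t in seq_len(nbins - 1)) {
    n0 <- sum(counts[1:t])
    n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1):nbins] * centers[(t + 1):nbins]) / n1
    bcv <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_edge <- edges[t + 1]
    }
  }
  best_edge
}

# All-pairs Hausdorff distance, O(|A||B|).
oracle_hausdorff <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(max(sqrt(apply(d2, 1, min))), max(sqrt(apply(d2, 2, min))))
}

# Exhaustive k-medoids: minimal total L1 cost over all medoid subsets.
oracle_kmedoids_cost <- function(values, k) {
  combos <- utils::combn(length(values), k)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    med <- values[combos[, j]]
    cost <- sum(apply(abs(outer(values, med, `-`)), 1, min))
    if (cost < best) best <- cost
  }
  best
}

# angle between two unit vectors, ignoring sign, in degrees
angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# relative rotation angle between two frames expressed as global_axes
frame_rotation_matrix <- function(axes) {
  rbind(axes$x_axis, axes$y_axis, axes$z_axis, deparse.level = 0)
}

# Rodrigues rotation about a unit axis by an angle in degrees
rotation_axis_angle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
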
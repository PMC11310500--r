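## Independent brute-force oracles and fixture builders. The oracles never
## call the package's optimized paths: confusion counts are an explicit
## triple loop over voxel indices, nearest-neighbor distances an explicit
## double loop over point pairs.

bruteConfusion <- function(gtArr, testArr, lo, hi) {
  tp <- fp <- fn <- tn <- 0L
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    g <- gtArr[i, j, k]; t_ <- testArr[i, j, k]
    if (g && t_) tp <- tp + 1L
    else if (!g && t_) fp <- fp + 1L
    else if (g && !t_) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

bruteNN <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2 +
                (A[i, 3] - B[j, 3])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

## Naive full distance-metric set: brute-force NN both ways, then the same
## seven statistics computed directly.
bruteDistanceMetrics <- function(A, B) {
  dAB <- bruteNN(A, B)
  dBA <- bruteNN(B, A)
  v <- c(dAB, dBA)
  c(HD_std = sqrt(mean((v - mean(v))^2)), HD_min = min(v),
    HD_median = median(v), HD_mean = mean(v), MDA = mean(dAB),
    HD_95 = unname(quantile(v, 0.95, type = 7)), HD_max = max(v))
}

## Solid sphere mask: voxel centers within radius r (voxels) of center
## (1-based voxel index), on a unit-spacing grid of dims d.
sphereMaskArray <- function(d, center, r) {
  ux <- (seq_len(d[1]) - center[1])^2
  uy <- (seq_len(d[2]) - center[2])^2
  uz <- (seq_len(d[3]) - center[3])^2
  outer(outer(ux, uy, "+"), uz, "+") <= r^2
}

sphereMask <- function(d, center, r, spacing = c(1, 1, 1),
                       organ = "brain", role = "ground_truth") {
  suppressWarnings(binaryMask(sphereMaskArray(d, center, r), organ = organ,
                              role = role, spacing = spacing))
}

randomMaskArray <- function(d, p = 0.3) {
  array(runif(prod(d)) < p, dim = d)
}

randomMask <- function(d, p = 0.3, organ = "brain", role = "ground_truth") {
  suppressWarnings(binaryMask(randomMaskArray(d, p), organ = organ,
                              role = role))
}
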
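# Independent oracles used across tests. Each is deliberately written as the
# dumbest correct implementation, sharing no code with the package.

# Full-grid voxel scan: loop every voxel, accumulate count and RAS sums.
brute_force_structure <- function(volume, codes) {
  d <- dim(volume$labels)
  A <- volume$affine
  n <- 0L; sx <- 0; sy <- 0; sz <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (volume$labels[i, j, k] %in% codes) {
      p <- A %*% c(i - 1, j - 1, k - 1, 1)
      n <- n + 1L; sx <- sx + p[1]; sy <- sy + p[2]; sz <- sz + p[3]
    }
  }
  list(n_voxels = n, volume_mm3 = n * volume$voxel_volume,
       centroid = c(sx, sy, sz) / n)
}

# Benjamini-Hochberg step-up computed literally from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[ord[k]] * m / k)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}

# Welch statistic, degrees of freedom, and two-sided p from the formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Expand a 2x2 confusion matrix (rows = actual, cols = predicted) into
# actual/predicted label vectors.
confusion_to_vectors <- function(cm, classes) {
  actual <- character(0); predicted <- character(0)
  for (i in 1:2) for (j in 1:2) {
    actual <- c(actual, rep(classes[i], cm[i, j]))
    predicted <- c(predicted, rep(classes[j], cm[i, j]))
  }
  list(actual = factor(actual, levels = classes),
       predicted = factor(predicted, levels = classes))
}

# Single-structure registry for geometric primitives.
single_registry <- function(name = "Sphere", codes = 1L) {
  structure(setNames(list(as.integer(codes)), name),
            reference = name, class = "structure_registry")
}
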
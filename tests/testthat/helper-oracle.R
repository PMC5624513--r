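# Independent brute-force oracles. These re-derive every information measure
# with straight-line loops over joint probability tables, sharing no helpers
# with the package internals, so agreement is a real cross-check.

oracle_entropy <- function(p) {
  h <- 0
  for (v in as.numeric(p)) if (v > 0) h <- h - v * log2(v)
  h
}

# all oracle_* below take a 3d joint array p[x, y, z]
oracle_marginal <- function(p, keep) {
  d <- dim(p)
  out <- array(0, d[keep])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)[keep]
    out[matrix(idx, 1)] <- out[matrix(idx, 1)] + p[i, j, k]
  }
  out
}

oracle_mi <- function(p2) {
  px <- rowSums(p2); py <- colSums(p2)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    v <- p2[i, j]
    if (v > 0) s <- s + v * log2(v / (px[i] * py[j]))
  }
  s
}

oracle_cmi <- function(p3) {
  # I(X;Y|Z) = sum p(x,y,z) log( p(z) p(x,y,z) / (p(x,z) p(y,z)) )
  pxz <- oracle_marginal(p3, c(1, 3))
  pyz <- oracle_marginal(p3, c(2, 3))
  pz <- oracle_marginal(p3, 3)
  s <- 0
  d <- dim(p3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- p3[i, j, k]
    if (v > 0) s <- s + v * log2(pz[k] * v / (pxz[i, k] * pyz[j, k]))
  }
  s
}

oracle_interaction_information <- function(p3) {
  oracle_cmi(p3) - oracle_mi(oracle_marginal(p3, c(1, 2)))
}

# specific information of source (axis 1) about state z of target (axis 2)
oracle_specific_information <- function(p2, z) {
  pz <- colSums(p2)
  px <- rowSums(p2)
  s <- 0
  for (i in seq_along(px)) {
    if (p2[i, z] > 0) {
      px_z <- p2[i, z] / pz[z]        # p(x|z)
      pz_x <- p2[i, z] / px[i]        # p(z|x)
      s <- s + px_z * (log2(1 / pz[z]) - log2(1 / pz_x))
    }
  }
  s
}

# full PID for target on axis 3, sources on axes 1 and 2
oracle_pid <- function(p3) {
  pxz <- oracle_marginal(p3, c(1, 3))
  pyz <- oracle_marginal(p3, c(2, 3))
  pz <- oracle_marginal(p3, 3)
  red <- 0
  for (z in seq_along(pz)) {
    if (pz[z] > 0) {
      red <- red + pz[z] * min(oracle_specific_information(pxz, z),
                               oracle_specific_information(pyz, z))
    }
  }
  i_xz <- oracle_mi(pxz)
  i_yz <- oracle_mi(pyz)
  ii <- oracle_interaction_information(p3)
  list(redundancy = red, unique_x = i_xz - red, unique_y = i_yz - red,
       synergy = ii + red, mi_x = i_xz, mi_y = i_yz)
}

# random discretized triplet with <= max_bins states per variable
random_triplet <- function(n, max_bins = 4) {
  bx <- sample(2:max_bins, 1); by <- sample(2:max_bins, 1)
  bz <- sample(2:max_bins, 1)
  # mix of independent and coupled draws so all PID regimes occur
  z <- sample.int(bz, n, replace = TRUE)
  x <- pmin(bx, pmax(1, z + sample(c(-1, 0, 1), n, replace = TRUE,
                                   prob = c(0.2, 0.6, 0.2))))
  y <- if (runif(1) < 0.5) {
    sample.int(by, n, replace = TRUE)
  } else {
    pmin(by, pmax(1, x + sample(c(-1, 0, 1), n, replace = TRUE)))
  }
  list(x = x, y = y, z = z, bins = c(bx, by, bz))
}

ml_joint3 <- function(x, y, z, bins) {
  p <- array(0, bins)
  for (i in seq_along(x)) p[x[i], y[i], z[i]] <- p[x[i], y[i], z[i]] + 1
  p / length(x)
}

# brute-force PR/ROC sweep over an explicit ordered pair list
oracle_pr_roc <- function(ordered_is_positive, n_pos, n_neg) {
  tp <- 0; fp <- 0
  aupr <- 0
  roc_x <- 0; roc_y <- 0; auroc <- 0
  for (k in seq_along(ordered_is_positive)) {
    if (ordered_is_positive[k]) {
      tp <- tp + 1
      aupr <- aupr + (1 / n_pos) * (tp / k)
    } else {
      fp <- fp + 1
      auroc <- auroc + (1 / n_neg) * (tp / n_pos)
    }
  }
  list(aupr = aupr, auroc = auroc)
}

# all permutations of a small index vector (list of integer vectors)
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# deterministic small expression fixture: two coupled genes plus noise genes
toy_expression <- function(n_cells = 60, n_noise = 1, seed = 42) {
  set.seed(seed)
  g1 <- rnorm(n_cells)
  g2 <- g1 + rnorm(n_cells, sd = 0.25)
  noise <- matrix(rnorm(n_noise * n_cells), n_noise)
  m <- rbind(g1, g2, noise)
  rownames(m) <- paste0("G", seq_len(nrow(m)))
  colnames(m) <- paste0("cell", seq_len(ncol(m)))
  m
}
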
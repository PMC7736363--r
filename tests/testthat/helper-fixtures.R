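# Small fixtures shared across test files; everything is built in code.

small_config <- function(seed = 1L, n_genes = 120L, noise_cv = 0.05,
                         fractions = c(0.1, 0.2, 0.3), ...) {
  synth_config(n_tissues = length(fractions), n_genes = n_genes,
               cycling_fraction = fractions, noise_cv = noise_cv,
               seed = seed, ...)
}

# tiny expression matrix: 3 genes x 2 tissues x 4 timepoints
tiny_matrix <- function() {
  tt <- c(0, 6, 12, 18)
  samp <- data.frame(sample = c(paste0("liver:CT", sprintf("%02d", tt)),
                                paste0("lung:CT", sprintf("%02d", tt))),
                     tissue = rep(c("liver", "lung"), each = 4),
                     time = rep(tt, 2))
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                g2 = c(10, 12, 10, 12, 9, 11, 9, 11),
                g3 = rep(2, 8))
  colnames(vals) <- samp$sample
  expr_matrix(vals, samp)
}

# brute-force Pearson/Spearman with explicit sums (independent oracle)
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
brute_spearman <- function(x, y) brute_pearson(rank(x), rank(y))

# All permutations of 1..n (n small), one row per permutation.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Kendall S between each row of a permutation matrix and identity ranking.
perm_s_values <- function(P) {
  n <- ncol(P)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sgn <- sign(P[, pr[, 2], drop = FALSE] - P[, pr[, 1], drop = FALSE])
  rowSums(sgn)
}
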
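# JTK-style nonparametric rhythm test: Kendall tau against phase-shifted
# cosine references, with the exact null distribution of Kendall's S.

#' Exact null distribution of Kendall's S statistic
#'
#' Distribution of `S = concordant - discordant` pairs between a fixed
#' tie-free reference ranking and a uniformly random permutation of n
#' distinct values. Computed by the classical convolution recurrence for
#' the number of inversions: the generating polynomial
#' `prod_{k=1..n} (1 + x + ... + x^(k-1))`. Counts are exact integers for
#' `n <= 18` (they stay below 2^53); beyond that, normalised probabilities
#' are returned with `count = NULL`.
#'
#' @param n Number of observations (`n >= 2`).
#' @return List with `S` (possible values, descending from `n(n-1)/2` in
#'   steps of 2), `prob` (exact probabilities), and `count` (exact
#'   permutation counts, or NULL for `n > 18`).
#' @export
kendall_s_null <- function(n) {
  stopifnot(n >= 2)
  d0 <- n * (n - 1) / 2
  coefs <- 1  # polynomial in x over inversion counts, constant term first
  for (k in 2:n) {
    # multiply by (1 + x + ... + x^(k-1)) via a sliding-window cumsum
    cs <- cumsum(c(coefs, rep(0, k - 1)))
    upper <- cs
    lower <- c(rep(0, k), cs[seq_len(length(cs) - k)])
    coefs <- upper - lower
  }
  # inversions d = 0..d0 ; S = d0 - 2d (d = 0 means perfect concordance)
  total <- sum(coefs)
  list(S = d0 - 2 * (0:d0),
       prob = coefs / total,
       count = if (n <= 18) coefs else NULL)
}

# Two-sided exact tail P(|S'| >= s) for s = 0..d0, returned as a lookup
# vector indexed by s + 1. The S-null is symmetric about 0.
kendall_s_tail <- function(n) {
  null <- kendall_s_null(n)
  s_abs <- abs(null$S)
  d0 <- n * (n - 1) / 2
  tail <- numeric(d0 + 1)
  for (k in 0:d0) tail[k + 1] <- sum(null$prob[s_abs >= k])
  pmin(1, tail)
}

jtk_references <- function(times, period, interval, offsets = NULL) {
  if (is.null(offsets)) offsets <- seq(0, period - interval, by = interval)
  refs <- t(vapply(offsets, function(off)
    cos(2 * pi * (times - off) / period), numeric(length(times))))
  rownames(refs) <- sprintf("T%g_off%g", period, offsets)
  refs
}

# Vectorised JTK over all rows of Y. Returns a p-value per gene: the exact
# two-sided tail of the best (by tie-corrected |tau|) reference's S,
# Bonferroni-corrected by the number of references tested.
jtk_p_matrix <- function(Y, times, config, offsets = NULL) {
  n <- length(times)
  interval <- unique(round(diff(sort(times)), 9))
  if (length(interval) != 1L)
    return(list(p = rep(NA_real_, nrow(Y)),
                reason = "JTK requires a complete regular timepoint grid"))
  grid <- period_grid(config)
  periods <- grid[abs(grid / interval - round(grid / interval)) < 1e-9]
  if (!length(periods))
    return(list(p = rep(NA_real_, nrow(Y)),
                reason = "no grid period is an integer number of sampling steps"))
  refs <- do.call(rbind, lapply(periods, function(T)
    jtk_references(times, T, interval, offsets)))
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  signY <- sign(Y[, ii, drop = FALSE] - Y[, jj, drop = FALSE])
  signR <- sign(refs[, ii, drop = FALSE] - refs[, jj, drop = FALSE])
  S <- signY %*% t(signR)                      # genes x refs
  nY <- rowSums(abs(signY))                    # untied pairs in the data
  nR <- rowSums(abs(signR))                    # untied pairs in each ref
  denom <- sqrt(outer(nY, nR))
  tau <- S / denom
  tau[!is.finite(tau)] <- 0
  best <- max.col(abs(tau), ties.method = "first")
  s_best <- abs(S[cbind(seq_len(nrow(S)), best)])
  tail <- kendall_s_tail(n)
  p <- pmin(1, nrow(refs) * tail[s_best + 1])
  p[nY == 0] <- 1                              # all-tied series
  list(p = p, reason = NULL, n_refs = nrow(refs))
}

#' JTK-style rank-based rhythmicity p-value
#'
#' For every grid period realisable in integer sampling steps and every
#' phase offset on the sampling-interval grid, the tie-corrected Kendall
#' tau between the series and a phase-shifted cosine reference is computed.
#' The p-value is the exact two-sided tail of Kendall's S for the
#' best-matching reference, from the exact permutation null (see
#' [kendall_s_null()]), Bonferroni-corrected by the number of references
#' tested and clipped to `[0, 1]`. Requires a complete regular grid of at
#' least 6 timepoints; an all-tied series returns 1.
#'
#' @inheritParams best_period
#' @param offsets Optional explicit phase offsets (hours); `NULL` means all
#'   sampling-interval steps within each period. Passing a single offset
#'   together with a single-period grid gives the uncorrected exact test.
#' @return A p-value in `[0, 1]` (NA, with a message, if the grid is not
#'   regular or no period is realisable).
#' @export
jtk_p <- function(times, values, config = detection_config(),
                  offsets = NULL) {
  ok <- is.finite(values) & is.finite(times)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 6) stop("JTK needs at least 6 timepoints")
  res <- jtk_p_matrix(matrix(values, 1), times, config, offsets)
  if (!is.null(res$reason)) message(res$reason)
  res$p
}
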
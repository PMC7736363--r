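# Lomb-Scargle periodogram with the classical single-frequency null.

# Standard-normalised Lomb-Scargle power for all rows of Y at one frequency
# (cycles per hour), with the usual phase offset tau making the cosine and
# sine terms orthogonal. Normalisation is by the total sample variance
# (n - 1 denominator), under which the single-frequency null tail is
# exactly (1 - 2z/(n-1))^((n-3)/2) for Gaussian noise.
ls_power_matrix <- function(Y, times, freq) {
  n <- length(times)
  w <- 2 * pi * freq
  tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
  ct <- cos(w * (times - tau))
  st <- sin(w * (times - tau))
  Yc <- Y - rowMeans(Y)
  s2 <- rowSums(Yc^2) / (n - 1)
  pow <- ((Yc %*% ct)^2 / sum(ct^2) + (Yc %*% st)^2 / sum(st^2)) / (2 * s2)
  as.numeric(pow)
}

ls_p_matrix <- function(Y, times, config) {
  n <- length(times)
  freqs <- unique(1 / period_grid(config))
  pows <- vapply(freqs, function(f) ls_power_matrix(Y, times, f),
                 numeric(nrow(Y)))
  if (is.null(dim(pows))) pows <- matrix(pows, nrow = 1)
  zmax <- apply(pows, 1, max)
  base <- pmax(0, 1 - 2 * zmax / (n - 1))
  p1 <- base^((n - 3) / 2)
  p <- pmin(1, length(freqs) * p1)
  const <- rowSums((Y - rowMeans(Y))^2) <= 1e-24 * (rowMeans(Y^2) + 1)
  p[const] <- 1
  p
}

#' Lomb-Scargle rhythmicity p-value over a period grid
#'
#' Evaluates the standard-normalised Lomb-Scargle periodogram at the
#' frequencies `1/T` for every period `T` on the configured grid. The
#' single-frequency null tail for Gaussian noise,
#' `(1 - 2z/(n-1))^((n-3)/2)`, is Bonferroni-corrected by the number of
#' grid frequencies and clipped to `[0, 1]`. A constant series returns 1.
#' For an uncorrected, exactly calibrated p-value, pass a config whose grid
#' contains a single period.
#'
#' @inheritParams best_period
#' @return A p-value in `[0, 1]`.
#' @export
lombscargle_p <- function(times, values, config = detection_config()) {
  ok <- is.finite(values) & is.finite(times)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 4) stop("Lomb-Scargle needs at least 4 timepoints")
  ls_p_matrix(matrix(values, 1), times, config)
}
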
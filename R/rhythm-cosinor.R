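#' @importFrom stats pf pchisq setNames
NULL

cosinor_design <- function(times, period) {
  cbind(intercept = 1, c = cos(2 * pi * times / period),
        s = sin(2 * pi * times / period))
}

# Vectorised cosinor fit: Y is genes x timepoints. Returns per-gene
# baseline, amplitude, phase, p (F-test of the harmonic terms), rss.
cosinor_fit_matrix <- function(Y, times, period) {
  n <- length(times)
  X <- cosinor_design(times, period)
  qx <- qr(X)
  coef <- t(qr.coef(qx, t(Y)))            # genes x 3
  fitted <- coef %*% t(X)
  rss1 <- rowSums((Y - fitted)^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  df2 <- n - 3
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
  p <- pf(Fstat, 2, df2, lower.tail = FALSE)
  amp <- sqrt(coef[, 2]^2 + coef[, 3]^2)
  phase <- ((period / (2 * pi)) * atan2(coef[, 3], coef[, 2])) %% period
  # constant series: no rhythm signal, amplitude 0, p 1
  scale <- rowMeans(Y^2) + 1
  const <- rss0 <= 1e-24 * scale
  if (any(const)) {
    p[const] <- 1
    amp[const] <- 0
    phase[const] <- 0
  }
  # noiseless in-class series: rss1 ~ 0 but rss0 > 0 -> p underflows to 0
  perfect <- !const & rss1 <= 1e-24 * scale
  p[perfect] <- 0
  list(baseline = coef[, 1], amplitude = amp, phase = phase, p = p,
       rss = rss1)
}

#' Harmonic (cosinor) regression at a fixed period
#'
#' Least-squares fit of `y = M + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`.
#' Baseline is `M`, amplitude `sqrt(a^2 + b^2)`, phase the time of the
#' fitted peak `(T/2*pi) * atan2(b, a) mod T` measured from time zero, and
#' the p-value comes from the F-test of the two harmonic terms against the
#' intercept-only model. A constant series returns amplitude 0 and p = 1.
#'
#' @param times Sampling times in hours (at least 4 distinct values).
#' @param values Numeric vector of expression values (NAs dropped pairwise).
#' @param period Period T in hours.
#' @return List with `baseline`, `amplitude`, `phase`, `p`, `rss`.
#' @examples
#' t <- seq(0, 46, by = 2)
#' y <- 10 + 4 * cos(2 * pi * (t - 6) / 24)
#' cosinor_fit(t, y, 24)
#' @export
cosinor_fit <- function(times, values, period) {
  ok <- is.finite(values) & is.finite(times)
  times <- times[ok]; values <- values[ok]
  if (length(unique(times)) < 4)
    stop("cosinor fit needs at least 4 distinct timepoints")
  res <- cosinor_fit_matrix(matrix(values, 1), times, period)
  lapply(res, as.numeric)
}

#' Detection configuration for rhythmicity analysis
#'
#' @param period_min,period_max Period grid bounds in hours.
#' @param period_step Grid step in hours.
#' @param methods Subset of `c("cosinor", "lombscargle", "jtk")`.
#' @param q_threshold BH q-value below which a gene is called rhythmic.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(period_min = 20, period_max = 28,
                             period_step = 0.5,
                             methods = c("cosinor", "lombscargle", "jtk"),
                             q_threshold = 0.05) {
  if (period_min > period_max) stop("period_min must be <= period_max")
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(methods)) stop("at least one method is required")
  structure(list(period_min = period_min, period_max = period_max,
                 period_step = period_step, methods = methods,
                 q_threshold = q_threshold), class = "detection_config")
}

period_grid <- function(config) {
  seq(config$period_min, config$period_max, by = config$period_step)
}

# Vectorised best-period search: returns per-gene period minimising the
# cosinor residual sum of squares over the grid (ties -> smallest period).
best_period_matrix <- function(Y, times, config) {
  grid <- period_grid(config)
  rss <- vapply(grid, function(T)
    cosinor_fit_matrix(Y, times, T)$rss, numeric(nrow(Y)))
  if (is.null(dim(rss))) rss <- matrix(rss, nrow = 1)
  grid[max.col(-rss, ties.method = "first")]
}

#' Best period on the grid by cosinor residual sum of squares
#'
#' @inheritParams cosinor_fit
#' @param config A [detection_config()].
#' @return The grid period (hours) minimising the cosinor RSS; ties go to
#'   the smallest period.
#' @export
best_period <- function(times, values, config = detection_config()) {
  ok <- is.finite(values) & is.finite(times)
  best_period_matrix(matrix(values[ok], 1), times[ok], config)
}
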
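#' Integrate several p-values by Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. Zero p-values are floored at
#' 1e-300 (with a warning) before taking logs. With a single p-value the
#' method is the identity.
#'
#' @param ps Numeric vector of p-values in `(0, 1]` (NAs dropped).
#' @return The integrated p-value.
#' @examples
#' meta_integrate(c(0.01, 0.02, 0.03))
#' @export
meta_integrate <- function(ps) {
  ps <- ps[!is.na(ps)]
  if (!length(ps)) stop("no p-values to integrate")
  if (any(ps < 0 | ps > 1)) stop("p-values must lie in [0, 1]")
  if (any(ps == 0)) {
    warning("p-value of 0 floored at 1e-300 before Fisher integration")
    ps <- pmax(ps, 1e-300)
  }
  X <- -2 * sum(log(ps))
  stats::pchisq(X, df = 2 * length(ps), lower.tail = FALSE)
}

# Row-wise Fisher integration over a p-value matrix (NAs allowed per cell);
# silent flooring, used by detect_all which warns once.
fisher_rows <- function(P) {
  P <- pmax(P, 1e-300)
  k <- rowSums(!is.na(P))
  X <- -2 * rowSums(log(P), na.rm = TRUE)
  out <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
  out[k == 0] <- NA_real_
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`,
#' clipped at 1; monotone nondecreasing in p and order-preserving.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(ps) {
  stats::p.adjust(ps, method = "BH")
}

#' Detect rhythmic genes in every tissue
#'
#' For each tissue (analysed independently) and each gene: the period is
#' chosen on the configured grid by minimum cosinor residual sum of
#' squares; baseline, amplitude and phase come from the cosinor fit at that
#' period; the configured method p-values (cosinor F-test,
#' [lombscargle_p()], [jtk_p()]) are integrated with Fisher's method into
#' `p_meta`; q-values are Benjamini-Hochberg adjusted across all genes
#' within the tissue; a gene is rhythmic when `q < q_threshold`. Relative
#' amplitude is `AMP / baseline` (NA when baseline <= 0, which excludes the
#' gene from amplitude-based screens).
#'
#' @param x An [expr_matrix()] or a named per-tissue list of them (e.g. the
#'   `tissues` element returned by the filters).
#' @param config A [detection_config()].
#' @return data.frame with one row per gene per tissue and columns `gene`,
#'   `tissue`, `p_cosinor`, `p_ls`, `p_jtk`, `p_meta`, `q`, `period`,
#'   `phase`, `baseline`, `AMP`, `rAMP`, `rhythmic`.
#' @export
detect_all <- function(x, config = detection_config()) {
  tl <- as_tissue_list(x)
  floored <- FALSE
  res <- lapply(names(tl), function(tt) {
    m <- tl[[tt]]
    if (!nrow(m$values))
      return(NULL)
    ord <- order(m$samples$time)
    times <- m$samples$time[ord]
    Y <- m$values[, ord, drop = FALSE]
    per <- best_period_matrix(Y, times, config)
    base <- amp <- phase <- p_cos <- numeric(nrow(Y))
    for (T in unique(per)) {
      sel <- per == T
      fit <- cosinor_fit_matrix(Y[sel, , drop = FALSE], times, T)
      base[sel] <- fit$baseline
      amp[sel] <- fit$amplitude
      phase[sel] <- fit$phase
      p_cos[sel] <- fit$p
    }
    # like the other components, correct the cosinor p for its own
    # period-grid search (the F-test was taken at the RSS-minimising period)
    p_cos <- pmin(1, length(period_grid(config)) * p_cos)
    p_ls <- if ("lombscargle" %in% config$methods)
      ls_p_matrix(Y, times, config) else rep(NA_real_, nrow(Y))
    p_jtk <- rep(NA_real_, nrow(Y))
    if ("jtk" %in% config$methods) {
      jt <- jtk_p_matrix(Y, times, config)
      if (!is.null(jt$reason))
        message("tissue '", tt, "': JTK skipped (", jt$reason, ")")
      p_jtk <- jt$p
    }
    if (!"cosinor" %in% config$methods) p_cos_use <- rep(NA_real_, nrow(Y))
    else p_cos_use <- p_cos
    P <- cbind(cosinor = p_cos_use, ls = p_ls, jtk = p_jtk)
    if (any(P == 0, na.rm = TRUE)) floored <<- TRUE
    p_meta <- fisher_rows(P)
    q <- bh_adjust(p_meta)
    ramp <- ifelse(base > 0, amp / base, NA_real_)
    data.frame(gene = rownames(Y), tissue = tt,
               p_cosinor = p_cos, p_ls = p_ls, p_jtk = p_jtk,
               p_meta = p_meta, q = q, period = per, phase = phase,
               baseline = base, AMP = amp, rAMP = ramp,
               rhythmic = !is.na(q) & q < config$q_threshold,
               row.names = NULL)
  })
  if (floored)
    warning("some method p-values were 0 and were floored at 1e-300 ",
            "before Fisher integration")
  do.call(rbind, res)
}

#' Per-tissue summary of q, amplitude and relative-amplitude distributions
#'
#' Mirrors the per-tissue descriptive panels of a multi-tissue rhythmicity
#' analysis: expressed and rhythmic counts, quartiles of the q-value over
#' all expressed genes, and quartiles of AMP and rAMP over rhythmic genes
#' only (NA and flagged when a tissue has no rhythmic genes).
#'
#' @param results data.frame from [detect_all()].
#' @return data.frame with one row per tissue.
#' @export
summarize_distributions <- function(results) {
  stopifnot(nrow(results) > 0)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  out <- lapply(split(results, results$tissue), function(d) {
    rhy <- d[d$rhythmic, , drop = FALSE]
    qq <- qs(d$q)
    if (nrow(rhy)) {
      qa <- qs(rhy$AMP); qr <- qs(rhy$rAMP)
    } else {
      qa <- qr <- rep(NA_real_, 3)
    }
    data.frame(tissue = d$tissue[1], n_expressed = nrow(d),
               n_rhythmic = nrow(rhy),
               q_q25 = qq[1], q_median = qq[2], q_q75 = qq[3],
               amp_q25 = qa[1], amp_median = qa[2], amp_q75 = qa[3],
               ramp_q25 = qr[1], ramp_median = qr[2], ramp_q75 = qr[3],
               no_rhythmic = nrow(rhy) == 0, row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
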
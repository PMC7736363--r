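#' Per-tissue cycling percentage
#'
#' The screen's dependent variable: for each tissue, the number of
#' expressed genes, the number called rhythmic, and
#' `pct_cycling = 100 * n_cycling / n_expressed`. Tissues with no expressed
#' genes are dropped with a warning.
#'
#' @param results data.frame from [detect_all()].
#' @return data.frame `tissue`, `n_expressed`, `n_cycling`, `pct_cycling`,
#'   ordered by `pct_cycling` descending.
#' @export
pct_cycling <- function(results) {
  out <- lapply(split(results, results$tissue), function(d) {
    data.frame(tissue = d$tissue[1], n_expressed = nrow(d),
               n_cycling = sum(d$rhythmic), row.names = NULL)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  empty <- out$n_expressed == 0
  if (any(empty)) {
    warning("dropping tissue(s) with no expressed genes: ",
            paste(out$tissue[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out$pct_cycling <- 100 * out$n_cycling / out$n_expressed
  out[order(-out$pct_cycling, out$tissue), , drop = FALSE]
}

#' Pearson and Spearman correlation of two vectors
#'
#' Pearson r with a two-sided p-value from the t-statistic
#' `r * sqrt((n-2)/(1-r^2))` on `n - 2` df, and Spearman rho (Pearson on
#' average ranks) with, by default, the same t-approximation; an exact
#' permutation p-value for Spearman is available for small n.
#' Zero-variance input yields NAs with `degenerate = TRUE`, which excludes
#' the record from downstream ranking.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite.
#' @param spearman_exact Use the exact Spearman permutation null
#'   (only for `n <= 8`).
#' @return One-row data.frame: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `degenerate`.
#' @export
correlate <- function(x, y, spearman_exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(pearson_r = NA_real_, pearson_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_,
                      n = n, degenerate = TRUE))
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = spearman_exact && n <= 8))
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = n, degenerate = FALSE)
}

fisher_z <- function(r) {
  clamped <- abs(r) >= 1 - 1e-12
  if (any(clamped, na.rm = TRUE))
    warning("|r| = 1 clamped to 1 - 1e-12 before Fisher transformation")
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

screen_records <- function(genes, feats, pct, feature) {
  recs <- lapply(seq_along(genes), function(i) {
    cbind(data.frame(gene = genes[i], feature = feature),
          correlate(feats[[i]], pct))
  })
  recs <- do.call(rbind, recs)
  recs$z_pearson <- fisher_z(recs$pearson_r)
  recs$z_spearman <- fisher_z(recs$spearman_rho)
  recs$sig_pearson <- !is.na(recs$pearson_p) & recs$pearson_p < 0.05
  recs$sig_spearman <- !is.na(recs$spearman_p) & recs$spearman_p < 0.05
  recs
}

#' Screen relative amplitudes against the cycling percentage
#'
#' For every gene rhythmic in all tissues, correlates its per-tissue
#' relative amplitude (rAMP) vector against the tissues' cycling
#' percentages. Genes rhythmic in only a subset of tissues are excluded and
#' listed in a side table with their rhythmic-tissue count; genes with an
#' undefined rAMP in any tissue are likewise excluded.
#'
#' @param results data.frame from [detect_all()].
#' @param summaries data.frame from [pct_cycling()] (>= 3 tissues).
#' @return List with `records` (one correlation record per eligible gene)
#'   and `excluded` (data.frame `gene`, `n_rhythmic_tissues`).
#' @export
ramp_screen <- function(results, summaries) {
  tt <- summaries$tissue
  if (length(tt) < 3) stop("screen needs at least 3 tissues")
  res <- results[results$tissue %in% tt, , drop = FALSE]
  rhy_count <- tapply(res$rhythmic, res$gene, sum)
  n_tissue <- tapply(res$tissue, res$gene, function(v)
    length(unique(v)))
  eligible <- names(rhy_count)[rhy_count == length(tt) &
                                 n_tissue == length(tt)]
  excluded <- data.frame(gene = names(rhy_count)[!(names(rhy_count) %in%
                                                     eligible)])
  excluded$n_rhythmic_tissues <- as.integer(rhy_count[excluded$gene])
  feats <- lapply(eligible, function(g) {
    d <- res[res$gene == g, , drop = FALSE]
    d$rAMP[match(tt, d$tissue)]
  })
  ok <- vapply(feats, function(v) all(is.finite(v)), TRUE)
  if (!length(eligible) || !any(ok)) {
    warning("no gene is rhythmic (with defined rAMP) in every tissue")
    return(list(records = NULL, excluded = excluded))
  }
  recs <- screen_records(eligible[ok], feats[ok], summaries$pct_cycling,
                         "relative_amplitude")
  list(records = recs, excluded = excluded)
}

#' Screen mean expression levels against the cycling percentage
#'
#' For every gene expressed in all tissues, correlates its per-tissue mean
#' expression (over all timepoints) against the tissues' cycling
#' percentages. Rhythmicity is not required: non-cycling genes can carry
#' the signal. Genes absent (filtered) in any tissue are excluded;
#' zero-variance mean vectors are flagged degenerate and dropped from
#' ranking.
#'
#' @param x An [expr_matrix()] or per-tissue list of them (after
#'   expression filtering).
#' @param summaries data.frame from [pct_cycling()] (>= 3 tissues).
#' @return data.frame of correlation records (one per eligible gene).
#' @export
mean_screen <- function(x, summaries) {
  tt <- summaries$tissue
  if (length(tt) < 3) stop("screen needs at least 3 tissues")
  tl <- as_tissue_list(x)
  miss <- setdiff(tt, names(tl))
  if (length(miss)) stop("missing expression data for tissue(s): ",
                         paste(miss, collapse = ", "))
  common <- Reduce(intersect, lapply(tl[tt], function(m) rownames(m$values)))
  if (!length(common)) {
    warning("no gene is expressed in every tissue")
    return(NULL)
  }
  means <- vapply(tt, function(tn) rowMeans(tl[[tn]]$values)[common],
                  numeric(length(common)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  feats <- lapply(seq_along(common), function(i) as.numeric(means[i, ]))
  screen_records(common, feats, summaries$pct_cycling, "mean_level")
}

#' Rank genes by averaged Fisher Z across platforms
#'
#' Applies the Fisher transformation `z = atanh(r)` to each platform's
#' signed correlation (Pearson r and Spearman rho separately), averages z
#' across platforms without weighting, and ranks genes by signed average z,
#' descending, within each test family (ties broken by gene id). Only genes
#' present and non-degenerate in every platform are ranked.
#'
#' @param records Named list of correlation-record data.frames, one per
#'   platform (from [ramp_screen()]`$records` or [mean_screen()]).
#' @return data.frame `gene`, per-platform z columns, `avg_z_pearson`,
#'   `rank_pearson`, `avg_z_spearman`, `rank_spearman`.
#' @export
fisher_rank <- function(records) {
  stopifnot(is.list(records), length(records) >= 1)
  if (is.null(names(records)))
    names(records) <- paste0("platform", seq_along(records))
  keep <- lapply(records, function(d)
    d[!d$degenerate, c("gene", "z_pearson", "z_spearman")])
  genes <- Reduce(intersect, lapply(keep, `[[`, "gene"))
  if (!length(genes)) stop("no gene present in every platform's records")
  zp <- vapply(keep, function(d) d$z_pearson[match(genes, d$gene)],
               numeric(length(genes)))
  zs <- vapply(keep, function(d) d$z_spearman[match(genes, d$gene)],
               numeric(length(genes)))
  if (is.null(dim(zp))) { zp <- matrix(zp, 1); zs <- matrix(zs, 1) }
  out <- data.frame(gene = genes)
  for (k in seq_along(keep)) {
    out[[paste0("z_pearson_", names(records)[k])]] <- zp[, k]
    out[[paste0("z_spearman_", names(records)[k])]] <- zs[, k]
  }
  out$avg_z_pearson <- rowMeans(zp)
  out$avg_z_spearman <- rowMeans(zs)
  out$rank_pearson <- rank_signed(out$avg_z_pearson, out$gene)
  out$rank_spearman <- rank_signed(out$avg_z_spearman, out$gene)
  out[order(out$rank_pearson), , drop = FALSE]
}

rank_signed <- function(z, gene) {
  ord <- order(-z, gene)
  rk <- integer(length(z))
  rk[ord] <- seq_along(z)
  rk
}

#' Cross-platform intersection of significant correlations
#'
#' Genes significant (`p < alpha`) with the same correlation sign in both
#' platforms, per test family; the robust set replacing per-test multiple
#' testing correction in this screen design.
#'
#' @param records_p1,records_p2 Correlation-record data.frames.
#' @param alpha Significance threshold (default 0.05).
#' @param family `"pearson"` or `"spearman"`.
#' @return data.frame of intersecting genes with both platforms' r and p.
#' @export
robust_intersection <- function(records_p1, records_p2, alpha = 0.05,
                                family = c("pearson", "spearman")) {
  family <- match.arg(family)
  rcol <- if (family == "pearson") "pearson_r" else "spearman_rho"
  pcol <- if (family == "pearson") "pearson_p" else "spearman_p"
  sig <- function(d) d[!is.na(d[[pcol]]) & d[[pcol]] < alpha, , drop = FALSE]
  s1 <- sig(records_p1); s2 <- sig(records_p2)
  genes <- intersect(s1$gene, s2$gene)
  i1 <- match(genes, s1$gene); i2 <- match(genes, s2$gene)
  same <- sign(s1[[rcol]][i1]) == sign(s2[[rcol]][i2])
  genes <- genes[same]; i1 <- i1[same]; i2 <- i2[same]
  data.frame(gene = genes,
             r_p1 = s1[[rcol]][i1], p_p1 = s1[[pcol]][i1],
             r_p2 = s2[[rcol]][i2], p_p2 = s2[[pcol]][i2],
             row.names = NULL)
}

#' Correlation between two genes' per-tissue feature vectors
#'
#' Same contract as [correlate()], packaged per gene pair (e.g. the mean
#' level of a candidate regulator against the mean level of each core clock
#' gene across tissues).
#'
#' @param feature_a,feature_b Equal-length per-tissue feature vectors.
#' @param gene_a,gene_b Gene labels for the output record.
#' @return One-row data.frame with the pair's correlation statistics.
#' @export
gene_gene_correlation <- function(feature_a, feature_b,
                                  gene_a = "gene_a", gene_b = "gene_b") {
  cbind(data.frame(gene_a = gene_a, gene_b = gene_b),
        correlate(feature_a, feature_b))
}
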
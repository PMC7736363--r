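fake_results <- function(genes, tissues, rhythmic, ramp = NULL) {
  # rhythmic: genes x tissues logical; ramp optional matching matrix
  do.call(rbind, lapply(seq_along(tissues), function(j) {
    data.frame(gene = genes, tissue = tissues[j],
               q = ifelse(rhythmic[, j], 0.01, 0.5),
               rAMP = if (is.null(ramp)) 0.3 else ramp[, j],
               AMP = 1, baseline = 3, rhythmic = rhythmic[, j])
  }))
}

test_that("cycling percentage is counts-based and ordered", {
  genes <- sprintf("g%02d", 1:40)
  rhy <- cbind(rep(c(TRUE, FALSE), c(2, 38)),
               rep(c(TRUE, FALSE), c(10, 30)),
               rep(FALSE, 40))
  res <- fake_results(genes, c("a", "b", "c"), rhy)
  summ <- pct_cycling(res)
  expect_equal(summ$pct_cycling[summ$tissue == "a"], 5)
  expect_equal(summ$pct_cycling[summ$tissue == "b"], 25)
  expect_equal(summ$pct_cycling[summ$tissue == "c"], 0)
  expect_equal(summ$tissue, c("b", "a", "c"))  # descending
})

test_that("correlate matches closed forms and brute-force sums", {
  r <- correlate(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  r2 <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r2$pearson_r, 0.8)
  expect_equal(r2$spearman_rho, 0.8)
  # antisymmetry
  r3 <- correlate(c(1, 2, 3, 4), rev(c(1, 3, 2, 4)))
  expect_equal(correlate(c(1, 2, 3, 4), -c(1, 3, 2, 4))$pearson_r,
               -r2$pearson_r)
  expect_equal(correlate(c(1, 2, 3, 4), -c(1, 3, 2, 4))$spearman_rho,
               -r2$spearman_rho)
  # brute-force oracle on random draws
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(11); y <- rnorm(11)
    rc <- correlate(x, y)
    expect_equal(rc$pearson_r, brute_pearson(x, y), tolerance = 1e-10)
    expect_equal(rc$spearman_rho, brute_spearman(x, y), tolerance = 1e-10)
    tstat <- rc$pearson_r * sqrt(9 / (1 - rc$pearson_r^2))
    expect_equal(rc$pearson_p, 2 * pt(-abs(tstat), 9), tolerance = 1e-10)
  }
  # degenerate input flagged
  expect_true(correlate(rep(1, 5), 1:5)$degenerate)
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("Spearman exact permutation p agrees with Monte Carlo at small n", {
  set.seed(8)
  x <- rnorm(7); y <- rnorm(7)
  pe <- correlate(x, y, spearman_exact = TRUE)$spearman_p
  rho_obs <- brute_spearman(x, y)
  mc <- mean(replicate(4000, abs(brute_spearman(x, sample(y))) >=
                         abs(rho_obs) - 1e-12))
  expect_lt(abs(pe - mc), 4 * sqrt(mc * (1 - mc) / 4000) + 0.01)
})

test_that("ramp screen enforces rhythmic-everywhere eligibility", {
  genes <- sprintf("g%02d", 1:30)
  rhy <- matrix(TRUE, 30, 4)
  rhy[5, 2] <- FALSE                      # g05 rhythmic in 3 of 4 tissues
  fr <- c(0.05, 0.1, 0.15, 0.2)
  ramp <- matrix(rep(0.1 + 2 * fr, each = 30), 30)  # all track fractions
  ramp[7, ] <- c(0.3, 0.31, 0.29, 0.3)    # g07 flat-ish
  res <- fake_results(genes, letters[1:4], rhy, ramp)
  summ <- pct_cycling(res)
  scr <- suppressWarnings(ramp_screen(res, summ))  # exact rho = 1 clamped
  expect_false("g05" %in% scr$records$gene)
  expect_true("g05" %in% scr$excluded$gene)
  expect_equal(scr$excluded$n_rhythmic_tissues[scr$excluded$gene == "g05"], 3L)
  expect_true(all(c("g01", "g07") %in% scr$records$gene))
})

test_that("planted relative-amplitude regulator is recovered by the screen", {
  frac <- seq(0.05, 0.25, length.out = 8)
  cfg <- synth_config(n_tissues = 8, n_genes = 200, cycling_fraction = frac,
                      noise_cv = 0.02, seed = 42,
                      regulators = list(
                        regulator_spec("g0013", "relative_amplitude",
                                       0.1, 2)))
  ds <- generate_dataset(cfg)
  res <- detect_all(ds$matrices$microarray)
  summ <- pct_cycling(res)
  scr <- suppressWarnings(ramp_screen(res, summ))  # rho can hit 1
  rec <- scr$records[scr$records$gene == "g0013", ]
  expect_equal(nrow(rec), 1)
  expect_gt(rec$pearson_r, 0.9)
  expect_lt(rec$pearson_p, 0.05)
})

test_that("mean screen recovers a planted mean-level regulator as top ranked", {
  frac <- seq(0.02, 0.15, length.out = 12)
  cfg <- synth_config(n_genes = 300, cycling_fraction = frac,
                      noise_cv = 0.05, seed = 77,
                      regulators = list(
                        regulator_spec("g0100", "mean_level", 5, 40)))
  ds <- generate_dataset(cfg)
  recs <- suppressWarnings(lapply(ds$matrices, function(m) {
    res <- detect_all(m)
    mean_screen(filter_low_expressed(m)$tissues, pct_cycling(res))
  }))  # |rho| = 1 clamp warnings are expected at n = 12
  ranked <- fisher_rank(recs)
  expect_lte(ranked$rank_pearson[ranked$gene == "g0100"], 3)
  expect_lt(recs$microarray$pearson_p[recs$microarray$gene == "g0100"], 0.05)
  # gene filtered in one tissue is excluded from the screen
  expect_true(all(table(recs$microarray$gene) == 1))
})

test_that("degenerate and missing genes are excluded from mean screen", {
  tt <- c(0, 6, 12, 18)
  mk <- function(tissue, vals) {
    samp <- data.frame(sample = paste0(tissue, ":CT", tt), tissue = tissue,
                       time = tt)
    expr_matrix(matrix(vals, nrow = 2, ncol = 4,
                       dimnames = list(c("g1", "g2"), samp$sample)), samp)
  }
  tl <- list(a = mk("a", c(5, 7)), b = mk("b", c(5, 8)), c = mk("c", c(5, 9)))
  summ <- data.frame(tissue = c("a", "b", "c"), n_expressed = 2,
                     n_cycling = c(0, 1, 2), pct_cycling = c(0, 50, 100))
  recs <- suppressWarnings(mean_screen(tl, summ))  # r = 1 clamped
  expect_true(recs$degenerate[recs$gene == "g1"])   # constant mean 5
  expect_false(recs$degenerate[recs$gene == "g2"])
  expect_equal(recs$pearson_r[recs$gene == "g2"], 1)
})

test_that("Fisher z, averaging and ranking behave as specified", {
  expect_equal(atanh(0), 0)
  expect_equal(atanh(0.8), log(9) / 2)
  recs <- data.frame(gene = c("a", "b", "c"),
                     pearson_r = c(0.9, -0.2, 0.5),
                     spearman_rho = c(0.8, -0.1, 0.4),
                     degenerate = FALSE)
  recs$z_pearson <- atanh(recs$pearson_r)
  recs$z_spearman <- atanh(recs$spearman_rho)
  single <- fisher_rank(list(p1 = recs))
  expect_equal(single$avg_z_pearson, atanh(c(0.9, -0.2, 0.5))[
    match(single$gene, recs$gene)])
  two <- fisher_rank(list(p1 = recs, p2 = recs))
  expect_equal(two$avg_z_pearson, single$avg_z_pearson)
  expect_equal(single$gene[single$rank_pearson == 1], "a")
  # rank antisymmetry: negated features reverse the ranking
  neg <- recs
  neg$z_pearson <- -neg$z_pearson; neg$z_spearman <- -neg$z_spearman
  neg$pearson_r <- -neg$pearson_r; neg$spearman_rho <- -neg$spearman_rho
  rneg <- fisher_rank(list(p1 = neg))
  expect_equal(rneg$rank_pearson[match(single$gene, rneg$gene)],
               4 - single$rank_pearson)
  # |r| = 1 clamped with warning
  expect_warning(circascreen:::fisher_z(1), "clamped")
})

test_that("robust intersection requires significance and matching sign", {
  r1 <- data.frame(gene = c("a", "b", "c", "d"),
                   pearson_r = c(0.9, 0.8, -0.7, 0.9),
                   pearson_p = c(0.01, 0.02, 0.01, 0.2),
                   spearman_rho = 0.5, spearman_p = 0.5)
  r2 <- data.frame(gene = c("a", "b", "c", "d"),
                   pearson_r = c(0.8, -0.8, -0.6, 0.9),
                   pearson_p = c(0.03, 0.01, 0.04, 0.01),
                   spearman_rho = 0.5, spearman_p = 0.5)
  inter <- robust_intersection(r1, r2, 0.05, "pearson")
  expect_setequal(inter$gene, c("a", "c"))  # b: sign flip; d: p1 n.s.
})

test_that("null genes show calibrated screen significance rates", {
  # 500 null genes, 12 tissues: fraction with p < 0.05 near 0.05
  set.seed(91)
  pct <- seq(2, 15, length.out = 12)
  hits_p <- hits_s <- logical(500)
  for (i in 1:500) {
    rc <- correlate(rnorm(12), pct)
    hits_p[i] <- rc$pearson_p < 0.05
    hits_s[i] <- rc$spearman_p < 0.05
  }
  expect_gt(mean(hits_p), 0.02); expect_lt(mean(hits_p), 0.08)
  expect_gt(mean(hits_s), 0.02); expect_lt(mean(hits_s), 0.08)
})

test_that("gene-gene correlation mirrors correlate", {
  x <- c(1, 3, 2, 5, 4)
  gg <- gene_gene_correlation(x, x, "Rorc_like", "Rorc_like")
  expect_equal(gg$pearson_r, 1)
  ds <- generate_dataset(synth_config(
    n_tissues = 6, n_genes = 60,
    cycling_fraction = seq(0.05, 0.3, length.out = 6), seed = 3,
    regulators = list(regulator_spec("g0001", "mean_level", 5, 30),
                      regulator_spec("g0002", "mean_level", 3, 20))))
  m <- ds$matrices$microarray
  mean_by_tissue <- function(g) vapply(tissues(m), function(tt)
    mean(m$values[g, m$samples$tissue == tt]), 0)
  gg2 <- gene_gene_correlation(mean_by_tissue("g0001"),
                               mean_by_tissue("g0002"), "g0001", "g0002")
  expect_gt(gg2$pearson_r, 0.9)  # shared linear driver
})
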
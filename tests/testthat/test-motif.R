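jaspar_fixture <- function() {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA1151.1 RORC",
    "A [ 10  0 20  5  0  0 ]",
    "C [  0  0  0  5 40  0 ]",
    "G [ 30 40 20  5  0  0 ]",
    "T [  0  0  0 25  0 40 ]",
    ">MA0000.1 uniformish",
    "A 1 1",
    "C 1 1",
    "G 1 1",
    "T 1 1"), path)
  path
}

test_that("JASPAR parsing normalises counts with pseudocounts", {
  pwms <- read_jaspar(jaspar_fixture())
  expect_named(pwms, c("MA1151.1", "MA0000.1"))
  p1 <- pwms$MA1151.1
  expect_equal(nrow(p1$prob), 6)
  expect_equal(rowSums(p1$prob), rep(1, 6))
  # position 1: counts (10, 0, 30, 0), N = 40, pseudocount 0.1 * 0.25
  expect_equal(unname(p1$prob[1, ]),
               (c(10, 0, 30, 0) + 0.025) / 40.1)
  # all-equal counts give a uniform matrix
  expect_equal(unname(pwms$MA0000.1$prob),
               matrix(0.25, 2, 4), tolerance = 1e-12)
})

test_that("JASPAR write -> read round-trips probabilities to 1e-9", {
  p <- example_rore_pwm()
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(p, path)
  back <- read_jaspar(path)[[1]]
  expect_equal(back$prob, p$prob, tolerance = 1e-9)
  expect_equal(back$id, p$id)
})

test_that("malformed JASPAR rows raise an error with the line number", {
  path <- tempfile()
  writeLines(c(">MA0001.1 bad", "A [ 1 2 3 ]", "C [ 1 2 ]",
               "G [ 1 2 3 ]", "T [ 1 2 3 ]"), path)
  expect_error(read_jaspar(path), "unequal")
  path2 <- tempfile()
  writeLines(c(">MA0001.1 bad", "A [ 1 x 3 ]", "C [ 1 2 3 ]",
               "G [ 1 2 3 ]", "T [ 1 2 3 ]"), path2)
  expect_error(read_jaspar(path2), "line 2")
})

test_that("promoter windows follow the strand-aware definition", {
  w <- promoter_window(5000, "+")
  expect_equal(c(w$start, w$end), c(4000, 5101))
  w <- promoter_window(5000, "-")
  expect_equal(c(w$start, w$end), c(4900, 6001))
  w <- promoter_window(200, "+")
  expect_equal(c(w$start, w$end), c(0, 301))
  w <- promoter_window(100, "-", chrom_length = 600)
  expect_equal(c(w$start, w$end), c(0, 600))
})

test_that("score-to-p table handles degenerate single-position motifs", {
  p1 <- pwm("one", matrix(c(1, 0, 0, 0), 1))
  tab <- score_pvalue_table(p1)
  expect_equal(tab$score, 2)            # log2(1 / 0.25)
  expect_equal(score_to_p(tab, 2), 0.25)
  expect_equal(tab$lowmass, 0.75)
  uni <- pwm("uni", matrix(0.25, 3, 4))
  tu <- score_pvalue_table(uni)
  expect_equal(tu$score, 0)
  expect_equal(score_to_p(tu, 0), 1)
  # p monotone nonincreasing in score
  tab2 <- score_pvalue_table(example_rore_pwm())
  expect_true(all(diff(tab2$pval) <= 1e-15))
})

test_that("DP score-to-p table equals brute-force enumeration (width 4)", {
  set.seed(12)
  counts <- matrix(rpois(16, 8) + 1, 4, 4)
  prob <- counts / rowSums(counts)
  p <- pwm("rand4", prob)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  tab <- score_pvalue_table(p, bg)
  words <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  lo <- tab$bits
  scores <- lo[cbind(1, words[, 1])] + lo[cbind(2, words[, 2])] +
    lo[cbind(3, words[, 3])] + lo[cbind(4, words[, 4])]
  wprob <- bg[words[, 1]] * bg[words[, 2]] * bg[words[, 3]] * bg[words[, 4]]
  for (s in quantile(scores, c(0.05, 0.25, 0.5, 0.9, 0.999))) {
    expect_equal(score_to_p(tab, s), sum(wprob[scores >= s - 1e-12]),
                 tolerance = 1e-9)
  }
})

test_that("scanning is strand-consistent and skips N windows", {
  p <- example_rore_pwm()
  expect_equal(nrow(scan_pwm(c(x = strrep("N", 200)), p)), 0)
  expect_equal(nrow(scan_pwm(c(x = "ACGT"), p)), 0)  # shorter than width
  # reverse complement of a sequence mirrors the hit set
  pr <- generate_promoters(20, 300, p, 1, seed = 6)
  seqs <- as.character(pr$sequences)
  hits_f <- scan_pwm(seqs, p)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  hits_r <- scan_pwm(rc, p)
  expect_equal(nrow(hits_f), nrow(hits_r))
  key_f <- paste(hits_f$gene_id, nchar(seqs[hits_f$gene_id]) -
                   (hits_f$offset + nrow(p$prob)), chartr("+-", "-+",
                                                          hits_f$strand))
  key_r <- paste(hits_r$gene_id, hits_r$offset, hits_r$strand)
  expect_setequal(key_f, key_r)
  # a palindromic PWM hits both strands at the same offsets
  pal <- pwm("pal", rbind(c(0.97, 0.01, 0.01, 0.01),
                          c(0.01, 0.97, 0.01, 0.01),
                          c(0.01, 0.01, 0.97, 0.01),
                          c(0.01, 0.01, 0.01, 0.97)))  # ACGT palindrome
  h <- scan_pwm(c(s = paste0(strrep("A", 30), "ACGT", strrep("C", 30))),
                pal, p_threshold = 1e-2)
  off <- h$offset[h$score == max(h$score)]
  expect_setequal(h$strand[h$offset == 30], c("+", "-"))
})

test_that("planted instances are recovered at p < 1e-4", {
  p <- example_rore_pwm()
  pr <- generate_promoters(200, 1100, p, 0.4, seed = 9)
  hits <- scan_pwm(pr$sequences, p)
  recall <- mean(pr$truth$gene_id %in% hits$gene_id)
  expect_gte(recall, 0.95)
})

test_that("motif fractions count rhythmic genes with at least one hit", {
  hits <- data.frame(gene_id = c("g1", "g1", "g2"), motif_id = "M",
                     offset = 1, strand = "+", score = 5, p = 1e-5)
  sets <- list(liver = c("g1", "g2"), lung = c("g2", "g3"),
               empty = character())
  fr <- motif_fraction(sets, hits)
  expect_equal(fr$fraction[fr$tissue == "liver"], 1)
  expect_equal(fr$fraction[fr$tissue == "lung"], 0.5)
  expect_true(is.na(fr$fraction[fr$tissue == "empty"]))
  expect_true(fr$undefined[fr$tissue == "empty"])
  # no hits anywhere -> fraction 0
  fr0 <- motif_fraction(list(liver = c("g1", "g2")),
                        hits[hits$p > 1, ])
  expect_equal(fr0$fraction, 0)
  # invariant to duplicated hits and gene order
  fr2 <- motif_fraction(list(liver = c("g2", "g1")), rbind(hits, hits))
  expect_equal(fr2$fraction, 1)
})

test_that("planted motif fraction is recovered up to the background rate", {
  p <- example_rore_pwm()
  pr <- generate_promoters(400, 1100, p, 0.08, seed = 15)
  hits <- scan_pwm(pr$sequences, p)
  genes <- names(pr$sequences)
  sets <- list(all = genes)
  fr <- motif_fraction(sets, hits)$fraction
  # expected: planted 8% plus background false positives (~2*1089 windows
  # at an effective rate below 1e-4 each); subtracting the empirical
  # background leaves the planted fraction within binomial error
  bg_rate <- mean(setdiff(genes, pr$truth$gene_id) %in% hits$gene_id)
  planted_rec <- mean(pr$truth$gene_id %in% hits$gene_id)
  expect_equal(fr, planted_rec * 0.08 + bg_rate * 0.92, tolerance = 1e-12)
  expect_gte(planted_rec, 0.95)
  expect_lt(bg_rate, 0.25)
  expect_gte(fr, 0.08 * 0.95)
})
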
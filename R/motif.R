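DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param id Motif identifier (e.g. a JASPAR id such as `MA1151.1`).
#' @param prob Numeric matrix, width x 4 (columns A, C, G, T), each row
#'   summing to 1 within 1e-9.
#' @param name Optional motif name.
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, prob, name = id) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(prob) <- DNA_BASES
  if (any(prob < 0)) stop("PWM probabilities must be nonnegative")
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop("each PWM row must sum to 1 (within 1e-9)")
  structure(list(id = id, name = name, prob = prob), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "(", x$name, "), width", nrow(x$prob), "\n")
  invisible(x)
}

#' Read motifs from a JASPAR-format PFM file
#'
#' Parses the JASPAR text format (header `>ID NAME` followed by four base
#' rows `A [ 12 0 5 ... ]`, brackets optional). Count matrices are
#' converted to probabilities with a pseudocount of `0.1 * background` per
#' cell: `p = (count + 0.1*bg) / (N + 0.1)`. Rows that already sum to ~1
#' per position are taken as probabilities verbatim (so write/read
#' round-trips preserve probabilities). Malformed rows raise an error with
#' the offending line number.
#'
#' @param path Path to the JASPAR file.
#' @param background Base frequencies used for the pseudocount.
#' @return Named list of [pwm()] objects (names are motif ids, preserved
#'   verbatim).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR header ('>') lines found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    first <- heads[h]
    last <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    hdr <- strsplit(sub("^>\\s*", "", lines[first]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    body_idx <- (first + 1):last
    body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
    if (length(body_idx) != 4)
      stop("motif '", id, "' (line ", first, "): expected 4 base rows, got ",
           length(body_idx))
    rows <- matrix(NA_real_, 4, 0)
    widths <- integer(4)
    parsed <- vector("list", 4)
    for (k in 1:4) {
      ln <- lines[body_idx[k]]
      cleaned <- gsub("[][]", " ", ln)
      cleaned <- sub(sprintf("^\\s*%s", DNA_BASES[k]), "", cleaned)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(cleaned),
                                                   "\\s+")[[1]]))
      if (any(is.na(vals)) || !length(vals))
        stop("malformed matrix row at line ", body_idx[k], " in ", path)
      parsed[[k]] <- vals
      widths[k] <- length(vals)
    }
    if (length(unique(widths)) != 1)
      stop("rows of motif '", id, "' have unequal lengths (line ",
           body_idx[1], ")")
    counts <- t(do.call(rbind, parsed))        # width x 4
    colsum <- rowSums(counts)
    if (all(abs(colsum - 1) < 1e-6)) {
      prob <- counts
    } else {
      prob <- sweep(counts + 0.1 * rep(background, each = nrow(counts)),
                    1, colsum + 0.1, "/")
    }
    out[[id]] <- pwm(id, prob, name)
  }
  out
}

#' Write motifs in JASPAR-like format (probability rows)
#' @param pwms A [pwm()] or list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$name), con)
    for (k in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[k],
                         paste(format(p$prob[, k], digits = 15),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Promoter window around a transcription start site
#'
#' Strand-aware window covering `upstream` bp before and `downstream` bp
#' after the TSS (TSS included): plus strand
#' `[tss - upstream, tss + downstream + 1)`, minus strand
#' `[tss - downstream, tss + upstream + 1)`, 0-based half-open, clipped at
#' 0 and at the chromosome end. Minus-strand sequences are
#' reverse-complemented before scanning.
#'
#' @param tss 0-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream Window extents in bp.
#' @param chrom_length Optional chromosome length for right clipping.
#' @return List with `start`, `end` (0-based half-open), `strand`.
#' @export
promoter_window <- function(tss, strand, upstream = 1000, downstream = 100,
                            chrom_length = NULL) {
  stopifnot(tss >= 0, strand %in% c("+", "-"))
  if (strand == "+") {
    start <- tss - upstream; end <- tss + downstream + 1
  } else {
    start <- tss - downstream; end <- tss + upstream + 1
  }
  start <- max(0, start)
  if (!is.null(chrom_length)) end <- min(end, chrom_length)
  list(start = start, end = end, strand = strand)
}

# log2 odds matrix (width x 4) with -Inf allowed for zero probabilities
log_odds <- function(pwm, background) {
  if (any(background <= 0 & apply(pwm$prob > 0, 2, any)))
    stop("zero background frequency with nonzero PWM probability")
  sweep(log2(pwm$prob), 2, log2(background), "-")
}

#' Exact score-to-p-value table for a PWM
#'
#' Log-odds scores `log2(p_motif / p_background)` are discretised to
#' `bin`-bit bins (default 1/1000 bit) and the exact null distribution of
#' the total word score under the 0-order background model is accumulated
#' by dynamic programming over positions. The p-value of a score s is the
#' total null probability of scoring `>= s`, exact up to discretisation.
#' Impossible words (probability-0 positions, score -Inf) contribute only
#' to the denominator.
#'
#' @param pwm A [pwm()].
#' @param background Base frequencies (A, C, G, T), summing to 1.
#' @param bin Discretisation step in bits.
#' @return Object of class `score_pvalue_table`: list with `score`
#'   (ascending bin scores in bits), `prob`, `pval` (`P(S >= score)`),
#'   `bits` (the binned log-odds matrix) and `bin`.
#' @export
score_pvalue_table <- function(pwm, background = rep(0.25, 4),
                               bin = 1 / 1000) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  lo <- log_odds(pwm, background)
  ib <- round(lo / bin)                       # integer bins, -Inf allowed
  w <- nrow(ib)
  offset <- 0                                 # bin index of vec[1]
  vec <- 1                                    # P(partial score = bin)
  lowmass <- 0                                # P(score = -Inf)
  for (i in seq_len(w)) {
    fin <- is.finite(ib[i, ])
    lowmass <- lowmass + sum(vec) * sum(background[!fin])
    if (!any(fin)) { vec <- numeric(0); break }
    shifts <- ib[i, fin]
    wts <- background[fin]
    lo_s <- min(shifts); hi_s <- max(shifts)
    newlen <- length(vec) + (hi_s - lo_s)
    new <- numeric(newlen)
    for (k in seq_along(shifts)) {
      pos <- (shifts[k] - lo_s) + seq_along(vec)
      new[pos] <- new[pos] + wts[k] * vec
    }
    vec <- new
    offset <- offset + lo_s
  }
  score <- (offset + seq_along(vec) - 1) * bin
  pval <- rev(cumsum(rev(vec)))               # P(S >= score), finite part
  structure(list(score = score, prob = vec, pval = pmin(1, pval),
                 lowmass = lowmass, bits = ib * bin, bin = bin,
                 motif_id = pwm$id),
            class = "score_pvalue_table")
}

#' Look up exact p-values for observed scores
#' @param table A [score_pvalue_table()].
#' @param scores Numeric scores in bits (as produced by the same table's
#'   binned log-odds).
#' @return `P(S >= score)` for each score; scores below the achievable
#'   range give 1, and -Inf gives 1.
#' @export
score_to_p <- function(table, scores) {
  eps <- table$bin / 2
  idx <- findInterval(scores + eps, table$score)
  p <- rep(1, length(scores))
  pos <- idx >= 1 & is.finite(scores)
  p[pos] <- table$pval[pmin(idx[pos], length(table$pval))]
  above <- is.finite(scores) & scores > table$score[length(table$score)] + eps
  p[above] <- table$pval[length(table$pval)]
  p
}

reverse_complement_pwm <- function(p) {
  pwm(p$id, p$prob[rev(seq_len(nrow(p$prob))), rev(seq_len(4)), drop = FALSE],
      p$name)
}

# integer codes 1..4 for A,C,G,T; NA for anything else (N etc.)
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

scan_one_strand <- function(codes, bits, table) {
  w <- nrow(bits)
  L <- length(codes)
  if (L < w) return(list(offset = integer(), score = numeric(),
                         p = numeric()))
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  for (i in seq_len(w)) {
    b <- bits[i, codes[i:(i + n_off - 1L)]]
    b[is.na(b)] <- NA_real_
    sc <- sc + b
  }
  p <- rep(NA_real_, n_off)
  fin <- !is.na(sc)
  p[fin] <- score_to_p(table, sc[fin])
  list(offset = 0:(n_off - 1L), score = sc, p = p)
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Scores every offset of every sequence on both strands with the binned
#' log-odds of the PWM and reports positions whose exact null p-value (see
#' [score_pvalue_table()]) is below `p_threshold`. Windows containing
#' non-ACGT characters are skipped. A gene "has the motif" when it has at
#' least one hit in its promoter.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   promoter sequences.
#' @param pwm A [pwm()].
#' @param background Base frequencies for log-odds and the null model.
#' @param p_threshold Hit threshold on the exact p-value (default 1e-4).
#' @return data.frame `gene_id`, `motif_id`, `offset` (0-based start on the
#'   given sequence), `strand`, `score` (bits), `p`.
#' @export
scan_pwm <- function(sequences, pwm, background = rep(0.25, 4),
                     p_threshold = 1e-4) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  tab_f <- score_pvalue_table(pwm, background)
  rc <- reverse_complement_pwm(pwm)
  tab_r <- score_pvalue_table(rc, background)
  hits <- list()
  for (g in names(sequences)) {
    codes <- encode_dna(sequences[[g]])
    for (st in c("+", "-")) {
      tab <- if (st == "+") tab_f else tab_r
      sc <- scan_one_strand(codes, tab$bits, tab)
      keep <- !is.na(sc$p) & sc$p < p_threshold
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = g, motif_id = pwm$id, offset = sc$offset[keep],
          strand = st, score = sc$score[keep], p = sc$p[keep])
      }
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Fraction of rhythmic genes carrying a motif, per tissue
#'
#' For each tissue and motif: the number of rhythmic genes with at least
#' one promoter hit divided by the number of rhythmic genes. Tissues with
#' an empty rhythmic set are flagged with an NA fraction.
#'
#' @param rhythmic_sets Named list (per tissue) of rhythmic gene id
#'   vectors, or a [detect_all()] results data.frame.
#' @param hits Hits data.frame from [scan_pwm()] (one or more motifs).
#' @return data.frame `tissue`, `motif_id`, `n_rhythmic`, `n_with_hit`,
#'   `fraction`, `undefined`.
#' @export
motif_fraction <- function(rhythmic_sets, hits) {
  if (is.data.frame(rhythmic_sets)) {
    rhythmic_sets <- lapply(split(rhythmic_sets, rhythmic_sets$tissue),
                            function(d) d$gene[d$rhythmic])
  }
  motifs <- unique(hits$motif_id)
  if (!length(motifs)) motifs <- NA_character_
  out <- list()
  for (tt in names(rhythmic_sets)) {
    genes <- unique(rhythmic_sets[[tt]])
    for (mo in motifs) {
      with_hit <- unique(hits$gene_id[hits$motif_id %in% mo])
      n <- length(genes)
      k <- sum(genes %in% with_hit)
      out[[length(out) + 1L]] <- data.frame(
        tissue = tt, motif_id = mo, n_rhythmic = n, n_with_hit = k,
        fraction = if (n > 0) k / n else NA_real_, undefined = n == 0)
    }
  }
  do.call(rbind, out)
}

#' Example ROR-response-element-like PWM
#'
#' A sharp 12-position matrix (~17.5 bits of information) shaped like the
#' nuclear-receptor half-site (A/T)A(A/T)NT(A/G)GGTCAA recognised by ROR
#' and REV-ERB factors. Synthetic scanning fixture, not a database matrix;
#' sharp enough that instances sampled from it are recovered by
#' [scan_pwm()] at p < 1e-4 with high probability.
#'
#' @param id Motif id for the object.
#' @return A [pwm()].
#' @export
example_rore_pwm <- function(id = "RORE_synthetic") {
  strong <- function(b) { v <- rep(0.005, 4); v[b] <- 0.985; v }
  half <- function(b1, b2) { v <- rep(0.01, 4); v[c(b1, b2)] <- 0.49; v }
  rows <- rbind(
    half(1, 4),        # A/T
    strong(1),         # A
    half(1, 4),        # A/T
    rep(0.25, 4),      # N
    strong(4),         # T
    half(1, 3),        # A/G
    strong(3),         # G
    strong(3),         # G
    strong(4),         # T
    strong(2),         # C
    strong(1),         # A
    strong(1))         # A
  pwm(id, rows)
}
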
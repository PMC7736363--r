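#' Configuration for the synthetic multi-tissue circadian generator
#'
#' Describes the study conditions the generator emulates: a panel of tissues
#' sampled on one or more regular time grids, with a tissue-specific
#' fraction of genes oscillating as pure cosines around log-normal
#' baselines, multiplicative Gaussian noise, and optional planted
#' "regulator" genes whose relative amplitude or mean level is linear in
#' each tissue's cycling fraction.
#'
#' Defaults mirror a mouse-like design: 12 tissues sampled both at 24
#' timepoints in 2-h intervals and at 8 timepoints in 6-h intervals over
#' 48 h, with cycling fractions spanning 2-15% from the most to the least
#' rhythmic tissue.
#'
#' @param n_tissues Number of tissues.
#' @param n_genes Number of genes.
#' @param cycling_fraction Numeric vector, length `n_tissues`, of per-tissue
#'   proportions of rhythmic genes, each in `[0, 1]`.
#' @param sampling_designs Named list of designs, each a numeric vector
#'   `c(interval_h = , span_h = )`; `span_h / interval_h` must be integral.
#' @param baseline_logmean,baseline_logsd Log-normal parameters of the
#'   gene-level baseline expression (log scale).
#' @param baseline_tissue_logsd Log-sd of the tissue-specific deviation
#'   around each gene's baseline (captures cross-tissue expression
#'   variation while keeping genes correlated across tissues).
#' @param relamp_range Length-2 vector `(min, max)` in `(0, 1]` from which
#'   rhythmic genes' relative amplitudes are drawn uniformly.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise (sd = `noise_cv` * signal), `>= 0`.
#' @param period_hours Waveform period in hours.
#' @param regulators List of [regulator_spec()] objects to plant.
#' @param tissue_names Optional character vector of tissue labels; defaults
#'   to a mouse-like panel ordered from highest to lowest cycling fraction.
#' @param seed Integer RNG seed; identical configs give bit-identical data.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_tissues = 12L,
                         n_genes = 1000L,
                         cycling_fraction = seq(0.15, 0.02,
                                                length.out = n_tissues),
                         sampling_designs = list(
                           microarray = c(interval_h = 2, span_h = 48),
                           rnaseq = c(interval_h = 6, span_h = 48)),
                         baseline_logmean = 2,
                         baseline_logsd = 1,
                         baseline_tissue_logsd = 0.25,
                         relamp_range = c(0.1, 0.5),
                         noise_cv = 0.05,
                         period_hours = 24,
                         regulators = list(),
                         tissue_names = NULL,
                         seed = 1L) {
  if (is.null(tissue_names)) {
    panel <- c("liver", "kidney", "lung", "brown_adipose", "heart",
               "adrenal", "aorta", "cerebellum", "hypothalamus", "muscle",
               "white_adipose", "brainstem")
    tissue_names <- if (n_tissues <= length(panel)) panel[seq_len(n_tissues)]
                    else sprintf("tissue%02d", seq_len(n_tissues))
  }
  cfg <- structure(list(
    n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
    cycling_fraction = as.numeric(cycling_fraction),
    sampling_designs = sampling_designs,
    baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
    baseline_tissue_logsd = baseline_tissue_logsd,
    relamp_range = as.numeric(relamp_range), noise_cv = noise_cv,
    period_hours = period_hours, regulators = regulators,
    tissue_names = tissue_names, seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_genes <= 0) stop("n_genes must be positive")
    if (n_tissues <= 0) stop("n_tissues must be positive")
    if (length(cycling_fraction) != n_tissues)
      stop("cycling_fraction must have one entry per tissue")
    if (any(cycling_fraction < 0 | cycling_fraction > 1))
      stop("cycling fractions must lie in [0, 1]")
    if (noise_cv < 0) stop("noise_cv must be >= 0")
    if (length(relamp_range) != 2 || relamp_range[1] <= 0 ||
        relamp_range[2] > 1 || relamp_range[1] > relamp_range[2])
      stop("relamp_range must be within (0, 1] with min <= max")
    if (period_hours <= 0) stop("period_hours must be positive")
    if (length(tissue_names) != n_tissues)
      stop("tissue_names must have one entry per tissue")
    for (d in sampling_designs) {
      if (!all(c("interval_h", "span_h") %in% names(d)))
        stop("each sampling design needs interval_h and span_h")
      k <- d[["span_h"]] / d[["interval_h"]]
      if (abs(k - round(k)) > 1e-9)
        stop("span_h / interval_h must give an integer timepoint count")
    }
    for (sp in regulators) {
      if (!inherits(sp, "regulator_spec"))
        stop("regulators must be a list of regulator_spec objects")
      feat <- sp$intercept + sp$slope * cycling_fraction
      if (any(feat <= 0))
        stop("regulator '", sp$gene_id,
             "': planted feature is nonpositive for some tissue")
      if (sp$mode == "relative_amplitude") {
        if (any(feat > 1))
          stop("regulator '", sp$gene_id,
               "': planted relative amplitude exceeds 1")
        if (any(round(cycling_fraction * n_genes) < 1))
          stop("relative_amplitude regulator requires a nonempty rhythmic ",
               "set in every tissue")
      }
    }
  })
  invisible(cfg)
}

#' Specification of a planted regulator gene
#'
#' A regulator's feature (relative amplitude or mean expression level) in
#' tissue t is `intercept + slope * f_t`, where `f_t` is that tissue's
#' cycling fraction, so that the planted feature has Pearson r = 1 with the
#' cycling fraction by construction.
#'
#' @param gene_id Gene id (must exist in the generated gene set, e.g.
#'   `"g0001"`).
#' @param mode `"mean_level"` or `"relative_amplitude"`.
#' @param intercept,slope Linear coefficients `a`, `b` of the planted
#'   feature `a + b * f_t`.
#' @return An object of class `regulator_spec`.
#' @export
regulator_spec <- function(gene_id,
                           mode = c("mean_level", "relative_amplitude"),
                           intercept, slope) {
  mode <- match.arg(mode)
  structure(list(gene_id = gene_id, mode = mode,
                 intercept = intercept, slope = slope),
            class = "regulator_spec")
}

gene_ids_for <- function(n) sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))

# Core waveform-parameter draw (no regulators, no noise).
draw_truth <- function(cfg) {
  genes <- gene_ids_for(cfg$n_genes)
  nt <- cfg$n_tissues
  mu_g <- stats::rnorm(cfg$n_genes, cfg$baseline_logmean, cfg$baseline_logsd)
  eps <- matrix(stats::rnorm(cfg$n_genes * nt, 0, cfg$baseline_tissue_logsd),
                cfg$n_genes, nt)
  B <- exp(mu_g + eps)
  rhythmic <- matrix(FALSE, cfg$n_genes, nt)
  for (j in seq_len(nt)) {
    k <- round(cfg$cycling_fraction[j] * cfg$n_genes)
    if (k > 0) rhythmic[sample.int(cfg$n_genes, k), j] <- TRUE
  }
  A <- matrix(stats::runif(cfg$n_genes * nt, cfg$relamp_range[1],
                           cfg$relamp_range[2]), cfg$n_genes, nt)
  A[!rhythmic] <- 0
  phi <- matrix(stats::runif(cfg$n_genes * nt, 0, cfg$period_hours),
                cfg$n_genes, nt)
  dimnames(B) <- dimnames(A) <- dimnames(phi) <- dimnames(rhythmic) <-
    list(genes, cfg$tissue_names)
  structure(list(genes = genes, tissues = cfg$tissue_names,
                 fractions = stats::setNames(cfg$cycling_fraction,
                                             cfg$tissue_names),
                 period = cfg$period_hours,
                 baseline = B, relamp = A, phase = phi, rhythmic = rhythmic,
                 regulators = data.frame(gene_id = character(),
                                         mode = character(),
                                         intercept = numeric(),
                                         slope = numeric())),
            class = "synth_truth")
}

#' Plant a regulator gene into a synthetic truth object
#'
#' For `mode = "mean_level"` the gene's per-tissue baseline is set to
#' `a + b * f_t`; for `mode = "relative_amplitude"` the gene's relative
#' amplitude is set to `a + b * f_t` and the gene is made rhythmic in every
#' tissue (another rhythmic gene is demoted where needed so that the size of
#' each tissue's rhythmic set is preserved).
#'
#' @param truth A `synth_truth` object (from [generate_dataset()]).
#' @param spec A [regulator_spec()].
#' @param fractions Per-tissue cycling fractions; defaults to the truth's.
#' @return The modified `synth_truth`.
#' @export
plant_regulator <- function(truth, spec, fractions = truth$fractions) {
  stopifnot(inherits(truth, "synth_truth"),
            inherits(spec, "regulator_spec"))
  g <- spec$gene_id
  if (!g %in% truth$genes) stop("gene '", g, "' not present in truth")
  feat <- spec$intercept + spec$slope * as.numeric(fractions)
  if (any(feat <= 0))
    stop("planted feature nonpositive for some tissue (gene '", g, "')")
  if (spec$mode == "mean_level") {
    truth$baseline[g, ] <- feat
  } else {
    if (any(feat > 1))
      stop("planted relative amplitude outside (0, 1] (gene '", g, "')")
    for (j in seq_along(truth$tissues)) {
      if (!truth$rhythmic[g, j]) {
        cand <- which(truth$rhythmic[, j] &
                        !(truth$genes %in% c(g, truth$regulators$gene_id)))
        if (!length(cand))
          stop("tissue '", truth$tissues[j],
               "' has no rhythmic slot available for the regulator")
        drop <- cand[length(cand)]
        truth$rhythmic[drop, j] <- FALSE
        truth$relamp[drop, j] <- 0
        truth$rhythmic[g, j] <- TRUE
      }
    }
    truth$relamp[g, ] <- feat
  }
  truth$regulators <- rbind(truth$regulators,
                            data.frame(gene_id = g, mode = spec$mode,
                                       intercept = spec$intercept,
                                       slope = spec$slope))
  truth
}

design_times <- function(d) seq(0, d[["span_h"]] - d[["interval_h"]],
                                by = d[["interval_h"]])

# Noiseless signal of one tissue at times tt: B * (1 + A cos(2pi (t-phi)/T))
signal_matrix <- function(truth, j, tt) {
  B <- truth$baseline[, j]
  A <- truth$relamp[, j]
  ph <- truth$phase[, j]
  out <- matrix(0, length(B), length(tt))
  for (k in seq_along(tt)) {
    out[, k] <- B * (1 + A * cos(2 * pi * (tt[k] - ph) / truth$period))
  }
  out
}

#' Generate synthetic multi-tissue circadian expression data
#'
#' Draws one shared set of waveform parameters (the truth), plants any
#' configured regulators, then renders one expression matrix per sampling
#' design from that same truth: matrices at different time resolutions are
#' subsamples of one underlying noisy realisation, so designs whose grids
#' nest share identical columns at shared timepoints. Rhythmic genes follow
#' `B * (1 + A_rel * cos(2*pi*(t - phi)/T))`; non-rhythmic genes are flat at
#' `B`. Noise is multiplicative Gaussian with sd = `noise_cv * signal`,
#' floored at zero. Identical config and seed give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list with elements `matrices` (named list of [expr_matrix()]
#'   objects, one per sampling design) and `truth` (a `synth_truth` holding
#'   per-gene waveform parameters, per-tissue rhythmic sets and regulator
#'   specifications).
#' @examples
#' cfg <- synth_config(n_tissues = 3, n_genes = 50,
#'                     cycling_fraction = c(0.1, 0.2, 0.3), seed = 7)
#' ds <- generate_dataset(cfg)
#' dim(ds$matrices$microarray)
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  truth <- draw_truth(config)
  for (sp in config$regulators)
    truth <- plant_regulator(truth, sp, config$cycling_fraction)
  grids <- lapply(config$sampling_designs, design_times)
  union_t <- sort(unique(unlist(grids)))
  nt <- config$n_tissues
  # one noisy realisation per tissue on the union grid, then subsample
  noisy <- vector("list", nt)
  for (j in seq_len(nt)) {
    sig <- signal_matrix(truth, j, union_t)
    if (config$noise_cv > 0) {
      z <- matrix(stats::rnorm(length(sig)), nrow(sig), ncol(sig))
      sig <- pmax(sig * (1 + config$noise_cv * z), 0)
    }
    noisy[[j]] <- sig
  }
  matrices <- lapply(seq_along(grids), function(di) {
    tt <- grids[[di]]
    idx <- match(tt, union_t)
    cols <- lapply(seq_len(nt), function(j) noisy[[j]][, idx, drop = FALSE])
    vals <- do.call(cbind, cols)
    samp <- data.frame(
      sample = as.vector(vapply(truth$tissues, function(tn)
        sprintf("%s:CT%02d", tn, as.integer(tt)), character(length(tt)))),
      tissue = rep(truth$tissues, each = length(tt)),
      time = rep(tt, nt))
    colnames(vals) <- samp$sample
    rownames(vals) <- truth$genes
    expr_matrix(vals, samp)
  })
  names(matrices) <- names(config$sampling_designs)
  list(matrices = matrices, truth = truth)
}

#' Per-tissue rhythmic gene sets of a synthetic truth
#' @param truth A `synth_truth`.
#' @return Named list (per tissue) of rhythmic gene id vectors.
#' @export
rhythmic_sets <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  lapply(stats::setNames(seq_along(truth$tissues), truth$tissues),
         function(j) truth$genes[truth$rhythmic[, j]])
}

#' Write a synthetic truth object as JSON
#' @param truth A `synth_truth`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(genes = truth$genes, tissues = truth$tissues,
              fractions = as.list(truth$fractions), period = truth$period,
              baseline = truth$baseline, relative_amplitude = truth$relamp,
              phase = truth$phase,
              rhythmic_sets = rhythmic_sets(truth),
              regulators = truth$regulators)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Generate promoter sequences with planted motif instances
#'
#' Produces fixed-length promoter sequences of i.i.d. background bases; a
#' chosen fraction of genes receive one motif instance sampled
#' position-by-position from the PWM's probabilities, inserted at a recorded
#' offset and strand. Deterministic under `seed`.
#'
#' @param gene_ids Character vector of gene ids (or a single integer n,
#'   expanded to default ids matching [generate_dataset()]).
#' @param length Promoter length in bp (must be >= motif width).
#' @param pwm A [pwm()] object.
#' @param planted_fraction Proportion of genes given a planted instance,
#'   in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param background Base frequencies (A, C, G, T) of the background.
#' @return List with `sequences` (a named `Biostrings::DNAStringSet`) and
#'   `truth` (data.frame `gene_id`, `offset` 0-based, `strand`; one row per
#'   planted instance).
#' @export
generate_promoters <- function(gene_ids, length = 1100, pwm,
                               planted_fraction, seed = 1L,
                               background = rep(0.25, 4)) {
  if (is.numeric(gene_ids) && base::length(gene_ids) == 1L)
    gene_ids <- gene_ids_for(gene_ids)
  stopifnot(inherits(pwm, "pwm"))
  w <- nrow(pwm$prob)
  if (length < w) stop("promoter length must be >= motif width")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n <- base::length(gene_ids)
  mat <- matrix(sample(bases, n * length, replace = TRUE, prob = background),
                n, length)
  n_plant <- round(planted_fraction * n)
  planted <- if (n_plant > 0) sort(sample.int(n, n_plant)) else integer()
  truth <- data.frame(gene_id = character(), offset = integer(),
                      strand = character())
  for (i in planted) {
    inst <- vapply(seq_len(w), function(k)
      sample(bases, 1, prob = pwm$prob[k, ]), "")
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") inst <- rev(c(T = "A", G = "C", C = "G", A = "T")[inst])
    off <- sample.int(length - w + 1L, 1) - 1L  # 0-based
    mat[i, (off + 1):(off + w)] <- inst
    truth <- rbind(truth, data.frame(gene_id = gene_ids[i], offset = off,
                                     strand = strand))
  }
  seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(seqs) <- gene_ids
  list(sequences = seqs, truth = truth)
}
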
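write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic screen pipeline
#'
#' Orchestrates simulate -> preprocess -> detect -> screen -> motif -> svd
#' on a synthetic configuration, writing one TSV per stage output plus a
#' JSON manifest (inputs, seed, per-stage row counts). Stage outputs are
#' written to a staging directory and promoted only when the stage
#' succeeds; any failure aborts with the failing stage named.
#'
#' @param config A [synth_config()] (drives the simulate stage and seed).
#' @param detection A [detection_config()].
#' @param alpha Significance threshold of the correlation screen.
#' @param min_mean Mean-expression floor for the preprocess stage.
#' @param pwm_motif A [pwm()] scanned over promoters (default
#'   [example_rore_pwm()]).
#' @param promoter_length Length of generated promoters (bp).
#' @param motif_planted_fraction Fraction of promoters given a planted
#'   motif instance.
#' @param p_threshold Motif-scan p-value threshold.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = synth_config(),
                         detection = detection_config(),
                         alpha = 0.05, min_mean = 0.5,
                         pwm_motif = example_rore_pwm(),
                         promoter_length = 1100,
                         motif_planted_fraction = 0.08,
                         p_threshold = 1e-4,
                         outdir, quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  staging <- file.path(outdir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  manifest <- list(seed = config$seed, alpha = alpha,
                   q_threshold = detection$q_threshold,
                   min_mean = min_mean, stages = list())
  say <- function(...) if (!quiet) message(...)
  promote <- function(files) {
    for (f in files) file.rename(file.path(staging, f), file.path(outdir, f))
    files
  }
  stage <- function(name, fun) {
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res$counts
    promote(res$files)
    res$value
  }

  sim <- stage("simulate", function() {
    ds <- generate_dataset(config)
    files <- character()
    for (nm in names(ds$matrices)) {
      mf <- paste0("matrix_", nm, ".tsv"); sf <- paste0("samples_", nm, ".tsv")
      write_expr_matrix(ds$matrices[[nm]], file.path(staging, mf),
                        file.path(staging, sf))
      files <- c(files, mf, sf)
    }
    write_truth(ds$truth, file.path(staging, "truth.json"))
    prom <- generate_promoters(ds$truth$genes, promoter_length, pwm_motif,
                               motif_planted_fraction,
                               seed = config$seed + 1L)
    Biostrings::writeXStringSet(prom$sequences,
                                file.path(staging, "promoters.fa"))
    # synthetic TSS table: promoters laid end-to-end on one contig,
    # 0-based half-open BED intervals
    n <- length(prom$sequences)
    bed <- data.frame(chrom = "chrS",
                      start = (seq_len(n) - 1L) * (promoter_length + 100L),
                      end = (seq_len(n) - 1L) * (promoter_length + 100L) +
                        promoter_length,
                      name = names(prom$sequences), score = 0L,
                      strand = "+")
    utils::write.table(bed, file.path(staging, "tss.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_tsv(prom$truth, file.path(staging, "promoter_truth.tsv"))
    list(value = list(ds = ds, prom = prom),
         counts = list(n_genes = config$n_genes,
                       n_tissues = config$n_tissues,
                       designs = names(ds$matrices)),
         files = c(files, "truth.json", "promoters.fa", "tss.bed",
                   "promoter_truth.tsv"))
  })

  filt <- stage("preprocess", function() {
    out <- lapply(sim$ds$matrices, filter_low_expressed, min_mean = min_mean)
    files <- character()
    for (nm in names(out)) {
      f <- paste0("filter_report_", nm, ".tsv")
      write_tsv(out[[nm]]$report, file.path(staging, f))
      files <- c(files, f)
    }
    list(value = out,
         counts = lapply(out, function(o) sum(o$report$n_output)),
         files = files)
  })

  det <- stage("detect", function() {
    out <- lapply(names(filt), function(nm)
      detect_all(filt[[nm]]$tissues, detection))
    names(out) <- names(filt)
    files <- character()
    for (nm in names(out)) {
      f <- paste0("rhythm_", nm, ".tsv")
      write_tsv(out[[nm]], file.path(staging, f))
      files <- c(files, f)
    }
    list(value = out, counts = lapply(out, nrow), files = files)
  })

  scr <- stage("screen", function() {
    summaries <- lapply(det, pct_cycling)
    mean_recs <- lapply(names(det), function(nm)
      mean_screen(filt[[nm]]$tissues, summaries[[nm]]))
    names(mean_recs) <- names(det)
    ramp_recs <- lapply(names(det), function(nm)
      ramp_screen(det[[nm]], summaries[[nm]])$records)
    names(ramp_recs) <- names(det)
    files <- character()
    for (nm in names(det)) {
      f <- paste0("tissue_summary_", nm, ".tsv")
      write_tsv(summaries[[nm]], file.path(staging, f)); files <- c(files, f)
      f <- paste0("mean_screen_", nm, ".tsv")
      write_tsv(mean_recs[[nm]], file.path(staging, f)); files <- c(files, f)
      if (!is.null(ramp_recs[[nm]])) {
        f <- paste0("ramp_screen_", nm, ".tsv")
        write_tsv(ramp_recs[[nm]], file.path(staging, f))
        files <- c(files, f)
      }
    }
    ranked <- fisher_rank(mean_recs)
    write_tsv(ranked, file.path(staging, "mean_screen_fisher_rank.tsv"))
    files <- c(files, "mean_screen_fisher_rank.tsv")
    inter <- NULL
    if (length(mean_recs) >= 2) {
      inter <- robust_intersection(mean_recs[[1]], mean_recs[[2]], alpha)
      write_tsv(inter, file.path(staging, "mean_screen_intersection.tsv"))
      files <- c(files, "mean_screen_intersection.tsv")
    }
    list(value = list(summaries = summaries, mean = mean_recs,
                      ramp = ramp_recs, ranked = ranked,
                      intersection = inter),
         counts = list(n_ranked = nrow(ranked),
                       n_intersection = if (is.null(inter)) 0L
                                        else nrow(inter)),
         files = files)
  })

  mot <- stage("motif", function() {
    hits <- scan_pwm(sim$prom$sequences, pwm_motif,
                     p_threshold = p_threshold)
    frac <- motif_fraction(det[[1]], hits)
    write_tsv(hits, file.path(staging, "motif_hits.tsv"))
    write_tsv(frac, file.path(staging, "motif_fraction.tsv"))
    list(value = list(hits = hits, fraction = frac),
         counts = list(n_hits = nrow(hits)),
         files = c("motif_hits.tsv", "motif_fraction.tsv"))
  })

  svd_res <- stage("svd", function() {
    # feature matrix: per-tissue mean level of the most broadly rhythmic
    # genes on the first platform (the clock-gene-panel analogue)
    d1 <- det[[1]]
    summ <- scr$summaries[[1]]
    rhy <- tapply(d1$rhythmic, d1$gene, sum)
    panel <- names(rhy)[order(-rhy, names(rhy))]
    panel <- panel[seq_len(min(20, length(panel)))]
    panel <- panel[rhy[panel] > 0]
    if (length(panel) < 2)
      return(list(value = NULL, counts = list(skipped = "fewer than 2 ",
                                              n_panel = length(panel)),
                  files = character()))
    m <- sim$ds$matrices[[1]]
    fm <- vapply(summ$tissue, function(tn) {
      keep <- m$samples$tissue == tn
      rowMeans(m$values[panel, keep, drop = FALSE])
    }, numeric(length(panel)))
    res <- svd_project(fm)
    out <- outlier_gene(res)
    write_tsv(data.frame(component = seq_along(res$d), d = res$d),
              file.path(staging, "svd_singular_values.tsv"))
    write_tsv(data.frame(gene = rownames(res$gene_proj), res$gene_proj),
              file.path(staging, "svd_gene_projections.tsv"))
    write_tsv(out, file.path(staging, "svd_outliers.tsv"))
    list(value = list(svd = res, outliers = out),
         counts = list(n_panel = length(panel)),
         files = c("svd_singular_values.tsv", "svd_gene_projections.tsv",
                   "svd_outliers.tsv"))
  })

  manifest$outputs <- list.files(outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  unlink(staging, recursive = TRUE)
  say("pipeline complete: ", outdir)
  invisible(list(manifest = manifest, simulate = sim, preprocess = filt,
                 detect = det, screen = scr, motif = mot, svd = svd_res))
}
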
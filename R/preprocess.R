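#' @title Expression filters and probe collapse
#' @description Filters mirror standard practice for circadian time-course
#'   data: a mean-expression floor applied per tissue (a gene can count as
#'   expressed in some tissues only), a negative-control floor for
#'   array-style data, and collapse of multiple probes per gene to the probe
#'   with the highest average signal. Filters are idempotent and their
#'   reports additive.
#' @name preprocess
NULL

filter_report <- function(tissue, n_input, n_removed_low = 0L,
                          n_removed_negative = 0L, n_collapsed = 0L) {
  data.frame(tissue = tissue, n_input = n_input,
             n_removed_low = n_removed_low,
             n_removed_negative = n_removed_negative,
             n_collapsed = n_collapsed,
             n_output = n_input - n_removed_low - n_removed_negative -
               n_collapsed)
}

#' Remove genes below a mean-expression floor, per tissue
#'
#' A gene is retained in a tissue when its mean over all of that tissue's
#' timepoints is `>= min_mean` (inclusive). Because expression is
#' tissue-specific, the result is a per-tissue list of matrices.
#'
#' @param x An [expr_matrix()] or a named per-tissue list of them.
#' @param min_mean Mean-expression threshold (default 0.5, the conventional
#'   TPM floor).
#' @return List with `tissues` (named per-tissue list of `expr_matrix`) and
#'   `report` (data.frame, one row per tissue with filter counts).
#' @export
filter_low_expressed <- function(x, min_mean = 0.5) {
  stopifnot(min_mean >= 0)
  tl <- as_tissue_list(x)
  rep_rows <- list()
  out <- lapply(names(tl), function(tt) {
    m <- tl[[tt]]
    keep <- rowMeans(m$values) >= min_mean
    rep_rows[[tt]] <<- filter_report(tt, nrow(m$values),
                                     n_removed_low = sum(!keep))
    if (!any(keep)) {
      warning("tissue '", tt, "': no gene passes the expression filter")
      return(structure(list(values = m$values[keep, , drop = FALSE],
                            samples = m$samples), class = "expr_matrix"))
    }
    expr_matrix(m$values[keep, , drop = FALSE], m$samples)
  })
  names(out) <- names(tl)
  list(tissues = out, report = do.call(rbind, rep_rows))
}

#' Remove genes below the negative-control average, per tissue
#'
#' For each tissue, one scalar threshold is computed: the mean of all
#' negative-control rows over all of that tissue's timepoints. By default a
#' gene is removed when every one of its timepoint values lies below that
#' threshold (a gene with any timepoint above the negative-control average
#' counts as expressed); `compare = "mean"` instead removes genes whose mean
#' lies below it. Negative-control rows themselves are dropped from the
#' output.
#'
#' @param x An [expr_matrix()] or a named per-tissue list of them.
#' @param negative_ids Character vector of negative-control row ids; must be
#'   nonempty and present in the matrix.
#' @param compare `"all_timepoints"` (default) or `"mean"`.
#' @return List with `tissues` and `report`, as [filter_low_expressed()].
#' @export
filter_negative_controls <- function(x, negative_ids,
                                     compare = c("all_timepoints", "mean")) {
  compare <- match.arg(compare)
  tl <- as_tissue_list(x)
  if (!length(negative_ids)) stop("negative_ids must be nonempty")
  rep_rows <- list()
  out <- lapply(names(tl), function(tt) {
    m <- tl[[tt]]
    miss <- setdiff(negative_ids, rownames(m$values))
    if (length(miss))
      stop("negative-control id(s) absent from tissue '", tt, "': ",
           paste(miss, collapse = ", "))
    thr <- mean(m$values[negative_ids, , drop = FALSE])
    test <- m$values[!(rownames(m$values) %in% negative_ids), , drop = FALSE]
    below <- if (compare == "all_timepoints") {
      apply(test < thr, 1, all)
    } else {
      rowMeans(test) < thr
    }
    rep_rows[[tt]] <<- filter_report(tt, nrow(m$values),
                                     n_removed_negative = sum(below) +
                                       length(negative_ids))
    expr_matrix(test[!below, , drop = FALSE], m$samples)
  })
  names(out) <- names(tl)
  list(tissues = out, report = do.call(rbind, rep_rows))
}

#' Collapse multiple probes per gene to the highest-average probe
#'
#' For genes measured by several probes, the probe with the highest mean
#' across all samples is retained and relabelled with the gene id; exact
#' ties are broken by the lexicographically smallest probe id.
#'
#' @param x An [expr_matrix()] whose rownames are probe ids.
#' @param probe_to_gene Named character vector or two-column data.frame
#'   (`probe`, `gene`) mapping every probe to a gene.
#' @return An [expr_matrix()] with one row per gene.
#' @export
collapse_duplicates <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene$gene),
                                     probe_to_gene$probe)
  probes <- rownames(x$values)
  miss <- setdiff(probes, names(probe_to_gene))
  if (length(miss))
    stop("probe map does not cover probe(s): ", paste(miss, collapse = ", "))
  gene <- probe_to_gene[probes]
  means <- rowMeans(x$values)
  ord <- order(gene, -means, probes)  # per gene: highest mean, then lex id
  keep <- ord[!duplicated(gene[ord])]
  vals <- x$values[keep, , drop = FALSE]
  rownames(vals) <- gene[keep]
  expr_matrix(vals, x$samples)
}
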
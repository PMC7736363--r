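#' Gene-by-sample expression matrix with tissue/time metadata
#'
#' The unit every stage of the pipeline consumes: a numeric matrix of
#' nonnegative expression values (genes in rows, samples in columns) paired
#' with a sample sheet giving, for each column, its tissue label and
#' circadian sampling time in hours. Columns are stored in canonical order:
#' tissue-major (alphabetical), time-ascending within tissue.
#'
#' @param values Numeric matrix, genes x samples; rownames are gene ids.
#' @param samples data.frame with columns `sample`, `tissue`, `time`
#'   (hours). `sample` must match `colnames(values)` one-to-one.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`, columns reordered canonically.
#' @examples
#' v <- matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' s <- data.frame(sample = paste0("s", 1:4),
#'                 tissue = rep(c("liver", "lung"), each = 2),
#'                 time = c(0, 6, 0, 6))
#' m <- expr_matrix(v, s)
#' @export
expr_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have gene ids as rownames")
  req <- c("sample", "tissue", "time")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  samples <- samples[req]
  samples$sample <- as.character(samples$sample)
  samples$tissue <- as.character(samples$tissue)
  samples$time <- as.numeric(samples$time)
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as colnames")
  missing_ann <- setdiff(colnames(values), samples$sample)
  if (length(missing_ann))
    stop("sample sheet is missing annotation for column(s): ",
         paste(missing_ann, collapse = ", "))
  extra <- setdiff(samples$sample, colnames(values))
  if (length(extra))
    stop("sample sheet lists sample(s) absent from the matrix: ",
         paste(extra, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite or negative value at gene '",
         rownames(values)[bad[1, 1]], "', sample '",
         colnames(values)[bad[1, 2]], "'")
  }
  key <- paste(samples$tissue, samples$time)
  if (anyDuplicated(key))
    stop("duplicate (tissue, time) column: ", key[which(duplicated(key))[1]])
  grids <- tapply(samples$time, samples$tissue,
                  function(t) paste(sort(t), collapse = ","))
  if (length(unique(grids)) > 1L)
    stop("all tissues must share the same timepoint grid")
  ord <- order(samples$tissue, samples$time)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, samples$sample, drop = FALSE]
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(unique(x$samples$tissue)), "tissue(s),",
      length(unique(x$samples$time)), "timepoint(s)\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tissue labels of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of unique tissue labels (sorted).
#' @export
tissues <- function(x) sort(unique(x$samples$tissue))

#' Split an expression matrix by tissue
#'
#' @param x An `expr_matrix`.
#' @return Named list of single-tissue `expr_matrix` objects.
#' @export
split_tissues <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- lapply(tissues(x), function(tt) {
    keep <- x$samples$tissue == tt
    expr_matrix(x$values[, keep, drop = FALSE],
                x$samples[keep, , drop = FALSE])
  })
  names(out) <- tissues(x)
  out
}

# Accept either an expr_matrix or a named per-tissue list of them.
as_tissue_list <- function(x) {
  if (inherits(x, "expr_matrix")) return(split_tissues(x))
  if (is.list(x) && length(x) && all(vapply(x, inherits, TRUE, "expr_matrix"))) {
    if (is.null(names(x)))
      names(x) <- vapply(x, function(m) unique(m$samples$tissue)[1], "")
    return(x)
  }
  stop("expected an expr_matrix or a named list of per-tissue expr_matrix")
}

#' Read an expression matrix and its sample sheet from TSV files
#'
#' The matrix file has a `gene` id column followed by one column per sample;
#' the sample sheet has columns `sample`, `tissue`, `time_h`. Malformed
#' cells (non-numeric or negative) raise an error naming the offending
#' gene/sample cell.
#'
#' @param path Path to the matrix TSV.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @return An [expr_matrix()].
#' @export
read_expr_matrix <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (!ncol(tab) || names(tab)[1] != "gene")
    stop("matrix file must have a leading 'gene' column: ", path)
  genes <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals), dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at gene '", genes[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "': '", vals[bad[1, 1], bad[1, 2]], "'")
  rownames(num) <- genes
  sheet <- utils::read.delim(sample_sheet, check.names = FALSE)
  if (!all(c("sample", "tissue", "time_h") %in% names(sheet)))
    stop("sample sheet must have columns sample, tissue, time_h: ",
         sample_sheet)
  expr_matrix(num, data.frame(sample = sheet$sample, tissue = sheet$tissue,
                              time = sheet$time_h))
}

#' Write an expression matrix and its sample sheet as TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the matrix TSV.
#' @param sample_sheet Output path for the sample sheet TSV (columns
#'   `sample`, `tissue`, `time_h`).
#' @return Invisibly, `x`.
#' @export
write_expr_matrix <- function(x, path, sample_sheet) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample = x$samples$sample, tissue = x$samples$tissue,
                      time_h = x$samples$time)
  utils::write.table(sheet, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
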
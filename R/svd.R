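#' Singular value decomposition of a gene-by-tissue feature matrix
#'
#' Full SVD `X = U D V'` of a complete feature matrix (e.g. clock-gene mean
#' expression across tissues) with a deterministic sign convention: each
#' right singular vector (eigengene) is flipped so that its
#' largest-magnitude entry is positive, with the matching flip applied to
#' the left vector. Projections map the genes (rows, `U D`) and tissues
#' (columns, `V D`) onto components 1 and 2.
#'
#' @param m Numeric matrix with at least 2 rows (genes) and 2 columns
#'   (tissues); no missing cells.
#' @param center Subtract column means first (off by default; raw values
#'   enter the decomposition).
#' @return Object of class `svd_result`: list with `d` (singular values,
#'   descending), `u`, `v`, `gene_proj` (rows x first two components),
#'   `tissue_proj` (columns x first two components), `center`.
#' @export
svd_project <- function(m, center = FALSE) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("feature matrix must be complete and finite")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (center) m <- sweep(m, 2, colMeans(m))
  sv <- svd(m)
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  ncomp <- min(2L, length(sv$d))
  gene_proj <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  tissue_proj <- sv$v[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(gene_proj) <- rownames(m)
  rownames(tissue_proj) <- colnames(m)
  colnames(gene_proj) <- colnames(tissue_proj) <-
    paste0("component", seq_len(ncomp))
  structure(list(d = sv$d, u = sv$u, v = sv$v, gene_proj = gene_proj,
                 tissue_proj = tissue_proj, center = center),
            class = "svd_result")
}

#' Rank genes by distance from the gene-cluster centroid
#'
#' Operationalises "one gene sits apart from the cluster" on the
#' component-1/2 projection: the Euclidean distance of each gene's
#' projection from the centroid of all genes' projections, ranked
#' descending. An interpretation layer over the decomposition, not a
#' formal cluster test.
#'
#' @param result An [svd_project()] result with at least 3 genes.
#' @return data.frame `gene`, `distance`, `rank` (1 = farthest).
#' @export
outlier_gene <- function(result) {
  stopifnot(inherits(result, "svd_result"))
  pr <- result$gene_proj
  if (nrow(pr) < 3) stop("need at least 3 genes")
  centroid <- colMeans(pr)
  d <- sqrt(rowSums(sweep(pr, 2, centroid)^2))
  ord <- order(-d, rownames(pr))
  data.frame(gene = rownames(pr)[ord], distance = d[ord],
             rank = seq_along(d), row.names = NULL)
}
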
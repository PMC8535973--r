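#' Expression matrix container
#'
#' A lightweight gene-by-sample expression container carrying a scale tag
#' (`"linear"` for TPM/FPKM-like non-negative values, `"log2"` for
#' log-transformed values) and a per-sample cohort label. Every pipeline
#' stage consumes and produces this class.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Rownames are gene symbols, colnames are sample ids; both mandatory
#'   and unique.
#' @param scale Either `"linear"` or `"log2"`.
#' @param cohort Character vector of per-sample cohort labels, either
#'   named by sample id or in column order. Defaults to a single cohort
#'   `"cohort1"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `scale`, `cohort`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("A", "B"), c("s1", "s2", "s3"))), scale = "linear")
#' dim(m)
expression_matrix <- function(values, scale = c("linear", "log2"),
                              cohort = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (anyNA(values)) stop("missing expression values are not allowed")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression must be non-negative")
  }
  if (is.null(cohort)) cohort <- rep("cohort1", ncol(values))
  if (!is.null(names(cohort))) {
    if (!setequal(names(cohort), colnames(values))) {
      stop("cohort names do not match sample ids")
    }
    cohort <- cohort[colnames(values)]
  } else {
    if (length(cohort) == 1L) cohort <- rep(cohort, ncol(values))
    if (length(cohort) != ncol(values)) {
      stop("`cohort` must have one label per sample")
    }
    names(cohort) <- colnames(values)
  }
  structure(list(values = values, scale = scale,
                 cohort = as.character(cohort)),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale, %d cohort(s)]\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$cohort))))
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Sample ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param m An `expr_matrix`.
#' @param genes Character vector of gene symbols to keep (default all).
#' @param samples Character vector of sample ids to keep (default all).
#' @return An `expr_matrix` restricted to the requested rows/columns, in
#'   the requested order.
#' @export
subset_expr <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  coh <- m$cohort
  names(coh) <- colnames(v)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) {
      stop("genes not present: ", paste(missing, collapse = ", "))
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) {
      stop("samples not present: ", paste(missing, collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
    coh <- coh[samples]
  }
  expression_matrix(v, scale = m$scale, cohort = coh)
}

#' Convert a linear expression matrix to log2(x + 1)
#'
#' Clustering, differential expression and PCA in this package operate on a
#' single declared scale, log2(TPM + 1); microarray inputs already on log
#' scale pass through unchanged.
#'
#' @param m An `expr_matrix`.
#' @return An `expr_matrix` with `scale = "log2"`.
#' @export
to_log2 <- function(m) {
  if (m$scale == "log2") return(m)
  expression_matrix(log2(m$values + 1), scale = "log2", cohort = m$cohort)
}
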
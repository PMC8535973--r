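# small in-code fixtures shared across test files

make_expr <- function(values, scale = "log2", cohort = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  expression_matrix(values, scale = scale, cohort = cohort)
}

rand_expr <- function(n_genes, n_samples, scale = "log2", seed = NULL,
                      cohort = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples)
  if (scale == "linear") v <- abs(v)
  make_expr(v, scale = scale, cohort = cohort)
}

# two planted duplicate-sample groups for consensus sanity checks
dup_groups_expr <- function(n_per = 6, n_genes = 10, seed = 1) {
  set.seed(seed)
  a <- rnorm(n_genes, 0, 1)
  b <- rnorm(n_genes, 5, 1)
  v <- cbind(matrix(rep(a, n_per), n_genes),
             matrix(rep(b, n_per), n_genes))
  make_expr(v)
}
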
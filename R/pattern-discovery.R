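#' Subsampled consensus clustering of a regulator panel
#'
#' Identifies expression patterns by clustering repeated random subsamples
#' of the samples and recording, for every sample pair, the fraction of
#' co-subsamplings in which the pair landed in the same cluster. The
#' consensus matrices over a range of k, their empirical CDFs and the
#' proportion of ambiguous clustering (PAC) support choosing the number of
#' patterns via [select_k()].
#'
#' All stochastic steps operate on samples ordered by sample id, so the
#' result is invariant (equivariant) to the column order of the input.
#'
#' @param m An `expr_matrix`, typically already restricted to the regulator
#'   panel; rows are standardized internally before clustering.
#' @param panel Optional character vector (or single `gene_sets` entry) of
#'   panel genes; at least 2 must match `m`.
#' @param k_range Integer vector of cluster numbers to evaluate (all >= 2).
#' @param reps Number of subsampling repetitions (default 1000).
#' @param p_item Fraction of samples drawn per repetition (default 0.8).
#' @param base_method Base clusterer: `"kmeans"` (Euclidean, default) or
#'   `"hclust"` (average linkage on 1 - Spearman correlation).
#' @param seed Master seed; per-rep seeds are derived by a counter so
#'   repetitions are independent of execution order.
#' @param pac_band Lower/upper consensus bounds `(u1, u2)` defining PAC
#'   (default `c(0.1, 0.9)`).
#' @return A `consensus_result`: list with `k_range`, `reps`, `p_item`,
#'   and per-k entries holding `consensus` (n x n), `assignments`, `pac`,
#'   `cdf` (a function), plus `delta_area` across k.
#' @export
consensus_cluster <- function(m, panel = NULL, k_range = 2:6, reps = 1000,
                              p_item = 0.8,
                              base_method = c("kmeans", "hclust"),
                              seed = 1L, pac_band = c(0.1, 0.9)) {
  base_method <- match.arg(base_method)
  stopifnot(inherits(m, "expr_matrix"))
  if (reps < 1) stop("reps must be >= 1")
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]")
  if (!is.null(panel)) {
    panel <- intersect(trimws(as.character(panel)), gene_ids(m))
    if (length(panel) < 2L) stop("fewer than 2 panel genes match the matrix")
    m <- subset_expr(m, genes = panel)
  }
  x <- m$values
  n <- ncol(x)
  if (any(k_range < 2)) stop("k_range entries must be >= 2")
  if (max(k_range) >= n) stop("k must be smaller than the number of samples")
  rs <- apply(x, 1, stats::sd)
  if (all(rs == 0)) stop("constant-expression panel: degenerate distance")
  if (any(rs == 0)) x <- x[rs > 0, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)

  # canonical sample order: all randomness indexes into this ordering
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  ids <- colnames(x)
  n_sub <- max(2L, floor(p_item * n))

  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)

  for (r in seq_len(reps)) {
    set.seed((seed + 7919L * r) %% .Machine$integer.max)
    idx <- sort(sample.int(n, n_sub))
    ind <- matrix(0, n, 1)
    ind[idx, 1] <- 1
    co_sample <- co_sample + tcrossprod(ind)
    sub <- x[, idx, drop = FALSE]
    for (k in k_range) {
      cl <- .base_cluster(sub, k, base_method)
      memb <- matrix(0, n, k)
      memb[cbind(idx, cl)] <- 1
      co_cluster[[as.character(k)]] <-
        co_cluster[[as.character(k)]] + tcrossprod(memb)
    }
  }

  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never)) {
    warning(sprintf("%d sample pair(s) never co-subsampled; consensus set to 0",
                    sum(never)))
  }
  per_k <- lapply(k_range, function(k) {
    cc <- co_cluster[[as.character(k)]]
    cons <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    ut <- cons[upper.tri(cons)]
    cdf <- stats::ecdf(ut)
    pac <- cdf(pac_band[2]) - cdf(pac_band[1])
    list(consensus = cons,
         assignments = assign_clusters(cons, k),
         pac = pac, cdf = cdf,
         auc = .cdf_area(ut))
  })
  names(per_k) <- as.character(k_range)
  aucs <- vapply(per_k, `[[`, 0, "auc")
  delta <- c(aucs[1], diff(aucs) / pmax(aucs[-length(aucs)], .Machine$double.eps))
  structure(list(k_range = k_range, reps = reps, p_item = p_item,
                 base_method = base_method, pac_band = pac_band,
                 per_k = per_k, delta_area = stats::setNames(delta, names(per_k)),
                 sample_ids = ids),
            class = "consensus_result")
}

# area under the empirical CDF of upper-triangle consensus values
.cdf_area <- function(u) {
  s <- sort(u)
  if (length(s) < 2L) return(0)
  f <- seq_along(s) / length(s)
  sum(diff(s) * f[-length(f)])
}

.base_cluster <- function(sub, k, base_method) {
  if (base_method == "kmeans") {
    stats::kmeans(t(sub), centers = k, nstart = 3, iter.max = 50)$cluster
  } else {
    rho <- stats::cor(sub, method = "spearman")
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    stats::cutree(hc, k = k)
  }
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result over k = {%s}, %d reps, p_item = %.2f\n",
              paste(x$k_range, collapse = ", "), x$reps, x$p_item))
  pac <- vapply(x$per_k, `[[`, 0, "pac")
  cat("PAC:", paste(sprintf("k=%s: %.4f", names(pac), pac), collapse = "  "),
      "\n")
  invisible(x)
}

#' Select the number of clusters from a consensus result
#'
#' Default criterion: minimize PAC over the evaluated band, ties broken
#' toward the smallest k. `forced_k` overrides the criterion (with a
#' message), mirroring the common practice of fixing k on biological
#' grounds.
#'
#' @param r A `consensus_result`.
#' @param method Currently `"pac"`.
#' @param forced_k Optional integer in `r$k_range` that overrides selection.
#' @return The selected k (integer).
#' @export
select_k <- function(r, method = "pac", forced_k = NULL) {
  stopifnot(inherits(r, "consensus_result"))
  if (!is.null(forced_k)) {
    if (!forced_k %in% r$k_range) stop("forced_k outside evaluated k_range")
    message("select_k: using forced_k = ", forced_k)
    return(as.integer(forced_k))
  }
  method <- match.arg(method, "pac")
  pac <- vapply(r$per_k, `[[`, 0, "pac")
  as.integer(r$k_range[which.min(pac)])  # which.min takes the first == smallest k
}

#' Cut a consensus matrix into k clusters
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - consensus`, cut at k. Labels are renumbered by decreasing cluster
#' size; size ties are broken by the smallest member sample id.
#'
#' @param consensus Symmetric matrix with entries in `[0, 1]`, sample ids
#'   as dimnames.
#' @param k Number of clusters (1 <= k <= n).
#' @return Named integer vector mapping sample id to cluster in `1..k`.
#' @export
assign_clusters <- function(consensus, k) {
  n <- nrow(consensus)
  if (k > n) stop("k exceeds the number of samples")
  if (max(abs(consensus - t(consensus))) > 1e-8) {
    stop("consensus matrix must be symmetric")
  }
  if (min(consensus) < -1e-12 || max(consensus) > 1 + 1e-12) {
    stop("consensus entries must lie in [0, 1]")
  }
  ids <- rownames(consensus)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == 1L) return(stats::setNames(rep(1L, n), ids))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  cl <- stats::cutree(hc, k = k)
  # renumber: descending size, ties by smallest member id
  sizes <- tabulate(cl, nbins = k)
  min_id <- vapply(seq_len(k), function(g) min(ids[cl == g]), "")
  new_order <- order(-sizes, min_id)
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  stats::setNames(relabel[cl], ids)
}

#' Proportion of ambiguous clustering for one consensus matrix
#' @param consensus Consensus matrix.
#' @param band `(u1, u2)` consensus band (default `c(0.1, 0.9)`).
#' @return PAC in `[0, 1]`: the CDF mass of upper-triangle consensus values
#'   falling in `(u1, u2]`.
#' @export
pac_score <- function(consensus, band = c(0.1, 0.9)) {
  ut <- consensus[upper.tri(consensus)]
  f <- stats::ecdf(ut)
  f(band[2]) - f(band[1])
}
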
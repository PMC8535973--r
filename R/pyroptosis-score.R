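#' Univariate Cox screen of candidate signature genes
#'
#' Fits one single-covariate Cox model per gene and keeps genes whose Wald
#' p-value falls below `alpha`. Constant genes are skipped with a warning;
#' genes whose fit fails (e.g. perfect separation) are likewise skipped.
#'
#' @param m An `expr_matrix` (samples must cover the clinical table).
#' @param clinical Data.frame with `sample_id`, `time`, `event`.
#' @param genes Character vector or `overlap_deg_set` of candidate genes.
#' @param alpha Wald p-value threshold (default 0.05).
#' @return Character vector of prognostic genes, input order preserved.
#' @export
screen_prognostic <- function(m, clinical, genes, alpha = 0.05) {
  if (inherits(genes, "overlap_deg_set")) genes <- genes$genes
  stopifnot(inherits(m, "expr_matrix"))
  common <- intersect(clinical$sample_id, sample_ids(m))
  if (length(common) < 3L) stop("too few samples shared with clinical table")
  cl <- clinical[match(common, clinical$sample_id), ]
  if (sum(cl$event) < 10) stop("fewer than 10 events: screen unreliable")
  x <- m$values[, common, drop = FALSE]
  genes <- intersect(genes, rownames(x))
  if (length(genes) == 0L) stop("no candidate genes present in the matrix")
  keep <- logical(length(genes))
  n_const <- 0L
  for (i in seq_along(genes)) {
    v <- x[genes[i], ]
    if (stats::sd(v) == 0) { n_const <- n_const + 1L; next }
    fit <- tryCatch(cox_fit(v, cl$time, cl$event), error = function(e) NULL)
    if (!is.null(fit) && fit$p[1] < alpha) keep[i] <- TRUE
  }
  if (n_const > 0L) warning(n_const, " constant gene(s) skipped")
  out <- genes[keep]
  if (length(out) == 0L) {
    stop("no gene passed the prognostic screen; consider reviewing alpha")
  }
  out
}

#' Fit the principal-component pyroptosis-score model
#'
#' PCA on centered (not scaled) expression of the prognostic genes; the
#' first two right-singular directions in gene space become the loading
#' vectors `w1`, `w2` onto which samples are projected. Per component, the
#' sign is fixed so the largest-|loading| gene has a positive coefficient.
#' Centering only (no unit-variance scaling) lets the largest block of
#' well-correlated genes dominate PC1.
#'
#' @param m An `expr_matrix` restricted (or restrictable) to the model
#'   genes: >= 2 genes, >= 3 samples.
#' @param genes Optional character vector selecting the model genes.
#' @return A `ps_model`: list with `genes`, `centers`, `w1`, `w2`,
#'   `var_explained` (length 2), `sign_flips`.
#' @export
fit_ps_model <- function(m, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.null(genes)) m <- subset_expr(m, genes = genes)
  x <- m$values
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (ncol(x) < 3L) stop("need at least 3 samples")
  centers <- rowMeans(x)
  xc <- x - centers
  sv <- svd(t(xc))                       # samples x genes; v = gene loadings
  if (length(sv$d) < 2L || sv$d[2] <= max(dim(xc)) * .Machine$double.eps * sv$d[1]) {
    stop("centered expression has rank < 2")
  }
  w1 <- sv$v[, 1]; w2 <- sv$v[, 2]
  flips <- c(w1[which.max(abs(w1))] < 0, w2[which.max(abs(w2))] < 0)
  if (flips[1]) w1 <- -w1
  if (flips[2]) w2 <- -w2
  tot <- sum(sv$d^2)
  structure(list(genes = rownames(x),
                 centers = centers,
                 w1 = stats::setNames(w1, rownames(x)),
                 w2 = stats::setNames(w2, rownames(x)),
                 var_explained = sv$d[1:2]^2 / tot,
                 sign_flips = flips),
            class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("ps_model: %d gene(s); PC1/PC2 variance explained %.1f%% / %.1f%%\n",
              length(x$genes), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Compute the pyroptosis score
#'
#' `PS(sample) = <x - centers, w1> + <x - centers, w2>`: the sample's PC1
#' coordinate plus its PC2 coordinate under the fitted model. On the
#' training matrix the scores average to zero.
#'
#' @param model A `ps_model`.
#' @param m An `expr_matrix` containing all model genes.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_ps <- function(model, m) {
  stopifnot(inherits(model, "ps_model"), inherits(m, "expr_matrix"))
  missing <- setdiff(model$genes, gene_ids(m))
  if (length(missing)) {
    stop("model gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  xc <- m$values[model$genes, , drop = FALSE] - model$centers
  drop(crossprod(xc, model$w1 + model$w2))
}

# Standardized two-group log-rank z for every candidate cut position at
# once. Samples are sorted by score; a cut after sorted position m puts
# positions 1..m in the low group. Cumulative at-risk and event counts by
# rank position make the whole scan O(n_event x n).
.logrank_scan <- function(scores, times, events, positions) {
  ord <- order(scores)
  ts <- times[ord]; es <- events[ord]
  et <- sort(unique(ts[es == 1]))
  at_risk <- outer(et, ts, function(t, ti) as.numeric(ti >= t))
  evt_at <- outer(et, seq_along(ts), function(t, i) {
    as.numeric(ts[i] == t & es[i] == 1)
  })
  cum_risk <- t(apply(at_risk, 1, cumsum))
  cum_evt <- t(apply(evt_at, 1, cumsum))
  n_t <- cum_risk[, length(ts)]
  d_t <- cum_evt[, length(ts)]
  n1 <- n_t - cum_risk[, positions, drop = FALSE]   # high-group at risk
  d1 <- d_t - cum_evt[, positions, drop = FALSE]
  o <- colSums(d1)
  e <- colSums(d_t * n1 / n_t)
  vt <- d_t * (n_t - d_t) / pmax(n_t - 1, 1)
  v <- colSums(vt * (n1 / n_t) * (1 - n1 / n_t))
  z <- ifelse(v > 0, (o - e) / sqrt(v), NA_real_)
  z
}

#' Maximally selected survival cutpoint for the pyroptosis score
#'
#' Scans candidate cutpoints (midpoints of consecutive sorted unique score
#' values) whose resulting high/low groups each hold at least `minprop` of
#' the samples and picks the cut maximizing the absolute standardized
#' log-rank statistic; ties take the lower cutpoint. An optional
#' permutation p-value re-maximizes over label permutations, an honest
#' account of the selection process.
#'
#' @param ps Named numeric vector of per-sample scores.
#' @param clinical Data.frame with `sample_id`, `time`, `event` covering
#'   the scored samples.
#' @param minprop Minimum group fraction on each side (default 0.1).
#' @param n_perm Permutations for the selection-adjusted p-value (default
#'   0: p-value reported as `NA`).
#' @return A `ps_result`: list with `ps`, `cutpoint`, `group` (factor
#'   high/low), `statistic` (max |z|), `minprop`, `perm_p`.
#' @export
find_cutpoint <- function(ps, clinical, minprop = 0.1, n_perm = 0) {
  ids <- names(ps)
  if (is.null(ids)) {
    if (length(ps) != nrow(clinical)) stop("unnamed ps must match clinical rows")
    ids <- clinical$sample_id
    names(ps) <- ids
  }
  missing <- setdiff(ids, clinical$sample_id)
  if (length(missing)) stop("samples missing from clinical table: ",
                            paste(missing, collapse = ", "))
  cl <- clinical[match(ids, clinical$sample_id), ]
  times <- cl$time; events <- cl$event
  if (sum(events) == 0L) stop("no events")
  n <- length(ps)
  su <- sort(unique(ps))
  if (length(su) < 2L) stop("no admissible candidate cutpoint")
  cand <- (su[-1] + su[-length(su)]) / 2
  n_low <- vapply(su[-length(su)], function(v) sum(ps <= v), 0)
  admissible <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cand <- cand[admissible]
  positions <- n_low[admissible]         # sorted-rank index of each cut
  if (length(cand) == 0L) stop("no admissible candidate cutpoint")

  scan_max <- function(scores) {
    az <- abs(.logrank_scan(scores, times, events, positions))
    if (all(is.na(az))) return(list(stat = NA_real_, cut = NA_real_))
    best <- which.max(ifelse(is.na(az), -Inf, az))  # first max = lower cut
    list(stat = az[best], cut = cand[best])
  }
  obs <- scan_max(ps)
  if (is.na(obs$stat)) stop("no admissible candidate cutpoint with events on both sides")
  perm_p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      exceed <- exceed + (scan_max(sample(ps))$stat >= obs$stat - 1e-12)
    }
    perm_p <- (exceed + 1) / (n_perm + 1)
  }
  group <- factor(ifelse(ps > obs$cut, "high", "low"), levels = c("low", "high"))
  structure(list(ps = ps, cutpoint = obs$cut, group = group,
                 statistic = obs$stat, minprop = minprop, perm_p = perm_p),
            class = "ps_result")
}

#' @export
print.ps_result <- function(x, ...) {
  cat(sprintf(
    "ps_result: cutpoint %.4f (max |z| = %.3f); %d high / %d low%s\n",
    x$cutpoint, x$statistic, sum(x$group == "high"), sum(x$group == "low"),
    if (!is.na(x$perm_p)) sprintf("; permutation p = %.4g", x$perm_p) else ""))
  invisible(x)
}
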
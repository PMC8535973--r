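#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `min(1, cummin(m * p_(i) / i))` mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m * p[o] / (m:1)))[ro]
}

# Newton iteration with bisection safeguard for the inverse of trigamma.
# Solves trigamma(y) = x for y > 0; x must be positive.
.trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100) {
  vapply(x, function(xi) {
    if (xi <= 0) stop("trigamma inverse requires positive input")
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    lo <- 1e-8; hi <- 1e8
    for (it in seq_len(max_iter)) {
      f <- trigamma(y) - xi
      if (f > 0) lo <- max(lo, y) else hi <- min(hi, y)
      step <- f / psigamma(y, 2)   # Newton: f' = psigamma(, 2) < 0
      y_new <- y - step
      if (!is.finite(y_new) || y_new <= lo || y_new >= hi) {
        y_new <- (lo + hi) / 2     # safeguard bisection
      }
      if (abs(y_new - y) < tol * (1 + abs(y))) return(y_new)
      y <- y_new
    }
    y
  }, 0)
}

# Moment-matching fit of the scaled inverse-chi-square prior on gene
# variances: log s2 ~ logF. Returns d0 (prior df, possibly Inf) and s0sq.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    warning("too few positive variances; using d0 = Inf")
    return(list(d0 = Inf, s0sq = stats::median(s2[ok])))
  }
  z <- log(s2[ok])
  if (stats::var(z) < 1e-12) {
    # observed variances do not vary at all: point-mass prior at their
    # common value (the moments fit collapses)
    return(list(d0 = Inf, s0sq = exp(mean(z))))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(ev)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated group-contrast differential expression
#'
#' One-way layout on log2 expression: per gene, group means and a residual
#' variance pooled across all K groups (df = n - K). An empirical-Bayes
#' prior on the gene variances is fitted by moment matching on the log
#' sample variances (digamma/trigamma matching, Newton iteration with
#' bisection safeguard); the posterior variance
#' `s2_post = (d0 * s0sq + d * s2_g) / (d0 + d)` yields a moderated t with
#' `d0 + d` degrees of freedom per contrast, with BH-adjusted p-values.
#'
#' @param m A log2-scale `expr_matrix`.
#' @param groups Named vector (sample id -> cluster label) or unnamed
#'   vector in column order; must partition the samples, each contrasted
#'   level with >= 2 samples.
#' @param contrasts List of label pairs to contrast; default all pairwise
#'   combinations of the group levels.
#' @param d0 Optional override of the prior df: `0` recovers the ordinary
#'   pooled-variance t, `Inf` fixes every posterior variance at `s0sq`.
#' @param s0sq Optional override of the prior variance (required if
#'   `d0 = Inf` is forced without data-driven fitting; defaults to the
#'   fitted value).
#' @return List of `contrast_table` data.frames, one per contrast, each
#'   with `gene`, `diff` (log2 mean difference, first minus second label),
#'   `t`, `p`, `fdr`, `s2_post`, and attributes `d0`, `s0sq`, `contrast`.
#' @export
moderated_de <- function(m, groups, contrasts = NULL, d0 = NULL, s0sq = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("moderated_de expects log2-scale expression")
  x <- m$values
  ids <- colnames(x)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), ids)) stop("groups must cover all samples")
    groups <- groups[ids]
  } else if (length(groups) != ncol(x)) {
    stop("groups must have one label per sample")
  }
  g <- factor(as.character(groups))
  levs <- levels(g)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(levs, 2, simplify = FALSE)
  }
  for (ct in contrasts) {
    if (!all(ct %in% levs)) stop("contrast label not present: ",
                                 paste(setdiff(ct, levs), collapse = ", "))
    if (any(table(g)[ct] < 2)) {
      stop("contrast group with fewer than 2 samples: ",
           paste(ct[table(g)[ct] < 2], collapse = ", "))
    }
  }
  n <- ncol(x); K <- nlevels(g)
  d <- n - K
  if (d < 1) stop("no residual degrees of freedom")
  counts <- as.vector(table(g))
  means <- vapply(levs, function(l) rowMeans(x[, g == l, drop = FALSE]),
                  numeric(nrow(x)))
  # pooled residual SS across all groups
  ss <- rowSums(x^2) - as.vector(means^2 %*% counts)
  s2 <- pmax(ss, 0) / d
  zero_var <- s2 <= 1e-300

  if (is.null(d0)) {
    prior <- .fit_variance_prior(s2[!zero_var], d)
    d0 <- prior$d0
    if (is.null(s0sq)) s0sq <- prior$s0sq
  } else if (is.null(s0sq)) {
    if (is.infinite(d0)) {
      prior <- .fit_variance_prior(s2[!zero_var], d)
      s0sq <- prior$s0sq
    } else s0sq <- 0
  }
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else {
    (d0 * s0sq + d * s2) / (d0 + d)
  }
  df_total <- d0 + d

  lapply(contrasts, function(ct) {
    i <- match(ct[1], levs); j <- match(ct[2], levs)
    md <- means[, i] - means[, j]
    se <- sqrt(s2_post * (1 / counts[i] + 1 / counts[j]))
    tt <- ifelse(se > 0, md / se, 0)
    p <- if (is.finite(df_total)) 2 * stats::pt(-abs(tt), df_total) else {
      2 * stats::pnorm(-abs(tt))
    }
    # genes with zero residual variance carry no within-group information
    tt[zero_var] <- 0
    p[zero_var] <- 1
    out <- data.frame(gene = rownames(x), diff = md, t = tt, p = p,
                      fdr = bh_fdr(p), s2_post = s2_post,
                      flagged = zero_var,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "contrast") <- ct
    attr(out, "d0") <- d0
    attr(out, "s0sq") <- s0sq
    class(out) <- c("contrast_table", "data.frame")
    out
  })
}

#' Genes differential in every pairwise contrast
#'
#' The Venn-center rule: a gene qualifies as a pattern-related signature
#' gene only if its BH-adjusted p-value is below the threshold in all
#' supplied contrasts.
#'
#' @param tables List of `contrast_table`s over a common gene universe.
#' @param fdr_threshold Qualification threshold (default 0.01).
#' @return List with `genes` (character vector, input row order) and
#'   `qualification` (gene x contrast logical matrix).
#' @export
overlap_degs <- function(tables, fdr_threshold = 0.01) {
  stopifnot(length(tables) >= 1L)
  genes <- tables[[1]]$gene
  for (tb in tables[-1]) {
    if (!identical(tb$gene, genes)) {
      stop("mismatched gene universes across contrast tables")
    }
  }
  qual <- vapply(tables, function(tb) tb$fdr < fdr_threshold,
                 logical(length(genes)))
  if (is.null(dim(qual))) qual <- matrix(qual, nrow = length(genes))
  colnames(qual) <- vapply(tables, function(tb)
    paste(attr(tb, "contrast"), collapse = "_vs_"), "")
  rownames(qual) <- genes
  structure(list(genes = genes[rowSums(qual) == ncol(qual)],
                 qualification = qual,
                 fdr_threshold = fdr_threshold),
            class = "overlap_deg_set")
}

#' @export
print.overlap_deg_set <- function(x, ...) {
  cat(sprintf("overlap_deg_set: %d gene(s) below fdr %g in all %d contrast(s)\n",
              length(x$genes), x$fdr_threshold, ncol(x$qualification)))
  invisible(x)
}
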
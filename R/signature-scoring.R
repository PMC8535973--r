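#' Single-sample gene set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by decreasing expression (ties get
#' average ranks). Walking down the ranked list, the weighted fraction of
#' gene-set hits encountered so far, with weight `|rank|^alpha`, is
#' compared to the fraction of misses; the enrichment score is the sum of
#' the differences over all positions. Scores therefore depend only on
#' within-sample ranks.
#'
#' @param m An `expr_matrix`.
#' @param sets A `gene_sets` collection; each set must match at least 1 and
#'   at most `nrow(m) - 1` genes.
#' @param alpha Rank weight exponent (default 0.25). `alpha = 0` gives the
#'   unweighted Kolmogorov-Smirnov-style running sum.
#' @param normalize If `TRUE`, min-max rescale each signature across
#'   samples (the common published variant); default `FALSE` (raw scores).
#' @return An `ssgsea_profile`: list with `scores` (signatures x samples
#'   matrix), `alpha`, `normalized`.
#' @export
ssgsea_score <- function(m, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  genes <- gene_ids(m)
  n <- length(genes)
  matched <- lapply(sets, function(s) intersect(trimws(s), genes))
  bad <- names(sets)[lengths(matched) == 0L]
  if (length(bad)) {
    stop("gene set(s) with empty intersection: ", paste(bad, collapse = ", "))
  }
  full <- names(sets)[lengths(matched) >= n]
  if (length(full)) {
    stop("gene set(s) covering every gene (miss fraction undefined): ",
         paste(full, collapse = ", "))
  }
  scores <- matrix(NA_real_, length(sets), ncol(m$values),
                   dimnames = list(names(sets), sample_ids(m)))
  for (j in seq_len(ncol(m$values))) {
    x <- m$values[, j]
    rk <- rank(x, ties.method = "average")   # high expression -> high rank
    ord <- order(-x, seq_along(x))           # decreasing; stable in ties
    w <- rk[ord]^alpha
    for (s in seq_along(matched)) {
      hit <- genes[ord] %in% matched[[s]]
      p_in <- cumsum(w * hit) / sum(w[hit])
      p_out <- cumsum(!hit) / (n - sum(hit))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 1, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    scores <- (scores - rng[1, ]) / span
  }
  structure(list(scores = scores, alpha = alpha, normalized = normalize),
            class = "ssgsea_profile")
}

#' @export
print.ssgsea_profile <- function(x, ...) {
  cat(sprintf("ssgsea_profile: %d signature(s) x %d sample(s), alpha = %g%s\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$normalized) ", min-max normalized" else ""))
  invisible(x)
}

#' ESTIMATE-style immune/stromal scores and tumor purity
#'
#' Immune and stromal scores are unnormalized ssGSEA scores on the two
#' signature sets; their sum is the ESTIMATE score, which maps to tumor
#' purity through `purity = cos(a + b * estimate_score)` with the method's
#' published constants (overridable). Arguments leaving `(0, pi/2)` are
#' clamped into `(0, 1]` with a warning.
#'
#' @param m An `expr_matrix`.
#' @param stromal_set,immune_set Character vectors of signature genes.
#' @param purity_constants Numeric `c(a, b)` of the purity cosine
#'   (defaults `c(0.6049872018, 0.0001467884)`).
#' @return A data.frame with `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `purity`.
#' @export
estimate_scores <- function(m, stromal_set, immune_set,
                            purity_constants = c(0.6049872018, 0.0001467884)) {
  prof <- ssgsea_score(m, gene_sets(list(stromal = stromal_set,
                                         immune = immune_set)),
                       alpha = 0.25, normalize = FALSE)
  stromal <- prof$scores["stromal", ]
  immune <- prof$scores["immune", ]
  est <- stromal + immune
  arg <- purity_constants[1] + purity_constants[2] * est
  if (any(arg <= 0 | arg >= pi / 2)) {
    warning("purity cosine argument outside (0, pi/2); clamped")
  }
  purity <- pmin(pmax(cos(arg), .Machine$double.eps), 1)
  data.frame(sample_id = sample_ids(m), stromal_score = stromal,
             immune_score = immune, estimate_score = est,
             purity = purity, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `|query|` genes are drawn from the
#' universe; p-values are BH-adjusted across sets.
#'
#' @param query Character vector of genes of interest (must lie inside
#'   `universe`).
#' @param universe Character vector, the gene background (no duplicates).
#' @param sets A `gene_sets` collection.
#' @return Data.frame with `set`, `set_size`, `overlap`, `p`, `fdr`,
#'   sorted by increasing p.
#' @export
ora_enrich <- function(query, universe, sets) {
  query <- unique(trimws(query))
  if (length(query) == 0L) stop("empty query")
  if (anyDuplicated(universe)) stop("universe contains duplicates")
  universe <- trimws(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside universe: ", paste(outside, collapse = ", "))
  }
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(sets), function(nm) {
    in_set <- intersect(trimws(sets[[nm]]), universe)
    ov <- length(intersect(query, in_set))
    p <- stats::phyper(ov - 1, length(in_set), n_u - length(in_set), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(in_set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
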
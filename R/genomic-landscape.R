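#' Per-gene mutation frequency over a panel
#'
#' Counts, per panel gene, the distinct samples carrying at least one
#' non-Silent record, plus the overall fraction of samples altered in any
#' panel gene.
#'
#' @param mutations Data.frame as from [read_mutations()] (`sample_id`,
#'   `gene`, `class`).
#' @param panel Character vector of panel genes.
#' @param n_samples Cohort size (>= number of distinct samples observed).
#' @return List with `table` (gene, mutated_samples, freq; sorted by freq
#'   descending, ties alphabetical) and `overall_fraction`.
#' @export
mutation_summary <- function(mutations, panel, n_samples) {
  observed <- length(unique(mutations$sample_id))
  if (n_samples < observed) {
    stop("n_samples smaller than the number of distinct samples observed")
  }
  nonsilent <- mutations[mutations$class != "Silent", , drop = FALSE]
  per_gene <- vapply(panel, function(g) {
    length(unique(nonsilent$sample_id[nonsilent$gene == g]))
  }, 0L)
  tab <- data.frame(gene = panel, mutated_samples = per_gene,
                    freq = per_gene / n_samples, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$freq, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  altered <- unique(nonsilent$sample_id[nonsilent$gene %in% panel])
  list(table = tab, overall_fraction = length(altered) / n_samples)
}

#' Pairwise co-mutation test
#'
#' Fisher's exact test (two-sided) on the 2x2 sample-level mutated/wild
#' table of two genes; the odds ratio is the Haldane-corrected
#' cross-product when any cell is zero.
#'
#' @param mutations Mutation records (`sample_id`, `gene`, `class`).
#' @param gene_a,gene_b The two genes.
#' @param n_samples Cohort size.
#' @return List with `odds_ratio`, `p`, `table` (2x2 counts).
#' @export
comutation_test <- function(mutations, gene_a, gene_b, n_samples) {
  nonsilent <- mutations[mutations$class != "Silent", , drop = FALSE]
  observed <- length(unique(mutations$sample_id))
  if (n_samples < observed) stop("n_samples smaller than observed samples")
  sa <- unique(nonsilent$sample_id[nonsilent$gene == gene_a])
  sb <- unique(nonsilent$sample_id[nonsilent$gene == gene_b])
  if (length(sa) == 0L) warning("gene ", gene_a, " never mutated; all-wild")
  if (length(sb) == 0L) warning("gene ", gene_b, " never mutated; all-wild")
  a <- length(intersect(sa, sb))
  b <- length(setdiff(sa, sb))
  cc <- length(setdiff(sb, sa))
  d <- n_samples - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("A_mut", "A_wild"), c("B_mut", "B_wild")))
  p <- stats::fisher.test(tab)$p.value
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else (a * d) / (b * cc)
  list(odds_ratio = or, p = p, table = tab)
}

#' CNV gain/loss frequency per panel gene
#'
#' @param cnv Data.frame as from [read_cnv()] (`sample_id`, `gene`,
#'   `state`).
#' @param panel Character vector of panel genes.
#' @return Data.frame with `gene`, `gain_freq`, `loss_freq`, `dominant`
#'   (`amplification` / `deletion` / `balanced` by strict frequency
#'   comparison; ties balanced). Frequencies are over the samples with a
#'   call for the gene.
#' @export
cnv_frequency <- function(cnv, panel) {
  if (!all(cnv$state %in% -2:2)) stop("CNV state outside {-2,...,2}")
  out <- lapply(panel, function(g) {
    st <- cnv$state[cnv$gene == g]
    n <- length(st)
    gain <- if (n) sum(st > 0) / n else 0
    loss <- if (n) sum(st < 0) / n else 0
    dom <- if (gain > loss) "amplification" else if (loss > gain) "deletion" else "balanced"
    data.frame(gene = g, gain_freq = gain, loss_freq = loss, dominant = dom,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample tumor mutation burden
#'
#' Raw count of nonsilent records per sample (no per-megabase
#' normalization; downstream comparisons are rank-based). Samples listed
#' in `sample_ids` but absent from the table get 0.
#'
#' @param mutations Mutation records (`sample_id`, `gene`, `class`).
#' @param sample_ids Optional universe of samples to report (default: the
#'   samples observed in the table).
#' @return Named integer vector of nonsilent counts.
#' @export
tmb <- function(mutations, sample_ids = NULL) {
  nonsilent <- mutations[mutations$class != "Silent", , drop = FALSE]
  counts <- table(nonsilent$sample_id)
  if (is.null(sample_ids)) sample_ids <- sort(unique(mutations$sample_id))
  out <- stats::setNames(integer(length(sample_ids)), sample_ids)
  hit <- intersect(names(counts), sample_ids)
  out[hit] <- as.integer(counts[hit])
  out
}
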
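#' Read a gene-by-sample expression TSV
#'
#' Expects a first column `gene_id` and one column per sample. An optional
#' cohort map TSV (`sample_id`, `cohort`) attaches per-sample cohort
#' labels; samples without a mapping raise an error.
#'
#' @param path Expression TSV path.
#' @param cohort_path Optional cohort map TSV path.
#' @param scale `"linear"` or `"log2"`, the scale of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, cohort_path = NULL,
                            scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1] != "gene_id") {
    stop("expression TSV must start with a `gene_id` column")
  }
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(tab[[1]])
  cohort <- NULL
  if (!is.null(cohort_path)) {
    cm <- utils::read.delim(cohort_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "cohort") %in% names(cm))) {
      stop("cohort map must have columns sample_id, cohort")
    }
    missing <- setdiff(colnames(v), cm$sample_id)
    if (length(missing)) {
      stop("samples without cohort label: ", paste(missing, collapse = ", "))
    }
    cohort <- stats::setNames(as.character(cm$cohort), cm$sample_id)
    cohort <- cohort[colnames(v)]
  }
  expression_matrix(v, scale = scale, cohort = cohort)
}

#' Read a clinical table TSV
#'
#' Columns `sample_id`, `time` (survival days), `event` (0/1); any further
#' columns are kept as covariates. Validation of times/events is deferred
#' to [filter_samples()], which implements the cohort inclusion rules.
#'
#' @param path Clinical TSV path.
#' @return A data.frame with unique `sample_id`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab))) {
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in clinical table")
  tab
}

#' Convert FPKM to TPM
#'
#' Per sample j, `TPM_ij = FPKM_ij / sum_i FPKM_ij * 1e6`, so each column
#' sums to one million. Only the linear scale is accepted.
#'
#' @param m An `expr_matrix` of linear FPKM values.
#' @return An `expr_matrix` of linear TPM values.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear") stop("fpkm_to_tpm requires linear-scale input")
  if (any(m$values < 0)) stop("negative FPKM values")
  cs <- colSums(m$values)
  if (any(cs <= 0)) {
    stop("all-zero expression column(s): ",
         paste(colnames(m$values)[cs <= 0], collapse = ", "))
  }
  expression_matrix(sweep(m$values, 2, cs, "/") * 1e6,
                    scale = "linear", cohort = m$cohort)
}

#' Filter a clinical table by minimum follow-up and event completeness
#'
#' Drops samples with survival time below `min_days` (strictly), missing or
#' non-positive time, or a missing/ambiguous event indicator (anything not
#' coercible to 0/1). The removed ids are attached as attribute
#' `"removed"`.
#'
#' @param clinical Data.frame as from [read_clinical()].
#' @param min_days Minimum survival time retained, in days (default 30).
#' @return The filtered clinical table; `attr(, "removed")` holds the
#'   dropped sample ids.
#' @export
filter_samples <- function(clinical, min_days = 30) {
  ev <- suppressWarnings(as.numeric(clinical$event))
  tm <- suppressWarnings(as.numeric(clinical$time))
  ok <- !is.na(tm) & tm > 0 & tm >= min_days & !is.na(ev) & ev %in% c(0, 1)
  removed <- clinical$sample_id[!ok]
  out <- clinical[ok, , drop = FALSE]
  out$time <- tm[ok]
  out$event <- ev[ok]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all samples removed by filter")
  attr(out, "removed") <- removed
  out
}

#' Merge expression cohorts on their common genes
#'
#' Rows are restricted to the intersection of gene ids (in the order of the
#' first matrix); sample columns are concatenated in input order and keep
#' their cohort labels.
#'
#' @param mats List of `expr_matrix` objects on the same scale with
#'   pairwise-disjoint sample ids.
#' @return A single merged `expr_matrix`.
#' @export
merge_cohorts <- function(mats) {
  stopifnot(length(mats) >= 1L, all(vapply(mats, inherits, TRUE, "expr_matrix")))
  scales <- vapply(mats, function(m) m$scale, "")
  if (length(unique(scales)) != 1L) stop("all cohorts must share one scale")
  ids <- unlist(lapply(mats, sample_ids))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- Reduce(intersect, lapply(mats, gene_ids))
  if (length(genes) == 0L) stop("empty gene intersection across cohorts")
  v <- do.call(cbind, lapply(mats, function(m) m$values[genes, , drop = FALSE]))
  cohort <- unlist(lapply(mats, function(m) m$cohort))
  expression_matrix(v, scale = scales[1], cohort = cohort)
}

#' Location-scale batch correction across cohorts
#'
#' Per gene g and cohort c, standardizes within cohort and restores pooled
#' moments: `x' = (x - mean_gc) / sd_gc * sd_g + mean_g`, where `mean_g` is
#' the grand mean and `sd_g` the pooled within-cohort standard deviation
#' (df-weighted; this choice makes the operation exactly idempotent).
#' Degenerate (gene, cohort) pairs with zero variance are centered only,
#' with a warning. A deliberately non-EB adjustment: deterministic, and the
#' per-cohort gene means agree exactly after correction. `method = "eb"`
#' reserves room for an empirical-Bayes variant and currently errors.
#'
#' @param m A log2-scale `expr_matrix` with at least two cohorts, each of
#'   size at least two.
#' @param method Only `"loc_scale"` is implemented.
#' @return The batch-adjusted `expr_matrix`.
#' @export
correct_batch <- function(m, method = c("loc_scale", "eb")) {
  method <- match.arg(method)
  if (method == "eb") stop("empirical-Bayes batch correction not implemented")
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("correct_batch expects log2-scale expression")
  coh <- m$cohort
  cohorts <- unique(coh)
  if (length(cohorts) < 2L) stop("nothing to correct: a single cohort")
  n_c <- table(coh)
  if (any(n_c < 2L)) {
    stop("cohort(s) with fewer than 2 samples: ",
         paste(names(n_c)[n_c < 2L], collapse = ", "))
  }
  v <- m$values
  grand_mean <- rowMeans(v)
  means <- vapply(cohorts, function(cc)
    rowMeans(v[, coh == cc, drop = FALSE]), numeric(nrow(v)))
  vars <- vapply(cohorts, function(cc)
    apply(v[, coh == cc, drop = FALSE], 1, stats::var), numeric(nrow(v)))
  df <- as.numeric(n_c[cohorts]) - 1
  pooled_sd <- sqrt(as.vector(vars %*% df) / sum(df))
  out <- v
  n_degenerate <- 0L
  for (cc in cohorts) {
    sel <- coh == cc
    mu <- means[, cc]
    sdc <- sqrt(vars[, cc])
    scl <- ifelse(sdc > 0, pooled_sd / sdc, 1)
    n_degenerate <- n_degenerate + sum(sdc == 0 & pooled_sd > 0)
    out[, sel] <- (v[, sel, drop = FALSE] - mu) * scl + grand_mean
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d (gene, cohort) pairs had zero variance: centered only",
                    n_degenerate))
  }
  expression_matrix(out, scale = "log2", cohort = m$cohort)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description (ignored), then member gene symbols,
#' tab-separated. Duplicate members within a line are dropped with a
#' warning; duplicate set names or malformed lines are errors.
#'
#' @param path GMT file path.
#' @return A `gene_sets` object: a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", i))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicate members dropped", fields[1]))
      members <- unique(members)
    }
    nms[i] <- fields[1]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(sets, class = "gene_sets")
}

#' Construct a gene-set collection in code
#' @param sets Named list of character vectors of gene symbols.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s)")
  structure(sets, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_sets` object.
#' @param path Output path.
#' @param descriptions Optional per-set description column (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-like mutation table TSV
#'
#' Required columns: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`. The variant classification vocabulary is
#' enforced at read time.
#'
#' @param path TSV path.
#' @param vocabulary Allowed variant classes (defaults to the MAF standard
#'   coding classes plus `Silent`).
#' @return A data.frame with columns `sample_id`, `gene`, `class`.
#' @export
read_mutations <- function(path, vocabulary = maf_vocabulary()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% names(tab))) {
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(tab$Tumor_Sample_Barcode),
                    gene = as.character(tab$Hugo_Symbol),
                    class = as.character(tab$Variant_Classification),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$class), vocabulary)
  if (length(bad)) {
    stop("variant classification outside vocabulary: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' The MAF variant-classification vocabulary used by this package
#' @return Character vector of allowed classes; all but `Silent` count as
#'   nonsilent.
#' @export
maf_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
    "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site", "Silent")
}

#' Read a per-gene per-sample CNV call TSV
#'
#' Columns `gene`, `sample`, `state` with integral states in -2..2
#' (GISTIC-style: deep loss, loss, neutral, gain, amplification).
#'
#' @param path TSV path.
#' @return A data.frame with columns `sample_id`, `gene`, `state`.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "state")
  if (!all(need %in% names(tab))) {
    stop("CNV TSV must have columns: ", paste(need, collapse = ", "))
  }
  st <- tab$state
  if (!all(st %in% -2:2)) stop("CNV state outside {-2,...,2}")
  data.frame(sample_id = as.character(tab$sample),
             gene = as.character(tab$gene),
             state = as.integer(st), stringsAsFactors = FALSE)
}

#' Match gene-set members against an expression matrix
#'
#' Symbols are matched case-sensitively after whitespace trimming;
#' unmatched members are dropped, with a message giving the dropped count.
#'
#' @param sets A `gene_sets` object.
#' @param m An `expr_matrix`.
#' @param min_size Sets retaining fewer members than this are dropped.
#' @return A `gene_sets` object restricted to genes present in `m`.
#' @export
match_gene_sets <- function(sets, m, min_size = 1L) {
  genes <- gene_ids(m)
  matched <- lapply(sets, function(s) intersect(trimws(s), genes))
  dropped <- sum(lengths(sets)) - sum(lengths(matched))
  if (dropped > 0) {
    message(sprintf("match_gene_sets: %d unmatched member(s) dropped", dropped))
  }
  keep <- lengths(matched) >= min_size
  if (!all(keep)) {
    message("match_gene_sets: dropped set(s): ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  structure(matched[keep], class = "gene_sets")
}
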
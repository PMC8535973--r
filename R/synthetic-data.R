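#' Configuration for the synthetic study generator
#'
#' Encodes the statistical world the pipeline assumes: K expression
#' patterns planted in a regulator panel and a block of signature genes,
#' multi-cohort batch effects, survival whose log-hazard is linear (or a
#' step) in a latent pattern score, censoring, and a mutation burden tied
#' to the same latent score.
#'
#' Pattern effects: pattern k carries a score `c_k` on an equally spaced
#' grid from -1 to 1; a regulator gene shifts by `delta * c_k` (all
#' regulators share direction +1). The latent score is the mean regulator
#' effect realized in the sample -- `delta * c_k` plus the sample's mean
#' regulator noise -- plus an extra independent Gaussian disturbance of
#' scale 0.25, so downstream scores can meaningfully track L both between
#' and within patterns. Signature genes get +1/-1 directions with a 70/30
#' split, and the induced (+) block responds more strongly than the
#' repressed (-) block: one dominant co-regulated block anchors PC1 and
#' its sign convention. Noise genes carry no pattern effect.
#'
#' @param seed Integer seed; the full output is reproducible per seed.
#' @param k_patterns Number of planted patterns (default 3).
#' @param n_per_pattern Samples per pattern (default 50).
#' @param n_regulators Regulator-panel size (default 33).
#' @param n_signature_genes Pattern-responsive non-panel genes (default
#'   100).
#' @param n_noise_genes Unstructured genes (default 1867, for a 2000-gene
#'   universe).
#' @param delta Per-gene pattern shift between adjacent patterns, log2
#'   units (default 2: planted patterns separated by two residual sd, a
#'   clearly present but noise-embedded structure).
#' @param sigma Residual sd, log2 units (default 1).
#' @param n_cohorts Number of cohorts (default 2); batch effects are an
#'   additive shift `N(0, batch_shift_sd^2)` plus a scale factor drawn
#'   uniformly from `batch_scale_range`, per (gene, cohort).
#' @param batch_shift_sd,batch_scale_range Batch effect magnitudes
#'   (defaults 1 and `c(0.8, 1.25)`).
#' @param baseline_hazard Exponential baseline hazard per day (default
#'   `log(2)/730`: two-year median survival at L = 0).
#' @param beta Log-hazard coefficient on the latent score L (default 0.5).
#' @param censoring Target censoring fraction in `[0, 1)` (default 0.3),
#'   achieved with uniform censoring calibrated on the drawn event times.
#' @param hazard_model `"loglinear"` (default) or `"step"` (hazard jumps
#'   by `exp(beta)` at L > 0; used to test cutpoint recovery).
#' @param tmb_intercept,tmb_slope Per-sample nonsilent mutation count is
#'   `Poisson(exp(a + b * L))` (defaults `log(20)` and 0.3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, k_patterns = 3L, n_per_pattern = 50L,
                       n_regulators = 33L, n_signature_genes = 100L,
                       n_noise_genes = 1867L, delta = 2, sigma = 1,
                       n_cohorts = 2L, batch_shift_sd = 1,
                       batch_scale_range = c(0.8, 1.25),
                       baseline_hazard = log(2) / 730, beta = 0.5,
                       censoring = 0.3,
                       hazard_model = c("loglinear", "step"),
                       tmb_intercept = log(20), tmb_slope = 0.3) {
  hazard_model <- match.arg(hazard_model)
  stopifnot(k_patterns >= 1, n_per_pattern >= 1, n_regulators >= 2,
            n_signature_genes >= 0, n_noise_genes >= 0,
            delta >= 0, sigma > 0, n_cohorts >= 1,
            censoring >= 0, censoring < 1, baseline_hazard > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic multi-cohort study with planted ground truth
#'
#' Draws expression (log2 scale, Gaussian noise around gene baselines,
#' pattern effects per [sim_config()], per-(gene, cohort) batch effects),
#' a clinical table (exponential survival, log-linear or step hazard in
#' the latent score, calibrated uniform censoring), a MAF-like mutation
#' table whose per-sample burden tracks the latent score, CNV calls, and
#' the regulator-panel gene set.
#'
#' @param cfg A `sim_config`.
#' @return A list with `expression` (`expr_matrix`, log2), `clinical`
#'   (data.frame), `mutations`, `cnv`, `sets` (`gene_sets` holding
#'   `regulator_panel`), and `truth` (pattern labels, latent score `L`,
#'   gene roles, effect directions, `true_cutpoint` in step mode).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$k_patterns
  n <- K * cfg$n_per_pattern
  pattern <- rep(seq_len(K), each = cfg$n_per_pattern)
  ids <- sprintf("S%04d", seq_len(n))
  regs <- sprintf("REG%02d", seq_len(cfg$n_regulators))
  sigs <- if (cfg$n_signature_genes)
    sprintf("SIG%04d", seq_len(cfg$n_signature_genes)) else character(0)
  nse <- if (cfg$n_noise_genes)
    sprintf("NSE%04d", seq_len(cfg$n_noise_genes)) else character(0)
  genes <- c(regs, sigs, nse)
  G <- length(genes)

  c_k <- if (K == 1L) 0 else seq(-1, 1, length.out = K)
  dir <- c(rep(1, length(regs)),
           sample(c(-1, 1), length(sigs), replace = TRUE, prob = c(0.3, 0.7)),
           rep(0, length(nse)))
  names(dir) <- genes
  # induced (+) block responds more strongly than the repressed (-) block:
  # one dominant co-regulated block anchors PC1 and its sign convention
  mag <- rep(0, G)
  mag[seq_along(regs)] <- cfg$delta
  if (length(sigs)) {
    si <- length(regs) + seq_along(sigs)
    mag[si] <- cfg$delta * ifelse(dir[si] > 0,
                                  stats::runif(length(sigs), 0.8, 1.3),
                                  stats::runif(length(sigs), 0.5, 0.8))
  }
  baseline <- stats::rnorm(G, mean = 6, sd = 1.5)
  effect <- outer(dir * mag, c_k)                  # G x K
  noise <- matrix(stats::rnorm(G * n, sd = cfg$sigma), G, n)
  x <- baseline + effect[, pattern] + noise
  dimnames(x) <- list(genes, ids)

  cohort <- sprintf("cohort%d", rep_len(seq_len(cfg$n_cohorts), n))
  if (cfg$n_cohorts > 1L) {
    for (cc in unique(cohort)) {
      shift <- stats::rnorm(G, sd = cfg$batch_shift_sd)
      scl <- stats::runif(G, cfg$batch_scale_range[1], cfg$batch_scale_range[2])
      sel <- cohort == cc
      x[, sel] <- x[, sel, drop = FALSE] * scl + shift
    }
  }

  # mean regulator effect realized in the sample (pattern shift plus the
  # sample's mean regulator noise, pre-batch), plus independent disturbance
  reg_effect <- cfg$delta * c_k[pattern] +
    colMeans(noise[seq_along(regs), , drop = FALSE])
  L <- reg_effect + stats::rnorm(n, sd = 0.25)
  rate <- if (cfg$hazard_model == "step") {
    cfg$baseline_hazard * exp(cfg$beta * (L > 0))
  } else {
    cfg$baseline_hazard * exp(cfg$beta * L)
  }
  t_event <- stats::rexp(n, rate)
  if (cfg$censoring > 0) {
    cmax <- stats::uniroot(function(cm) mean(pmin(t_event / cm, 1)) - cfg$censoring,
                           lower = min(t_event) * 1e-6,
                           upper = max(t_event) * 1e6, tol = 1e-8)$root
    cens <- stats::runif(n, 0, cmax)
  } else {
    cens <- rep(Inf, n)
  }
  time <- pmax(pmin(t_event, cens), 1e-3)
  event <- as.numeric(t_event <= cens)
  clinical <- data.frame(sample_id = ids, time = time, event = event,
                         age = round(stats::rnorm(n, 62, 10)),
                         stringsAsFactors = FALSE)

  tmb_counts <- stats::rpois(n, exp(cfg$tmb_intercept + cfg$tmb_slope * L))
  silent_counts <- stats::rpois(n, 0.15 * exp(cfg$tmb_intercept))
  vocab <- setdiff(maf_vocabulary(), "Silent")
  mut_genes <- c(regs, sigs)
  rec <- function(counts, classes) {
    tot <- sum(counts)
    if (tot == 0L) return(NULL)
    data.frame(sample_id = rep(ids, counts),
               gene = sample(mut_genes, tot, replace = TRUE),
               class = sample(classes, tot, replace = TRUE,
                              prob = if (length(classes) > 1)
                                c(0.6, rep(0.4 / (length(classes) - 1),
                                           length(classes) - 1)) else 1),
               stringsAsFactors = FALSE)
  }
  mutations <- rbind(rec(tmb_counts, vocab), rec(silent_counts, "Silent"))
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            class = character(0), stringsAsFactors = FALSE)
  }

  cnv <- expand.grid(sample_id = ids, gene = regs, stringsAsFactors = FALSE)
  gene_bias <- stats::setNames(stats::runif(length(regs), -0.1, 0.1), regs)
  pr <- 0.12 + gene_bias[cnv$gene]
  u <- stats::runif(nrow(cnv))
  cnv$state <- ifelse(u < pr, sample(c(1L, 2L), nrow(cnv), replace = TRUE),
                      ifelse(u < 0.24, sample(c(-1L, -2L), nrow(cnv),
                                              replace = TRUE), 0L))
  cnv <- cnv[, c("sample_id", "gene", "state")]

  truth <- list(pattern = stats::setNames(pattern, ids),
                L = stats::setNames(L, ids),
                roles = stats::setNames(
                  rep(c("regulator", "signature", "noise"),
                      c(length(regs), length(sigs), length(nse))), genes),
                directions = dir,
                pattern_scores = c_k,
                true_cutpoint = if (cfg$hazard_model == "step") 0 else NA_real_)
  list(expression = expression_matrix(x, scale = "log2", cohort = cohort),
       clinical = clinical,
       mutations = mutations,
       cnv = cnv,
       sets = gene_sets(list(regulator_panel = regs)),
       truth = truth,
       config = cfg)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length (any label types).
#' @return ARI in `[-1, 1]`; 1 = identical partitions, ~0 = chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Recovery metrics against generator truth
#'
#' @param truth The `truth` element of [simulate_study()] output.
#' @param assignments Optional named cluster assignment (sample -> label).
#' @param ps Optional named pyroptosis scores.
#' @param deg_set Optional `overlap_deg_set` to score against the true
#'   signature genes.
#' @return List with any of `ari`, `spearman_L_ps`, `de_recall`,
#'   `de_false_inclusion`.
#' @export
truth_metrics <- function(truth, assignments = NULL, ps = NULL,
                          deg_set = NULL) {
  out <- list()
  if (!is.null(assignments)) {
    ids <- names(truth$pattern)
    if (!all(ids %in% names(assignments))) stop("misaligned sample ids")
    out$ari <- adjusted_rand_index(truth$pattern, assignments[ids])
  }
  if (!is.null(ps)) {
    ids <- intersect(names(truth$L), names(ps))
    if (length(ids) < 3L) stop("misaligned sample ids")
    out$spearman_L_ps <- spearman_assoc(truth$L[ids], ps[ids])$rho
  }
  if (!is.null(deg_set)) {
    true_sig <- names(truth$roles)[truth$roles == "signature"]
    found <- if (inherits(deg_set, "overlap_deg_set")) deg_set$genes else deg_set
    out$de_recall <- length(intersect(found, true_sig)) / length(true_sig)
    out$de_false_inclusion <- if (length(found)) {
      mean(!(found %in% c(true_sig,
                          names(truth$roles)[truth$roles == "regulator"])))
    } else 0
  }
  out
}
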
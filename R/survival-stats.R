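#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @return A `km_fit` list: `time` (distinct event times, sorted), `surv`,
#'   `var` (Greenwood), `n_risk`, `n_event`.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), 0)
  n_event <- vapply(et, function(t) sum(times == t & events == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1)))
  gw[n_risk == n_event] <- 0
  structure(list(time = et, surv = surv, var = gw,
                 n_risk = n_risk, n_event = n_event),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param fit A `km_fit`.
#' @param t Times at which to evaluate (step function, right-continuous).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  vapply(t, function(ti) {
    idx <- sum(fit$time <= ti)
    if (idx == 0L) 1 else fit$surv[idx]
  }, 0)
}

# Per-event-time O, E and hypergeometric variance pieces for >= 2 groups.
# Returns the chi-square statistic over the first G-1 groups.
.logrank_core <- function(times, events, g) {
  levs <- levels(g)
  G <- length(levs)
  et <- sort(unique(times[events == 1]))
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    nk <- vapply(levs, function(l) sum(at_risk & g == l), 0)
    dk <- vapply(levs, function(l) sum(times == t & events == 1 & g == l), 0)
    O <- O + dk
    E <- E + d * nk / n
    if (n > 1) {
      pk <- nk / n
      V <- V + d * (n - d) / (n - 1) * (diag(pk, G) - tcrossprod(pk))
    }
  }
  list(O = O, E = E, V = V, levels = levs)
}

#' Log-rank test across two or more groups
#'
#' Observed-minus-expected event counts with hypergeometric variance summed
#' over event times; chi-square with `#groups - 1` degrees of freedom.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `chi2`, `df`, `p`, and for two groups the standardized
#'   statistic `z = (O1 - E1) / sqrt(V11)`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank requires at least two groups")
  if (sum(events == 1) == 0L) stop("no events")
  core <- .logrank_core(times, events, g)
  G <- nlevels(g)
  idx <- seq_len(G - 1)
  om <- core$O[idx] - core$E[idx]
  Vsub <- core$V[idx, idx, drop = FALSE]
  chi2 <- tryCatch(drop(t(om) %*% solve(Vsub, om)),
                   error = function(e) {
                     drop(t(om) %*% MASS_ginv(Vsub) %*% om)
                   })
  z <- if (G == 2L && core$V[1, 1] > 0) om[1] / sqrt(core$V[1, 1]) else NA_real_
  list(chi2 = chi2, df = G - 1,
       p = stats::pchisq(chi2, G - 1, lower.tail = FALSE), z = z)
}

# minimal Moore-Penrose pseudoinverse (avoids a MASS dependency)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Breslow/Efron partial likelihood machinery ----------------------------

# One-off layout of risk sets and tie groups, shared by every Newton step.
.cox_prep <- function(X, times, events) {
  ord <- order(times, decreasing = TRUE)      # risk set = prefix of ord
  ev_times <- sort(unique(times[events == 1]))
  t_ord <- times[ord]
  at <- vapply(ev_times, function(t) sum(t_ord >= t), 0L)
  ev_ids <- lapply(ev_times, function(t) which(times == t & events == 1))
  d <- lengths(ev_ids)
  p <- ncol(X)
  xs <- vapply(ev_ids, function(ids)
    colSums(X[ids, , drop = FALSE]), numeric(p))
  xsum <- if (p == 1L) matrix(xs, ncol = 1L) else t(xs)
  list(ord = ord, at = at, ev_ids = ev_ids, d = d, xsum = xsum,
       ev_all = unlist(ev_ids))
}

# loglik, gradient and observed information at beta
.cox_derivs <- function(beta, X, prep, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # guard overflow; cancels in ratios
  w <- exp(eta)
  ord <- prep$ord
  Xo <- X[ord, , drop = FALSE]
  wo <- w[ord]
  S0 <- cumsum(wo)
  S1 <- apply(Xo * wo, 2, cumsum)
  S1 <- matrix(S1, ncol = p)
  # S2 flattened: cumulative sums of x_a x_b w over the p*p pairs
  Xpairs <- Xo[, rep(seq_len(p), times = p), drop = FALSE] *
    Xo[, rep(seq_len(p), each = p), drop = FALSE]
  S2 <- apply(Xpairs * wo, 2, cumsum)
  S2 <- matrix(S2, ncol = p * p)

  if (ties == "breslow" || all(prep$d == 1L)) {
    at <- prep$at; d <- prep$d
    s0 <- S0[at]
    s1 <- S1[at, , drop = FALSE]
    s2 <- S2[at, , drop = FALSE]
    ll <- sum(eta[prep$ev_all]) - sum(d * log(s0))
    ratio <- s1 / s0
    grad <- colSums(prep$xsum - d * ratio)
    rpairs <- ratio[, rep(seq_len(p), times = p), drop = FALSE] *
      ratio[, rep(seq_len(p), each = p), drop = FALSE]
    info <- matrix(colSums(d * (s2 / s0 - rpairs)), p, p)
    return(list(loglik = ll, gradient = grad, information = info))
  }

  # Efron tie handling: loop over event times, averaging out tied subjects
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  for (i in seq_along(prep$at)) {
    ids <- prep$ev_ids[[i]]
    d <- prep$d[i]
    s0 <- S0[prep$at[i]]; s1 <- S1[prep$at[i], ]
    s2 <- matrix(S2[prep$at[i], ], p, p)
    wd <- w[ids]
    s0d <- sum(wd)
    s1d <- colSums(X[ids, , drop = FALSE] * wd)
    s2d <- crossprod(X[ids, , drop = FALSE] * sqrt(wd))
    ll <- ll + sum(eta[ids])
    for (j in seq_len(d)) {
      f <- (j - 1) / d
      s0j <- s0 - f * s0d
      s1j <- s1 - f * s1d
      s2j <- s2 - f * s2d
      ll <- ll - log(s0j)
      grad <- grad + prep$xsum[i, ] / d - s1j / s0j
      info <- info + s2j / s0j - tcrossprod(s1j / s0j)
    }
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Cox proportional hazards by Newton-Raphson
#'
#' Maximizes the Breslow (default) or Efron partial likelihood by
#' Newton-Raphson with step-halving; the log partial likelihood is
#' guaranteed non-decreasing across accepted iterations and its trace is
#' returned. Wald standard errors come from the inverse observed
#' information at the optimum.
#'
#' @param x Covariate vector or matrix (samples in rows; no constant
#'   column).
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol Convergence tolerance on the coefficient update (default
#'   1e-9).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return A `cox_fit` list: `beta`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p` (Wald), `loglik`, `loglik_trace`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(x, times, events, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 50) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(times), length(times) == length(events),
            all(times > 0), all(events %in% c(0, 1)))
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  if (sum(events) < p + 1) stop("fewer events than covariates + 1")
  prep <- .cox_prep(X, times, events)
  beta <- numeric(p)
  dv <- .cox_derivs(beta, X, prep, ties)
  trace <- dv$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(dv$information, dv$gradient),
                     error = function(e) stop("singular information matrix"))
    # step-halving to guarantee monotone log partial likelihood
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      dv_new <- .cox_derivs(beta_new, X, prep, ties)
      if (dv_new$loglik >= dv$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) stop("step-halving failed to improve the likelihood")
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    dv <- dv_new
    trace <- c(trace, dv$loglik)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("Cox fit did not converge in ", max_iter, " iterations")
  if (max(abs(beta * sds)) > 50) {
    stop("monotone likelihood (perfect separation) suspected for covariate: ",
         colnames(X)[which.max(abs(beta * sds))])
  }
  se <- sqrt(diag(solve(dv$information)))
  zcrit <- stats::qnorm(0.975)
  structure(list(beta = stats::setNames(drop(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = exp(drop(beta)),
                 ci_lower = exp(drop(beta) - zcrit * se),
                 ci_upper = exp(drop(beta) + zcrit * se),
                 p = 2 * stats::pnorm(-abs(drop(beta) / se)),
                 loglik = dv$loglik, loglik_trace = trace,
                 converged = converged, ties = ties,
                 n = nrow(X), n_events = sum(events)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties, %d samples, %d events)\n",
              x$ties, x$n, x$n_events))
  print(data.frame(beta = x$beta, se = x$se, HR = x$hr,
                   ci95 = sprintf("[%.3f, %.3f]", x$ci_lower, x$ci_upper),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Cases are subjects with an event by the horizon `t`, controls those
#' still event-free past `t`; both are weighted by the inverse probability
#' of remaining uncensored (Kaplan-Meier of the censoring distribution).
#' Marker ties count 0.5.
#'
#' @param marker Numeric risk marker (higher = more case-like).
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @param horizon The evaluation time t.
#' @return AUC in `[0, 1]`.
#' @export
td_roc_auc <- function(marker, times, events, horizon) {
  stopifnot(length(marker) == length(times), length(times) == length(events))
  cases <- which(times <= horizon & events == 1)
  controls <- which(times > horizon)
  if (length(cases) == 0L) stop("no events by the horizon")
  if (length(controls) == 0L) stop("no subjects event-free past the horizon")
  cens_km <- km_fit(times, 1 - events)
  g_at <- function(t) {
    # left limit G(t-): censoring survival just before t
    idx <- sum(cens_km$time < t)
    if (idx == 0L) 1 else cens_km$surv[idx]
  }
  w_case <- 1 / vapply(times[cases], g_at, 0)
  w_ctrl <- rep(1 / max(g_at(horizon + .Machine$double.eps), 1e-12),
                length(controls))
  mc <- marker[cases]; mk <- marker[controls]
  num <- 0
  for (i in seq_along(mc)) {
    num <- num + w_case[i] * sum(w_ctrl * ((mc[i] > mk) + 0.5 * (mc[i] == mk)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Two-or-more-group location comparison
#'
#' Two groups: Wilcoxon rank-sum (exact when combined n <= 20 and no ties,
#' else normal approximation with tie correction) or Welch t. More than
#' two: Kruskal-Wallis (tie-corrected) or one-way ANOVA. `"auto"` selects
#' the nonparametric test.
#'
#' @param values Numeric vector.
#' @param labels Group labels (each group non-empty).
#' @param test `"auto"`, `"nonparametric"` or `"parametric"`.
#' @return List with `statistic`, `p`, `method`.
#' @export
compare_groups <- function(values, labels,
                           test = c("auto", "nonparametric", "parametric")) {
  test <- match.arg(test)
  g <- factor(labels)
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    stop("need at least two non-empty groups")
  }
  nonpar <- test != "parametric"
  if (nlevels(g) == 2L) {
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    if (nonpar) {
      exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(values)
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = FALSE))
      list(statistic = unname(wt$statistic), p = wt$p.value,
           method = if (exact) "wilcoxon_exact" else "wilcoxon_normal")
    } else {
      tt <- stats::t.test(a, b)
      list(statistic = unname(tt$statistic), p = tt$p.value, method = "welch_t")
    }
  } else {
    if (nonpar) {
      kw <- stats::kruskal.test(values, g)
      list(statistic = unname(kw$statistic), p = kw$p.value,
           method = "kruskal_wallis")
    } else {
      av <- stats::oneway.test(values ~ g, var.equal = TRUE)
      list(statistic = unname(av$statistic), p = av$p.value, method = "anova")
    }
  }
}

#' Spearman rank correlation with permutation or t-approximation p-value
#'
#' Pearson correlation of average ranks; exact permutation p for n <= 8,
#' else the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance")
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact_permutation")
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), method = "t_approx")
  }
}

# all permutations of 1..n as rows (n <= 8 -> at most 40320)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}
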
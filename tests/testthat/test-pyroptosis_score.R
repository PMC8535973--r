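test_that("screen_prognostic keeps all non-constant genes at alpha = 1", {
  sim <- simulate_study(sim_config(seed = 41, n_per_pattern = 40,
                                   n_signature_genes = 10, n_noise_genes = 10))
  e <- sim$expression
  genes <- gene_ids(e)[1:20]
  out <- screen_prognostic(e, sim$clinical, genes, alpha = 1)
  expect_setequal(out, genes)

  v <- e$values
  v["REG01", ] <- 5
  e2 <- make_expr(v, cohort = e$cohort)
  expect_warning(out2 <- screen_prognostic(e2, sim$clinical, genes, alpha = 1),
                 "constant")
  expect_false("REG01" %in% out2)
})

test_that("screen_prognostic has calibrated type-I inclusion and high power", {
  set.seed(42)
  inc_null <- logical(200)
  for (i in seq_len(200)) {
    x <- rnorm(300)
    s <- rand_surv(300, rate = 0.01, cens_frac = 0.2)   # survival indep of x
    m <- make_expr(matrix(x, 1, 300,
                          dimnames = list("g1", sprintf("p%03d", 1:300))))
    cl <- data.frame(sample_id = sample_ids(m), time = s$time, event = s$event)
    got <- tryCatch(screen_prognostic(m, cl, "g1", alpha = 0.05),
                    error = function(e) character(0))
    inc_null[i] <- length(got) == 1L
  }
  expect_gte(mean(inc_null), 0.02)
  expect_lte(mean(inc_null), 0.08)

  inc_alt <- logical(50)
  for (i in seq_len(50)) {
    s <- rand_surv(300, rate = 0.005, cens_frac = 0.2, beta = 0.8)
    m <- make_expr(matrix(s$x, 1, 300,
                          dimnames = list("g1", sprintf("p%03d", 1:300))))
    cl <- data.frame(sample_id = sample_ids(m), time = s$time, event = s$event)
    got <- tryCatch(screen_prognostic(m, cl, "g1", alpha = 0.05),
                    error = function(e) character(0))
    inc_alt[i] <- length(got) == 1L
  }
  expect_gte(mean(inc_alt), 0.95)
})

test_that("fit_ps_model matches an independent covariance eigendecomposition", {
  set.seed(43)
  m <- rand_expr(5, 20, seed = 43)
  mod <- fit_ps_model(m)
  cv <- cov(t(m$values))
  ei <- eigen(cv, symmetric = TRUE)
  for (comp in 1:2) {
    v <- ei$vectors[, comp]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(if (comp == 1) mod$w1 else mod$w2), v,
                 tolerance = 1e-8)
  }
  expect_equal(sum(mod$w1^2), 1)
  expect_lt(abs(sum(mod$w1 * mod$w2)), 1e-10)
  expect_equal(mod$var_explained, ei$values[1:2] / sum(ei$values),
               tolerance = 1e-8)
})

test_that("fit_ps_model is invariant to sample duplication and checks rank", {
  m <- rand_expr(4, 10, seed = 44)
  v2 <- cbind(m$values, m$values)
  colnames(v2) <- sprintf("s%03d", 1:20)
  m2 <- make_expr(v2)
  mod <- fit_ps_model(m); mod2 <- fit_ps_model(m2)
  expect_equal(mod$w1, mod2$w1, tolerance = 1e-8)
  expect_equal(mod$w2, mod2$w2, tolerance = 1e-8)

  # rank-1 data: only one direction of variation
  base <- rnorm(6)
  v <- outer(c(1, 2), base) + 5
  dimnames(v) <- list(c("g1", "g2"), sprintf("s%d", 1:6))
  expect_error(fit_ps_model(expression_matrix(v, "log2")), "rank")
  expect_error(fit_ps_model(rand_expr(1, 5)), "2 genes")
})

test_that("compute_ps centers training data and is translation/order equivariant", {
  m <- rand_expr(6, 15, seed = 45)
  mod <- fit_ps_model(m)
  ps <- compute_ps(mod, m)
  expect_equal(mean(ps), 0, tolerance = 1e-10)

  # gene row order invariance (exact)
  m_shuf <- subset_expr(m, genes = rev(gene_ids(m)))
  expect_identical(compute_ps(mod, m_shuf), ps)

  # adding a constant to one gene shifts every score equally
  v <- m$values; v[2, ] <- v[2, ] + 3
  ps2 <- compute_ps(mod, make_expr(v))
  shift <- ps2 - ps
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-10)

  expect_error(compute_ps(mod, rand_expr(3, 4, seed = 46)), "absent")
})

test_that("compute_ps equals the closed-form 2x2 eigenproblem on a toy", {
  v <- rbind(g1 = c(0, 2, 0, 3), g2 = c(0, 0, 2, 4))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v, "log2")
  mod <- fit_ps_model(m)
  # hand eigenvectors of the 2x2 covariance via the rotation angle
  cv <- cov(t(v))
  theta <- 0.5 * atan2(2 * cv[1, 2], cv[1, 1] - cv[2, 2])
  w1 <- c(cos(theta), sin(theta))
  w2 <- c(-sin(theta), cos(theta))
  if (w1[which.max(abs(w1))] < 0) w1 <- -w1
  if (w2[which.max(abs(w2))] < 0) w2 <- -w2
  expect_equal(unname(mod$w1), w1, tolerance = 1e-10)
  expect_equal(unname(mod$w2), w2, tolerance = 1e-10)
  ps <- compute_ps(mod, m)
  centered <- v - rowMeans(v)
  expect_equal(ps, drop(crossprod(centered, w1 + w2)), tolerance = 1e-10)
})

test_that("find_cutpoint locates the event boundary on a 1..10 grid", {
  ps <- setNames(as.numeric(1:10), paste0("s", 1:10))
  cl <- data.frame(sample_id = names(ps),
                   time = c(5, 6, 7, 100, 100, 100, 100, 100, 100, 100),
                   event = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  res <- find_cutpoint(ps, cl, minprop = 0.1)
  expect_gt(res$cutpoint, 3)
  expect_lt(res$cutpoint, 4)
  expect_equal(unname(res$group[paste0("s", 1:3)] == "low"), rep(TRUE, 3))

  # minprop = 0.5 admits only the median split
  res2 <- find_cutpoint(ps, cl, minprop = 0.5)
  expect_equal(res2$cutpoint, 5.5)
})

test_that("find_cutpoint agrees with an exhaustive survdiff scan", {
  skip_if_not_installed("survival")
  set.seed(47)
  for (rep in 1:3) {
    n <- 40
    ps <- setNames(rnorm(n), sprintf("p%02d", 1:n))
    s <- rand_surv(n, rate = 0.02, cens_frac = 0.25, beta = 0.5, x = ps)
    cl <- data.frame(sample_id = names(ps), time = s$time, event = s$event)
    res <- find_cutpoint(ps, cl, minprop = 0.1)
    su <- sort(unique(ps))
    cand <- (su[-1] + su[-length(su)]) / 2
    best <- -Inf; best_cut <- NA
    for (cc in cand) {
      hi <- ps > cc
      if (sum(hi) < 0.1 * n || sum(!hi) < 0.1 * n) next
      z <- sqrt(survival::survdiff(survival::Surv(cl$time, cl$event) ~ hi)$chisq)
      if (z > best + 1e-12) { best <- z; best_cut <- cc }
    }
    expect_equal(res$cutpoint, best_cut)
    expect_equal(res$statistic, best, tolerance = 1e-10)
  }
})

test_that("find_cutpoint permutation p-value behaves sensibly", {
  set.seed(48)
  n <- 40
  ps <- setNames(rnorm(n), sprintf("p%02d", 1:n))
  s <- rand_surv(n, rate = 0.02, cens_frac = 0.2)  # null: ps unrelated
  cl <- data.frame(sample_id = names(ps), time = s$time, event = s$event)
  res <- find_cutpoint(ps, cl, n_perm = 100)
  expect_true(res$perm_p > 0 && res$perm_p <= 1)
  expect_true(is.na(find_cutpoint(ps, cl)$perm_p))
  cl0 <- cl; cl0$event <- 0
  expect_error(find_cutpoint(ps, cl0), "no events")
})

test_that("re-fitting on a bootstrap reproduces the score (stability)", {
  sim <- simulate_study(sim_config(seed = 49, n_per_pattern = 60,
                                   n_signature_genes = 60, n_noise_genes = 40))
  e <- correct_batch(sim$expression)
  de <- moderated_de(e, sim$truth$pattern)
  ov <- overlap_degs(de, 0.01)
  prog <- screen_prognostic(e, sim$clinical, ov)
  mod <- fit_ps_model(e, prog)
  ps <- compute_ps(mod, e)
  set.seed(50)
  boot_ids <- sample(sample_ids(e), replace = TRUE)
  v <- e$values[, boot_ids]
  colnames(v) <- sprintf("b%03d", seq_along(boot_ids))
  mod_b <- fit_ps_model(make_expr(v), prog)
  ps_b <- compute_ps(mod_b, e)
  expect_gte(abs(cor(ps, ps_b)), 0.95)
})
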
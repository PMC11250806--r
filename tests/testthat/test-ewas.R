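# Step-by-step oracle for the empirical-Bayes moderation closed forms,
# written independently of the package internals.
moderate_oracle <- function(Y, X, j_status = 2) {
  n <- nrow(X)
  d <- n - ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  R <- Y - X %*% B
  s2 <- colSums(R^2) / d
  u <- sqrt(XtXi[j_status, j_status])
  G <- length(s2)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  rhs <- mean((e - mean(e))^2 * G / (G - 1)) - trigamma(d / 2)
  if (rhs > 0) {
    # invert trigamma by plain uniroot
    f <- function(x) trigamma(x) - rhs
    d0 <- 2 * stats::uniroot(f, c(1e-8, 1e8), tol = 1e-12)$root
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(log(s2)))   # degenerate: shrink to the geometric mean
  }
  s2_post <- if (is.infinite(d0)) rep(s02, G) else
    (d0 * s02 + d * s2) / (d0 + d)
  t <- B[j_status, ] / (u * sqrt(s2_post))
  list(d0 = d0, s02 = s02, t = t, df = d0 + d,
       p = 2 * pt(-abs(t), d0 + d), se = u * sqrt(s2_post))
}

test_that("probewise OLS reproduces closed-form two-group differences", {
  ds <- toy_dataset(n = 24, p = 30, effect = 1.2, seed = 14)
  X <- cbind(`(Intercept)` = 1,
             status = as.integer(ds$samples$status == "case"))
  fit <- fit_probewise_models(ds, X)
  case <- ds$samples$status == "case"
  expect_equal(fit$coef,
               colMeans(ds$values[case, ]) - colMeans(ds$values[!case, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$df, 22)
  # duplicating a sample row leaves the estimate, raises df by 1
  v2 <- rbind(ds$values, ds$values[1, ])
  X2 <- rbind(X, X[1, ])
  fit2 <- fit_probewise_models(v2, X2)
  expect_equal(fit2$df, fit$df + 1)
  expect_equal(unname(fit2$coef[5]),
               unname(lm(v2[, 5] ~ X2[, 2])$coefficients[2]),
               tolerance = 1e-10)
})

test_that("probewise fits recover a planted effect with covariates", {
  cfg <- small_config(n_batches = 1, samples_per_batch = 300,
                      case_fraction_per_batch = 0.5, n_probes = 500,
                      n_signal_probes = 50, effect_size_m = 1,
                      noise_sd = 0.7, seed = 17)
  pan <- generate_reference_panel(500, 6, seed = cfg$seed)
  out <- generate_batch(cfg, 1, pan)
  X <- build_design(out$dataset$samples)
  fit <- fit_probewise_models(out$dataset, X)
  sig <- match(out$truth$signal_probe_ids, fit$probe_id)
  est <- mean(fit$coef[sig])
  se <- sd(fit$coef[sig]) / sqrt(length(sig))
  expect_lt(abs(est - 1), 3 * se)
  # rank deficiency is reported with the aliased column
  Xbad <- cbind(X, dup = X[, "status"])
  expect_error(fit_probewise_models(out$dataset, Xbad), "aliased")
})

test_that("moderation matches the independent closed-form oracle to 1e-8", {
  set.seed(19)
  n <- 20
  p <- 50
  Y <- matrix(rnorm(n * p, sd = rep(runif(p, 0.5, 2), each = n)), n, p,
              dimnames = list(NULL, sprintf("cg%03d", 1:p)))
  X <- cbind(`(Intercept)` = 1, status = rep(0:1, each = n / 2))
  tab <- moderate(fit_probewise_models(Y, X))
  ora <- moderate_oracle(Y, X)
  expect_lt(max(abs(tab$t - ora$t)), 1e-8)
  expect_lt(max(abs(tab$P.Value - ora$p)), 1e-8)
  expect_lt(max(abs(tab$SE - ora$se)), 1e-8)
  expect_equal(attr(tab, "d0"), ora$d0, tolerance = 1e-6)
  expect_equal(attr(tab, "s02"), ora$s02, tolerance = 1e-8)
})

test_that("moderation agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(23)
  n <- 16
  p <- 120
  Y <- matrix(rnorm(n * p, sd = rep(runif(p, 0.3, 3), each = n)), n, p,
              dimnames = list(NULL, sprintf("cg%03d", 1:p)))
  X <- cbind(`(Intercept)` = 1, status = rep(0:1, n / 2))
  tab <- moderate(fit_probewise_models(Y, X))
  ref <- limma::eBayes(limma::lmFit(t(Y), X))
  expect_equal(tab$t, unname(ref$t[, "status"]), tolerance = 1e-6)
  expect_equal(tab$P.Value, unname(ref$p.value[, "status"]),
               tolerance = 1e-6)
  expect_equal(attr(tab, "d0"), ref$df.prior, tolerance = 1e-4)
})

test_that("moderated t reduces to ordinary t with equal variances and shrinks otherwise", {
  set.seed(29)
  n <- 12
  X <- cbind(1, status = rep(0:1, each = 6))
  # identical residual variance across probes: s_post = s exactly
  base <- rnorm(n)
  base <- qr.resid(qr(X), base)
  Y <- sapply(1:30, function(j) base + X[, 2] * j * 0.1)
  colnames(Y) <- sprintf("cg%02d", 1:30)
  fit <- fit_probewise_models(Y, X)
  tab <- moderate(fit)
  t_ord <- fit$coef / (fit$u * fit$s)
  expect_equal(tab$t, unname(t_ord), tolerance = 1e-10)
  # heterogeneous variances: shrinkage direction follows s^2 vs s0^2
  Y2 <- matrix(rnorm(n * 40, sd = rep(c(0.2, 3), each = n * 20)), n, 40,
               dimnames = list(NULL, sprintf("cg%02d", 1:40)))
  fit2 <- fit_probewise_models(Y2, X)
  tab2 <- moderate(fit2)
  s02 <- attr(tab2, "s02")
  t_ord2 <- fit2$coef / (fit2$u * fit2$s)
  hi <- fit2$s^2 > s02
  expect_true(all(abs(tab2$t[hi]) >= abs(t_ord2[hi]) - 1e-12))
  expect_true(all(abs(tab2$t[!hi]) <= abs(t_ord2[!hi]) + 1e-12))
})

test_that("BH adjustment matches hand computation and an exhaustive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- sort(runif(10))
  expect_true(all(diff(bh_fdr(p)) >= 0))
  # exhaustive step-up oracle on all vectors of length <= 8
  oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, 0), 1)
    q
  }
  set.seed(31)
  for (len in c(1, 2, 3, 5, 8)) {
    pv <- runif(len)
    expect_equal(bh_fdr(pv), oracle(pv), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("directional agreement counts matching signs, zeros disagree", {
  D <- rbind(rep(1, 8),                 # all positive
             c(rep(1, 4), rep(-1, 4)),  # half match
             c(rep(1, 7), 0))           # zero counts as disagreement
  expect_equal(directional_agreement(D, c(1, 1, 1)), c(1, 0.5, 7 / 8))
  expect_equal(directional_agreement(D, c(-1, -1, -1)), c(0, 0.5, 0))
})

test_that("agreement reaches 1 for well-powered consistent effects", {
  cfg <- small_config(n_batches = 8, samples_per_batch = rep(100, 8),
                      case_fraction_per_batch = rep(0.5, 8), n_probes = 300,
                      n_signal_probes = 30, effect_size_m = 1,
                      noise_sd = 0.5, seed = 37)
  st <- generate_study(cfg)
  m <- merge_batches(st$batches)
  tab <- run_ewas(m, include_study_factor = TRUE)
  sig <- tab$agreement[match(st$truth$signal_probe_ids, tab$probe_id)]
  expect_gte(mean(sig == 1), 0.95)
})

test_that("run_ewas is calibrated under the null and powered under signal", {
  cfg <- small_config(n_batches = 1, samples_per_batch = 200,
                      case_fraction_per_batch = 0.5, n_probes = 5000,
                      n_signal_probes = 0, effect_size_m = 0,
                      batch_mean_shift_sd = 0, noise_sd = 1, seed = 43)
  pan <- generate_reference_panel(5000, 6, seed = cfg$seed)
  null_ds <- generate_batch(cfg, 1, pan)$dataset
  tab <- run_ewas(null_ds)
  expect_gt(mean(tab$P.Value < 0.05), 0.04)
  expect_lt(mean(tab$P.Value < 0.05), 0.06)
  # power: planted effects at 100/5000 probes, n = 800 pooled
  cfg2 <- small_config(n_batches = 4, samples_per_batch = rep(200, 4),
                       case_fraction_per_batch = rep(0.5, 4),
                       n_probes = 5000, n_signal_probes = 100,
                       effect_size_m = 0.5, noise_sd = 1, seed = 47)
  st <- generate_study(cfg2)
  m <- merge_batches(st$batches)
  tab2 <- run_ewas(m, include_study_factor = TRUE)
  sig <- match(st$truth$signal_probe_ids, tab2$probe_id)
  expect_gte(sum(tab2$P.Value[sig] < 0.05), 80)
  # pooled vs per-cohort designs differ only by the study-factor columns
  expect_equal(setdiff(colnames(build_design(m$samples, TRUE)),
                       colnames(build_design(m$samples, FALSE))),
               paste0("batch_", sort(unique(m$samples$batch))[-1]))
})
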
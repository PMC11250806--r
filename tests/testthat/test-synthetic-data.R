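test_that("reference panels are valid, deterministic, and discriminating", {
  p <- generate_reference_panel(100, 2, seed = 1)
  expect_equal(dim(p$reference_beta), c(2, 100))
  expect_true(all(p$reference_beta >= 0 & p$reference_beta <= 1))
  expect_identical(p, generate_reference_panel(100, 2, seed = 1))
  # brute-force spread scan on the documented discriminating subset
  p6 <- generate_reference_panel(100, 6, seed = 1)
  expect_gte(length(p6$discriminating), 100)
  spread <- apply(p6$reference_beta[, p6$discriminating, drop = FALSE], 2,
                  function(v) max(v) - min(v))
  expect_true(all(spread >= 0.3))
  expect_error(generate_reference_panel(0, 2), "positive")
  expect_error(generate_reference_panel(10, 1), "n_celltypes")
})

test_that("generate_batch plants the configured case effect", {
  cfg <- small_config(n_batches = 1, samples_per_batch = 200,
                      case_fraction_per_batch = 0.5, n_probes = 500,
                      n_signal_probes = 50, effect_size_m = 1,
                      batch_mean_shift_sd = 0, noise_sd = 0.1)
  panel <- generate_reference_panel(500, 6, seed = cfg$seed)
  out <- generate_batch(cfg, 1, panel)
  ds <- out$dataset
  sig <- out$truth$signal_probe_ids
  case <- ds$samples$status == "case"
  diffs <- colMeans(ds$values[case, sig]) - colMeans(ds$values[!case, sig])
  expect_lt(abs(mean(diffs) - 1), 0.1)   # sample-mean oracle
  expect_equal(sum(case), 100)
  # metadata is complete
  expect_true(all(ds$samples$sex %in% c("F", "M")))
  expect_true(all(ds$samples$age >= cfg$age_range[1] &
                    ds$samples$age <= cfg$age_range[2]))
})

test_that("case counts use documented half-up rounding", {
  cfg <- small_config(n_batches = 1, samples_per_batch = 100,
                      case_fraction_per_batch = 0.8, n_probes = 120,
                      n_signal_probes = 5)
  panel <- generate_reference_panel(120, 6, seed = cfg$seed)
  ds <- generate_batch(cfg, 1, panel)$dataset
  expect_equal(sum(ds$samples$status == "case"), 80)
  # 0.5 boundary rounds up (floor(x + .5)), not to even
  cfg2 <- small_config(n_batches = 1, samples_per_batch = 10,
                       case_fraction_per_batch = 0.25, n_probes = 120,
                       n_signal_probes = 5)
  ds2 <- generate_batch(cfg2, 1, panel)$dataset
  expect_equal(sum(ds2$samples$status == "case"), 3)  # 2.5 -> 3
})

test_that("null simulation yields uniform per-probe t-test p-values", {
  cfg <- small_config(n_batches = 1, samples_per_batch = 100,
                      case_fraction_per_batch = 0.5, n_probes = 2000,
                      n_signal_probes = 0, effect_size_m = 0,
                      batch_mean_shift_sd = 0, noise_sd = 1, seed = 5)
  panel <- generate_reference_panel(2000, 6, seed = cfg$seed)
  ds <- generate_batch(cfg, 1, panel)$dataset
  case <- ds$samples$status == "case"
  pvals <- vapply(seq_len(ncol(ds$values)), function(j)
    stats::t.test(ds$values[case, j], ds$values[!case, j])$p.value, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("generate_study is deterministic and shares structure", {
  cfg <- small_config()
  st <- generate_study(cfg)
  expect_length(st$batches, 3)
  st2 <- generate_study(cfg)
  expect_identical(st$batches, st2$batches)
  expect_identical(st$truth$signal_probe_ids, st2$truth$signal_probe_ids)
  # shared probe universe, globally unique sample ids
  ids <- unlist(lapply(st$batches, function(d) d$samples$sample_id))
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(vapply(st$batches, function(d)
    identical(d$probes$probe_id, st$batches[[1]]$probes$probe_id), TRUE)))
  # default configuration mirrors the eight-cohort design
  expect_equal(sim_config()$n_batches, 8)
  expect_length(generate_study(small_config(
    n_batches = 8, samples_per_batch = rep(20, 8),
    case_fraction_per_batch = rep(0.5, 8), n_probes = 50,
    n_signal_probes = 2))$batches, 8)
})

test_that("planted effects are recoverable by OLS within 3 SE at n = 400", {
  cfg <- small_config(n_batches = 2, samples_per_batch = c(200, 200),
                      case_fraction_per_batch = c(0.5, 0.5), n_probes = 400,
                      n_signal_probes = 40, effect_size_m = 0.8,
                      noise_sd = 0.8, seed = 11)
  st <- generate_study(cfg)
  m <- merge_batches(st$batches)
  X <- build_design(m$samples, include_study_factor = TRUE)
  fit <- fit_probewise_models(m, X)
  sig <- match(st$truth$signal_probe_ids, fit$probe_id)
  est <- mean(fit$coef[sig])
  se <- sd(fit$coef[sig]) / sqrt(length(sig))
  expect_lt(abs(est - 0.8), 3 * se + 1e-9)
})

test_that("simulated M-values convert back to valid beta-values", {
  st <- generate_study(small_config())
  for (d in st$batches) {
    b <- m_to_beta(d$values)
    expect_true(all(b > 0 & b < 1))
  }
})

test_that("zero batch-shift SD gives equal batch means in expectation", {
  cfg <- small_config(batch_mean_shift_sd = 0, batch_confound = 0,
                      effect_size_m = 0, n_signal_probes = 0,
                      samples_per_batch = c(150, 150, 150),
                      case_fraction_per_batch = c(0.5, 0.5, 0.5),
                      batch_var_scale_range = c(1, 1), seed = 9)
  st <- generate_study(cfg)
  expect_true(all(st$truth$batch_shifts$mean_shift == 0))
  means <- vapply(st$batches, function(d) mean(d$values), 0)
  expect_lt(diff(range(means)), 0.05)
})

test_that("ground truth serializes to JSON", {
  st <- generate_study(small_config(n_probes = 60, n_signal_probes = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(st$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$signal_probe_ids), st$truth$signal_probe_ids)
})
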
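test_that("CV splits partition samples, stratify, and reproduce from seed", {
  ds <- toy_dataset(n = 300, p = 10, seed = 73)
  pro <- eval_protocol(n_repeats = 10, n_folds = 3, seed = 5)
  splits <- make_cv_splits(ds, pro)
  expect_length(splits, 30)
  for (r in 1:10) {
    reps <- Filter(function(s) attr(s, "repeat") == r, splits)
    vals <- lapply(reps, `[[`, "validation")
    expect_equal(sort(lengths(vals)), c(100, 100, 100))
    expect_setequal(unlist(vals), ds$samples$sample_id)
  }
  # train/validation disjoint and jointly exhaustive per split
  for (s in splits[1:6]) {
    expect_length(intersect(s$train, s$validation), 0)
    expect_setequal(c(s$train, s$validation), ds$samples$sample_id)
  }
  # stratification keeps both classes in every fold
  cls <- setNames(ds$samples$status, ds$samples$sample_id)
  for (s in splits)
    expect_length(unique(cls[s$validation]), 2)
  expect_identical(splits, make_cv_splits(ds, pro))
  expect_false(identical(splits,
                         make_cv_splits(ds, eval_protocol(10, 3, seed = 6))))
})

test_that("roc_auc equals the brute-force pairwise concordance oracle", {
  auc_oracle <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(1:10, rep(c(0, 1), each = 5)), 1)
  expect_equal(roc_auc(1:10, rep(c(1, 0), each = 5)), 0)
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(runif(n), sample(c(1, 3), 1)))  # induces ties
    expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("unbiased evaluation keeps fold bookkeeping and provenance clean", {
  ds <- toy_dataset(n = 90, p = 60, effect = 2.5, seed = 79, n_signal = 8)
  pro <- eval_protocol(n_repeats = 2, n_folds = 3, seed = 3)
  res <- evaluate_unbiased(ds, model_spec("logreg_l2", seed = 1),
                           list(strategy = "dm_top", k = 10), pro)
  expect_equal(nrow(res$per_fold), 6)
  expect_named(res$per_fold,
               c("repeat", "fold", "auc", "accuracy", "sensitivity",
                 "specificity"))
  expect_false(res$provenance$biased)
  expect_gt(res$aggregate["mean", "auc"], 0.9)   # planted strong signal
})

test_that("the leakage audit rejects selectors fitted on validation samples", {
  ds <- toy_dataset(n = 60, p = 30, seed = 81)
  pro <- eval_protocol(n_repeats = 1, n_folds = 3, seed = 2)
  # a compromised selector that claims provenance over all samples
  with_mocked_bindings(
    run_selector = function(train, selector)
      methbench:::selection_result("dm_top", train$probes$probe_id[1:5],
                                   1:5, ds$samples$sample_id),
    .package = "methbench",
    expect_error(
      evaluate_unbiased(ds, model_spec("logreg_l2"),
                        list(strategy = "dm_top", k = 5), pro),
      "leakage audit"))
})

test_that("biased evaluation tags whole-data panels and matches unbiased when clean", {
  ds <- toy_dataset(n = 90, p = 60, effect = 2, seed = 83, n_signal = 8)
  pro <- eval_protocol(n_repeats = 2, n_folds = 3, seed = 4)
  dm <- run_ewas(ds)
  ord <- order(dm$P.Value)[1:10]
  panel_all <- methbench:::selection_result("dm_top_whole_data",
                                            dm$probe_id[ord],
                                            dm$P.Value[ord],
                                            ds$samples$sample_id)
  res <- evaluate_biased(ds, model_spec("logreg_l2"), panel_all, pro)
  expect_true(res$provenance$biased)
  expect_equal(nrow(res$per_fold), 6)
  # a panel with empty provenance is not flagged
  panel_ext <- methbench:::selection_result("external", dm$probe_id[ord],
                                            dm$P.Value[ord], character())
  expect_false(evaluate_biased(ds, model_spec("logreg_l2"), panel_ext,
                               pro)$provenance$biased)
  expect_error(
    evaluate_biased(ds, model_spec("logreg_l2"),
                    methbench:::selection_result("x", "nope", 1, character()),
                    pro),
    "subset")
})

test_that("hold-out evaluation enforces batch disjointness", {
  cfg <- small_config(seed = 87)
  st <- generate_study(cfg)
  m <- merge_batches(st$batches)
  tr <- subset_dataset(m, samples = m$samples$batch != "batch3")
  te <- subset_dataset(m, samples = m$samples$batch == "batch3")
  res <- evaluate_holdout(tr, te, model_spec("logreg_l2"),
                          list(strategy = "dm_top", k = 20))
  expect_equal(nrow(res$per_fold), 1)
  expect_gt(res$per_fold$auc, 0.9)    # strong planted signal transfers
  expect_error(evaluate_holdout(m, te, model_spec("logreg_l2"),
                                list(strategy = "dm_top", k = 20)),
               "disjoint")
})

test_that("hold-out CV consistency under a same-distribution split", {
  cfg <- small_config(n_batches = 4, samples_per_batch = rep(80, 4),
                      case_fraction_per_batch = rep(0.5, 4),
                      batch_mean_shift_sd = 0, n_probes = 300,
                      n_signal_probes = 20, effect_size_m = 0.8,
                      noise_sd = 1, seed = 89)
  st <- generate_study(cfg)
  m <- merge_batches(st$batches)
  tr <- subset_dataset(m, samples = !m$samples$batch %in% "batch4")
  te <- subset_dataset(m, samples = m$samples$batch == "batch4")
  sel <- list(strategy = "dm_top", k = 50)
  cv <- evaluate_unbiased(tr, model_spec("logreg_l2"), sel,
                          eval_protocol(3, 3, seed = 7))
  ho <- evaluate_holdout(tr, te, model_spec("logreg_l2"), sel)
  expect_lt(abs(cv$aggregate["mean", "auc"] - ho$per_fold$auc), 0.05)
})

test_that("eval results serialize as tidy TSV", {
  ds <- toy_dataset(n = 40, p = 30, effect = 2, seed = 91)
  res <- evaluate_unbiased(ds, model_spec("decision_tree"),
                           list(strategy = "anova_f", k = 5),
                           eval_protocol(1, 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_result(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2)
  expect_equal(unique(tab$model), "decision_tree")
  expect_equal(unique(tab$selection), "anova_f")
})
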
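#' Evaluation protocol
#'
#' @param n_repeats number of cross-validation repetitions (default 10).
#' @param n_folds folds per repetition (default 3).
#' @param stratified stratify fold assignment by class (default `TRUE`).
#' @param seed integer seed for the fold draws.
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(n_repeats = 10, n_folds = 3, stratified = TRUE,
                          seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "eval_protocol")
}

#' Repeated cross-validation splits
#'
#' Produces `n_repeats * n_folds` (train, validation) sample-id pairs; within
#' each repeat the validation sets partition the samples. Stratified mode
#' assigns folds within each class so every fold sees both classes.
#'
#' @param ds a [methyl_dataset] (or a sample sheet data.frame).
#' @param protocol an [eval_protocol()].
#' @return List of `list(train, validation)` character-id pairs, with
#'   `repeat`/`fold` attributes on each element.
#' @export
make_cv_splits <- function(ds, protocol) {
  samples <- if (inherits(ds, "methyl_dataset")) ds$samples else ds
  ids <- samples$sample_id
  cls <- samples$status
  if (min(table(cls)) < 2) stop("need >= 2 samples per class")
  set.seed(protocol$seed)
  out <- list()
  for (r in seq_len(protocol$n_repeats)) {
    fold <- integer(length(ids))
    if (protocol$stratified) {
      for (lev in unique(cls)) {
        idx <- sample(which(cls == lev))
        fold[idx] <- rep(seq_len(protocol$n_folds),
                         length.out = length(idx))
      }
    } else {
      fold[sample(seq_along(ids))] <- rep(seq_len(protocol$n_folds),
                                          length.out = length(ids))
    }
    for (f in seq_len(protocol$n_folds)) {
      if (!protocol$stratified &&
          length(unique(cls[fold != f])) < 2)
        stop("a class is absent from a training fold; use stratified splits")
      el <- list(train = ids[fold != f], validation = ids[fold == f])
      attr(el, "repeat") <- r
      attr(el, "fold") <- f
      out[[length(out) + 1]] <- el
    }
  }
  out
}

#' ROC area under the curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half; computed from midranks, which equals
#' the brute-force pairwise concordance count.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1/"case" = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as01(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fold_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as01(labels)
  pred <- as.integer(scores >= threshold)
  c(auc = roc_auc(scores, y),
    accuracy = mean(pred == y),
    sensitivity = if (sum(y == 1) > 0) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (sum(y == 0) > 0) mean(pred[y == 0] == 0) else NA_real_)
}

eval_result <- function(per_fold, provenance) {
  agg <- rbind(mean = colMeans(per_fold[, c("auc", "accuracy", "sensitivity",
                                            "specificity")], na.rm = TRUE),
               sd = apply(per_fold[, c("auc", "accuracy", "sensitivity",
                                       "specificity")], 2, stats::sd,
                          na.rm = TRUE))
  structure(list(per_fold = per_fold, aggregate = agg,
                 provenance = provenance),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("eval_result [", x$provenance$preparation %||% "cv", ", ",
      x$provenance$model$family, ", ",
      x$provenance$selection %||% "fixed panel", "]: mean AUC ",
      round(x$aggregate["mean", "auc"], 3), " over ",
      nrow(x$per_fold), " folds\n", sep = "")
  invisible(x)
}

# features-on-scale helper: classifier features are raw probe values on the
# spec's scale; covariates never enter the classifier.
feature_matrix <- function(ds, probe_ids, scale) {
  ds <- convert_scale(ds, scale)
  ds$values[, probe_ids, drop = FALSE]
}

#' Cross-validated evaluation with within-fold (unbiased) feature selection
#'
#' For every CV fold: fit the selector on the training samples only, reduce
#' both partitions to the selected probes, train the classifier, score the
#' validation samples, and record AUC / accuracy / sensitivity /
#' specificity. A leakage audit asserts that the selector's `fitted_on`
#' provenance never intersects the validation samples.
#'
#' @param ds a [methyl_dataset].
#' @param spec a [model_spec()].
#' @param selector selector specification for [run_selector()].
#' @param protocol an [eval_protocol()].
#' @return An `eval_result` with one row per fold.
#' @export
evaluate_unbiased <- function(ds, spec, selector, protocol) {
  splits <- make_cv_splits(ds, protocol)
  rows <- lapply(splits, function(sp) {
    train <- subset_dataset(ds, samples = sp$train)
    sel <- run_selector(train, selector)
    if (length(intersect(sel$fitted_on, sp$validation)) > 0)
      stop("leakage audit failed: selector was fitted on validation samples")
    xt <- feature_matrix(train, sel$probe_ids, spec$scale)
    val <- subset_dataset(ds, samples = sp$validation)
    xv <- feature_matrix(val, sel$probe_ids, spec$scale)
    model <- train_classifier(spec, xt, train$samples$status)
    m <- fold_metrics(score_samples(model, xv), val$samples$status)
    c(`repeat` = attr(sp, "repeat"), fold = attr(sp, "fold"), m)
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  eval_result(per_fold,
              list(model = spec, selection = selector$strategy,
                   biased = FALSE, protocol = protocol))
}

#' Cross-validated evaluation with a fixed pre-selected panel (biased)
#'
#' Identical folds and bookkeeping to [evaluate_unbiased()], but the feature
#' panel is fixed in advance. Panels fitted on all samples (e.g.
#' [select_biased_panel()]) overlap every validation fold, which is exactly
#' the feature-selection bias this function quantifies; the result is tagged
#' `biased` accordingly.
#'
#' @param ds a [methyl_dataset].
#' @param spec a [model_spec()].
#' @param panel a `selection_result` whose probes are in `ds`.
#' @param protocol an [eval_protocol()].
#' @return An `eval_result` tagged as biased when the panel provenance
#'   overlaps validation samples.
#' @export
evaluate_biased <- function(ds, spec, panel, protocol) {
  stopifnot(inherits(panel, "selection_result"))
  if (!all(panel$probe_ids %in% ds$probes$probe_id))
    stop("panel probes must be a subset of the dataset probes")
  splits <- make_cv_splits(ds, protocol)
  biased <- FALSE
  rows <- lapply(splits, function(sp) {
    if (length(intersect(panel$fitted_on, sp$validation)) > 0)
      biased <<- TRUE
    train <- subset_dataset(ds, samples = sp$train)
    val <- subset_dataset(ds, samples = sp$validation)
    xt <- feature_matrix(train, panel$probe_ids, spec$scale)
    xv <- feature_matrix(val, panel$probe_ids, spec$scale)
    model <- train_classifier(spec, xt, train$samples$status)
    m <- fold_metrics(score_samples(model, xv), val$samples$status)
    c(`repeat` = attr(sp, "repeat"), fold = attr(sp, "fold"), m)
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  eval_result(per_fold,
              list(model = spec, selection = panel$strategy,
                   biased = biased, protocol = protocol))
}

#' Hold-out evaluation on disjoint cohort batches
#'
#' Trains on one dataset and tests on another whose batch sets must be
#' disjoint (cohort-level allocation, so batch-level preprocessing cannot
#' leak). With a selector specification, selection runs on the full training
#' set; with a fixed `selection_result` panel the features are taken as
#' given (biased when the panel saw the test cohorts).
#'
#' @param train_ds,test_ds [methyl_dataset]s with disjoint batch sets.
#' @param spec a [model_spec()].
#' @param selector_or_panel selector list (see [run_selector()]) or a
#'   `selection_result`.
#' @param n_repeats number of seeded training repeats to average over
#'   (useful for the stochastic deep families; default 1).
#' @return An `eval_result` with one row per training repeat.
#' @export
evaluate_holdout <- function(train_ds, test_ds, spec, selector_or_panel,
                             n_repeats = 1) {
  overlap <- intersect(unique(train_ds$samples$batch),
                       unique(test_ds$samples$batch))
  if (length(overlap) > 0)
    stop("train and test batch sets must be disjoint; shared: ",
         paste(overlap, collapse = ", "))
  if (inherits(selector_or_panel, "selection_result")) {
    sel <- selector_or_panel
  } else {
    sel <- run_selector(train_ds, selector_or_panel)
  }
  if (!all(sel$probe_ids %in% test_ds$probes$probe_id))
    stop("selected probes missing from the test dataset")
  xt <- feature_matrix(train_ds, sel$probe_ids, spec$scale)
  xv <- feature_matrix(test_ds, sel$probe_ids, spec$scale)
  rows <- lapply(seq_len(n_repeats), function(r) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    model <- train_classifier(sp, xt, train_ds$samples$status)
    m <- fold_metrics(score_samples(model, xv), test_ds$samples$status)
    c(`repeat` = r, fold = 1, m)
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  eval_result(per_fold,
              list(model = spec, selection = sel$strategy,
                   biased = length(intersect(sel$fitted_on,
                                             test_ds$samples$sample_id)) > 0,
                   holdout = TRUE))
}

#' Feature-selection bias gap experiment
#'
#' On a single dataset, runs [evaluate_unbiased()] (within-fold top-k DM
#' selection) and [evaluate_biased()] (top-k DM panel fitted on all samples)
#' for every model specification and reports the per-model AUC gap with a
#' sign-flip permutation p-value over the paired fold differences.
#'
#' @param ds a [methyl_dataset].
#' @param model_specs list of [model_spec()]s.
#' @param protocol an [eval_protocol()].
#' @param k panel size (default 200).
#' @param n_perm permutations for the gap p-value (default 1000).
#' @return data.frame with one row per model: unbiased and biased mean AUC,
#'   the gap, and the permutation p-value; per-cell `eval_result`s in the
#'   `"results"` attribute.
#' @export
bias_gap_experiment <- function(ds, model_specs, protocol, k = 200,
                                n_perm = 1000) {
  pooled <- run_ewas(ds, include_study_factor = FALSE)
  ord <- order(pooled$P.Value, seq_len(nrow(pooled)))[seq_len(k)]
  panel <- selection_result("dm_top_whole_data", pooled$probe_id[ord],
                            pooled$P.Value[ord], ds$samples$sample_id)
  res <- list()
  rows <- lapply(model_specs, function(spec) {
    unb <- evaluate_unbiased(ds, spec, list(strategy = "dm_top", k = k),
                             protocol)
    bia <- evaluate_biased(ds, spec, panel, protocol)
    res[[spec$family]] <<- list(unbiased = unb, biased = bia)
    d <- bia$per_fold$auc - unb$per_fold$auc
    set.seed(protocol$seed)
    perm <- replicate(n_perm,
                      mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    data.frame(model = spec$family,
               auc_unbiased = mean(unb$per_fold$auc),
               auc_biased = mean(bia$per_fold$auc),
               gap = mean(d),
               p_gap = (1 + sum(abs(perm) >= abs(mean(d)))) / (1 + n_perm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}

#' Write evaluation results as tidy TSV
#'
#' One row per fold with model/selection/preparation provenance columns.
#'
#' @param result an `eval_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_result <- function(result, path) {
  df <- result$per_fold
  df$model <- result$provenance$model$family
  df$selection <- result$provenance$selection %||% "panel"
  df$biased <- isTRUE(result$provenance$biased)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
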
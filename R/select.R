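#' @title Feature-selection strategies
#' @description Seven selection strategies with a uniform result contract.
#'   Every selector records the exact sample ids it was fitted on
#'   (`fitted_on`), which the evaluation layer audits against validation
#'   samples to rule out leakage. Ties in any ranking are broken by probe
#'   universe order (deterministic).
#' @name feature_selection
NULL

selection_result <- function(strategy, probe_ids, scores, fitted_on) {
  structure(list(strategy = strategy,
                 probe_ids = as.character(probe_ids),
                 scores = as.numeric(scores),
                 fitted_on = as.character(fitted_on)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$strategy, "]: ", length(x$probe_ids),
      " probes, fitted on ", length(x$fitted_on), " samples\n", sep = "")
  invisible(x)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
}

as01 <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "case")
  else as.integer(labels != 0)
}

#' Top-k differentially methylated probes from training data
#'
#' Runs the per-cohort-style EWAS (covariates age + sex, no study factor) on
#' the training samples only and takes the k probes with the smallest
#' moderated p-values. This is the unbiased, within-fold counterpart of
#' [select_biased_panel()].
#'
#' @param train a [methyl_dataset] containing both classes.
#' @param k number of probes (default 200).
#' @return A `selection_result` whose `fitted_on` is exactly the training
#'   sample ids.
#' @export
select_dm_top <- function(train, k = 200) {
  stopifnot(inherits(train, "methyl_dataset"))
  check_two_classes(train$samples$status)
  if (k > ncol(train$values))
    stop("k exceeds the number of probes")
  tab <- run_ewas(train, include_study_factor = FALSE)
  ord <- order(tab$P.Value, seq_len(nrow(tab)))[seq_len(k)]
  selection_result("dm_top", tab$probe_id[ord], tab$P.Value[ord],
                   train$samples$sample_id)
}

#' Pre-selected panel from a pooled DM analysis (biased)
#'
#' Filters the pooled table to probes whose directional agreement reaches the
#' threshold (by default 1: consistent sign in every cohort), ranks by
#' p-value, and takes the top k. Because the pooled analysis saw every
#' sample, panels built this way carry feature-selection bias by
#' construction; `fitted_on` records all pooled samples so the evaluation
#' layer can tag results as biased.
#'
#' @param pooled_dm a pooled `dm_table` with agreement values (see
#'   [run_ewas()]).
#' @param agreement_threshold minimum agreement (default 1.0).
#' @param k panel size (default 200); if fewer consistent probes exist, all
#'   are returned with a warning.
#' @return A `selection_result` with strategy `"biased_panel"`.
#' @export
select_biased_panel <- function(pooled_dm, agreement_threshold = 1.0,
                                k = 200) {
  if (all(is.na(pooled_dm$agreement)))
    stop("pooled_dm has no agreement values; run a pooled analysis first")
  keep <- which(!is.na(pooled_dm$agreement) &
                  pooled_dm$agreement >= agreement_threshold)
  if (length(keep) == 0) {
    warning("no probes reach agreement ", agreement_threshold,
            "; returning an empty panel")
    return(selection_result("biased_panel", character(), numeric(),
                            attr(pooled_dm, "sample_ids")))
  }
  if (length(keep) < k)
    warning("only ", length(keep), " consistent probes available; ",
            "returning all of them")
  ord <- keep[order(pooled_dm$P.Value[keep], keep)]
  ord <- ord[seq_len(min(k, length(ord)))]
  selection_result("biased_panel", pooled_dm$probe_id[ord],
                   pooled_dm$P.Value[ord], attr(pooled_dm, "sample_ids"))
}

#' Top variance fraction of probes
#'
#' Ranks probes by cross-sample variance (descending) and retains
#' `ceiling(fraction * n_probes)` of them; the ceiling rule reproduces the
#' 15239 / 3048 / 305 feature counts of the 5% / 1% / 0.1% selectors on a
#' 304,765-probe universe.
#'
#' @param x samples-by-probes matrix (or [methyl_dataset]).
#' @param fraction fraction in (0, 1).
#' @param fitted_on sample ids for provenance; defaults to the matrix row
#'   names.
#' @return A `selection_result` with strategy `"variance_top"`.
#' @export
select_variance_top <- function(x, fraction, fitted_on = NULL) {
  if (inherits(x, "methyl_dataset")) {
    if (is.null(fitted_on)) fitted_on <- x$samples$sample_id
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 samples to compute variances")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  if (is.null(fitted_on)) fitted_on <- rownames(x)
  n_keep <- ceiling(fraction * ncol(x))
  v <- apply(x, 2, stats::var)
  ord <- order(-v, seq_along(v))[seq_len(n_keep)]
  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(x)))
  selection_result("variance_top", ids[ord], v[ord], fitted_on)
}

#' Top-k probes by one-way ANOVA F
#'
#' Between-class F statistic per probe; for two classes `F = t^2` of the
#' pooled-variance two-sample t-test.
#'
#' @param x samples-by-probes matrix.
#' @param labels per-sample class labels.
#' @param k number of probes (default 200).
#' @param fitted_on provenance sample ids (defaults to row names).
#' @return A `selection_result` with strategy `"anova_f"`.
#' @export
select_anova_f <- function(x, labels, k = 200, fitted_on = NULL) {
  x <- as.matrix(x)
  check_two_classes(labels)
  if (k > ncol(x)) stop("k exceeds the number of probes")
  if (is.null(fitted_on)) fitted_on <- rownames(x)
  f <- factor(labels)
  n <- nrow(x)
  g <- nlevels(f)
  grand <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (lev in levels(f)) {
    idx <- f == lev
    m <- colMeans(x[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - grand)^2
    ssw <- ssw + colSums(sweep(x[idx, , drop = FALSE], 2, m)^2)
  }
  F <- (ssb / (g - 1)) / (ssw / (n - g))
  ord <- order(-F, seq_along(F))[seq_len(k)]
  selection_result("anova_f", colnames(x)[ord], F[ord], fitted_on)
}

# Proximal-gradient (ISTA) solver for the L1-penalized squared-hinge linear
# SVM: min_w ||w||_1 + C * sum_i max(0, 1 - y_i (x_i'w + b))^2. Features are
# standardized internally; the intercept is unpenalized.
l1_svc_fit <- function(x, y01, C = 1, max_iter = 5000, tol = 1e-7) {
  y <- ifelse(y01 == 1, 1, -1)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  n <- nrow(Xs)
  p <- ncol(Xs)
  # Lipschitz constant of the smooth part: 2C * lambda_max(X'X) (power iter.)
  vpi <- stats::rnorm(p)
  for (i in 1:30) {
    vpi <- crossprod(Xs, Xs %*% vpi)
    vpi <- vpi / sqrt(sum(vpi^2))
  }
  L <- 2 * C * as.numeric(crossprod(Xs %*% vpi)) + 1e-8
  step <- 1 / L
  w <- numeric(p)
  b <- 0
  obj_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- 1 - y * (Xs %*% w + b)
    act <- marg > 0
    gw <- -2 * C * crossprod(Xs, as.numeric(act) * y * pmax(marg, 0))
    gb <- -2 * C * sum(y[act] * marg[act])
    w_new <- w - step * as.numeric(gw)
    w_new <- sign(w_new) * pmax(abs(w_new) - step, 0)   # soft threshold, lam=1
    b <- b - step * gb
    obj <- sum(abs(w_new)) + C * sum(pmax(1 - y * (Xs %*% w_new + b), 0)^2)
    if (is.finite(obj_old) && abs(obj_old - obj) < tol * max(1, obj)) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
    obj_old <- obj
  }
  if (!converged)
    warning("L1-SVC did not converge within ", max_iter, " iterations")
  list(coef = w / sdv, iterations = it, converged = converged)
}

#' Top-k probes by L1-penalized linear model coefficients
#'
#' Fits an L1-regularized linear classifier and ranks probes by absolute
#' coefficient. `"logistic"` uses the lasso logistic path (glmnet), picking
#' the least-penalized path point with at least k nonzero coefficients where
#' one exists; `"linear_svc"` uses the in-package proximal-gradient
#' squared-hinge SVM. When sparsity yields fewer than k nonzero
#' coefficients, the panel is padded with the next-largest magnitudes (ties
#' by probe order).
#'
#' @param x samples-by-probes matrix.
#' @param labels class labels.
#' @param model `"logistic"` or `"linear_svc"`.
#' @param k panel size (default 200).
#' @param max_iter iteration cap (default 5000).
#' @param fitted_on provenance sample ids (defaults to row names).
#' @return A `selection_result`.
#' @export
select_l1_model <- function(x, labels, model = c("logistic", "linear_svc"),
                            k = 200, max_iter = 5000, fitted_on = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  check_two_classes(labels)
  if (k > ncol(x)) stop("k exceeds the number of probes")
  if (is.null(fitted_on)) fitted_on <- rownames(x)
  y <- as01(labels)
  if (model == "logistic") {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          nlambda = 50, maxit = max_iter)
    nz <- fit$df
    j <- if (any(nz >= k)) which(nz >= k)[1] else length(nz)
    coefs <- as.numeric(fit$beta[, j])
  } else {
    coefs <- l1_svc_fit(x, y, C = 1, max_iter = max_iter)$coef
  }
  ord <- order(-abs(coefs), seq_along(coefs))[seq_len(k)]
  selection_result(paste0("l1_", model), colnames(x)[ord], abs(coefs)[ord],
                   fitted_on)
}

#' Top-k probes by extremely-randomized-trees importance
#'
#' Fits an extra-trees ensemble (ranger with the extratrees split rule) and
#' ranks probes by impurity importance, normalized to sum to 1.
#'
#' @param x samples-by-probes matrix.
#' @param labels class labels.
#' @param k panel size (default 200).
#' @param seed mandatory seed for the ensemble.
#' @param num_trees number of trees (default 100).
#' @param fitted_on provenance sample ids (defaults to row names).
#' @return A `selection_result` with strategy `"extratrees"`.
#' @export
select_tree_importance <- function(x, labels, k = 200, seed = 1L,
                                   num_trees = 100, fitted_on = NULL) {
  x <- as.matrix(x)
  check_two_classes(labels)
  if (k > ncol(x)) stop("k exceeds the number of probes")
  if (is.null(fitted_on)) fitted_on <- rownames(x)
  fit <- ranger::ranger(x = x, y = factor(as01(labels)),
                        num.trees = num_trees, splitrule = "extratrees",
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, seq_along(imp))[seq_len(k)]
  selection_result("extratrees", names(imp)[ord], imp[ord], fitted_on)
}

#' Run a selector specification on a training dataset
#'
#' Uniform dispatcher used by the evaluation layer: builds the feature matrix
#' on the dataset's scale and calls the requested strategy with the training
#' sample ids as provenance.
#'
#' @param train a [methyl_dataset].
#' @param selector list with `strategy` in `dm_top`, `variance`, `anova_f`,
#'   `l1_logistic`, `l1_svc`, `extratrees` and strategy parameters (`k`,
#'   `fraction`, `seed`, ...).
#' @return A `selection_result`.
#' @export
run_selector <- function(train, selector) {
  stopifnot(inherits(train, "methyl_dataset"), is.list(selector))
  k <- selector$k %||% 200
  labels <- train$samples$status
  ids <- train$samples$sample_id
  switch(selector$strategy,
    dm_top = select_dm_top(train, k = k),
    variance = select_variance_top(train$values,
                                   fraction = selector$fraction %||% 0.05,
                                   fitted_on = ids),
    anova_f = select_anova_f(train$values, labels, k = k, fitted_on = ids),
    l1_logistic = select_l1_model(train$values, labels, "logistic", k = k,
                                  max_iter = selector$max_iter %||% 5000,
                                  fitted_on = ids),
    l1_svc = select_l1_model(train$values, labels, "linear_svc", k = k,
                             max_iter = selector$max_iter %||% 5000,
                             fitted_on = ids),
    extratrees = select_tree_importance(train$values, labels, k = k,
                                        seed = selector$seed %||% 1L,
                                        num_trees = selector$num_trees %||% 100,
                                        fitted_on = ids),
    stop("unknown selector strategy: ", selector$strategy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a selection result as TSV with a JSON provenance sidecar
#'
#' @param sel a `selection_result`.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  utils::write.table(
    data.frame(probe_id = sel$probe_ids, score = sel$scores,
               rank = seq_along(sel$probe_ids)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(strategy = sel$strategy,
                            fitted_on = sel$fitted_on),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}
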